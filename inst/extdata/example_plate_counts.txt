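# HO cleavage assay plate counts (example)
galr_colonies: 100
cells_plated_gal: 10000
galr_assayed: 250
foar_colonies: 50
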