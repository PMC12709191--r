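Package: sirtaseq
Title: Split-Read Mapping and Classification of Chromosome Rearrangements at
    Interstitial Telomere-Like Sites
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing pooled-clone short-read sequencing of an
    inducible double-strand-break assay in budding yeast. Detects gross
    chromosomal rearrangement (GCR) split reads within a defined repair
    region, calls breakpoint coordinates at nucleotide resolution, realigns
    the clipped portion of each read, classifies events as de novo telomere
    additions, deletions or translocations (with subtelomeric translocation
    classes A, B and C), quantifies event frequencies per feature, bin and
    nucleotide, and scans sequences for telomere-likeness (T+G content and
    G/T ratio). A seeded simulator builds a toy genome with subtelomeric
    X and Y-prime repeat architecture and emits pooled-clone reads with a
    ground-truth table, so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
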