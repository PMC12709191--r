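---
title: "Mapping chromosome rearrangements at telomere-like sites: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping chromosome rearrangements at telomere-like sites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirtaseq)
```

## The assay and the quantity being measured

A single double-strand break is induced by the HO endonuclease at a
recognition site integrated distal to the last essential gene on a yeast
chromosome arm. Survivors that also lose a `URA3` marker placed distal to
the cut site (selected on 5-FOA) must have undergone a gross chromosomal
rearrangement (GCR) — a de novo telomere addition (dnTA), a large deletion,
or a non-reciprocal translocation — with a breakpoint somewhere between the
cut site and the most distal essential gene. That interval is the **repair
region**: `sirtaseq` derives it from the annotations as
`[HO_cut_site start, essential-gene end)` on a left arm, and every
downstream coordinate comes from that one object.

Thirty surviving clones are pooled and sequenced with short (150 nt) reads.
A **GCR split read** anchors in the repair region while its soft-clipped
tail derives from the rearrangement partner. Because every clone in the
pool lost the distal arm, the fraction of split reads with a given property
is a proxy for the fraction of GCR events with that property; `sirtaseq`
reports this read-weighted quantity (and an event-weighted count next to
it). Following the assay's published rule, frequencies are divided by the
total number of split reads mapping to the repair region after the
singleton adjustment described below.

Interstitial telomere-like sequences called SiRTAs (sites of
repair-associated telomere addition) are hotspots for these events. A SiRTA
is bipartite: a distal **Stim** (Cdc13-binding, Tel11-like) and a **Core**
where the new telomere is actually added. A site is called a *functional*
SiRTA when its dnTA share of total split reads reaches 6.6% (inclusive).

## Breakpoint definition and its intrinsic ambiguity

The location of a split read is *the coordinate at which the read first
diverges from the reference*. Internally all coordinates are 0-based
half-open; every table reports 1-based positions. When the acquired
sequence happens to match the reference for a few bases past the biological
junction, the divergence point shifts by that terminal homology — an
ambiguity intrinsic to the definition, not an implementation artifact. The
simulator therefore reports the *observable* divergence coordinate
(`breakpoint_div`) alongside the drawn junction, and the pipeline is
compared against the former. For Class A junctions, which sit inside an
interrupted microhomology block, the divergence point is only defined up to
that block; this is why nucleotide-exact recovery is asserted on the
truth-alignment path, while the raw-read path tolerates a few bases of
slack.

## Classification rules

For each split read the clip is re-oriented to read 5'→3' away from the
junction and the decision proceeds:

1. **Telomeric clip.** The TG1-3 / C1-3A recognizer accepts a clip whose
   longest pattern-consistent run covers at least 90% of a 30 nt comparison
   window and is at least 8 nt. The pattern family (runs of G at most 3,
   runs of T exactly 1, or the A/C complement) is closed under reversal and
   complementation, so the recognizer is exactly strand-symmetric. A
   run-based rather than prefix-based rule is used precisely to keep that
   symmetry; the telomeric *prefix* length is computed separately where
   order matters.
2. **Tract-then-target.** If a telomeric prefix (>= 8 nt) is followed by at
   least 12 nt of sequence that places on the genome in subtelomeric
   context (X, Y', ITS or telomere annotation), the read is routed to
   translocation as a Class C candidate and flagged `tg_then_target`. A
   purely telomeric clip is a dnTA; a flag (`tg_places_at_its`) records
   TG clips that also align to interstitial telomeric tracts, the
   recombination caveat that applies at strongly telomere-like SiRTAs.
3. **Deletion.** A clip with exactly one best placement, on the broken
   chromosome, entirely telomere-proximal to the URA3 marker, and outside
   repeat annotations. "Unambiguous unique sequence" is operationalised as
   `n_equivalent == 1` plus the repeat exclusion; no numeric uniqueness
   score exists in the source assay, which worked by eye.
4. **Translocation.** Any other placeable clip — including every
   multi-mapping case, since repeat-identical targets cannot be resolved at
   this read length (a *cis* large deletion and a *trans* translocation
   into an identical Y' copy are indistinguishable by construction).
5. **Unclassified** otherwise; these reads stay in the denominator.

Translocation classes are assigned with precedence **C → B → A** (a clip
with tract + ATATATAT + Y' sequence is a Class C candidate, and the
precedence mirrors that):

* **C** — telomeric tract at the junction followed by Y'/ITS context.
* **B** — the exact `ATATATAT` motif at the junction with the continuation
  placing at a Y'-element start (tolerance 2 nt). Zero mismatches are
  allowed within the motif match, but because divergence-point calling can
  absorb up to a few leading motif bases into the anchor (the motif is an
  AT repeat), a front-trimmed motif of >= 5 bases also qualifies.
* **A** — best placement strictly internal to an X or Y' element *and*
  junction microhomology between the two flanks. Flanks are taken
  two-sided (40 nt each way) around both junction partners from the
  *genome*, oriented as they sit in the fused product, so the test is
  insensitive to where inside the homology block the divergence point
  landed and to read errors.

**Microhomology scoring** is the best ungapped local alignment
(match +1 / mismatch −1) over all offset pairs, reporting the
maximal-score window's span and identity. The presence call requires
span >= 14 at identity >= 0.8: with an 8 nt span the call fires on ~19% of
unrelated 40-mer pairs under maximal-score-window semantics, while 14 nt
keeps that below 1% and sits comfortably under the 19–33 bp interrupted
homologies the assay actually observes at Class A junctions.

## Filtering and read-support model

Events are collapsed by (type, class, target chromosome) with breakpoints
clustered within ±2 nt. Within a cluster, coordinates carrying at least
15% of the cluster's reads (minimum 2) stand as independent events —
distinct hotspot nucleotides a few bases apart are real and frequent at
SiRTA Cores — while low-support satellites (alignment jitter from
substitution errors adjacent to the junction) merge into the nearest peak.
Setting `merge_window = 0` disables coordinate merging entirely.

With `N` total split reads over `n = 30` clones, the expected support per
event is `lambda = N / n`, and a Poisson model predicts
`n * lambda * exp(-lambda)` true singletons. Following the assay's rule,
events supported by one read are removed only when the experiment yielded
**more than 200** split reads (strict `>`); below that, singletons are kept
to avoid discarding true events. The filter log records the decision and
the removed support, and removed plus retained support always reconciles
with the total.

The overall GCR frequency from plate counts is
`(GalR colonies / cells plated) x (FOA-resistant / GalR assayed)`,
dilution-invariant by construction.

## Clip placement

`realign_clip()` is a seed-and-extend Hamming search over both strands
using a 12-mer index, returning every placement within
`max_mismatch = floor(len / 25)` substitutions and the multiplicity of the
best score (`n_equivalent`). Disjoint seeds guarantee, by pigeonhole, that
the hit set equals a brute-force sliding-window scan — property-tested
against an independent `Biostrings` oracle. There is no indel-aware
realignment; external aligners produce the SAM for real data, and
`align_reads()` is only a toy-genome anchorer for the simulated FASTQ path
(it prefers in-region anchors, mirroring the assay's repair-region-first
alignment pass).

## What the simulator emulates — and what it does not

`build_toy_genome()` constructs, deterministically per seed, a ~9 kb repair
chromosome (unique distal sequence, URA3, HO cut site, SiRTA with Tel11
Stim and an imperfect TG-rich Core, last essential gene) and donor
chromosomes whose subtelomeres carry an X element and Y' elements separated
by 80–150 nt interstitial TG1-3 tracts, with `ATATATAT` immediately
preceding 75% of Y' starts by default. Y' copies are mutated from one
master at 95% identity so multi-mapping ambiguity exists in miniature. A
25 bp segment flanking the designated Class A breakpoint is planted
(reverse-complemented, ~90% identity) inside one X and one Y' interior to
provide the interrupted junction microhomology Class A events require.

Pools default to 30 clones, one event each, with breakpoints drawn 55% at
the SiRTA Core, 25% adjacent to the cut site and 20% uniform — the hotspot
structure the assay maps. The default event mixture (60% dnTA, 10%
deletion, 8/12/10% translocation classes A/B/C) spans all classifier paths
at plausible proportions. Reads are single-end 150 nt at 30x per clone with
substitution errors only (0.001/base): pairing adds no information to the
implemented per-read rules, and indel realism is irrelevant to junction
classification. Telomere-addition tracts default to 200–300 nt — a mature,
telomerase-elongated telomere, as in pools grown for many generations —
because a short nascent tract would truncate the junction-spanning read
window and systematically under-weight dnTA in the read-level mixture,
violating the clone-uniform-coverage premise of the split-read proxy.

Not modelled: PCR duplicates, GC bias, quality profiles, diploid genomes,
unequal clone growth (available via the `weights` argument but off by
default, since pools are made from equal culture volumes). A green
simulation test therefore establishes rule fidelity and internal
consistency, not robustness to library-preparation artifacts.

## Telomere-likeness scan

`tg_windows()` slides a 50 nt window in 10 nt steps along the caller's
3'→5' (TG-rich) strand — the reverse complement of the reference top
strand on a left arm — reporting exact T+G percentage and G/T ratio (an
`Inf` sentinel when a window has no T, ranked as maximal). The source
assay states neither window nor step; 50/10 resolves SiRTA-scale features
(~100–300 nt) while smoothing base-level noise, and both are exposed as
options. `rank_tg_peaks()` merges super-threshold windows and ranks by
peak G/T ratio, then T+G percentage, with a deterministic leftmost
tie-break.

## Numerical and degenerate-input choices

* `min_clip` defaults to 10 nt: shorter tails place and classify
  unreliably (no threshold exists in the source, which inspected 150 nt
  reads manually). Clips shorter than the 12 nt seed are `unclassified`
  with a `clip_too_short` flag.
* When a read is clipped on both sides the longer clip is analysed.
* Reads are never dropped for low mapping quality (the assay deliberately
  mined low-MAPQ reads); wrong-side clips are excluded from the split-read
  set with an audited reason, and boundary breakpoints are flagged rather
  than dropped.
* An empty pool yields zero-count tables with zero denominators reported
  as 0% rather than NaN.
* The repair-region boundary convention follows the binned-map coordinates
  (cut-site proximal edge to essential-gene far edge); the source's prose
  "~19.9 kb" for one arm disagrees with its own bin span (20.1 kb), and
  the bin convention wins. The exact cut-site boundary remains
  configuration, not a guess.

## Known limitations

* *cis* deletions into repeat-identical subtelomeric targets are counted
  as translocations, exactly as the assay's rule dictates; no attempt is
  made to resolve them.
* Divergence-point breakpoints shift by junction terminal homology (see
  above); consumers needing biological junctions should use the
  simulator's drawn coordinates.
* `align_reads()` is not a general aligner: no indels, no quality use, and
  designed for simulator-scale genomes only.
* Cross-pool inferential statistics (ANOVA across biological replicates)
  are out of scope; the package stops at per-pool tables.
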