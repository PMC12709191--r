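# Seeded pooled-clone simulator. Builds a miniature genome with the repeat
# architecture the analysis assumes (a repair chromosome carrying URA3, the
# HO cut site, a bipartite SiRTA and the last essential gene; donor
# chromosomes with subtelomeric X and Y' elements separated by interstitial
# telomeric tracts), samples a pool of clones each carrying one known GCR
# event, and emits reads plus a truth table so every pipeline stage is
# testable without external data.

EVENT_TYPES <- c("telomere_addition", "deletion", "translocation_A",
                 "translocation_B", "translocation_C", "hocs_indel")

#' Configuration of the toy genome
#'
#' Defaults encode the assayed architecture at reduced scale: one repair
#' chromosome (left arm: telomere at coordinate 0) and `n_chromosomes - 1`
#' donor chromosomes whose subtelomeres (built as right arms so acquired
#' segments run through to the donor terminus) carry an X element and Y'
#' elements separated by ~80-150 bp interstitial TG1-3 tracts, with the
#' 5'-ATATATAT-3' motif immediately preceding a configurable fraction of Y'
#' starts.
#'
#' @param n_chromosomes Total chromosomes (1 repair + donors). Default 3.
#' @param chrom_length Length of every chromosome in nt. Default 9000.
#' @param repair_chrom Name of the repair chromosome. Default `"chrR"`.
#' @param sirta_spec List with `start`, `stim_len`, `core_offset`,
#'   `core_len`, `sirta_len` (offsets in nt; see defaults).
#' @param n_yprime Total number of Y' elements across donors. Default 4.
#' @param yprime_identity Pairwise identity of Y' copies to their master
#'   sequence, in \[0.9, 1\]. Default 0.95.
#' @param its_lengths Length range (nt) for interstitial telomeric tracts.
#'   Default `c(80, 150)`.
#' @param atat_motif_fraction Fraction of Y' starts immediately preceded by
#'   ATATATAT. Default 0.75.
#' @param seed Integer seed; the whole construction is deterministic in it.
#' @return A `ToyGenomeConfig` list.
#' @export
toy_genome_config <- function(n_chromosomes = 3L, chrom_length = 9000L,
                              repair_chrom = "chrR",
                              sirta_spec = list(start = 4100L, stim_len = 52L,
                                                core_offset = 60L,
                                                core_len = 160L,
                                                sirta_len = 300L),
                              n_yprime = 4L, yprime_identity = 0.95,
                              its_lengths = c(80L, 150L),
                              atat_motif_fraction = 0.75, seed = 1L) {
  stopifnot(n_chromosomes >= 2L, chrom_length >= 6000L,
            yprime_identity >= 0.9, yprime_identity <= 1,
            atat_motif_fraction >= 0, atat_motif_fraction <= 1,
            length(its_lengths) == 2L, its_lengths[1] <= its_lengths[2])
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chrom_length = as.integer(chrom_length),
                 repair_chrom = repair_chrom, sirta_spec = sirta_spec,
                 n_yprime = as.integer(n_yprime),
                 yprime_identity = yprime_identity,
                 its_lengths = as.integer(its_lengths),
                 atat_motif_fraction = atat_motif_fraction,
                 seed = as.integer(seed)),
            class = "ToyGenomeConfig")
}

# substitute `n` random positions of `seq` with a different base
.mutate_seq <- function(seq, n) {
  if (n <= 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample.int(length(chars), n)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

# SiRTA G-rich strand: two Tel11 Cdc13 binding sites in the Stim, an
# imperfect telomere-like Core (TG1-3 with periodic interruptions)
.sirta_gstrand <- function(stim_len, core_len) {
  tel11 <- "GTGTGGGTGTG"
  spacer <- rand_dna(stim_len - 2L * nchar(tel11) - 5L)
  stim <- paste0(rand_dna(5L), tel11, spacer, tel11)
  stim <- substr(stim, 1L, stim_len)
  core <- make_tg_tract(core_len)
  chars <- strsplit(core, "", fixed = TRUE)[[1]]
  brk <- seq(9L, core_len, by = 11L)
  chars[brk] <- sample(c("A", "C"), length(brk), replace = TRUE)
  list(stim = stim, core = paste(chars, collapse = ""))
}

#' Build the toy genome and its annotations
#'
#' Deterministic given `config$seed`. The repair chromosome layout (left
#' arm, telomere-proximal = low coordinates) is: unique distal sequence,
#' URA3 marker, HO cut site, unique spacer, SiRTA (Stim + Core, TG-rich on
#' the bottom strand as on a left arm), unique sequence, last essential
#' gene. Donors carry X / ITS / (ATATATAT) / Y' architecture ending in a
#' terminal telomeric tract. A ~25 bp segment of the repair region adjacent
#' to the Class A breakpoint is planted (at ~90% identity, reverse
#' complemented) inside one X and one Y' element to provide the interrupted
#' junction microhomology that Class A translocations use.
#'
#' @param config A [toy_genome_config()].
#' @return A `ToyGenome` list: `genome`, `annotations`, and `info` (repair
#'   geometry, Y' starts with motif status, planted Class A sites).
#' @export
build_toy_genome <- function(config = toy_genome_config()) {
  stopifnot(inherits(config, "ToyGenomeConfig"))
  with_seed(config$seed, .build_toy_genome(config))
}

.build_toy_genome <- function(config) {
  L <- config$chrom_length
  rc <- config$repair_chrom
  ss <- config$sirta_spec

  # ---- repair chromosome ----
  ura3_start <- 1500L; ura3_end <- 2300L
  hocs_start <- 2600L; hocs_end <- 2630L
  sirta_start <- ss$start
  sirta_end <- sirta_start + ss$sirta_len
  gene_start <- L - 1000L; gene_end <- L - 200L
  if (sirta_end + 400L > gene_start || hocs_end > sirta_start) {
    stop2("toy genome config cannot fit features within chrom_length")
  }
  base <- rand_dna(L)
  sg <- .sirta_gstrand(ss$stim_len, ss$core_len)
  stim_start <- sirta_start
  core_start <- sirta_start + ss$core_offset
  core_end <- core_start + ss$core_len
  # left arm: TG-rich strand is the bottom strand, so insert revcomp
  substr(base, stim_start + 1L, stim_start + ss$stim_len) <- revcomp(sg$stim)
  substr(base, core_start + 1L, core_end) <- revcomp(sg$core)
  chrR <- base

  anns <- list(
    data.frame(chrom = rc, start = ura3_start, end = ura3_end,
               kind = "URA3_marker", strand = "+", label = "URA3"),
    data.frame(chrom = rc, start = hocs_start, end = hocs_end,
               kind = "HO_cut_site", strand = "+", label = "HOcs"),
    data.frame(chrom = rc, start = sirta_start, end = sirta_end,
               kind = "SiRTA", strand = "-", label = "SiRTA"),
    data.frame(chrom = rc, start = stim_start,
               end = stim_start + ss$stim_len,
               kind = "SiRTA_stim", strand = "-", label = "Stim"),
    data.frame(chrom = rc, start = core_start, end = core_end,
               kind = "SiRTA_core", strand = "-", label = "Core1"),
    data.frame(chrom = rc, start = gene_start, end = gene_end,
               kind = "essential_gene", strand = "+", label = "ESS1")
  )

  # ---- donors ----
  n_donors <- config$n_chromosomes - 1L
  yp_per_donor <- table(rep(seq_len(n_donors), length.out = config$n_yprime))
  yp_master <- rand_dna(1800L)
  x_master <- rand_dna(500L)
  tel_len <- 250L
  n_motif <- round(config$atat_motif_fraction * config$n_yprime)
  motif_idx <- if (n_motif > 0L) sort(sample.int(config$n_yprime, n_motif)) else integer(0)
  mut_n <- round((1 - config$yprime_identity) * 1800L)

  seqs <- list()
  seqs[[rc]] <- chrR
  yp_info <- list(); k_yp <- 0L
  for (d in seq_len(n_donors)) {
    dn <- paste0("chrD", d)
    n_yp <- as.integer(yp_per_donor[as.character(d)])
    # assemble right-to-left from the terminus
    parts <- list(); feats <- list()
    pos <- L  # current right boundary
    tel <- make_tg_tract(tel_len)
    pos <- pos - tel_len
    parts <- c(list(tel), parts)
    feats[[length(feats) + 1L]] <- data.frame(
      chrom = dn, start = pos, end = pos + tel_len, kind = "telomere",
      strand = "+", label = "TEL")
    for (j in rev(seq_len(n_yp))) {
      k <- k_yp + j
      ycopy <- .mutate_seq(yp_master, mut_n)
      pos <- pos - 1800L
      parts <- c(list(ycopy), parts)
      feats[[length(feats) + 1L]] <- data.frame(
        chrom = dn, start = pos, end = pos + 1800L, kind = "Yprime_element",
        strand = "+", label = paste0("Yp", k))
      has_motif <- k %in% motif_idx
      if (has_motif) {
        pos <- pos - 8L
        parts <- c(list(ATAT_MOTIF), parts)
      }
      its_len <- sample(config$its_lengths[1]:config$its_lengths[2], 1L)
      its <- make_tg_tract(its_len)
      pos <- pos - its_len
      parts <- c(list(its), parts)
      feats[[length(feats) + 1L]] <- data.frame(
        chrom = dn, start = pos, end = pos + its_len, kind = "ITS",
        strand = "+", label = paste0("ITS", k))
      yp_info[[k]] <- data.frame(chrom = dn,
                                 start = pos + its_len + if (has_motif) 8L else 0L,
                                 motif = has_motif, stringsAsFactors = FALSE)
    }
    xcopy <- .mutate_seq(x_master, round((1 - config$yprime_identity) * 500L))
    pos <- pos - 500L
    parts <- c(list(xcopy), parts)
    feats[[length(feats) + 1L]] <- data.frame(
      chrom = dn, start = pos, end = pos + 500L, kind = "X_element",
      strand = "+", label = paste0("X", d))
    if (pos < 500L) stop2("toy genome config cannot fit features within chrom_length")
    parts <- c(list(rand_dna(pos)), parts)
    seqs[[dn]] <- paste(unlist(parts), collapse = "")
    stopifnot(nchar(seqs[[dn]]) == L)
    anns <- c(anns, feats)
    k_yp <- k_yp + n_yp
  }
  yp_info <- do.call(rbind, yp_info)

  # ---- plant Class A microhomology ----
  # breakpoint inside the SiRTA Core; the 25 bp upstream (lost-side) flank
  # is copied (revcomp, ~90% identity) into one X and one Y' interior
  bpA <- core_start + 60L
  plant <- .mutate_seq(revcomp(substr0(chrR, bpA - 25L, bpA)), 3L)
  yp1 <- yp_info[1L, ]
  a_sites <- data.frame(chrom = character(), target = integer(),
                        element = character(), stringsAsFactors = FALSE)
  tgt_y <- yp1$start + 900L
  s <- seqs[[yp1$chrom]]
  substr(s, tgt_y + 1L, tgt_y + 25L) <- plant
  seqs[[yp1$chrom]] <- s
  a_sites <- rbind(a_sites, data.frame(chrom = yp1$chrom, target = tgt_y,
                                       element = "Yprime_element"))
  xf <- do.call(rbind, anns)
  x1 <- xf[xf$kind == "X_element", ][1L, ]
  tgt_x <- x1$start + 250L
  s <- seqs[[x1$chrom]]
  substr(s, tgt_x + 1L, tgt_x + 25L) <- plant
  seqs[[x1$chrom]] <- s
  a_sites <- rbind(a_sites, data.frame(chrom = x1$chrom, target = tgt_x,
                                       element = "X_element"))

  gen <- genome(unlist(seqs))
  ann <- annotation_set(do.call(rbind, anns), gen)
  info <- list(repair_chrom = rc, ura3_start = ura3_start,
               hocs_end = hocs_end, core_start = core_start,
               core_end = core_end, sirta_start = sirta_start,
               sirta_end = sirta_end, yprime = yp_info,
               class_a_sites = a_sites, class_a_breakpoint = bpA,
               gene_end = gene_end)
  structure(list(genome = gen, annotations = ann, info = info,
                 config = unclass(config)),
            class = "ToyGenome")
}

default_mixture <- function() {
  c(telomere_addition = 0.60, deletion = 0.10, translocation_A = 0.08,
    translocation_B = 0.12, translocation_C = 0.10, hocs_indel = 0)
}

#' Sample the GCR events of one pool of clones
#'
#' Assigns each clone one event drawn from `mixture`, with breakpoints from
#' a spatial mixture concentrated at the SiRTA Core and adjacent to the HO
#' cut site over a uniform background (Class A breakpoints sit at the
#' planted microhomology site). Deletion targets are drawn in unique
#' sequence telomere-proximal to URA3; Class B/C targets are Y' starts
#' carrying the ATATATAT motif.
#'
#' @param mixture Named probabilities over
#'   `r paste(EVENT_TYPES, collapse = ", ")`; must sum to 1.
#' @param n_clones Pool size (default 30, the assay's pool of selected
#'   survivors).
#' @param genome,annotations From [build_toy_genome()].
#' @param seed Integer seed.
#' @param info The `info` element of a `ToyGenome` (required for
#'   translocation targets).
#' @param spatial Zone weights for breakpoints:
#'   `c(sirta_core, hocs, uniform)`.
#' @return A `PoolTruth`: `events` data frame (one row per clone; the
#'   `breakpoint` column is the 1-based reported coordinate of the first
#'   divergent base, i.e. the 0-based coordinate of the first retained
#'   base), plus the configuration echo and seed.
#' @export
sample_pool_events <- function(mixture = default_mixture(), n_clones = 30L,
                               genome, annotations, seed = 1L, info = NULL,
                               spatial = c(sirta_core = 0.55, hocs = 0.25,
                                           uniform = 0.20)) {
  stopifnot(n_clones >= 1L)
  if (!all(names(mixture) %in% EVENT_TYPES)) {
    stop2("unknown event type(s): ",
          paste(setdiff(names(mixture), EVENT_TYPES), collapse = ", "))
  }
  if (abs(sum(mixture) - 1) > 1e-9) stop2("mixture must sum to 1")
  if (is.null(info)) stop2("`info` (from build_toy_genome) is required")
  region <- repair_region_span(annotations, info$repair_chrom)
  with_seed(seed, {
    types <- sample(names(mixture), n_clones, replace = TRUE, prob = mixture)
    margin <- 200L
    draw_bp <- function() {
      zone <- sample(names(spatial), 1L, prob = spatial)
      switch(zone,
        sirta_core = sample(info$core_start:(info$core_end - 1L), 1L),
        hocs = info$hocs_end + sample(0:99, 1L),
        uniform = sample(info$hocs_end:(region$end - margin), 1L))
    }
    yp_m <- info$yprime[info$yprime$motif, , drop = FALSE]
    rows <- lapply(seq_len(n_clones), function(i) {
      ty <- types[i]
      bp <- NA_integer_; tchrom <- NA_character_; tpos <- NA_integer_
      tstrand <- NA_character_; tract <- ""
      if (ty == "telomere_addition") {
        bp <- draw_bp()
        # mature healed telomere: tracts are elongated to wild-type length
        # before the pool is grown, so junction-spanning coverage stays
        # clone-uniform (the premise of the split-read proxy)
        tract <- make_tg_tract(sample(200:300, 1L))
      } else if (ty == "deletion") {
        bp <- draw_bp()
        tchrom <- info$repair_chrom
        tpos <- sample(100:(info$ura3_start - 300L), 1L)
        tstrand <- "+"
      } else if (ty == "translocation_A") {
        site <- info$class_a_sites[sample.int(nrow(info$class_a_sites), 1L), ]
        bp <- info$class_a_breakpoint
        tchrom <- site$chrom; tpos <- site$target; tstrand <- "-"
      } else if (ty == "translocation_B") {
        if (!nrow(yp_m)) stop2("no motif-bearing Y' start for translocation_B")
        j <- sample.int(nrow(yp_m), 1L)
        bp <- draw_bp()
        tchrom <- yp_m$chrom[j]; tpos <- yp_m$start[j]; tstrand <- "-"
      } else if (ty == "translocation_C") {
        if (!nrow(yp_m)) stop2("no motif-bearing Y' start for translocation_C")
        j <- sample.int(nrow(yp_m), 1L)
        bp <- draw_bp()
        tchrom <- yp_m$chrom[j]; tpos <- yp_m$start[j]; tstrand <- "-"
        tract <- make_tg_tract(sample(25:45, 1L))
      }
      data.frame(clone_id = sprintf("clone%02d", i), event_type = ty,
                 breakpoint = bp, target_chrom = tchrom, target_pos = tpos,
                 target_strand = tstrand, tract = tract,
                 stringsAsFactors = FALSE)
    })
    events <- do.call(rbind, rows)
    structure(list(events = events, mixture = mixture,
                   n_clones = as.integer(n_clones), seed = as.integer(seed)),
              class = "PoolTruth")
  })
}

#' Rearranged chromosome sequence of one clone
#'
#' Builds the product chromosome of a GCR event: a telomere addition
#' truncates the chromosome at the breakpoint and caps it with the TG1-3
#' tract; a deletion joins the breakpoint to unique sequence
#' telomere-proximal to URA3 in cis; translocations (non-reciprocal) join
#' the breakpoint to donor subtelomeric sequence through to the donor
#' terminus (Class B via the ATATATAT motif at a Y' start; Class C through
#' a telomeric tract into the Y'). Every GCR product lacks both the URA3
#' marker and the HO cut-site sequence.
#'
#' @param genome A `Genome`.
#' @param event One-row events data frame from [sample_pool_events()].
#' @param annotations The toy `AnnotationSet` (for URA3 validation).
#' @return Product DNA string with attributes `prefix_len` (nt preceding
#'   the retained reference segment), `retained_chrom`, `retained_start`.
#' @export
synthesize_clone_sequence <- function(genome, event, annotations) {
  if (is.data.frame(event)) { stopifnot(nrow(event) == 1L); event <- as.list(event) }
  rc_ann <- features_of_kind(annotations, "URA3_marker")
  ho_ann <- features_of_kind(annotations, "HO_cut_site")
  chrom <- if (event$event_type == "hocs_indel") ho_ann$chrom[1L] else {
    if (is.na(event$breakpoint)) stop2("event has no breakpoint")
    rc_ann$chrom[1L]
  }
  chr <- genome_seq(genome, chrom)
  len <- nchar(chr)
  if (event$event_type == "hocs_indel") {
    ho <- ho_ann[1L, ]
    mid <- (ho$start + ho$end) %/% 2L
    return(structure(paste0(substr0(chr, 0L, mid), substr0(chr, mid + 2L, len)),
                     prefix_len = 0L, retained_chrom = chrom,
                     retained_start = 0L))
  }
  bp <- event$breakpoint
  retained <- substr0(chr, bp, len)
  tail_seq <- switch(event$event_type,
    telomere_addition = revcomp(event$tract),
    deletion = {
      ura3 <- rc_ann[1L, ]
      if (event$target_pos >= ura3$start) {
        stop2("deletion target inside the retained segment would retain URA3")
      }
      substr0(chr, 0L, event$target_pos)
    },
    translocation_A = {
      d <- genome_seq(genome, event$target_chrom)
      revcomp(substr0(d, event$target_pos, nchar(d)))
    },
    translocation_B = {
      d <- genome_seq(genome, event$target_chrom)
      revcomp(substr0(d, event$target_pos - 8L, nchar(d)))
    },
    translocation_C = {
      d <- genome_seq(genome, event$target_chrom)
      revcomp(paste0(event$tract, substr0(d, event$target_pos - 8L, nchar(d))))
    },
    stop2("unknown event type: ", event$event_type))
  product <- paste0(tail_seq, retained)
  if (nrow(rc_ann)) {
    ura3_seq <- substr0(chr, rc_ann$start[1L], rc_ann$end[1L])
    if (grepl(ura3_seq, product, fixed = TRUE)) {
      stop2("synthesized product retains the URA3 marker")
    }
  }
  # The observable breakpoint is the divergence coordinate: where a read
  # stops matching the reference. When the acquired tail chances to match
  # the reference bases immediately distal to the junction, the divergence
  # point shifts by that terminal homology; record the shifted coordinates
  # so truth and pipeline share one convention.
  tl <- nchar(tail_seq)
  shift <- 0L
  while (shift < tl && bp - shift - 1L >= 0L &&
         substr(tail_seq, tl - shift, tl - shift) ==
         substr(chr, bp - shift, bp - shift)) {
    shift <- shift + 1L
  }
  structure(product, prefix_len = tl - shift, retained_chrom = chrom,
            retained_start = bp - shift, junction_shift = shift)
}

#' Simulate pooled sequencing reads
#'
#' Uniform single-end read starts per clone at the requested fold-coverage,
#' substitution errors only, constant base quality; deterministic per seed.
#' Clones are weighted equally by default (pools are made from equal culture
#' volumes); an optional weight vector models unequal clone representation.
#' With `genome` supplied, a truth SAM is produced: reads overlapping the
#' retained reference segment of their clone are emitted with the exact
#' soft-clip CIGAR of the junction (reads with fewer than `min_anchor`
#' aligned bases, or lying entirely in acquired sequence, are emitted
#' unmapped).
#'
#' @param clones Named list/vector of clone product sequences, as returned
#'   by [synthesize_clone_sequence()] (attributes are used for the truth
#'   SAM when present).
#' @param depth Fold-coverage per clone.
#' @param read_len Read length in nt (default 150).
#' @param error_rate Per-base substitution probability (default 0.001,
#'   < 0.05).
#' @param seed Integer seed.
#' @param genome Optional `Genome`; required to emit the truth SAM.
#' @param weights Optional per-clone relative weights (default equal).
#' @param paired Emit paired-end reads in the FASTQ (mates flank a ~450 nt
#'   fragment); the truth SAM is single-end only.
#' @param fastq_path,sam_path Optional output paths.
#' @param min_anchor Minimum aligned bases for a mapped truth-SAM record.
#' @param base_qual Constant Phred+33 quality character (default `"I"`).
#' @return List with `reads` (data frame: read_id, clone, start, strand,
#'   seq), `fastq` (character lines), and `sam` (lines, when `genome` is
#'   given). Files are written when paths are supplied.
#' @export
simulate_reads <- function(clones, depth = 30, read_len = 150L,
                           error_rate = 0.001, seed = 1L, genome = NULL,
                           weights = NULL, paired = FALSE,
                           fastq_path = NULL, sam_path = NULL,
                           min_anchor = 20L, base_qual = "I") {
  stopifnot(depth > 0, error_rate >= 0, error_rate < 0.05)
  nm <- names(clones)
  if (is.null(nm)) nm <- paste0("clone", seq_along(clones))
  if (is.null(weights)) weights <- rep(1, length(clones))
  stopifnot(length(weights) == length(clones), all(weights > 0))
  weights <- weights / mean(weights)
  lens <- vapply(clones, nchar, integer(1))
  if (any(read_len > lens)) stop2("read_len exceeds a clone length")
  if (paired && !is.null(sam_path)) stop2("truth SAM is single-end only")

  with_seed(seed, {
    all_rows <- vector("list", length(clones))
    for (ci in seq_along(clones)) {
      cl <- as.character(clones[[ci]])
      L <- lens[ci]
      n <- max(1L, round(depth * L / read_len * weights[ci]))
      starts0 <- sample.int(L - read_len + 1L, n, replace = TRUE) - 1L
      seqs <- substring(cl, starts0 + 1L, starts0 + read_len)
      if (error_rate > 0) {
        err <- which(stats::runif(n * read_len) < error_rate)
        for (e in err) {
          r <- (e - 1L) %/% read_len + 1L
          p <- (e - 1L) %% read_len + 1L
          old <- substr(seqs[r], p, p)
          substr(seqs[r], p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
        }
      }
      strands <- ifelse(stats::runif(n) < 0.5, "+", "-")
      all_rows[[ci]] <- data.frame(
        read_id = sprintf("%s_r%04d", nm[ci], seq_len(n)), clone = nm[ci],
        start = starts0, strand = strands, seq = seqs,
        stringsAsFactors = FALSE)
    }
    reads <- do.call(rbind, all_rows)
    rownames(reads) <- NULL

    # FASTQ (as-sequenced orientation)
    fq_seq <- ifelse(reads$strand == "-", revcomp(reads$seq), reads$seq)
    qual <- strrep(base_qual, read_len)
    if (paired) {
      frag <- 450L
      # mate 1 = the simulated read; mate 2 = revcomp read one fragment away
      fastq <- character(0)  # built below
      mate2_start <- pmin(reads$start + frag - read_len,
                          lens[match(reads$clone, nm)] - read_len)
      m2 <- substring(unlist(clones)[match(reads$clone, nm)],
                      mate2_start + 1L, mate2_start + read_len)
      fastq <- c(rbind(paste0("@", reads$read_id, "/1"), fq_seq, "+", qual),
                 rbind(paste0("@", reads$read_id, "/2"), revcomp(m2), "+", qual))
    } else {
      fastq <- as.vector(rbind(paste0("@", reads$read_id), fq_seq, "+", qual))
    }

    sam <- NULL
    if (!is.null(genome)) {
      hdr <- c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", names(genome$sequences),
                       nchar(genome$sequences)))
      pref <- vapply(clones, function(x) {
        p <- attr(x, "prefix_len"); if (is.null(p)) 0L else as.integer(p)
      }, integer(1))
      rchrom <- vapply(clones, function(x) {
        p <- attr(x, "retained_chrom"); if (is.null(p)) NA_character_ else p
      }, character(1))
      rstart <- vapply(clones, function(x) {
        p <- attr(x, "retained_start"); if (is.null(p)) 0L else as.integer(p)
      }, integer(1))
      ci <- match(reads$clone, nm)
      P <- pref[ci]; s <- reads$start
      anchor <- s + read_len - pmax(s, P)
      unmapped <- is.na(rchrom[ci]) | anchor < min_anchor
      clip <- pmax(0L, P - s)
      cigar <- ifelse(clip > 0L, sprintf("%dS%dM", clip, read_len - clip),
                      sprintf("%dM", read_len))
      pos1 <- rstart[ci] + pmax(0L, s - P) + 1L
      flag <- ifelse(reads$strand == "-", 16L, 0L)
      mapq <- ifelse(clip > 0L, 5L, 60L)
      recs <- ifelse(unmapped,
        paste(reads$read_id, 4L, "*", 0L, 0L, "*", "*", 0L, 0L, fq_seq, qual,
              sep = "\t"),
        paste(reads$read_id, flag, rchrom[ci], pos1, mapq, cigar, "*", 0L,
              0L, reads$seq, qual, sep = "\t"))
      sam <- c(hdr, recs)
    }

    if (!is.null(fastq_path)) writeLines(fastq, fastq_path)
    if (!is.null(sam_path) && !is.null(sam)) writeLines(sam, sam_path)
    invisible(list(reads = reads, fastq = fastq, sam = sam,
                   fastq_path = fastq_path, sam_path = sam_path))
  })
}

#' Simulate a whole pool: clones, reads, truth
#'
#' Convenience wrapper tying [sample_pool_events()],
#' [synthesize_clone_sequence()] and [simulate_reads()] together.
#'
#' @param toy A `ToyGenome` from [build_toy_genome()].
#' @param truth A `PoolTruth` from [sample_pool_events()].
#' @param ... Passed to [simulate_reads()].
#' @return The [simulate_reads()] result plus `clones` and `truth`.
#' @export
simulate_pool <- function(toy, truth, ...) {
  clones <- lapply(seq_len(nrow(truth$events)), function(i) {
    synthesize_clone_sequence(toy$genome, truth$events[i, ], toy$annotations)
  })
  names(clones) <- truth$events$clone_id
  sim <- simulate_reads(clones, genome = toy$genome, ...)
  sim$clones <- clones
  # observable (divergence) breakpoint per clone; equals the drawn junction
  # minus any chance terminal homology with the reference
  truth$events$breakpoint_div <- truth$events$breakpoint -
    vapply(clones, function(x) attr(x, "junction_shift") %||% 0L, integer(1))
  sim$truth <- truth
  sim
}

#' Write / read a pool truth table
#'
#' Tab-separated truth table with the seed and mixture echoed as `#`
#' comments.
#'
#' @param truth A `PoolTruth`.
#' @param path File path.
#' @return `path` (write) or a `PoolTruth` (read).
#' @export
write_pool_truth <- function(truth, path) {
  hdr <- c(sprintf("# seed=%d", truth$seed),
           sprintf("# n_clones=%d", truth$n_clones),
           sprintf("# mixture=%s",
                   paste(sprintf("%s:%g", names(truth$mixture), truth$mixture),
                         collapse = ",")))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(truth$events, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pool_truth
#' @export
read_pool_truth <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  events <- utils::read.table(text = lines[!startsWith(lines, "#")],
                              sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
  events$tract[is.na(events$tract)] <- ""
  get1 <- function(key) sub(paste0("# ", key, "="), "",
                            grep(paste0("^# ", key, "="), meta, value = TRUE))
  mix_raw <- strsplit(strsplit(get1("mixture"), ",")[[1]], ":")
  mixture <- as.numeric(vapply(mix_raw, `[`, "", 2L))
  names(mixture) <- vapply(mix_raw, `[`, "", 1L)
  structure(list(events = events, mixture = mixture,
                 n_clones = as.integer(get1("n_clones")),
                 seed = as.integer(get1("seed"))),
            class = "PoolTruth")
}
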