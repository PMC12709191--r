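# Seed-and-extend placement of clipped read tails on a small genome.
# Stands in for the second alignment pass of the assay (the realignment of
# repair-region reads to the full reference): a 12-mer index seeds ungapped
# (Hamming) comparison on both strands. Completeness: a clip of length L
# carries floor(L / 25) tolerated mismatches by default, and the seeds are
# disjoint 12-mers, so by pigeonhole at least one seed is error-free for
# every qualifying placement; the hit set therefore equals a brute-force
# sliding-window Hamming scan (property-tested against Biostrings).

#' Build a k-mer index of a genome
#'
#' Hashes every overlapping k-mer of the forward strand of each chromosome
#' to its 0-based positions. Build once and pass to [realign_clip()] /
#' [align_reads()] when placing many sequences.
#'
#' @param genome A `Genome`.
#' @param k Seed size (default 12).
#' @return A `GenomeIndex`.
#' @export
genome_index <- function(genome, k = 12L) {
  stopifnot(inherits(genome, "Genome"), k >= 4L)
  chroms <- lapply(genome$sequences, function(seq) {
    n <- nchar(seq)
    if (n < k) return(new.env(parent = emptyenv()))
    starts <- seq_len(n - k + 1L)
    kmers <- substring(seq, starts, starts + k - 1L)
    list2env(split(starts - 1L, kmers), hash = TRUE, parent = emptyenv())
  })
  structure(list(k = as.integer(k), chroms = chroms, genome = genome),
            class = "GenomeIndex")
}

empty_hits <- function() {
  data.frame(chrom = character(), start = integer(), strand = character(),
             mismatches = integer(), n_equivalent = integer(),
             stringsAsFactors = FALSE)
}

# Candidate 0-based diagonal starts for `s` (already strand-resolved) from
# disjoint seeds. `offsets0` are 0-based seed offsets within s.
.seed_candidates <- function(s, index, offsets0) {
  k <- index$k
  len <- nchar(s)
  out <- list()
  for (chrom in names(index$chroms)) {
    env <- index$chroms[[chrom]]
    clen <- genome_length(index$genome, chrom)
    starts <- integer(0)
    for (o in offsets0) {
      kmer <- substr(s, o + 1L, o + k)
      pos <- env[[kmer]]
      if (!is.null(pos)) starts <- c(starts, pos - o)
    }
    starts <- unique(starts)
    starts <- starts[starts >= 0L & starts + len <= clen]
    if (length(starts)) out[[chrom]] <- starts
  }
  out
}

#' Place a clipped tail on the genome
#'
#' Seed-and-extend search over both strands for ungapped placements of
#' `clip_seq` with at most `max_mismatch` substitutions. All qualifying
#' placements are returned; `n_equivalent` on every row is the number of
#' placements achieving the best (minimum) mismatch count, i.e. the
#' multi-mapping multiplicity used by the classifier.
#'
#' @param clip_seq DNA string (length >= seed size).
#' @param genome A `Genome` (ignored when `index` is supplied).
#' @param max_mismatch Maximum substitutions; default `floor(len / 25)`,
#'   a tolerant-local-alignment stand-in.
#' @param index Optional prebuilt [genome_index()].
#' @return Data frame with columns `chrom`, `start` (0-based), `strand`,
#'   `mismatches`, `n_equivalent`, ordered by mismatches then position.
#'   Zero rows when nothing qualifies.
#' @export
realign_clip <- function(clip_seq, genome = NULL, max_mismatch = NULL,
                         index = NULL) {
  if (is.null(index)) index <- genome_index(genome)
  k <- index$k
  len <- nchar(clip_seq)
  if (len < k) {
    stop2("clip (", len, " nt) shorter than seed size (", k,
          "); skip classification for this read")
  }
  mm <- if (is.null(max_mismatch)) len %/% 25L else as.integer(max_mismatch)
  # pigeonhole guarantee needs mm + 1 disjoint seeds, so mm <= len/k - 1
  mm <- max(0L, min(mm, len %/% k - 1L))
  bounds <- floor(seq(0L, len - k, length.out = mm + 1L))
  offsets0 <- as.integer(unique(bounds))

  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") clip_seq else revcomp(clip_seq)
    cand <- .seed_candidates(s, index, offsets0)
    rs <- charToRaw(s)
    for (chrom in names(cand)) {
      seq <- genome_seq(index$genome, chrom)
      for (st in cand[[chrom]]) {
        d <- sum(charToRaw(substr(seq, st + 1L, st + len)) != rs)
        if (d <= mm) {
          rows[[length(rows) + 1L]] <-
            data.frame(chrom = chrom, start = st, strand = strand,
                       mismatches = d, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) return(empty_hits())
  hits <- do.call(rbind, rows)
  hits <- unique(hits)
  best <- min(hits$mismatches)
  hits$n_equivalent <- sum(hits$mismatches == best)
  hits[order(hits$mismatches, hits$chrom, hits$start, hits$strand), ,
       drop = FALSE]
}

# Junction-side boundary coordinate (0-based, half-open sense) of a hit of a
# junction-oriented sequence: the genomic coordinate at which the acquired
# sequence starts, reading away from the breakpoint.
hit_junction_coord <- function(hit, len) {
  if (hit$strand == "+") hit$start else hit$start + len
}

# --- read anchoring for toy genomes (FASTQ path) ----------------------------

# Length of the clean anchor run in a mismatch-position vector, scanning from
# one end. A mismatch is absorbed when the next mismatch is > `lookahead`
# positions away (isolated sequencing error); a junction produces dense
# mismatches and stops the run.
.anchor_run <- function(mp, len, lookahead = 8L) {
  if (!length(mp)) return(len)
  mp <- c(mp, len + lookahead + 1L)
  for (i in seq_len(length(mp) - 1L)) {
    if (mp[i + 1L] - mp[i] <= lookahead) return(mp[i] - 1L)
  }
  len  # all mismatches isolated
}

#' Anchor raw reads on a toy genome
#'
#' A deliberately simple exact/near-exact anchorer for simulator-scale
#' genomes: each read (both strands) is seeded with end k-mers, placed on
#' its best ungapped diagonal, and the longest clean prefix or suffix run
#' becomes the anchor; the remainder becomes the soft clip. Not a general
#' read aligner - external aligners produce the SAM for real data.
#'
#' @param reads Named character vector of read sequences (names = read ids).
#' @param genome A `Genome`.
#' @param index Optional prebuilt [genome_index()].
#' @param min_anchor Minimum anchor length to accept a placement.
#' @param region Optional `RepairRegion`: placements anchored inside the
#'   region are preferred over longer anchors elsewhere, mirroring the
#'   assay's repair-region-first alignment pass (junction reads whose
#'   distal portion is the longer half would otherwise anchor on the donor
#'   and be lost from the region).
#' @return `AnchoredRead` data frame (see [parse_alignments()] for columns).
#' @export
align_reads <- function(reads, genome, index = NULL, min_anchor = 20L,
                        region = NULL) {
  if (is.null(index)) index <- genome_index(genome)
  k <- index$k
  out <- vector("list", length(reads))
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  for (i in seq_along(reads)) {
    read <- reads[[i]]
    len <- nchar(read)
    if (len < k) next
    best <- NULL
    for (strand in c("+", "-")) {
      s <- if (strand == "+") read else revcomp(read)
      offs <- unique(pmax(0L, c(0L, k, len - 2L * k, len - k)))
      offs <- offs[offs + k <= len]
      cand <- .seed_candidates(s, index, offs)
      rs <- charToRaw(s)
      for (chrom in names(cand)) {
        seq <- genome_seq(index$genome, chrom)
        for (st in cand[[chrom]]) {
          mp <- which(charToRaw(substr(seq, st + 1L, st + len)) != rs)
          pre <- .anchor_run(mp, len)
          suf <- len - .anchor_run(len + 1L - rev(mp), len)
          # anchor on the side with the longer clean run
          if (pre >= len - suf) {
            a_len <- pre; side <- "right"
          } else {
            a_len <- len - suf; side <- "left"
          }
          if (a_len < min_anchor) next
          a_start <- if (side == "right") st else st + (len - a_len)
          in_reg <- !is.null(region) && chrom == region$chrom &&
            a_start < region$end && a_start + a_len > region$start
          cand_row <- list(chrom = chrom, start = st, strand = strand,
                           a_len = a_len, side = side, s = s,
                           in_reg = in_reg)
          better <- is.null(best) ||
            (in_reg && !best$in_reg) ||
            (in_reg == best$in_reg &&
             (a_len > best$a_len ||
              (a_len == best$a_len && st < best$start)))
          if (better) best <- cand_row
        }
      }
    }
    if (is.null(best)) next
    len_clip <- len - best$a_len
    if (best$side == "right") {
      anchor_start <- best$start
      anchor_end <- best$start + best$a_len
      clip_seq <- if (len_clip) substr(best$s, best$a_len + 1L, len) else ""
      clip_side <- "right"
    } else {
      anchor_start <- best$start + len_clip
      anchor_end <- best$start + len
      clip_seq <- if (len_clip) substr(best$s, 1L, len_clip) else ""
      clip_side <- "left"
    }
    out[[i]] <- data.frame(
      read_id = ids[i], chrom = best$chrom,
      anchor_start = anchor_start, anchor_end = anchor_end,
      strand = best$strand, clip_seq = clip_seq,
      clip_side = if (len_clip) clip_side else "none",
      mapq = 60L, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) res <- empty_anchored()
  rownames(res) <- NULL
  res
}
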