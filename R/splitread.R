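# GCR split-read identification: SAM parsing, clip extraction, breakpoint
# calling. A "GCR split read" is a read whose anchored segment lies in the
# repair region while its soft-clipped tail derives from elsewhere; the
# breakpoint is the reference coordinate at which the read first diverges.

empty_anchored <- function() {
  data.frame(read_id = character(), chrom = character(),
             anchor_start = integer(), anchor_end = integer(),
             strand = character(), clip_seq = character(),
             clip_side = character(), mapq = integer(),
             stringsAsFactors = FALSE)
}

.parse_cigar <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (!length(ops) || paste(ops, collapse = "") != cigar) return(NULL)
  list(len = as.integer(sub("[A-Z=]$", "", ops)),
       op = sub("^\\d+", "", ops))
}

#' Parse read alignments from a plain-text SAM file
#'
#' Returns the reads whose aligned segment overlaps the repair region, with
#' soft-clipped tails extracted into `clip_seq`. When a read is clipped on
#' both sides the longer clip is kept for analysis (the assay produces one
#' junction per read). Secondary and supplementary alignments are ignored;
#' hard-clipped records are skipped with a warning.
#'
#' @param path SAM file path.
#' @param genome A `Genome`; records on unknown references are an error.
#' @param region A `RepairRegion`; only overlapping reads are returned (pass
#'   `NULL` to keep all mapped reads).
#' @return `AnchoredRead` data frame: `read_id`, `chrom`, `anchor_start`,
#'   `anchor_end` (0-based half-open), `strand`, `clip_seq` (reference
#'   orientation, possibly empty), `clip_side` (`left`/`right`/`none`),
#'   `mapq`.
#' @export
parse_alignments <- function(path, genome, region = NULL) {
  if (!file.exists(path)) stop2("SAM file not found: ", path)
  lines <- readLines(path)
  body <- which(!startsWith(lines, "@"))
  if (!length(body)) return(empty_anchored())
  parts <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 11L)) {
    stop2("unparseable SAM record at line ", body[which(nf < 11L)[1]])
  }
  fmat <- t(vapply(parts, `[`, character(11L), 1:11))
  fld <- function(i) fmat[, i]
  flag <- suppressWarnings(as.integer(fld(2L)))
  pos <- suppressWarnings(as.integer(fld(4L)))
  if (anyNA(flag) || anyNA(pos)) {
    stop2("unparseable SAM record at line ",
          body[which(is.na(flag) | is.na(pos))[1]])
  }
  mapped <- bitwAnd(flag, 4L) == 0L & bitwAnd(flag, 256L) == 0L &
    bitwAnd(flag, 2048L) == 0L
  keep <- which(mapped)
  rname <- fld(3L)[keep]
  bad_ref <- !rname %in% names(genome$sequences)
  if (any(bad_ref)) {
    stop2("line ", body[keep[which(bad_ref)[1]]], ": reference '",
          rname[which(bad_ref)[1]], "' not in genome")
  }
  cigar <- fld(6L)[keep]
  # fast path: the overwhelmingly common [nS] nM [nS] shape
  simple <- grepl("^(\\d+S)?\\d+M(\\d+S)?$", cigar)
  lead_s <- trail_s <- ref_span <- integer(length(cigar))
  hard <- logical(length(cigar))
  if (any(simple)) {
    cap <- utils::strcapture("^(?:(\\d+)S)?(\\d+)M(?:(\\d+)S)?$",
                             cigar[simple],
                             proto = data.frame(a = integer(),
                                                b = integer(),
                                                c = integer()))
    lead_s[simple] <- ifelse(is.na(cap$a), 0L, cap$a)
    ref_span[simple] <- cap$b
    trail_s[simple] <- ifelse(is.na(cap$c), 0L, cap$c)
  }
  for (i in which(!simple)) {
    cg <- .parse_cigar(cigar[i])
    if (is.null(cg)) {
      stop2("line ", body[keep[i]], ": bad CIGAR '", cigar[i], "'")
    }
    if (any(cg$op == "H")) { hard[i] <- TRUE; next }
    ref_span[i] <- sum(cg$len[cg$op %in% c("M", "D", "N", "=", "X")])
    lead_s[i] <- if (cg$op[1] == "S") cg$len[1] else 0L
    n <- length(cg$op)
    trail_s[i] <- if (cg$op[n] == "S") cg$len[n] else 0L
  }
  if (any(hard)) {
    warning(sum(hard),
            " hard-clipped record(s) skipped (clip sequence not recoverable)")
    keep <- keep[!hard]
    lead_s <- lead_s[!hard]; trail_s <- trail_s[!hard]
    ref_span <- ref_span[!hard]
  }
  seq <- fld(10L)[keep]
  left <- lead_s >= trail_s & lead_s > 0L
  right <- !left & trail_s > 0L
  clip_side <- ifelse(left, "left", ifelse(right, "right", "none"))
  clip_seq <- character(length(keep))
  clip_seq[left] <- substr(seq[left], 1L, lead_s[left])
  clip_seq[right] <- substring(seq[right],
                               nchar(seq[right]) - trail_s[right] + 1L)
  res <- data.frame(
    read_id = fld(1L)[keep], chrom = fld(3L)[keep],
    anchor_start = pos[keep] - 1L,
    anchor_end = pos[keep] - 1L + as.integer(ref_span),
    strand = ifelse(bitwAnd(flag[keep], 16L) > 0L, "-", "+"),
    clip_seq = clip_seq, clip_side = clip_side,
    mapq = suppressWarnings(as.integer(fld(5L)[keep])),
    stringsAsFactors = FALSE)
  if (!is.null(region) && nrow(res)) {
    inr <- res$chrom == region$chrom &
      res$anchor_start < region$end & res$anchor_end > region$start
    res <- res[inr, , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}

#' Identify GCR split reads
#'
#' Keeps anchored reads whose clip is at least `min_clip` nt and points away
#' from the retained (centromeric) segment: for a left-arm repair region the
#' junction clip is on the left (telomere-proximal) side of the anchor.
#' Reads clipped on the wrong side are excluded here and recorded in the
#' `audit` attribute with their exclusion reason.
#'
#' @param reads `AnchoredRead` data frame (from [parse_alignments()] or
#'   [align_reads()]).
#' @param region A `RepairRegion`.
#' @param min_clip Minimum clip length in nt (default 10; shorter tails
#'   place and classify unreliably).
#' @return Subset of `reads` (the split reads), with an `audit` attribute
#'   data frame of excluded read ids and reasons.
#' @export
detect_split_reads <- function(reads, region, min_clip = 10L) {
  stopifnot(min_clip >= 1L)
  want_side <- if (region$orientation == "left") "left" else "right"
  in_region <- reads$chrom == region$chrom &
    reads$anchor_start < region$end & reads$anchor_end > region$start
  clip_len <- nchar(reads$clip_seq)
  reason <- rep(NA_character_, nrow(reads))
  reason[!in_region] <- "anchor_outside_region"
  reason[is.na(reason) & clip_len == 0L] <- "no_clip"
  reason[is.na(reason) & clip_len < min_clip] <- "clip_below_min"
  reason[is.na(reason) & reads$clip_side != want_side] <- "clip_wrong_side"
  keep <- is.na(reason)
  res <- reads[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "audit") <- data.frame(
    read_id = reads$read_id[!keep], reason = reason[!keep],
    stringsAsFactors = FALSE)
  res
}

#' Breakpoint coordinate of a split read
#'
#' The breakpoint is the reference coordinate at which the first nucleotide
#' of the read diverges from the reference: the base adjacent to the anchor
#' on the clipped side. Internally 0-based; `report` is the 1-based
#' coordinate used in all output tables.
#'
#' @param read One-row `AnchoredRead` data frame (non-empty clip).
#' @param region A `RepairRegion`.
#' @return List with `chrom`, `coordinate` (0-based position of the first
#'   divergent base), `report` (1-based), `side`, and `flagged` (`TRUE` when
#'   the clip is on the unexpected side for the region orientation or the
#'   breakpoint abuts/escapes the region boundary).
#' @export
breakpoint_coordinate <- function(read, region) {
  if (is.data.frame(read)) { stopifnot(nrow(read) == 1L); read <- as.list(read) }
  if (!nzchar(read$clip_seq)) stop2("read has no clip; no breakpoint to call")
  coord0 <- if (read$clip_side == "left") read$anchor_start - 1L
            else read$anchor_end
  want_side <- if (region$orientation == "left") "left" else "right"
  flagged <- read$clip_side != want_side ||
    coord0 < region$start || coord0 >= region$end
  list(chrom = read$chrom, coordinate = coord0, report = coord0 + 1L,
       side = read$clip_side, flagged = flagged)
}

#' Write / read the intermediate split-read table
#'
#' Tab-separated plain-text interchange so any pipeline stage can be
#' resumed or replaced by hand-crafted fixtures.
#'
#' @param reads `AnchoredRead` data frame.
#' @param path File path.
#' @return `path` (write) or the data frame (read).
#' @export
write_split_reads <- function(reads, path) {
  utils::write.table(reads, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_split_reads
#' @export
read_split_reads <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(read_id = "character",
                                         chrom = "character",
                                         strand = "character",
                                         clip_seq = "character",
                                         clip_side = "character"),
                          stringsAsFactors = FALSE)
  df$clip_seq[is.na(df$clip_seq)] <- ""
  df
}
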