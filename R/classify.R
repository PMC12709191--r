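# Event classification. Each split read becomes one GCR event call:
# telomere addition, deletion or translocation, with subtelomeric
# translocations subdivided into Class A (internal X/Y' target with
# junction microhomology), Class B (Y'-start target marked by the exact
# 5'-ATATATAT-3' motif) and Class C (telomeric tract at the junction
# followed by subtelomeric sequence).

ATAT_MOTIF <- "ATATATAT"
REPEAT_KINDS <- c("X_element", "Yprime_element", "ITS", "telomere")

#' Junction microhomology between two flanks
#'
#' Best ungapped local alignment between two flanks (match +1, mismatch -1),
#' scanned over every offset pair. Reports the maximal-score window's span,
#' identity and 1-based offsets in each flank. Ties are broken by longer
#' span, then smaller offset in `flank_a`, then in `flank_b`.
#' "Microhomology present" convention: span >= `window` and identity >=
#' `min_identity`. The defaults (14 nt, 0.8) keep the false-positive rate on
#' unrelated 40 nt flanks below 1% while sitting well under the 19-33 bp
#' interrupted junction homologies seen in Class A events.
#'
#' @param flank_a,flank_b DNA strings (junction-adjacent flanks, same
#'   orientation, both ending at the junction).
#' @param window Minimum span for the presence call (default 14).
#' @param min_identity Minimum identity for the presence call (default 0.8).
#' @return A `MicrohomologyReport` list: `span`, `identity`, `offsets`
#'   (a, b), `score`, `present`.
#' @export
microhomology <- function(flank_a, flank_b, window = 14L, min_identity = 0.8) {
  na <- nchar(flank_a); nb <- nchar(flank_b)
  stopifnot(na >= 1L, nb >= 1L)
  ra <- charToRaw(flank_a); rb <- charToRaw(flank_b)
  best <- list(score = -Inf, span = 0L, identity = 0,
               offsets = c(a = 0L, b = 0L))
  for (shift in -(na - 1L):(nb - 1L)) {
    ia <- max(1L, 1L - shift); ib <- ia + shift      # aligned start indices
    ov <- min(na - ia, nb - ib) + 1L
    if (ov < 1L) next
    sc <- ifelse(ra[ia:(ia + ov - 1L)] == rb[ib:(ib + ov - 1L)], 1L, -1L)
    p <- cumsum(sc)
    pmin_before <- cummin(c(0L, p[-ov]))
    gains <- p - pmin_before
    s <- max(gains)
    if (s < best$score) next
    ends <- which(gains == s)
    # leftmost-longest maximal-score window at this offset
    cand <- NULL
    for (e in ends) {
      st <- min(which(c(0L, p)[1:e] == pmin_before[e]))  # index into c(0,p)
      span <- e - (st - 1L)
      if (is.null(cand) || span > cand$span) {
        cand <- list(start = st, span = span, end = e)
      }
    }
    ident <- (cand$span + s) / (2 * cand$span)
    off_a <- ia + cand$start - 1L
    off_b <- ib + cand$start - 1L
    better <- s > best$score ||
      (s == best$score && (cand$span > best$span ||
        (cand$span == best$span && (off_a < best$offsets[["a"]] ||
          (off_a == best$offsets[["a"]] && off_b < best$offsets[["b"]])))))
    if (better) {
      best <- list(score = s, span = cand$span, identity = ident,
                   offsets = c(a = off_a, b = off_b))
    }
  }
  best$present <- best$span >= window && best$identity >= min_identity - 1e-9
  class(best) <- "MicrohomologyReport"
  best
}

#' @export
print.MicrohomologyReport <- function(x, ...) {
  cat(sprintf("Microhomology: span %d, identity %.3f, offsets a=%d b=%d (%s)\n",
              x$span, x$identity, x$offsets[["a"]], x$offsets[["b"]],
              if (x$present) "present" else "absent"))
  invisible(x)
}

# default classification parameters, overridable through run_config()
classify_params <- function(min_len = 8L, min_fraction = 0.9,
                            atat_mismatch = 0L, min_continuation = 12L,
                            mh_flank = 40L, mh_window = 14L,
                            mh_identity = 0.8, edge_tol = 2L) {
  list(min_len = min_len, min_fraction = min_fraction,
       atat_mismatch = atat_mismatch, min_continuation = min_continuation,
       mh_flank = mh_flank, mh_window = mh_window, mh_identity = mh_identity,
       edge_tol = edge_tol)
}

.starts_with_motif <- function(seq, motif, max_mismatch = 0L) {
  if (nchar(seq) < nchar(motif)) return(FALSE)
  hamming(substr(seq, 1L, nchar(motif)), motif) <= max_mismatch
}

# Do any of the best hits of a placement land in repeat (X/Y'/ITS/telomere)
# context?
.hits_in_repeats <- function(hits, len, annotations) {
  if (!nrow(hits)) return(FALSE)
  best <- hits[hits$mismatches == min(hits$mismatches), , drop = FALSE]
  for (i in seq_len(nrow(best))) {
    if (overlaps_kind(annotations, best$chrom[i], best$start[i],
                      best$start[i] + len, REPEAT_KINDS)) return(TRUE)
  }
  FALSE
}

#' Classify one split read into a GCR event
#'
#' Decision order: (1) a clip recognised as telomeric repeat is a de novo
#' telomere addition - unless the sequence beyond the telomeric tract is
#' long enough to place on the genome in subtelomeric context, in which case
#' the read is a translocation (Class C candidate, flagged
#' `tg_then_target`); (2) a clip with exactly one best placement in unique
#' sequence telomere-proximal to the URA3 marker on the broken chromosome is
#' a deletion; (3) any other placeable clip is a translocation (including
#' all ambiguous multi-mapping cases); (4) otherwise unclassified.
#'
#' @param read One-row `AnchoredRead` data frame with a non-empty clip.
#' @param genome A `Genome`.
#' @param annotations `AnnotationSet` with at least the URA3 marker and
#'   subtelomeric repeat features.
#' @param region A `RepairRegion`.
#' @param index Optional prebuilt [genome_index()].
#' @param params [classify_params()] list.
#' @return One-row data frame (`GCREvent` at read granularity): breakpoint
#'   (1-based report coordinate), `event_type`, `tclass`, target placement,
#'   `n_equivalent`, microhomology span/identity, `flags`.
#' @export
classify_event <- function(read, genome, annotations, region, index = NULL,
                           params = classify_params()) {
  if (is.null(index)) index <- genome_index(genome)
  if (is.data.frame(read)) { stopifnot(nrow(read) == 1L); read <- as.list(read) }
  bp <- breakpoint_coordinate(read, region)
  # clip read 5'->3' away from the junction into the acquired sequence
  clipJ <- if (read$clip_side == "left") revcomp(read$clip_seq) else read$clip_seq
  clen <- nchar(clipJ)
  flags <- character(0)
  if (bp$flagged) flags <- c(flags, "boundary")

  ev <- list(read_id = read$read_id, chrom = bp$chrom, breakpoint = bp$report,
             event_type = "unclassified", tclass = "not_applicable",
             target_chrom = NA_character_, target_pos = NA_integer_,
             target_strand = NA_character_, n_equivalent = 0L,
             mismatches = NA_integer_, tract_len = 0L,
             mh_span = NA_integer_, mh_identity = NA_real_, support = 1L)

  tel <- is_telomeric(clipJ, params$min_len, params$min_fraction)
  pref <- telomeric_prefix_len(clipJ, params$min_len)
  routed <- FALSE
  if (pref > 0L) {
    # telomeric tract at the junction; if enough non-telomeric sequence
    # follows and places in subtelomeric context, this is a Class C
    # translocation, not a simple telomere addition
    ev$tract_len <- pref
    cont <- if (pref < clen) substr(clipJ, pref + 1L, clen) else ""
    if (nchar(cont) >= max(params$min_continuation, index$k)) {
      hits_c <- realign_clip(cont, index = index)
      if (nrow(hits_c) && .hits_in_repeats(hits_c, nchar(cont), annotations)) {
        flags <- c(flags, "tg_then_target")
        ev$event_type <- "translocation"
        best <- hits_c[1L, ]
        ev$target_chrom <- best$chrom
        ev$target_pos <- hit_junction_coord(best, nchar(cont))
        ev$target_strand <- best$strand
        ev$n_equivalent <- best$n_equivalent
        ev$mismatches <- best$mismatches
        routed <- TRUE
      }
    }
  }
  if (!routed && tel != "no_match") {
    ev$event_type <- "telomere_addition"
    if (clen >= index$k) {
      hits_t <- tryCatch(realign_clip(clipJ, index = index),
                         error = function(e) empty_hits())
      if (.hits_in_repeats(hits_t, clen, annotations)) {
        flags <- c(flags, "tg_places_at_its")  # cis/trans ambiguity caveat
      }
    }
    routed <- TRUE
  }

  if (!routed) {
    if (clen < index$k) {
      flags <- c(flags, "clip_too_short")
    } else {
      hits <- realign_clip(clipJ, index = index)
      if (nrow(hits)) {
        best <- hits[hits$mismatches == min(hits$mismatches), , drop = FALSE]
        h1 <- best[1L, ]
        ev$target_chrom <- h1$chrom
        ev$target_pos <- hit_junction_coord(h1, clen)
        ev$target_strand <- h1$strand
        ev$n_equivalent <- h1$n_equivalent
        ev$mismatches <- h1$mismatches
        ura3 <- features_of_kind(annotations, "URA3_marker", region$chrom)
        is_del <- FALSE
        if (h1$n_equivalent == 1L && nrow(ura3) == 1L &&
            h1$chrom == region$chrom) {
          tel_side_ok <- if (region$orientation == "left") {
            h1$start + clen <= ura3$start
          } else {
            h1$start >= ura3$end
          }
          unique_seq <- !overlaps_kind(annotations, h1$chrom, h1$start,
                                       h1$start + clen, REPEAT_KINDS)
          is_del <- tel_side_ok && unique_seq
        }
        ev$event_type <- if (is_del) "deletion" else "translocation"
      } else {
        flags <- c(flags, "no_placement")
      }
    }
  }

  if (ev$event_type == "translocation") {
    cls <- translocation_class_impl(ev, clipJ, genome, annotations, region,
                                    index, params, flags)
    ev$tclass <- cls$class
    if (!is.null(cls$mh)) {
      ev$mh_span <- cls$mh$span
      ev$mh_identity <- cls$mh$identity
    }
  }
  ev$flags <- paste(flags, collapse = ",")
  as.data.frame(ev, stringsAsFactors = FALSE)
}

# Y'-start edges (the edge facing the centromere, where the ATATATAT motif
# immediately precedes the element) with both edges returned for mirrored
# arms.
.yprime_edges <- function(annotations) {
  yp <- features_of_kind(annotations, "Yprime_element")
  yp
}

translocation_class_impl <- function(ev, clipJ, genome, annotations, region,
                                     index, params, flags) {
  clen <- nchar(clipJ)
  # Class C: telomeric tract at the junction, then subtelomeric sequence
  if ("tg_then_target" %in% flags) return(list(class = "C", mh = NULL))

  # Class B: the exact ATATATAT motif at the junction with the continuation
  # at a Y' start. Divergence-point calling can absorb up to a few leading
  # motif bases into the anchor (the motif is AT-repeat and may chance-match
  # the reference distal to the junction), so a front-trimmed motif
  # (>= 5 matching bases, zero mismatches within the match) also qualifies.
  ml <- nchar(ATAT_MOTIF)
  for (trim in 0:3) {
    msub <- substr(ATAT_MOTIF, trim + 1L, ml)
    if (clen < nchar(msub) ||
        !.starts_with_motif(clipJ, msub, params$atat_mismatch)) next
    cont <- substr(clipJ, nchar(msub) + 1L, clen)
    if (nchar(cont) < index$k) next
    hits <- tryCatch(realign_clip(cont, index = index),
                     error = function(e) empty_hits())
    if (!nrow(hits)) next
    best <- hits[hits$mismatches == min(hits$mismatches), , drop = FALSE]
    yp <- .yprime_edges(annotations)
    for (i in seq_len(nrow(best))) {
      jc <- hit_junction_coord(best[i, ], nchar(cont))
      same <- yp[yp$chrom == best$chrom[i], , drop = FALSE]
      if (nrow(same) &&
          any(abs(same$start - jc) <= params$edge_tol |
              abs(same$end - jc) <= params$edge_tol)) {
        return(list(class = "B", mh = NULL))
      }
    }
  }

  # Class A: best placement strictly internal to an X or Y' element plus
  # junction microhomology between the lost-side flank and the acquired clip
  if (!is.na(ev$target_chrom)) {
    el <- features_of_kind(annotations, c("X_element", "Yprime_element"),
                           ev$target_chrom)
    jc <- ev$target_pos
    internal <- nrow(el) > 0L &&
      any(jc > el$start + params$edge_tol & jc < el$end - params$edge_tol)
    if (internal) {
      # two-sided genomic flanks centred on the junction: the divergence
      # point can sit anywhere inside an interrupted homology block, so
      # both sides of each junction partner are scanned
      w <- params$mh_flank
      bp0 <- ev$breakpoint - 1L          # first divergent base, 0-based
      rl <- genome_length(genome, region$chrom)
      flank_a <- genome_slice(genome, region$chrom, max(0L, bp0 + 1L - w),
                              min(rl, bp0 + 1L + w))
      tl <- genome_length(genome, ev$target_chrom)
      tb <- genome_slice(genome, ev$target_chrom, max(0L, jc - w),
                         min(tl, jc + w))
      # a junction-outward clip hitting the donor "+" strand enters the
      # product reverse-complemented when the clip is on the left
      flip <- if (region$orientation == "left") {
        identical(ev$target_strand, "+")
      } else {
        identical(ev$target_strand, "-")
      }
      flank_b <- if (flip) revcomp(tb) else tb
      mh <- microhomology(flank_a, flank_b, params$mh_window,
                          params$mh_identity)
      if (mh$present) return(list(class = "A", mh = mh))
      return(list(class = "other", mh = mh))
    }
  }
  list(class = "other", mh = NULL)
}

#' Translocation class of a classified event
#'
#' Assigns Class C, B, A or `other` (evaluated in that precedence order,
#' which resolves clips satisfying several rules, e.g. a telomeric tract
#' followed by ATATATAT and Y' sequence is Class C).
#'
#' @param event One-row event data frame from [classify_event()] with
#'   `event_type == "translocation"`.
#' @param clipJ Junction-oriented clip sequence of the supporting read.
#' @param genome,annotations,region,index,params As in [classify_event()].
#' @return One of `"A"`, `"B"`, `"C"`, `"other"`.
#' @export
translocation_class <- function(event, clipJ, genome, annotations, region,
                                index = NULL, params = classify_params()) {
  if (is.null(index)) index <- genome_index(genome)
  if (is.data.frame(event)) { stopifnot(nrow(event) == 1L); event <- as.list(event) }
  if (event$event_type != "translocation") {
    stop2("translocation_class applies only to translocation events")
  }
  flags <- strsplit(if (is.null(event$flags) || is.na(event$flags)) ""
                    else event$flags, ",")[[1]]
  translocation_class_impl(event, clipJ, genome, annotations, region, index,
                           params, flags)$class
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' Classify all split reads of a pool
#'
#' Driver over [classify_event()]: one classified event row per split read.
#'
#' @param reads Split-read `AnchoredRead` data frame
#'   (from [detect_split_reads()]).
#' @param genome,annotations,region,index,params As in [classify_event()].
#' @return Data frame with one row per read.
#' @export
classify_split_reads <- function(reads, genome, annotations, region,
                                 index = NULL, params = classify_params()) {
  if (is.null(index)) index <- genome_index(genome)
  rows <- lapply(seq_len(nrow(reads)), function(i) {
    classify_event(reads[i, ], genome, annotations, region, index, params)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- classify_event_empty()
  }
  rownames(res) <- NULL
  res
}

classify_event_empty <- function() {
  data.frame(read_id = character(), chrom = character(),
             breakpoint = integer(), event_type = character(),
             tclass = character(), target_chrom = character(),
             target_pos = integer(), target_strand = character(),
             n_equivalent = integer(), mismatches = integer(),
             tract_len = integer(), mh_span = integer(),
             mh_identity = numeric(), support = integer(),
             flags = character(), stringsAsFactors = FALSE)
}
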