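# Event filtering and frequency quantification. The assay's published
# quantity is read-weighted: the frequency of split reads meeting a
# criterion divided by the total number of GCR split reads mapping to the
# repair region (a validated proxy for the fraction of GCR events). An
# event-weighted count (each collapsed event once) is reported alongside.

#' Collapse per-read event calls into supported events
#'
#' Reads with the same event type, the same target signature and breakpoints
#' within `merge_window` nt of each other form a cluster. Within a cluster,
#' breakpoint coordinates carrying at least `peak_frac` of the cluster's
#' reads (and at least 2 reads) are treated as independent events - distinct
#' hotspot nucleotides a few bases apart are real and common at SiRTA Cores
#' - while low-support satellite coordinates (alignment jitter from
#' substitution errors adjacent to the junction) merge into the nearest
#' peak. `merge_window = 0` disables merging across coordinates.
#'
#' @param calls Per-read event table from [classify_split_reads()].
#' @param merge_window Breakpoint merge distance in nt (default 2).
#' @param peak_frac Minimum fraction of cluster support for a coordinate to
#'   stand as its own event (default 0.15).
#' @return Collapsed event table with a `support` column (read count).
#' @export
collapse_events <- function(calls, merge_window = 2L, peak_frac = 0.15) {
  if (!nrow(calls)) return(cbind(calls[0, ], event_id = character(0)))
  sig <- paste(calls$event_type, calls$tclass,
               ifelse(is.na(calls$target_chrom), ".", calls$target_chrom),
               sep = "|")
  out <- list()
  emit <- function(e, bp) {
    rep_row <- e[1L, ]
    rep_row$breakpoint <- bp
    rep_row$support <- nrow(e)
    rep_row
  }
  for (s in unique(sig)) {
    sub <- calls[sig == s, , drop = FALSE]
    sub <- sub[order(sub$breakpoint), , drop = FALSE]
    grp <- cumsum(c(1L, diff(sub$breakpoint) > merge_window))
    for (g in unique(grp)) {
      e <- sub[grp == g, , drop = FALSE]
      tab <- table(e$breakpoint)
      need <- max(2L, ceiling(peak_frac * nrow(e)))
      peaks <- as.integer(names(tab)[tab >= need])
      if (!length(peaks)) {
        peaks <- as.integer(names(tab)[which.max(tab)])
      }
      near <- vapply(e$breakpoint, function(b) {
        peaks[which.min(abs(peaks - b))]
      }, integer(1))
      for (p in peaks) {
        out[[length(out) + 1L]] <- emit(e[near == p, , drop = FALSE], p)
      }
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$breakpoint, res$event_type), , drop = FALSE]
  res$event_id <- sprintf("ev%03d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res
}

#' Singleton filter
#'
#' In experiments with more than `threshold` (default 200) GCR split reads,
#' events supported by a single read are unlikely to be real and are
#' removed; with `threshold` or fewer total reads singletons are kept to
#' avoid discarding true events. The boundary is a strict `>`.
#'
#' @param events Collapsed event table (with `support`).
#' @param total_split_reads Total split reads in the repair region.
#' @param threshold Read-count threshold (default 200).
#' @return List with `retained`, `removed` and `filter_log`.
#' @export
singleton_filter <- function(events, total_split_reads, threshold = 200L) {
  active <- total_split_reads > threshold
  drop <- active & events$support == 1L
  if (!nrow(events)) drop <- logical(0)
  list(
    retained = events[!drop, , drop = FALSE],
    removed = events[drop, , drop = FALSE],
    filter_log = data.frame(
      total_split_reads = total_split_reads, threshold = threshold,
      filter_active = active, n_removed = sum(drop),
      support_removed = sum(events$support[drop]),
      stringsAsFactors = FALSE)
  )
}

#' Poisson model of reads per event
#'
#' With `total_split_reads` reads spread over `n_events` independent clones,
#' the expected read support per event is `lambda = total / n_events`; the
#' Poisson pmf predicts how many events should appear with a given read
#' count, and in particular how many true events are expected to be
#' singletons - the diagnostic that motivates the singleton filter.
#'
#' @param total_split_reads Total split reads.
#' @param n_events Number of clones/events in the pool (default 30).
#' @param kmax Largest support value tabulated (default covers the mass).
#' @return List: `lambda`, `pmf` (named vector over 0..kmax),
#'   `expected_singletons` (`n_events * lambda * exp(-lambda)`).
#' @export
poisson_read_model <- function(total_split_reads, n_events = 30L,
                               kmax = NULL) {
  stopifnot(n_events >= 1L, total_split_reads >= 0)
  lambda <- total_split_reads / n_events
  if (is.null(kmax)) kmax <- max(10L, ceiling(lambda + 10 * sqrt(max(lambda, 1))))
  k <- 0:kmax
  pmf <- stats::dpois(k, lambda)
  names(pmf) <- k
  list(lambda = lambda, pmf = pmf,
       expected_singletons = n_events * stats::dpois(1, lambda))
}

.type_levels <- c("telomere_addition", "deletion", "translocation",
                  "unclassified")

# read-weighted and event-weighted counts of an event subset
.tally <- function(events) {
  c(reads = sum(events$support), events = nrow(events))
}

#' Event frequency tables
#'
#' For each resolution - per annotated feature, per fixed-size bin (bins
#' tile the region from its proximal boundary; the last bin is truncated at
#' the region end) - and each event type, the fraction of total split reads
#' whose breakpoint meets the criterion. Fractions are percentages of
#' `total_split_reads` (read-weighted, the assay's published quantity); an
#' event-weighted count is included.
#'
#' @param events Retained collapsed events.
#' @param region A `RepairRegion`.
#' @param annotations `AnnotationSet` (features overlapping the region are
#'   tabulated).
#' @param bin_sizes Integer vector of bin sizes in nt (default 1000 and
#'   100).
#' @param total_split_reads Denominator; defaults to the summed support of
#'   `events`.
#' @return List: `total_split_reads`, `by_type`, `by_feature`, `by_bin`
#'   (one data frame per bin size).
#' @export
event_frequencies <- function(events, region, annotations,
                              bin_sizes = c(1000L, 100L),
                              total_split_reads = NULL) {
  if (any(bin_sizes > region_length(region))) {
    stop2("bin size larger than the repair region")
  }
  if (is.null(total_split_reads)) total_split_reads <- sum(events$support)
  tot <- max(total_split_reads, 1L)  # avoid 0/0; fractions are 0 then
  bp0 <- events$breakpoint - 1L      # 0-based first-divergent-base coords

  by_type <- do.call(rbind, lapply(.type_levels, function(ty) {
    t <- .tally(events[events$event_type == ty, , drop = FALSE])
    data.frame(event_type = ty, reads = t[["reads"]], events = t[["events"]],
               pct_reads = 100 * t[["reads"]] / tot, stringsAsFactors = FALSE)
  }))

  feats <- annotations[annotations$chrom == region$chrom &
                       annotations$start < region$end &
                       annotations$end > region$start, , drop = FALSE]
  by_feature <- do.call(rbind, lapply(seq_len(nrow(feats)), function(i) {
    f <- feats[i, ]
    inside <- bp0 >= f$start & bp0 < f$end & events$chrom == f$chrom
    do.call(rbind, lapply(.type_levels, function(ty) {
      sel <- inside & events$event_type == ty
      t <- .tally(events[sel, , drop = FALSE])
      data.frame(feature = f$label, kind = f$kind,
                 start = f$start + 1L, end = f$end,
                 region_pct = region_fraction(f, region),
                 event_type = ty, reads = t[["reads"]],
                 events = t[["events"]],
                 pct_reads = 100 * t[["reads"]] / tot,
                 stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(by_feature)) by_feature <- data.frame()

  by_bin <- lapply(bin_sizes, function(size) {
    starts <- seq(region$start, region$end - 1L, by = size)
    ends <- pmin(starts + size, region$end)
    do.call(rbind, lapply(seq_along(starts), function(b) {
      inside <- bp0 >= starts[b] & bp0 < ends[b] &
        events$chrom == region$chrom
      rows <- lapply(.type_levels, function(ty) {
        sel <- inside & events$event_type == ty
        t <- .tally(events[sel, , drop = FALSE])
        data.frame(bin_start = starts[b] + 1L, bin_end = ends[b],
                   event_type = ty, reads = t[["reads"]],
                   events = t[["events"]],
                   pct_reads = 100 * t[["reads"]] / tot,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    }))
  })
  names(by_bin) <- as.character(bin_sizes)

  list(total_split_reads = total_split_reads, by_type = by_type,
       by_feature = by_feature, by_bin = by_bin)
}

#' Nucleotide-resolution event map of a feature
#'
#' One row per base of the feature with the percentage of total split reads
#' whose breakpoint falls on that base, split by event type. Rows are
#' emitted in 3'-5' orientation of the TG-rich strand (centromere to the
#' right for a left arm), matching how SiRTA maps are drawn.
#'
#' @param events Retained collapsed events.
#' @param feature One-row `AnnotationSet` within the region.
#' @param total_split_reads Denominator (defaults to summed support).
#' @param orientation Region orientation (`"left"` keeps ascending
#'   coordinates).
#' @return Data frame: `position` (1-based), one percentage column per
#'   event type.
#' @export
per_nucleotide_map <- function(events, feature, total_split_reads = NULL,
                               orientation = "left") {
  if (is.data.frame(feature)) { stopifnot(nrow(feature) == 1L); feature <- as.list(feature) }
  if (is.null(total_split_reads)) total_split_reads <- sum(events$support)
  tot <- max(total_split_reads, 1L)
  pos0 <- feature$start:(feature$end - 1L)
  out <- data.frame(position = pos0 + 1L)
  bp0 <- events$breakpoint - 1L
  for (ty in .type_levels) {
    sel <- events$event_type == ty & events$chrom == feature$chrom
    cnt <- vapply(pos0, function(p) sum(events$support[sel & bp0 == p]),
                  numeric(1))
    out[[paste0("pct_", ty)]] <- 100 * cnt / tot
  }
  if (orientation != "left") out <- out[rev(seq_len(nrow(out))), , drop = FALSE]
  attr(out, "orientation") <- "3'-5' TG-rich strand, centromere to the right"
  rownames(out) <- NULL
  out
}

#' Plate counts for the GCR frequency
#'
#' @param galr_colonies Galactose-resistant colonies counted.
#' @param cells_plated_gal Viable cells plated on galactose (from the
#'   dilution series).
#' @param galr_assayed Gal-resistant colonies patched to 5-FOA.
#' @param foar_colonies Of those, colonies surviving 5-FOA.
#' @return A `PlateCounts` list.
#' @export
plate_counts <- function(galr_colonies, cells_plated_gal, galr_assayed,
                         foar_colonies) {
  x <- list(galr_colonies = galr_colonies,
            cells_plated_gal = cells_plated_gal,
            galr_assayed = galr_assayed, foar_colonies = foar_colonies)
  if (any(unlist(x) < 0)) stop2("plate counts must be non-negative")
  if (foar_colonies > galr_assayed) {
    stop2("foar_colonies cannot exceed galr_assayed")
  }
  structure(x, class = "PlateCounts")
}

#' Read plate counts from a key: value text file
#'
#' Four fields, one per line: `galr_colonies`, `cells_plated_gal`,
#' `galr_assayed`, `foar_colonies`.
#'
#' @param path File path.
#' @return A `PlateCounts`.
#' @export
read_plate_counts <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "[:=]")
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(trimws(vapply(kv, `[`, "", 2L)))
  need <- c("galr_colonies", "cells_plated_gal", "galr_assayed",
            "foar_colonies")
  if (!all(need %in% keys)) {
    stop2("plate counts file must define: ", paste(need, collapse = ", "))
  }
  v <- vals[match(need, keys)]
  plate_counts(v[1], v[2], v[3], v[4])
}

#' Overall GCR frequency from plate counts
#'
#' The frequency of galactose-resistant colonies multiplied by the fraction
#' of those that survive 5-FOA counter-selection:
#' `(galr / plated) * (foar / assayed)`. Scale-invariant in the plating
#' dilution.
#'
#' @param counts A `PlateCounts`.
#' @return Numeric GCR frequency.
#' @export
gcr_frequency <- function(counts) {
  stopifnot(inherits(counts, "PlateCounts"))
  if (counts$galr_assayed == 0) stop2("galr_assayed is 0; frequency undefined")
  if (counts$cells_plated_gal == 0) stop2("cells_plated_gal is 0")
  (counts$galr_colonies / counts$cells_plated_gal) *
    (counts$foar_colonies / counts$galr_assayed)
}

#' Functional-SiRTA call
#'
#' A sequence is called a functional SiRTA when the fraction of total split
#' reads that are de novo telomere additions at the site reaches 6.6%
#' (inclusive at the boundary).
#'
#' @param feature_fraction_dnta Telomere-addition percentage at the feature.
#' @param threshold Percentage threshold (default 6.6).
#' @return `"functional"` or `"non_functional"`.
#' @export
sirta_call <- function(feature_fraction_dnta, threshold = 6.6) {
  if (feature_fraction_dnta >= threshold) "functional" else "non_functional"
}
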