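# End-to-end orchestration: simulate/ingest -> detect -> classify ->
# quantify, with every stage resumable from the previous stage's
# plain-text table and every filter decision logged.

#' Pipeline configuration
#'
#' Paths plus the tunable parameters of every stage. Flags beat the config
#' file, which beats these defaults.
#'
#' @param reference Path to a FASTA reference (or a `Genome`).
#' @param annotations Path to a BED-like annotation file (or an
#'   `AnnotationSet`).
#' @param alignments Optional SAM path.
#' @param reads Optional FASTQ path (used when `alignments` is absent).
#' @param out_dir Optional output directory for tables and the JSON report.
#' @param chrom Repair chromosome (default: the chromosome carrying the
#'   HO cut site).
#' @param orientation `"left"` or `"right"` arm.
#' @param min_clip,merge_window,singleton_threshold,bin_sizes,n_events
#'   Stage parameters (see the stage functions).
#' @param telomeric_min_len,telomeric_min_fraction [is_telomeric()]
#'   thresholds.
#' @param seed Seed recorded in outputs (the analysis itself is
#'   deterministic).
#' @param verbose Print progress.
#' @return A `RunConfig` list.
#' @export
run_config <- function(reference, annotations, alignments = NULL,
                       reads = NULL, out_dir = NULL, chrom = NULL,
                       orientation = "left", min_clip = 10L,
                       merge_window = 2L, singleton_threshold = 200L,
                       bin_sizes = c(1000L, 100L), n_events = 30L,
                       telomeric_min_len = 8L, telomeric_min_fraction = 0.9,
                       seed = 1L, verbose = FALSE) {
  structure(list(reference = reference, annotations = annotations,
                 alignments = alignments, reads = reads, out_dir = out_dir,
                 chrom = chrom, orientation = orientation,
                 min_clip = as.integer(min_clip),
                 merge_window = as.integer(merge_window),
                 singleton_threshold = as.integer(singleton_threshold),
                 bin_sizes = as.integer(bin_sizes),
                 n_events = as.integer(n_events),
                 telomeric_min_len = as.integer(telomeric_min_len),
                 telomeric_min_fraction = telomeric_min_fraction,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "RunConfig")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[setdiff(names(config), "verbose")]), tmp)
  unname(tools::md5sum(tmp))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop2("[", name, "] ", conditionMessage(e))
  })
}

#' Read a FASTQ file into a named vector
#'
#' @param path FASTQ path (plain text, 4 lines per record).
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stop2("truncated FASTQ: ", path)
  ids <- sub("^@", "", sub("\\s.*$", "", lines[seq(1L, length(lines), by = 4L)]))
  seqs <- toupper(lines[seq(2L, length(lines), by = 4L)])
  names(seqs) <- ids
  seqs
}

#' Run the full split-read pipeline
#'
#' ingest (SAM or FASTQ) -> split-read detection -> breakpoint calling and
#' classification -> event collapsing and singleton filtering -> frequency
#' tables and SiRTA calls. Deterministic given the config; when `out_dir`
#' is set, every table, the JSON report, and an audit of excluded reads are
#' written, each stamped with the config hash and seed.
#'
#' @param config A [run_config()].
#' @return A `PoolReport` list: totals, per-read calls, collapsed events,
#'   filter log, frequency tables, Poisson diagnostic, SiRTA calls.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  say <- function(...) if (config$verbose) message(...)

  genome <- .stage("reference", {
    if (inherits(config$reference, "Genome")) config$reference
    else load_reference(config$reference)
  })
  annotations <- .stage("annotations", {
    if (inherits(config$annotations, "AnnotationSet")) config$annotations
    else load_annotations(config$annotations, genome)
  })
  region <- .stage("region", {
    chrom <- config$chrom
    if (is.null(chrom)) {
      ho <- features_of_kind(annotations, "HO_cut_site")
      if (nrow(ho) == 0L) stop2("no HO_cut_site annotated and no chrom given")
      chrom <- ho$chrom[1L]
    }
    repair_region_span(annotations, chrom,
                       orientation = config$orientation)
  })
  index <- genome_index(genome)

  anchored <- .stage("ingest", {
    if (!is.null(config$alignments)) {
      parse_alignments(config$alignments, genome, region)
    } else if (!is.null(config$reads)) {
      align_reads(read_fastq(config$reads), genome, index = index,
                  region = region)
    } else stop2("config needs `alignments` (SAM) or `reads` (FASTQ)")
  })
  say("anchored reads overlapping region: ", nrow(anchored))

  split <- .stage("detect", detect_split_reads(anchored, region,
                                               config$min_clip))
  say("GCR split reads: ", nrow(split))

  params <- classify_params(min_len = config$telomeric_min_len,
                            min_fraction = config$telomeric_min_fraction)
  calls <- .stage("classify",
                  classify_split_reads(split, genome, annotations, region,
                                       index, params))
  collapsed <- .stage("collapse", collapse_events(calls, config$merge_window))
  total_split_reads <- nrow(calls)
  filt <- .stage("filter", singleton_filter(collapsed, total_split_reads,
                                            config$singleton_threshold))
  retained_total <- sum(filt$retained$support)
  freq <- .stage("quantify",
                 event_frequencies(filt$retained, region, annotations,
                                   config$bin_sizes,
                                   total_split_reads = retained_total))
  pois <- poisson_read_model(total_split_reads, config$n_events)

  sirtas <- features_of_kind(annotations, "SiRTA", region$chrom)
  sirta_calls <- do.call(rbind, lapply(seq_len(nrow(sirtas)), function(i) {
    f <- sirtas[i, ]
    bf <- freq$by_feature
    pct <- bf$pct_reads[bf$feature == f$label & bf$kind == "SiRTA" &
                        bf$event_type == "telomere_addition"]
    pct_all <- sum(bf$reads[bf$feature == f$label & bf$kind == "SiRTA"]) /
      max(retained_total, 1L) * 100
    data.frame(sirta = f$label, start = f$start + 1L, end = f$end,
               pct_split_reads = pct_all, pct_dnta = pct,
               region_pct = region_fraction(f, region),
               call = sirta_call(pct), stringsAsFactors = FALSE)
  }))

  report <- structure(list(
    config_hash = config_hash(config), seed = config$seed,
    region = region, total_split_reads = total_split_reads,
    retained_split_reads = retained_total,
    anchored_reads = nrow(anchored), calls = calls,
    events = filt$retained, removed = filt$removed,
    filter_log = filt$filter_log, frequencies = freq,
    poisson = pois, sirta_calls = sirta_calls,
    audit = attr(split, "audit")), class = "PoolReport")

  if (!is.null(config$out_dir)) write_pool_report(report, config$out_dir)
  report
}

#' @export
print.PoolReport <- function(x, ...) {
  cat("PoolReport:", x$total_split_reads, "GCR split reads in",
      sprintf("%s:%d-%d", x$region$chrom, x$region$start + 1L, x$region$end),
      "\n")
  print(x$frequencies$by_type, row.names = FALSE)
  if (!is.null(x$sirta_calls) && nrow(x$sirta_calls)) {
    cat("SiRTA calls:\n")
    print(x$sirta_calls, row.names = FALSE)
  }
  invisible(x)
}

.write_tsv <- function(df, path, stamp) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(stamp, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a PoolReport to disk
#'
#' Tab-separated tables plus a JSON summary, each stamped with the config
#' hash and seed so identical configs reproduce byte-identical outputs.
#'
#' @param report A `PoolReport`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pool_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- sprintf("# config_hash=%s seed=%d", report$config_hash,
                   report$seed)
  .write_tsv(report$calls, file.path(out_dir, "events_reads.tsv"), stamp)
  .write_tsv(report$events, file.path(out_dir, "events.tsv"), stamp)
  .write_tsv(report$frequencies$by_feature,
             file.path(out_dir, "freq_by_feature.tsv"), stamp)
  for (size in names(report$frequencies$by_bin)) {
    .write_tsv(report$frequencies$by_bin[[size]],
               file.path(out_dir, paste0("freq_bin_", size, ".tsv")), stamp)
  }
  .write_tsv(report$audit, file.path(out_dir, "audit.tsv"), stamp)
  js <- list(config_hash = report$config_hash, seed = report$seed,
             region = list(chrom = report$region$chrom,
                           start = report$region$start + 1L,
                           end = report$region$end,
                           orientation = report$region$orientation),
             total_split_reads = report$total_split_reads,
             retained_split_reads = report$retained_split_reads,
             lambda = report$poisson$lambda,
             expected_singletons = report$poisson$expected_singletons,
             filter_log = report$filter_log,
             by_type = report$frequencies$by_type,
             sirta_calls = report$sirta_calls)
  jsonlite::write_json(js, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}

#' Textual 1-kb histogram of split-read locations
#'
#' A quick terminal rendering of the binned event map (percent of total
#' split reads per interval, split by type).
#'
#' @param report A `PoolReport`.
#' @param bin_size Which bin table to draw (default 1000).
#' @param width Bar width in characters.
#' @return Character vector of lines, invisibly (also printed).
#' @export
report_histogram <- function(report, bin_size = 1000L, width = 40L) {
  tab <- report$frequencies$by_bin[[as.character(bin_size)]]
  if (is.null(tab)) stop2("no bin table of size ", bin_size)
  agg <- stats::aggregate(pct_reads ~ bin_start + bin_end, tab, sum)
  agg <- agg[order(agg$bin_start), ]
  mx <- max(agg$pct_reads, 1e-9)
  lines <- sprintf("%8d-%-8d %6.2f%% %s", agg$bin_start, agg$bin_end,
                   agg$pct_reads,
                   strrep("#", round(agg$pct_reads / mx * width)))
  cat(lines, sep = "\n")
  invisible(lines)
}
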