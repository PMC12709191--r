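# Shared fixtures, built once per test run. Everything is generated in code
# under fixed seeds; no data files.

.fx <- new.env(parent = emptyenv())

toy_fixture <- function() {
  if (is.null(.fx$toy)) {
    .fx$toy <- build_toy_genome(toy_genome_config(seed = 1))
  }
  .fx$toy
}

index_fixture <- function() {
  if (is.null(.fx$index)) .fx$index <- genome_index(toy_fixture()$genome)
  .fx$index
}

region_fixture <- function() {
  toy <- toy_fixture()
  repair_region_span(toy$annotations, toy$info$repair_chrom)
}

# one-row AnchoredRead builder
anchored_read <- function(read_id = "r1", chrom = "chrR",
                          anchor_start, anchor_end, strand = "+",
                          clip_seq = "", clip_side = "none", mapq = 60L) {
  data.frame(read_id = read_id, chrom = chrom,
             anchor_start = as.integer(anchor_start),
             anchor_end = as.integer(anchor_end), strand = strand,
             clip_seq = clip_seq, clip_side = clip_side,
             mapq = as.integer(mapq), stringsAsFactors = FALSE)
}

# compare a pipeline report against a simulated pool truth table;
# returns counts of exactly recovered breakpoints and classes
recovery_stats <- function(truth, report, bp_tol = 0L) {
  tr <- truth$events
  tr$type <- sub("_[ABC]$", "", tr$event_type)
  tr$tclass <- sub("translocation_", "", tr$event_type)
  tr$tclass[!grepl("translocation", tr$event_type)] <- NA
  bp_col <- if ("breakpoint_div" %in% names(tr)) "breakpoint_div" else "breakpoint"
  tru <- unique(tr[tr$event_type != "hocs_indel",
                   c(bp_col, "type", "tclass")])
  names(tru)[1] <- "bp"
  ev <- report$events
  hit <- mapply(function(b, ty) {
    any(abs(ev$breakpoint - b) <= bp_tol & ev$event_type == ty)
  }, tru$bp, tru$type)
  clo <- tru[!is.na(tru$tclass), , drop = FALSE]
  chit <- mapply(function(b, cl) {
    any(abs(ev$breakpoint - b) <= bp_tol & ev$tclass == cl)
  }, clo$bp, clo$tclass)
  list(bp_hit = sum(hit), bp_n = nrow(tru),
       class_hit = sum(chit), class_n = nrow(clo))
}

# truth clone-level event-type mixture in percent
truth_mixture_pct <- function(truth) {
  ty <- sub("_[ABC]$", "", truth$events$event_type)
  100 * table(factor(ty, levels = c("telomere_addition", "deletion",
                                    "translocation"))) / length(ty)
}

# estimated read-weighted mixture in percent from a report
report_mixture_pct <- function(report) {
  bt <- report$frequencies$by_type
  stats::setNames(bt$pct_reads, bt$event_type)[
    c("telomere_addition", "deletion", "translocation")]
}
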