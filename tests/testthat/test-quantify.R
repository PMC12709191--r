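# filtering, Poisson diagnostic, frequency tables, plate-count arithmetic

mk_calls <- function(bp, type = "telomere_addition", tclass = "not_applicable",
                     target_chrom = NA_character_) {
  n <- length(bp)
  data.frame(read_id = sprintf("r%03d", seq_len(n)), chrom = "chrR",
             breakpoint = as.integer(bp), event_type = rep(type, n),
             tclass = rep(tclass, n),
             target_chrom = rep(target_chrom, n), target_pos = NA_integer_,
             target_strand = NA_character_, n_equivalent = 1L,
             mismatches = 0L, tract_len = 0L, mh_span = NA_integer_,
             mh_identity = NA_real_, support = 1L, flags = "",
             stringsAsFactors = FALSE)
}

test_that("collapse_events merges jitter but keeps co-hotspot peaks", {
  # 20 reads at 4200, 18 at 4202, plus 1-read satellites at 4199/4203
  calls <- mk_calls(c(rep(4200, 20), rep(4202, 18), 4199, 4203))
  ev <- collapse_events(calls, merge_window = 2)
  expect_equal(nrow(ev), 2L)
  expect_setequal(ev$breakpoint, c(4200L, 4202L))
  expect_equal(sum(ev$support), 40L)
  # satellites joined their nearest peak
  expect_equal(ev$support[ev$breakpoint == 4200], 21L)
  expect_equal(ev$support[ev$breakpoint == 4202], 19L)

  # merge_window = 0 keeps every coordinate separate
  ev0 <- collapse_events(calls, merge_window = 0)
  expect_equal(nrow(ev0), 4L)

  # different types never merge
  calls2 <- rbind(mk_calls(rep(4200, 5)),
                  mk_calls(rep(4201, 5), type = "deletion"))
  expect_equal(nrow(collapse_events(calls2, merge_window = 2)), 2L)
})

test_that("singleton_filter applies the strict > 200 rule", {
  ev <- rbind(mk_calls(c(100, 200, 300)),
              within(mk_calls(400), support <- 50L))
  ev$support[1:3] <- 1L

  keep_all <- singleton_filter(ev, total_split_reads = 150)
  expect_equal(nrow(keep_all$removed), 0L)
  expect_false(keep_all$filter_log$filter_active)

  boundary <- singleton_filter(ev, total_split_reads = 200)
  expect_equal(nrow(boundary$removed), 0L)

  active <- singleton_filter(ev, total_split_reads = 300)
  expect_equal(nrow(active$removed), 3L)
  expect_true(all(active$removed$support == 1L))
  expect_equal(nrow(active$retained), 1L)
  # conservation of support across the filter
  expect_equal(sum(active$retained$support) + sum(active$removed$support),
               sum(ev$support))
})

test_that("poisson_read_model matches the closed-form pmf", {
  z <- poisson_read_model(0, 30)
  expect_equal(z$lambda, 0)
  expect_equal(unname(z$pmf[["0"]]), 1)

  m <- poisson_read_model(300, 30, kmax = 50)
  expect_equal(m$lambda, 10)
  expect_equal(unname(m$pmf[["1"]]), 10 * exp(-10))
  expect_equal(m$expected_singletons, 30 * 10 * exp(-10))
  for (lam in c(1, 5, 20)) {
    mm <- poisson_read_model(lam * 30, 30, kmax = 50)
    expect_gt(sum(mm$pmf), 0.999999)
  }
})

test_that("event_frequencies are consistent across resolutions", {
  region <- repair_region("chrR", 2600, 8800)
  ann <- annotation_set(data.frame(
    chrom = "chrR", start = c(4100, 2600), end = c(4400, 2630),
    kind = c("SiRTA", "HO_cut_site"), strand = c("-", "+"),
    label = c("SiRTA", "HOcs")))

  # all reads at one SiRTA coordinate, all telomere additions
  calls <- mk_calls(rep(4200, 40))
  ev <- collapse_events(calls)
  fr <- event_frequencies(ev, region, ann, bin_sizes = c(1000L, 100L))
  sirta_dnta <- fr$by_feature[fr$by_feature$feature == "SiRTA" &
                              fr$by_feature$event_type == "telomere_addition", ]
  expect_equal(sirta_dnta$pct_reads, 100)
  expect_equal(fr$by_type$pct_reads[fr$by_type$event_type ==
                                    "telomere_addition"], 100)

  # random events: bins tile the region and sums agree at every resolution
  set.seed(71)
  calls2 <- rbind(
    mk_calls(sample(2650:8700, 60, replace = TRUE)),
    mk_calls(sample(2650:8700, 25, replace = TRUE), type = "translocation",
             tclass = "B", target_chrom = "chrD1"))
  ev2 <- collapse_events(calls2, merge_window = 0)
  fr2 <- event_frequencies(ev2, region, ann, bin_sizes = c(1000L, 100L))
  for (size in c("1000", "100")) {
    tab <- fr2$by_bin[[size]]
    starts <- sort(unique(tab$bin_start))
    expect_equal(starts[1], region$start + 1L)
    expect_equal(max(tab$bin_end), region$end)
    # contiguous tiling
    ub <- unique(tab[, c("bin_start", "bin_end")])
    expect_equal(sum(ub$bin_end - ub$bin_start + 1L),
                 region_length(region))
    for (ty in unique(fr2$by_type$event_type)) {
      expect_equal(sum(tab$pct_reads[tab$event_type == ty]),
                   fr2$by_type$pct_reads[fr2$by_type$event_type == ty],
                   label = paste(size, ty))
    }
  }
  expect_error(event_frequencies(ev2, region, ann, bin_sizes = 10000L),
               "bin size")
})

test_that("per_nucleotide_map covers each base once and sums to the total", {
  region <- repair_region("chrR", 2600, 8800)
  feature <- data.frame(chrom = "chrR", start = 4100L, end = 4400L,
                        kind = "SiRTA", strand = "-", label = "SiRTA")
  calls <- mk_calls(c(rep(4200, 5), rep(3000, 45)))
  ev <- collapse_events(calls)
  pmap <- per_nucleotide_map(ev, feature, total_split_reads = 50)
  expect_equal(nrow(pmap), 300L)
  expect_identical(pmap$position, 4101:4400)
  expect_equal(pmap$pct_telomere_addition[pmap$position == 4200], 10)
  expect_equal(sum(pmap$pct_telomere_addition[pmap$position != 4200]), 0)
  # sum over bases equals the feature-level fraction
  ann <- annotation_set(feature)
  fr <- event_frequencies(ev, region, ann, bin_sizes = 100L,
                          total_split_reads = 50)
  feat_pct <- fr$by_feature$pct_reads[fr$by_feature$event_type ==
                                      "telomere_addition"]
  expect_equal(sum(pmap$pct_telomere_addition), feat_pct)
})

test_that("gcr_frequency does the plate arithmetic and is scale-invariant", {
  pc <- plate_counts(100, 1e4, 250, 50)
  expect_equal(gcr_frequency(pc), 0.002)
  expect_equal(gcr_frequency(plate_counts(0, 1e4, 250, 0)), 0)
  # all assayed colonies resistant: frequency equals the GalR frequency
  expect_equal(gcr_frequency(plate_counts(100, 1e4, 250, 250)), 0.01)
  for (k in c(2, 10, 100)) {
    expect_equal(gcr_frequency(plate_counts(100 * k, 1e4 * k, 250, 50)),
                 0.002)
  }
  expect_error(gcr_frequency(plate_counts(100, 1e4, 0, 0)), "undefined")
  expect_error(plate_counts(100, 1e4, 250, 300), "exceed")

  f <- tempfile()
  writeLines(c("# plate counts", "galr_colonies: 100",
               "cells_plated_gal: 10000", "galr_assayed: 250",
               "foar_colonies: 50"), f)
  expect_equal(gcr_frequency(read_plate_counts(f)), 0.002)
})

test_that("sirta_call threshold is 6.6% inclusive", {
  expect_equal(sirta_call(6.6), "functional")
  expect_equal(sirta_call(6.59), "non_functional")
  expect_equal(sirta_call(0), "non_functional")
  expect_equal(sirta_call(85), "functional")
})
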