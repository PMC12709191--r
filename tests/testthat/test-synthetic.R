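# pooled-clone simulator: determinism, architecture, constraints

test_that("build_toy_genome is deterministic and honours its config", {
  cfg <- toy_genome_config(seed = 1)
  t1 <- build_toy_genome(cfg)
  t2 <- build_toy_genome(cfg)
  expect_identical(t1$genome$sequences, t2$genome$sequences)
  expect_identical(as.data.frame(t1$annotations),
                   as.data.frame(t2$annotations))

  # every Y' start preceded by the motif at fraction 1
  t3 <- build_toy_genome(toy_genome_config(seed = 2,
                                           atat_motif_fraction = 1))
  for (i in seq_len(nrow(t3$info$yprime))) {
    yp <- t3$info$yprime[i, ]
    expect_true(yp$motif)
    expect_identical(substr(t3$genome$sequences[[yp$chrom]],
                            yp$start - 7L, yp$start), "ATATATAT")
  }

  # ITS tract lengths stay in the configured range
  its <- t1$annotations[t1$annotations$kind == "ITS", ]
  expect_true(all(its$end - its$start >= 80 & its$end - its$start <= 150))

  # features that cannot fit are rejected
  expect_error(build_toy_genome(toy_genome_config(seed = 1,
                                                  chrom_length = 6000L,
                                                  n_yprime = 6L)),
               "cannot fit")
  expect_error(toy_genome_config(yprime_identity = 0.8), "yprime_identity")
})

test_that("sample_pool_events validates the mixture and hits its targets", {
  toy <- toy_fixture()
  expect_error(sample_pool_events(c(telomere_addition = 0.9), 30,
                                  toy$genome, toy$annotations, seed = 1,
                                  info = toy$info), "sum to 1")
  expect_error(sample_pool_events(c(nonsense = 1), 30, toy$genome,
                                  toy$annotations, seed = 1,
                                  info = toy$info), "unknown event")

  all_t <- sample_pool_events(c(telomere_addition = 1), 30, toy$genome,
                              toy$annotations, seed = 4, info = toy$info)
  expect_equal(nrow(all_t$events), 30L)
  expect_true(all(all_t$events$event_type == "telomere_addition"))
  expect_false(anyDuplicated(all_t$events$clone_id) > 0)

  # determinism
  again <- sample_pool_events(c(telomere_addition = 1), 30, toy$genome,
                              toy$annotations, seed = 4, info = toy$info)
  expect_identical(all_t$events, again$events)

  # every Class B target is a motif-bearing Y' start
  toyB <- build_toy_genome(toy_genome_config(seed = 3,
                                             atat_motif_fraction = 1))
  b <- sample_pool_events(c(translocation_B = 1), 30, toyB$genome,
                          toyB$annotations, seed = 5, info = toyB$info)
  expect_true(all(paste(b$events$target_chrom, b$events$target_pos) %in%
                  paste(toyB$info$yprime$chrom, toyB$info$yprime$start)))

  # breakpoints stay inside the repair region
  region <- region_fixture()
  mix <- default_mixture()
  p <- sample_pool_events(mix, 30, toy$genome, toy$annotations, seed = 6,
                          info = toy$info)
  expect_true(all(p$events$breakpoint >= region$start &
                  p$events$breakpoint < region$end))
})

test_that("synthesized clones have the right junction structure", {
  toy <- toy_fixture()
  chrR <- toy$genome$sequences[["chrR"]]
  ura3 <- toy$annotations[toy$annotations$kind == "URA3_marker", ]
  ura3_seq <- substr(chrR, ura3$start + 1, ura3$end)
  hocs <- toy$annotations[toy$annotations$kind == "HO_cut_site", ]
  hocs_seq <- substr(chrR, hocs$start + 1, hocs$end)
  yp <- toy$info$yprime[toy$info$yprime$motif, ][1, ]

  tract <- make_tg_tract(60, seed = 2)
  ev <- data.frame(clone_id = "c", event_type = "telomere_addition",
                   breakpoint = toy$info$core_start + 30L,
                   target_chrom = NA, target_pos = NA, target_strand = NA,
                   tract = tract, stringsAsFactors = FALSE)
  cl <- synthesize_clone_sequence(toy$genome, ev, toy$annotations)
  shift <- attr(cl, "junction_shift")
  expect_true(startsWith(as.character(cl), revcomp(tract)))
  expect_equal(nchar(cl), 60L + nchar(chrR) - ev$breakpoint)
  expect_equal(attr(cl, "retained_start") + shift, ev$breakpoint)

  types <- list(
    del = data.frame(clone_id = "d", event_type = "deletion",
                     breakpoint = 5000L, target_chrom = "chrR",
                     target_pos = 700L, target_strand = "+", tract = ""),
    trB = data.frame(clone_id = "b", event_type = "translocation_B",
                     breakpoint = 5000L, target_chrom = yp$chrom,
                     target_pos = yp$start, target_strand = "-",
                     tract = ""),
    trC = data.frame(clone_id = "c", event_type = "translocation_C",
                     breakpoint = 5000L, target_chrom = yp$chrom,
                     target_pos = yp$start, target_strand = "-",
                     tract = make_tg_tract(33, seed = 7)))
  for (nm in names(types)) {
    cl <- synthesize_clone_sequence(toy$genome, types[[nm]],
                                    toy$annotations)
    expect_false(grepl(ura3_seq, cl, fixed = TRUE), label = nm)
    expect_false(grepl(hocs_seq, cl, fixed = TRUE), label = nm)
  }
  # translocation_B junction carries the motif then the Y' start
  clb <- synthesize_clone_sequence(toy$genome, types$trB, toy$annotations)
  P <- attr(clb, "prefix_len"); s <- attr(clb, "junction_shift")
  junction_out <- revcomp(substr(clb, 1, P))
  expect_identical(substr(junction_out, 1, 8 - s),
                   substr("ATATATAT", s + 1, 8))

  # a deletion target at/after URA3 would retain the marker
  bad <- data.frame(clone_id = "x", event_type = "deletion",
                    breakpoint = 5000L, target_chrom = "chrR",
                    target_pos = ura3$end + 100L, target_strand = "+",
                    tract = "")
  expect_error(synthesize_clone_sequence(toy$genome, bad, toy$annotations),
               "URA3")
})

test_that("simulate_reads is seeded, exact and well-counted", {
  toy <- toy_fixture()
  set.seed(61)
  clone <- structure(rand_dna(3000), prefix_len = 0L,
                     retained_chrom = "chrR", retained_start = 0L)
  clones <- list(c1 = clone)

  s1 <- simulate_reads(clones, depth = 10, read_len = 150, error_rate = 0,
                       seed = 9)
  s2 <- simulate_reads(clones, depth = 10, read_len = 150, error_rate = 0,
                       seed = 9)
  expect_identical(s1$fastq, s2$fastq)
  # read count = depth * length / read_len
  expect_equal(nrow(s1$reads), round(10 * 3000 / 150))
  # error-free reads are exact substrings of the clone
  for (i in sample(nrow(s1$reads), 20)) {
    expect_true(grepl(s1$reads$seq[i], clone, fixed = TRUE))
  }
  # with errors, reads diverge at roughly the configured rate
  s3 <- simulate_reads(clones, depth = 10, read_len = 150,
                       error_rate = 0.01, seed = 9)
  mm <- sum(vapply(seq_len(nrow(s3$reads)), function(i) {
    sum(charToRaw(s3$reads$seq[i]) !=
        charToRaw(substr(clone, s3$reads$start[i] + 1,
                         s3$reads$start[i] + 150)))
  }, numeric(1)))
  rate <- mm / (nrow(s3$reads) * 150)
  expect_gt(rate, 0.005); expect_lt(rate, 0.02)

  expect_error(simulate_reads(list(c1 = "ACGT"), depth = 1,
                              read_len = 150, seed = 1), "read_len")
  expect_error(simulate_reads(clones, depth = 1, error_rate = 0.2,
                              seed = 1), "error_rate")

  # clone weighting: default equal, weights scale linearly
  clones2 <- list(c1 = clone, c2 = clone)
  eq <- simulate_reads(clones2, depth = 10, seed = 2)
  cnt <- table(eq$reads$clone)
  expect_equal(unname(cnt[["c1"]]), unname(cnt[["c2"]]))
  wt <- simulate_reads(clones2, depth = 10, seed = 2, weights = c(1, 3))
  cntw <- table(wt$reads$clone)
  expect_gt(cntw[["c2"]], 2.5 * cntw[["c1"]])
})

test_that("truth SAM reproduces junction CIGARs and round-trips", {
  toy <- toy_fixture()
  truth <- sample_pool_events(c(translocation_B = 0.5, deletion = 0.5),
                              n_clones = 6, genome = toy$genome,
                              annotations = toy$annotations, seed = 13,
                              info = toy$info)
  sam <- tempfile(fileext = ".sam")
  sim <- simulate_pool(toy, truth, depth = 8, error_rate = 0, seed = 14,
                       sam_path = sam)
  lines <- readLines(sam)
  expect_true(any(startsWith(lines, "@SQ")))
  recs <- lines[!startsWith(lines, "@")]
  expect_equal(length(recs), nrow(sim$reads))
  # soft-clipped records exist and their clips match the acquired tails
  region <- region_fixture()
  reads <- parse_alignments(sam, toy$genome, region)
  split <- detect_split_reads(reads, region, min_clip = 10)
  expect_gt(nrow(split), 0)
  bad <- setdiff(unique(split$chrom), "chrR")
  expect_length(bad, 0)

  # truth table round-trip
  f <- tempfile()
  write_pool_truth(sim$truth, f)
  back <- read_pool_truth(f)
  expect_equal(back$events, sim$truth$events)
  expect_identical(back$mixture, sim$truth$mixture)
  expect_identical(back$seed, sim$truth$seed)
})
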