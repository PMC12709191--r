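# SAM parsing, split-read detection, breakpoint calling

sam_lines <- function(..., genome = toy_fixture()$genome) {
  c("@HD\tVN:1.6",
    sprintf("@SQ\tSN:%s\tLN:%d", names(genome$sequences),
            nchar(genome$sequences)),
    ...)
}
sam_rec <- function(id, flag, chrom, pos1, cigar, seq, mapq = 60) {
  paste(id, flag, chrom, pos1, mapq, cigar, "*", 0, 0, seq,
        strrep("I", nchar(seq)), sep = "\t")
}

test_that("parse_alignments extracts anchors and soft clips", {
  toy <- toy_fixture()
  region <- region_fixture()
  chr <- toy$genome$sequences[["chrR"]]
  f <- tempfile(fileext = ".sam")
  anchor <- substr(chr, 5001, 5070)                     # 70M inside region
  clip150 <- paste0(substr(chr, 5001, 5070), rand_dna(80))  # 70M80S
  writeLines(sam_lines(
    sam_rec("full", 0, "chrR", 5001, "70M", anchor),
    sam_rec("split", 0, "chrR", 5001, "70M80S", clip150),
    sam_rec("outside", 0, "chrR", 101, "70M", substr(chr, 101, 170)),
    sam_rec("secondary", 256, "chrR", 5001, "70M", anchor),
    sam_rec("unmapped", 4, "*", 0, "*", anchor)
  ), f)
  reads <- parse_alignments(f, toy$genome, region)
  expect_setequal(reads$read_id, c("full", "split"))
  full <- reads[reads$read_id == "full", ]
  expect_equal(full$clip_seq, "")
  expect_equal(full$clip_side, "none")
  expect_equal(full$anchor_start, 5000L)
  expect_equal(full$anchor_end, 5070L)
  split <- reads[reads$read_id == "split", ]
  expect_equal(nchar(split$clip_seq), 80L)
  expect_equal(split$clip_side, "right")
  expect_equal(split$anchor_end, 5070L)

  # without a region filter the outside read is kept too
  expect_equal(nrow(parse_alignments(f, toy$genome, NULL)), 3L)
})

test_that("parse_alignments rejects bad records and hard clips", {
  toy <- toy_fixture()
  f <- tempfile(fileext = ".sam")
  writeLines(sam_lines(sam_rec("r", 0, "chrZ", 100, "10M", rand_dna(10))), f)
  expect_error(parse_alignments(f, toy$genome), "not in genome")
  writeLines(sam_lines(sam_rec("r", 0, "chrR", 100, "10Q", rand_dna(10))), f)
  expect_error(parse_alignments(f, toy$genome), "CIGAR")
  writeLines(sam_lines("garbage\tonly three\tfields"), f)
  expect_error(parse_alignments(f, toy$genome), "unparseable")
  writeLines(sam_lines(
    sam_rec("h", 0, "chrR", 100, "20H130M", rand_dna(130)),
    sam_rec("ok", 0, "chrR", 100, "150M", rand_dna(150))), f)
  expect_warning(reads <- parse_alignments(f, toy$genome), "hard-clip")
  expect_equal(reads$read_id, "ok")
})

test_that("detect_split_reads applies clip length and orientation rules", {
  region <- region_fixture()  # left arm: junction clips are on the left
  reads <- rbind(
    anchored_read("a", anchor_start = 4200, anchor_end = 4340,
                  clip_seq = rand_dna(5), clip_side = "left"),
    anchored_read("b", anchor_start = 4200, anchor_end = 4340,
                  clip_seq = rand_dna(40), clip_side = "left"),
    anchored_read("c", anchor_start = 4200, anchor_end = 4350),
    anchored_read("d", anchor_start = 4200, anchor_end = 4300,
                  clip_seq = rand_dna(50), clip_side = "right"),
    anchored_read("e", anchor_start = 100, anchor_end = 250,
                  clip_seq = rand_dna(50), clip_side = "left"))
  split <- detect_split_reads(reads, region, min_clip = 10)
  expect_equal(split$read_id, "b")
  audit <- attr(split, "audit")
  expect_equal(audit$reason[audit$read_id == "a"], "clip_below_min")
  expect_equal(audit$reason[audit$read_id == "c"], "no_clip")
  expect_equal(audit$reason[audit$read_id == "d"], "clip_wrong_side")
  expect_equal(audit$reason[audit$read_id == "e"], "anchor_outside_region")
  # subset property, no duplicates
  expect_true(all(split$read_id %in% reads$read_id))
  expect_false(anyDuplicated(split$read_id) > 0)
  expect_error(detect_split_reads(reads, region, min_clip = 0), "min_clip")
})

test_that("breakpoint_coordinate reports the first divergent base", {
  region_r <- repair_region("chr", 40000, 61600, orientation = "right")
  r <- anchored_read(anchor_start = 44200, anchor_end = 44270,
                     clip_seq = rand_dna(80), clip_side = "right",
                     chrom = "chr")
  bp <- breakpoint_coordinate(r, region_r)
  expect_equal(bp$coordinate, 44270L)   # 0-based
  expect_equal(bp$report, 44271L)       # 1-based report
  expect_false(bp$flagged)

  region_l <- repair_region("chr", 40000, 61600, orientation = "left")
  l <- anchored_read(anchor_start = 44200, anchor_end = 44270,
                     clip_seq = rand_dna(80), clip_side = "left",
                     chrom = "chr")
  bpl <- breakpoint_coordinate(l, region_l)
  expect_equal(bpl$report, 44200L)
  expect_false(bpl$flagged)

  # wrong side for the orientation: flagged, not dropped
  expect_true(breakpoint_coordinate(r, region_l)$flagged)
  # anchor abutting the region edge: flagged
  edge <- anchored_read(anchor_start = 40000, anchor_end = 40100,
                        clip_seq = rand_dna(30), clip_side = "left",
                        chrom = "chr")
  expect_true(breakpoint_coordinate(edge, region_l)$flagged)
  expect_error(breakpoint_coordinate(
    anchored_read(anchor_start = 1, anchor_end = 10, chrom = "chr"),
    region_l), "no clip")
})

test_that("reads spanning one junction share one breakpoint", {
  toy <- toy_fixture()
  region <- region_fixture()
  truth <- sample_pool_events(c(telomere_addition = 1), n_clones = 4,
                              genome = toy$genome,
                              annotations = toy$annotations, seed = 77,
                              info = toy$info)
  sam <- tempfile(fileext = ".sam")
  sim <- simulate_pool(toy, truth, depth = 10, error_rate = 0, seed = 78,
                       sam_path = sam)
  reads <- parse_alignments(sam, toy$genome, region)
  split <- detect_split_reads(reads, region, min_clip = 10)
  expect_gt(nrow(split), 10)
  bps <- vapply(seq_len(nrow(split)), function(i) {
    breakpoint_coordinate(split[i, ], region)$report
  }, numeric(1))
  # per clone: all junction reads give the identical coordinate
  clone <- sub("_r\\d+$", "", split$read_id)
  per_clone <- tapply(bps, clone, function(x) length(unique(x)))
  expect_true(all(per_clone == 1L))
  expect_setequal(unique(bps), sim$truth$events$breakpoint_div)
})

test_that("split-read tables round-trip through TSV", {
  reads <- rbind(
    anchored_read("x", anchor_start = 4200, anchor_end = 4340,
                  clip_seq = rand_dna(20), clip_side = "left"),
    anchored_read("y", anchor_start = 4300, anchor_end = 4440))
  f <- tempfile()
  write_split_reads(reads, f)
  expect_identical(read_split_reads(f), reads)
})
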