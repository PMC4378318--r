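test_that("expected cut ends follow the blunting geometry", {
  idx <- toy_index(100L)                      # Sau96I-like: 5-mer, offset 1
  expect_equal(expected_end(idx, "+"), 101L)  # read begins with GNCC
  expect_equal(expected_end(idx, "-"), 104L)  # symmetric cut, exclusive end
  idx0 <- toy_index(100L, cut_offset = 0L)    # offset-0 enzyme: identity case
  expect_equal(expected_end(idx0, "+"), 100L)
  expect_equal(expected_end(idx0, "-"), 105L)
  expect_error(expected_end(idx, "x"), "strand")
})

test_that("reads assign to the nearest site within tolerance", {
  idx <- toy_index(100L)
  hit <- assign_reads(data.frame(chrom = "chr1", strand = "+", five_prime = 101L),
                      idx, tolerance = 2)
  expect_equal(hit$assignments, 1L)
  expect_equal(hit$counts$raw, 1L)

  near <- assign_reads(data.frame(chrom = "chr1", strand = "+", five_prime = 103L),
                       idx, tolerance = 2)
  expect_equal(near$assignments, 1L)          # distance 2 == tolerance

  far <- assign_reads(data.frame(chrom = "chr1", strand = "+", five_prime = 201L),
                      idx, tolerance = 2)
  expect_true(is.na(far$assignments))
  expect_equal(far$log$unassigned_by_reason$no_site_within_tolerance, 1L)

  off <- assign_reads(data.frame(chrom = "chrX", strand = "+", five_prime = 101L),
                      idx, tolerance = 2)
  expect_equal(off$log$unassigned_by_reason$chromosome_not_in_index, 1L)
})

test_that("equidistant reads take the leftmost site", {
  idx <- toy_index(c(100L, 104L))             # cut_plus at 101 and 105
  tie <- assign_reads(data.frame(chrom = "chr1", strand = "+", five_prime = 103L),
                      idx, tolerance = 2)
  expect_equal(tie$assignments, 1L)           # lower motif_start wins
})

test_that("interval assignment equals the brute-force nearest-site oracle", {
  set.seed(77)
  starts <- sort(sample(0:20000, 100))
  idx <- toy_index(starts)
  reads <- data.frame(
    chrom = "chr1",
    strand = sample(c("+", "-"), 1000, replace = TRUE),
    # cluster reads near sites so assignments, ties and misses all occur
    five_prime = pmax(0L, sample(starts, 1000, replace = TRUE) +
                        sample(-6:6, 1000, replace = TRUE)))
  for (tol in c(0L, 2L, 5L)) {
    got <- assign_reads(reads, idx, tolerance = tol)$assignments
    expect_identical(got, oracle_assign(reads, idx, tol))
  }
})

test_that("assignment conserves reads and ignores input order", {
  set.seed(11)
  idx <- toy_index(sort(sample(0:5000, 40)))
  reads <- data.frame(chrom = "chr1",
                      strand = sample(c("+", "-"), 500, replace = TRUE),
                      five_prime = sample(0:5000, 500, replace = TRUE))
  res <- assign_reads(reads, idx, tolerance = 2)
  expect_equal(res$log$n_assigned + res$log$n_unassigned, nrow(reads))
  shuffled <- reads[sample(nrow(reads)), ]
  res2 <- assign_reads(shuffled, idx, tolerance = 2)
  expect_equal(res2$counts$raw, res$counts$raw)
})

test_that("deduplication collapses identical read tuples", {
  idx <- toy_index(100L)
  reads <- data.frame(chrom = "chr1", strand = "+",
                      five_prime = c(101L, 101L, 101L, 102L))
  expect_equal(attr(assign_reads(reads, idx)$counts, "total"), 4)
  dd <- assign_reads(reads, idx, dedup = TRUE)
  expect_equal(attr(dd$counts, "total"), 2)   # two distinct tuples
})

test_that("RPM normalization rescales to a million and preserves raw counts", {
  tab <- cut_count_table(1:2, c(10L, 30L), library = "t")
  tab <- normalize_rpm(tab)
  expect_equal(tab$rpm, c(250000, 750000))
  expect_equal(tab$raw, c(10L, 30L))

  solo <- normalize_rpm(cut_count_table(1L, 5L))
  expect_equal(solo$rpm, 1e6)

  expect_error(normalize_rpm(cut_count_table(1:3, c(0L, 0L, 0L))),
               "empty library")
  expect_error(cut_count_table(1:2, c(-1L, 3L)), "non-negative")
  expect_error(cut_count_table(c(1L, 1L), c(1L, 2L)), "duplicate")
})

test_that("variant summaries expose cleavage-efficiency bias", {
  # 2 GGTCC sites with 10 reads each, 2 each of the others with 5
  idx <- toy_index(seq(0L, 700L, by = 100L),
                   variant = rep(c("GGTCC", "GGACC", "GGCCC", "GGGCC"), each = 2))
  tab <- cut_count_table(idx$site_id,
                         ifelse(idx$variant == "GGTCC", 10L, 5L))
  vf <- variant_cut_frequency(tab, idx)
  expect_equal(nrow(vf), 4L)
  ggtcc <- vf$mean_rpm_per_site[vf$variant == "GGTCC"]
  others <- vf$mean_rpm_per_site[vf$variant != "GGTCC"]
  expect_equal(unique(ggtcc / others), 2.0)
  expect_false(any(vf$absent))

  # a variant with no genomic site is reported with count 0 and flagged
  idx2 <- toy_index(c(0L, 100L), variant = c("GGTCC", "GGACC"))
  vf2 <- variant_cut_frequency(cut_count_table(1:2, c(3L, 3L)), idx2)
  expect_equal(vf2$n_sites[vf2$variant == "GGGCC"], 0L)
  expect_true(vf2$absent[vf2$variant == "GGGCC"])
})

test_that("alignment ingestion derives 5' ends from SAM and BED", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:chr1\tLN:10000",
    # plus read aligned at 1-based 101, 36M
    paste("r1", 0, "chr1", 101, 42, "36M", "*", 0, 0,
          strrep("A", 36), strrep("I", 36), sep = "\t"),
    # minus read whose alignment ends at 1-based 300
    paste("r2", 16, "chr1", 265, 42, "36M", "*", 0, 0,
          strrep("A", 36), strrep("I", 36), sep = "\t")), sam)
  reads <- read_alignments(sam, sample = "s")
  expect_equal(reads$five_prime, c(100L, 300L))
  expect_equal(reads$strand, c("+", "-"))
  expect_equal(reads$sample, rep("s", 2))

  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t101\tr1\t0\t+", "chr1\t299\t300\tr2\t0\t-"), bed)
  rb <- read_alignments(bed)
  expect_equal(rb$five_prime, c(100L, 300L))
})

test_that("count tables round-trip through TSV with site context", {
  g <- simulate_genome(c(chr1 = 20000L), gc_fraction = 0.5, seed = 2)
  idx <- build_index(g, "Sau96I")
  set.seed(3)
  tab <- normalize_rpm(cut_count_table(idx$site_id,
                                       rpois(nrow(idx), 4), library = "lib"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_counts(tab, idx, f)
  back <- read_counts(f, library = "lib")
  expect_equal(back$raw, tab$raw)
  expect_equal(back$rpm, tab$rpm)
  bg <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(tab, idx, bg)
  expect_match(readLines(bg, n = 1), "bedGraph")
})
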