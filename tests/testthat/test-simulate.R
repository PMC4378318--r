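test_that("simulated genomes are reproducible with controlled composition", {
  g1 <- simulate_genome(c(chr1 = 2000L), gc_fraction = 0.5, seed = 1)
  g2 <- simulate_genome(c(chr1 = 2000L), gc_fraction = 0.5, seed = 1)
  expect_identical(as.character(g1), as.character(g2))
  gc1 <- simulate_genome(1500L, gc_fraction = 1, seed = 2)
  expect_false(grepl("[AT]", as.character(gc1[[1]])))
  expect_error(simulate_genome(1500L, gc_fraction = 1.2, seed = 1), "gc_fraction")
  expect_error(simulate_genome(500L, gc_fraction = 0.5, seed = 1), ">= 1 kb")
  expect_error(simulate_genome(1500L, gc_fraction = 0.5), "seed")
})

test_that("site density matches the i.i.d. k-mer expectation at 1 Mb", {
  gc <- 0.42
  g <- simulate_genome(1e6, gc_fraction = gc, seed = 10)
  idx <- build_index(g, "Sau96I")
  pg <- gc / 2; pa <- (1 - gc) / 2
  base_p <- c(A = pa, C = pg, G = pg, T = pa)
  p_kmer <- sum(vapply(iupac_expand("GGNCC"), function(k)
    prod(base_p[strsplit(k, "")[[1]]]), 0))
  expected <- (1e6 - 4) * p_kmer
  expect_lt(abs(nrow(idx) - expected), 3 * sqrt(expected))
})

test_that("motif planting writes exact sequence at exact coordinates", {
  g <- simulate_genome(c(chr1 = 2000L), gc_fraction = 0, seed = 3,
                       plant = data.frame(chrom = "chr1", pos = 777L,
                                          seq = "GGTCC"))
  expect_equal(as.character(Biostrings::subseq(g[[1]], 778, 782)), "GGTCC")
  expect_error(simulate_genome(c(chr1 = 2000L), gc_fraction = 0, seed = 3,
                               plant = data.frame(chrom = "chr1", pos = 1998L,
                                                  seq = "GGTCC")), "overhangs")
})

test_that("cleavage probabilities compose occlusion, variant and NFR factors", {
  plant <- data.frame(chrom = "chr1",
                      pos = c(200L, 1000L, 2000L),
                      seq = "GGACC")
  g <- simulate_genome(c(chr1 = 5000L), gc_fraction = 0, seed = 4, plant = plant)
  idx <- build_index(g, "Sau96I")
  # hand-made model: one canonical core over the second site, one variant
  # core over the third, an NFR over the first
  model <- chromatin_model(c(chr1 = 5000L), seed = 5, variant_fraction = 0)
  model$cores <- data.frame(chrom = "chr1", start = c(950L, 1950L),
                            end = c(1097L, 2097L),
                            class = c("canonical", "variant"))
  model$nfr <- data.frame(chrom = "chr1", start = 150L, end = 350L)
  cfg <- sim_config(seed = 6, p0 = 0.2)
  p <- cut_probabilities(idx, model, cfg)
  cls <- attr(p, "site_class")
  expect_equal(cls, c("nfr", "canonical", "variant"))
  expect_equal(p[1], 0.2)                    # exposed: p0
  expect_equal(p[2], 0.2 * 0.05)             # occluded core
  expect_equal(p[3], 0.2 * 0.25)             # variant: m x occlusion
  expect_equal(p[3] / p[2], 5)

  # per-variant weights multiply in
  model$weights <- c(GGACC = 0.5)
  p2 <- cut_probabilities(idx, model, cfg)
  expect_equal(p2, p * 0.5, ignore_attr = TRUE)

  # naked mode drops the chromatin factors but keeps variant weights
  pn <- cut_probabilities(idx, model, sim_config(seed = 6, p0 = 0.2, naked = TRUE))
  expect_equal(unname(pn), rep(0.2 * 0.5, 3), ignore_attr = TRUE)
  model$weights <- NULL
  pn1 <- cut_probabilities(idx, model, sim_config(seed = 6, p0 = 0.2, naked = TRUE))
  expect_equal(unname(pn1), rep(0.2, 3), ignore_attr = TRUE)
})

test_that("sites outside the model's chromosomes fall back to linker", {
  idx <- toy_index(c(500L, 700L), chrom = c("chr1", "chrZ"))
  model <- chromatin_model(c(chr1 = 3000L), seed = 7)
  cfg <- sim_config(seed = 8, p0 = 0.1)
  expect_warning(p <- cut_probabilities(idx, model, cfg), "chrZ")
  expect_equal(p[idx$chrom == "chrZ"], 0.1, ignore_attr = TRUE)
})

test_that("libraries are reproducible and every read traces to one site", {
  g <- simulate_genome(c(chr1 = 20000L), gc_fraction = 0.5, seed = 20)
  idx <- build_index(g, "Sau96I")
  cfg <- sim_config(seed = 21, n_molecules = 5000L, p0 = 0.05, naked = TRUE)
  p <- cut_probabilities(idx, NULL, cfg)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- generate_library(g, idx, p, cfg, outdir = d1)
  s2 <- generate_library(g, idx, p, cfg, outdir = d2)
  expect_identical(readLines(file.path(d1, "reads.fastq")),
                   readLines(file.path(d2, "reads.fastq")))
  expect_true(all(s1$truth$site_id %in% idx$site_id))
  expect_equal(length(s1$fastq), nrow(s1$truth))
  # read 5' ends sit exactly at the strand-appropriate expected ends
  m <- match(s1$truth$site_id, idx$site_id)
  want <- ifelse(s1$truth$strand == "+", idx$cut_plus[m], idx$cut_minus[m])
  expect_equal(s1$truth$five_prime, want)
  expect_true(all(file.exists(file.path(d1, c("genome.fa", "truth_ends.bed",
                                              "provenance.tsv", "model.json")))))
})

test_that("error-free reads all carry the cleavage signature after the barcode", {
  g <- simulate_genome(c(chr1 = 30000L), gc_fraction = 0.5, seed = 22)
  idx <- build_index(g, "Sau96I")
  cfg <- sim_config(seed = 23, n_molecules = 4000L, p0 = 0.05, naked = TRUE,
                    barcode = "TGCA", sample = "nk")
  sim <- generate_library(g, idx, cut_probabilities(idx, NULL, cfg), cfg)
  dm <- demultiplex(sim$fastq, c(nk = "TGCA"), "Sau96I")
  expect_equal(dm$report$n_unassigned, 0L)
  expect_equal(dm$report$prefix_match_fraction, 1.0)
  # with substitution errors the fraction drops below 1 but stays high
  cfge <- sim_config(seed = 23, n_molecules = 4000L, p0 = 0.05, naked = TRUE,
                     barcode = "TGCA", sample = "nk", error_rate = 0.01)
  sime <- generate_library(g, idx, cut_probabilities(idx, NULL, cfge), cfge)
  fr <- demultiplex(sime$fastq, c(nk = "TGCA"), "Sau96I")$report$prefix_match_fraction
  expect_lt(fr, 1.0)
  expect_gt(fr, 0.9)
})

test_that("recovered RPM tracks truth probabilities across a heterogeneous model", {
  g <- simulate_genome(3e5, gc_fraction = 0.42, seed = 24)
  idx <- build_index(g, "Sau96I")
  model <- chromatin_model(attr(idx, "seqlengths"), seed = 25,
                           variant_fraction = 0.1,
                           weights = c(GGACC = 0.5, GGCCC = 1,
                                       GGGCC = 2, GGTCC = 4))
  cfg <- sim_config(seed = 26, n_molecules = 3e5, p0 = 0.02)
  p <- cut_probabilities(idx, model, cfg)
  sim <- generate_library(g, idx, p, cfg, emit_fastq = FALSE)
  tab <- normalize_rpm(assign_reads(sim$truth, idx)$counts)
  iso <- c(diff(idx$cut_plus) > 400, TRUE) & c(TRUE, diff(idx$cut_plus) > 400)
  expect_gt(cor(p[iso], tab$rpm[iso], method = "spearman"), 0.9)
})

test_that("naked digestion is more uniform than chromatin at equal depth", {
  g <- simulate_genome(2e5, gc_fraction = 0.42, seed = 27)
  idx <- build_index(g, "Sau96I")
  model <- chromatin_model(attr(idx, "seqlengths"), seed = 28)
  nk <- sim_config(seed = 29, n_molecules = 5e4, p0 = 0.02, naked = TRUE,
                   sample = "naked")
  ch <- sim_config(seed = 30, n_molecules = 5e5, p0 = 0.02, sample = "chromatin")
  tab_n <- normalize_rpm(assign_reads(
    generate_library(g, idx, cut_probabilities(idx, NULL, nk), nk,
                     emit_fastq = FALSE)$truth, idx)$counts)
  tab_c <- normalize_rpm(assign_reads(
    generate_library(g, idx, cut_probabilities(idx, model, ch), ch,
                     emit_fastq = FALSE)$truth, idx)$counts)
  cv <- function(x) stats::sd(x) / mean(x)
  expect_lt(cv(tab_n$rpm), cv(tab_c$rpm))
})

test_that("planted NFRs produce a central accessibility peak over the baseline", {
  nfr_centers <- seq(25000L, 275000L, by = 10000L)
  plant <- data.frame(chrom = "chr1",
                      pos = rep(nfr_centers, each = 2) + c(-40L, 40L),
                      seq = "GGACC")
  g <- simulate_genome(c(chr1 = 3e5), gc_fraction = 0.42, seed = 31,
                       plant = plant)
  idx <- build_index(g, "Sau96I")
  nfr <- data.frame(chrom = "chr1", start = nfr_centers - 100L,
                    end = nfr_centers + 100L)
  model <- chromatin_model(attr(idx, "seqlengths"), nfr = nfr, seed = 32,
                           variant_fraction = 0)
  cfg <- sim_config(seed = 33, n_molecules = 2e5, p0 = 0.02)
  sim <- generate_library(g, idx, cut_probabilities(idx, model, cfg), cfg,
                          emit_fastq = FALSE)
  tab <- normalize_rpm(assign_reads(sim$truth, idx)$counts)
  feats <- feature_set("chr1", nfr_centers - 100L, nfr_centers + 100L)
  prof <- metaprofile(tab, feats, flank = 1000, bin = 50, index = idx)
  central <- mean(prof$value[abs(prof$offset + 25) <= 100])
  flank_bins <- mean(prof$value[abs(prof$offset) > 700])
  expect_gt(central, 2 * flank_bins)
  # NFR window scores exceed scores at random positions
  set.seed(34)
  rand <- sample(5000:295000, 30)
  sc_nfr <- window_score(tab, feats, index = idx)
  sc_rand <- window_score(tab, feature_set("chr1", rand - 100L, rand + 100L),
                          index = idx)
  expect_gt(mean(sc_nfr$score), mean(sc_rand$score))
})

test_that("degenerate simulations fail with actionable errors", {
  g <- simulate_genome(c(chr1 = 2000L), gc_fraction = 0, seed = 35,
                       plant = data.frame(chrom = "chr1", pos = 1000L,
                                          seq = "GGACC"))
  idx <- build_index(g, "Sau96I")
  cfg <- sim_config(seed = 36, n_molecules = 5L, p0 = 0.01)
  expect_error(generate_library(g, idx, rep(1e-9, nrow(idx)), cfg),
               "no cut events")
  expect_error(sim_config(seed = 1, p0 = 0), "p0")
  expect_error(sim_config(seed = 1, size_min = 300L, size_max = 200L), "window")
})
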