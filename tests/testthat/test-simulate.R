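test_that("library simulation is seed-deterministic with correct totals", {
  cfg <- sim_config(seed = 11, depth = 1e5, n_replicates = 3)
  pre1 <- simulate_library(cfg)
  pre2 <- simulate_library(cfg)
  expect_identical(pre1, pre2)
  expect_true(all(colSums(pre1) == 1e5))
  pre3 <- simulate_library(sim_config(seed = 12, depth = 1e5, n_replicates = 3))
  expect_false(identical(pre1, pre3))
})

test_that("library skew follows the closed-form Hamming decay", {
  # lambda -> 0: all reads on the master genotype
  cfg0 <- sim_config(seed = 5, lambda = 1e-9, depth = 2e4, n_replicates = 1)
  pre0 <- simulate_library(cfg0)
  expect_identical(unname(pre0["AGGT-ACAT", 1]), 2e4L)

  # lambda = 1: flat weights, master is 1 of 65,536
  cfg1 <- sim_config(seed = 5, lambda = 1, depth = 2e5, n_replicates = 1)
  pre1 <- simulate_library(cfg1)
  expect_lt(max(pre1), 20)  # no genotype dominates a uniform pool

  # lambda = 0.1: share of reads at d = 1 is 8 * 3*lambda / (1+3*lambda)^8
  cfg <- sim_config(seed = 6, lambda = 0.1, depth = 1e6, n_replicates = 2)
  pre <- simulate_library(cfg)
  d <- hamming(rownames(pre))
  frac_d1 <- sum(pre[d == 1L, ]) / sum(pre)
  expected <- 8 * 0.3 / 1.3^8
  expect_equal(frac_d1, expected, tolerance = 0.02)
})

test_that("selection reweights by true fitness", {
  g <- rownames(simulate_library(sim_config(seed = 1, depth = 10,
                                            n_replicates = 1)))
  # two-genotype pool, w = (1, 0): all post reads on the fit genotype
  cfg <- sim_config(seed = 9, depth = 1e4, n_replicates = 2)
  pre <- matrix(c(5000L, 5000L, 4000L, 6000L), 2, 2,
                dimnames = list(c("AGGT-ACAT", "CCCC-GGGG"), c("rep1", "rep2")))
  truth <- data.frame(genotype = rownames(pre), w = c(1, 0))
  post <- simulate_selection(pre, truth, cfg)
  expect_identical(unname(post["AGGT-ACAT", ]), c(1e4L, 1e4L))

  # missing genotype in the truth is an error
  expect_error(simulate_selection(pre, truth[1, , drop = FALSE], cfg),
               "missing")

  # w == 1: post is a fresh multinomial of the pre proportions
  truth1 <- data.frame(genotype = rownames(pre), w = c(1, 1))
  post1 <- simulate_selection(pre, truth1, cfg)
  expect_equal(unname(post1[1, 1]) / 1e4, 0.5, tolerance = 0.05)
})

test_that("selection reduces Shannon diversity of the pool", {
  cfg <- sim_config(seed = 1, depth = 2e5, n_replicates = 2)
  ex <- simulate_experiment(cfg)
  H_pre <- shannon(rowSums(ex$counts[, ex$sheet$selection == "pre"]))
  H_post <- shannon(rowSums(ex$counts[, ex$sheet$selection == "post"]))
  expect_lt(H_post, H_pre)
})

test_that("overdispersion inflates replicate variance", {
  base <- sim_config(seed = 21, depth = 1e5, n_replicates = 6, phi = 0)
  od <- sim_config(seed = 21, depth = 1e5, n_replicates = 6, phi = 0.5)
  p0 <- simulate_library(base)
  p1 <- simulate_library(od)
  d <- hamming(rownames(p0))
  keep <- d <= 1
  cv0 <- apply(p0[keep, ], 1, sd) / rowMeans(p0[keep, ])
  cv1 <- apply(p1[keep, ], 1, sd) / rowMeans(p1[keep, ])
  expect_gt(median(cv1), median(cv0))
})

test_that("FASTQ output is byte-identical under a fixed seed and round-trips", {
  counts <- c("AGGT-ACAT" = 30L, "CGTA-TTAC" = 12L, "AGGT-ACAC" = 7L)
  cfg <- sim_config(seed = 31, error_rate = 0)
  f1 <- tempfile(fileext = ".fastq.gz")
  f2 <- tempfile(fileext = ".fastq.gz")
  write_amplicon_fastq(counts, f1, cfg)
  write_amplicon_fastq(counts, f2, cfg)
  expect_identical(readLines(f1), readLines(f2))

  rt <- parse_amplicons(f1)
  expect_identical(rt[names(counts)], counts)
  qc <- attr(rt, "qc")
  expect_identical(unname(qc["seen"]), 49L)
  expect_identical(unname(qc["passed"]), 49L)
})

test_that("sequencing errors push reads off the master at the expected rate", {
  n <- 4000L
  cfg <- sim_config(seed = 41, error_rate = 0.01)
  f <- tempfile(fileext = ".fastq.gz")
  write_amplicon_fastq(c("AGGT-ACAT" = n), f, cfg)
  counts <- parse_amplicons(f, qmin = 0)
  total <- sum(counts)
  off <- total - counts["AGGT-ACAT"]
  p_off <- 1 - 0.99^8
  # binomial 99.9% interval around the expectation
  expect_lt(abs(off / total - p_off), 3.3 * sqrt(p_off * (1 - p_off) / total))
})
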