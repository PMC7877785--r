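test_that("size factors follow median-of-ratios", {
  m <- matrix(c(10L, 20L, 40L, 10L, 20L, 40L), 3, 2)
  expect_equal(size_factors(m), c(1, 1))
  m2 <- cbind(m[, 1], 2L * m[, 1], m[, 1])
  sf <- size_factors(m2)
  expect_equal(sf[2] / sf[1], 2)
  expect_equal(sf[3], sf[1])

  # brute-force oracle on a random table, and agreement with DESeq2
  set.seed(8)
  r <- matrix(rpois(300, 50) + 1L, 50, 6)
  sf_pkg <- size_factors(r)
  log_gm <- rowMeans(log(r))
  sf_brute <- apply(r, 2, function(col) exp(median(log(col) - log_gm)))
  expect_equal(sf_pkg, sf_brute)
  if (requireNamespace("DESeq2", quietly = TRUE)) {
    expect_equal(unname(sf_pkg),
                 unname(DESeq2::estimateSizeFactorsForMatrix(r)),
                 tolerance = 1e-8)
  }

  # all-zero-sharing table falls back to totals
  z <- matrix(c(0L, 5L, 3L, 0L), 2, 2)
  expect_warning(sfz <- size_factors(z), "total-count")
  expect_equal(sfz[1] / sfz[2], 5 / 3, tolerance = 1e-8)
})

test_that("replicate fitness matches the wildtype-normalised formula", {
  rn <- c("AGGT-ACAT", "AGGT-ACAC")
  pre <- matrix(c(1000L, 100L), 2, 1, dimnames = list(rn, "rep1"))
  post <- matrix(c(2000L, 50L), 2, 1, dimnames = list(rn, "rep1"))
  rf <- replicate_fitness(pre, post, pseudocount = 0.5)
  # plug-in arithmetic from the defining formula
  expect_equal(rf$s["AGGT-ACAC", 1],
               log(50.5 / 2000.5) - log(100.5 / 1000.5))
  expect_equal(rf$s["AGGT-ACAC", 1], -1.381082, tolerance = 1e-5)
  expect_equal(rf$var["AGGT-ACAC", 1],
               1 / 50.5 + 1 / 2000.5 + 1 / 100.5 + 1 / 1000.5)

  # pre == post: s identically zero
  rf0 <- replicate_fitness(pre, pre)
  expect_true(all(rf0$s == 0))

  # genotype doubling against an unchanged master: s = log 2 (pseudocount 0)
  post2 <- pre
  post2["AGGT-ACAC", 1] <- 200L
  rf2 <- replicate_fitness(pre, post2, pseudocount = 0)
  expect_equal(rf2$s["AGGT-ACAC", 1], log(2))

  expect_error(replicate_fitness(pre, post[, c(1, 1)]), "structure")
})

test_that("replicate combination is inverse-variance weighted", {
  s <- matrix(c(0.1, 0.3, 0.2, 0, 0, 0), 2, 3, byrow = TRUE,
              dimnames = list(c("AGGT-ACAC", "AGGT-ACAT"), NULL))
  v <- matrix(1, 2, 3, dimnames = dimnames(s))
  comb <- combine_replicates(list(s = s, var = v))
  expect_equal(comb$s[comb$genotype == "AGGT-ACAC"], mean(c(0.1, 0.3, 0.2)))
  expect_equal(comb$f[comb$genotype == "AGGT-ACAT"], 1)

  # an infinite-variance replicate is ignored
  v2 <- v
  v2["AGGT-ACAC", 2] <- Inf
  comb2 <- combine_replicates(list(s = s, var = v2))
  expect_equal(comb2$s[comb2$genotype == "AGGT-ACAC"], mean(c(0.1, 0.2)))

  # all variances infinite: unestimable
  v3 <- v
  v3["AGGT-ACAC", ] <- Inf
  comb3 <- combine_replicates(list(s = s, var = v3))
  expect_true(is.na(comb3$s[comb3$genotype == "AGGT-ACAC"]))
})

test_that("differential test is calibrated at the trivial points", {
  d <- test_differential(c(0, 1, -2), c(1, 0.5, 0.5))
  expect_equal(d$p[1], 1)
  expect_identical(order(d$p), order(d$p_adj))  # BH is monotone
})

test_that("log2 fold-change matches brute-force recomputation", {
  set.seed(3)
  pre <- matrix(rpois(40, 200), 10, 4) + 1L
  post <- matrix(rpois(40, 200), 10, 4) + 1L
  fc <- log2_foldchange(pre, post)
  sf <- size_factors(cbind(pre, post))
  brute <- log2((rowMeans(sweep(post, 2, sf[5:8], "/")) + 0.5) /
                  (rowMeans(sweep(pre, 2, sf[1:4], "/")) + 0.5))
  expect_equal(fc, brute)
  # pooled post == pooled pre: 0
  expect_equal(log2_foldchange(pre, pre), rep(0, 10))
  # post = 4 x pre: 2 (equal size factors cancel the scaling)
  big <- matrix(1000L, 5, 2)
  expect_equal(log2_foldchange(big, 4L * big, sf = rep(1, 4)),
               rep(log2((4000 + 0.5) / (1000 + 0.5)), 5), tolerance = 1e-12)
})

test_that("fitness_table recovers simulated truth on well-covered genotypes", {
  cfg <- sim_config(seed = 5, depth = 2e5, n_replicates = 4)
  ex <- simulate_experiment(cfg, noise = FALSE)
  ft <- fitness_table(ex$counts, ex$sheet, temperature = "30")
  expect_equal(ft$f[ft$genotype == "AGGT-ACAT"], 1)
  w <- ex$truth$w[match(ft$genotype, ex$truth$genotype)]
  keep <- ft$n_pre / 4 >= 50
  rho <- cor(ft$f[keep], w[keep], method = "spearman")
  expect_gt(rho, 0.85)
  # genotypes never seen before selection are missing, not zero
  expect_true(all(is.na(ft$f[ft$n_pre == 0])))
})
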