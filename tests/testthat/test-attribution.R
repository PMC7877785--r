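# A reduced configuration keeps the tree models light; the complete tuning
# grid is exercised implicitly through the same code path.
fast_cfg <- function(seed = 1) {
  attr_config(nrounds = 60L, eta = 0.3, max_depth = 4L, nfold = 3L,
              seed = seed)
}

test_that("one-hot features have one base per site block", {
  g <- c("AGGT-ACAT", "CCCC-GGGG")
  X <- one_hot_features(g)
  expect_identical(dim(X), c(2L, 32L))
  for (site in GENOTYPE_SITES) {
    block <- X[, grepl(paste0("^[ACGT]", site, "$"), colnames(X))]
    expect_equal(unname(rowSums(block)), c(1, 1))
  }
  expect_equal(unname(X["AGGT-ACAT", "A2"]), 1)
  expect_equal(unname(X["AGGT-ACAT", "C2"]), 0)
})

test_that("a deterministic single-feature signal is learnt and attributed", {
  set.seed(30)
  g <- sample(enumerate_genotypes(), 4000)
  X <- one_hot_features(g)
  y <- ifelse(X[, "C21"] == 1, 1, 0)
  fit <- train_gbm(X, y, fast_cfg())
  expect_gt(fit$rho_test, 0.99)

  ds <- delta_shap(fit, X)
  c21 <- ds$delta_shap[ds$feature == "C21"]
  expect_gt(c21, 0)
  expect_gt(c21, 2 * max(abs(ds$delta_shap[ds$feature != "C21"])))

  # gain concentrates on site 21 features
  gs1 <- gain_share_test(fit, sites = 18:21, n_shuffles = 100, seed = 2)
  expect_gt(gs1$observed, 0.99)
})

test_that("signal spread over one region drives its gain share above the null", {
  set.seed(36)
  g <- sample(enumerate_genotypes(), 4000)
  X <- one_hot_features(g)
  right <- grepl("1[89]$|2[01]$", colnames(X))
  beta <- runif(sum(right), 0.5, 1.5)
  y <- as.numeric(X[, right] %*% beta)
  fit <- train_gbm(X, y, fast_cfg())
  gs <- gain_share_test(fit, sites = 18:21, n_shuffles = 200, seed = 2)
  expect_gt(gs$observed, 0.95)
  expect_gt(gs$observed, gs$ci[[2]])
  expect_lt(gs$p_greater, 0.05)
})

test_that("pure noise yields no held-out accuracy", {
  set.seed(31)
  g <- sample(enumerate_genotypes(), 3000)
  X <- one_hot_features(g)
  y <- rnorm(nrow(X))
  fit <- train_gbm(X, y, fast_cfg())
  expect_lt(abs(fit$rho_test), 0.1)
})

test_that("SHAP values satisfy local accuracy", {
  set.seed(32)
  g <- sample(enumerate_genotypes(), 3000)
  X <- one_hot_features(g)
  tl <- true_landscape(g)
  y <- log2(pmax(tl$w, 1e-10))
  fit <- train_gbm(X, y, fast_cfg())
  sh <- shap_values(fit, X)
  pred <- predict(fit$model, xgboost::xgb.DMatrix(X))
  scale <- diff(range(y))
  expect_lt(max(abs(rowSums(sh) - pred)), 1e-5 * scale)
})

test_that("a constant response gives zero SHAP everywhere", {
  set.seed(33)
  g <- sample(enumerate_genotypes(), 1500)
  X <- one_hot_features(g)
  fit <- train_gbm(X, rep(2.5, nrow(X)), fast_cfg())
  ds <- delta_shap(fit, X)
  expect_true(all(abs(ds$delta_shap) < 1e-8 | is.na(ds$delta_shap)))
})

test_that("permutation null of the gain share is centred on the region size", {
  set.seed(34)
  g <- sample(enumerate_genotypes(), 3000)
  X <- one_hot_features(g)
  tl <- true_landscape(g)
  fit <- train_gbm(X, log2(pmax(tl$w, 1e-10)), fast_cfg())
  gs <- gain_share_test(fit, sites = 18:21, n_shuffles = 400, seed = 3)
  expect_equal(gs$null_mean, 16 / 32, tolerance = 0.06)
})

test_that("identical replicates give LORO accuracy equal to held-out accuracy", {
  set.seed(35)
  g <- sample(enumerate_genotypes(), 2000)
  tl <- true_landscape(g)
  pre <- matrix(rep(200L, length(g) * 3), ncol = 3)
  post <- matrix(rep(as.integer(round(200 * tl$w * 50)), 3), ncol = 3)
  counts <- cbind(pre, post)
  rownames(counts) <- tl$genotype
  colnames(counts) <- c(paste0("r", 1:3, "_pre"), paste0("r", 1:3, "_post"))
  sheet <- sample_sheet(colnames(counts), rep(1:3, 2),
                        rep(c("pre", "post"), each = 3))
  loro <- leave_one_replicate_out(counts, sheet, config = fast_cfg())
  expect_equal(unname(loro$per_replicate),
               rep(loro$per_replicate[[1]], 3))
  # pooled-response fit on the same split gives the same accuracy
  fc <- log2_foldchange(counts[, 1:3], counts[, 4:6])
  fit <- train_gbm(one_hot_features(rownames(counts)), fc, fast_cfg())
  expect_equal(unname(loro$per_replicate[[1]]), fit$rho_test, tolerance = 0.02)
})
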