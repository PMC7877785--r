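## Gradient-boosted-tree modelling of fold-change from one-hot
## site/nucleotide features, exact tree SHAP attribution, ΔSHAP
## aggregation, the gain-share permutation test, and leave-one-replicate-out
## accuracy.

#' One-hot feature matrix of site/nucleotide identities
#'
#' 32 binary features (8 sites x 4 nucleotides); each genotype's eight
#' site-blocks sum to 1. Feature names encode base and site, e.g. `"C21"`.
#'
#' @param g Character vector of genotypes.
#' @return Numeric matrix (`length(g)` x 32) with genotype rownames.
#' @export
one_hot_features <- function(g) {
  m <- gt_base_matrix(g)
  cols <- as.vector(outer(GT_ALPHABET, GENOTYPE_SITES, paste0))
  out <- matrix(0, nrow(m), length(cols), dimnames = list(gt_format(g), cols))
  for (i in seq_len(8L)) {
    for (b in GT_ALPHABET) {
      out[, paste0(b, GENOTYPE_SITES[i])] <- as.numeric(m[, i] == b)
    }
  }
  out
}

#' Training configuration for the gradient-boosted model
#'
#' The default grid is a reduced, fast subset; `full_grid = TRUE` restores
#' the complete tuning grid (nrounds 100/200/500/1000, eta
#' 0.01/0.05/0.1/0.3, depth 4/6/8/10, subsample 0.5/0.75/1, min child
#' weight 5/10/20), which is desk-feasible but slow.
#'
#' @param nrounds,eta,max_depth,subsample,min_child_weight Candidate values.
#' @param nfold Cross-validation folds on the training split (default 5).
#' @param train_frac Fraction of genotypes used for training (default 2/3).
#' @param seed RNG seed for the split, the CV folds and xgboost.
#' @param full_grid Use the complete grid?
#' @param nthread Threads for xgboost (default 1, reproducible).
#' @return An `attr_config` list.
#' @export
attr_config <- function(nrounds = c(100L, 200L), eta = c(0.1, 0.3),
                        max_depth = c(4L, 6L), subsample = 0.75,
                        min_child_weight = 10, nfold = 5L,
                        train_frac = 2 / 3, seed = 1L, full_grid = FALSE,
                        nthread = 1L) {
  cfg <- as.list(environment())
  if (full_grid) {
    cfg$nrounds <- c(100L, 200L, 500L, 1000L)
    cfg$eta <- c(0.01, 0.05, 0.1, 0.3)
    cfg$max_depth <- c(4L, 6L, 8L, 10L)
    cfg$subsample <- c(0.5, 0.75, 1.0)
    cfg$min_child_weight <- c(5, 10, 20)
  }
  structure(cfg, class = "attr_config")
}

#' Train a gradient-boosted regression model of fold-change
#'
#' Two-thirds of the genotypes are used for training with k-fold
#' cross-validated grid search (RMSE objective); accuracy is the Spearman
#' correlation between predictions and observations on the held-out third.
#' colsample_bytree and gamma are fixed at 1.
#'
#' @param features Matrix from [one_hot_features()].
#' @param response Numeric response per genotype (log2 fold-change by
#'   default convention; relative fitness works equally).
#' @param config [attr_config()].
#' @return List with `model` (xgb.Booster), `best` (chosen
#'   hyperparameters), `rho_test` (held-out Spearman), `train_idx`,
#'   `test_idx`, `pred_test`.
#' @export
train_gbm <- function(features, response, config = attr_config()) {
  keep <- is.finite(response)
  features <- features[keep, , drop = FALSE]
  response <- response[keep]
  if (nrow(features) < 1000L) {
    stop("need at least 1,000 genotypes with a response; got ", nrow(features))
  }
  set.seed(config$seed)
  n <- nrow(features)
  train_idx <- sort(sample.int(n, round(config$train_frac * n)))
  test_idx <- setdiff(seq_len(n), train_idx)
  dtrain <- xgboost::xgb.DMatrix(features[train_idx, , drop = FALSE],
                                 label = response[train_idx])
  grid <- expand.grid(nrounds = config$nrounds, eta = config$eta,
                      max_depth = config$max_depth,
                      subsample = config$subsample,
                      min_child_weight = config$min_child_weight)
  cv_rmse <- numeric(nrow(grid))
  for (k in seq_len(nrow(grid))) {
    set.seed(config$seed + 1L)
    cv <- xgboost::xgb.cv(
      params = list(objective = "reg:squarederror", eta = grid$eta[k],
                    max_depth = grid$max_depth[k],
                    subsample = grid$subsample[k],
                    min_child_weight = grid$min_child_weight[k],
                    colsample_bytree = 1, gamma = 1,
                    nthread = config$nthread),
      data = dtrain, nrounds = grid$nrounds[k], nfold = config$nfold,
      metrics = "rmse", verbose = FALSE)
    log <- cv$evaluation_log
    cv_rmse[k] <- log$test_rmse_mean[nrow(log)]
  }
  best <- grid[which.min(cv_rmse), ]
  set.seed(config$seed + 2L)
  model <- xgboost::xgb.train(
    params = list(objective = "reg:squarederror", eta = best$eta,
                  max_depth = best$max_depth, subsample = best$subsample,
                  min_child_weight = best$min_child_weight,
                  colsample_bytree = 1, gamma = 1, nthread = config$nthread),
    data = dtrain, nrounds = best$nrounds, verbose = 0)
  pred <- stats::predict(model,
                         xgboost::xgb.DMatrix(features[test_idx, , drop = FALSE]))
  rho <- if (stats::sd(pred) == 0 || stats::sd(response[test_idx]) == 0)
    NA_real_ else stats::cor(pred, response[test_idx], method = "spearman")
  list(model = model, best = best, rho_test = rho,
       train_idx = train_idx, test_idx = test_idx, pred_test = pred,
       feature_names = colnames(features))
}

#' Exact SHAP values of a fitted tree model
#'
#' Tree-path-dependent SHAP contributions (exact for tree ensembles); each
#' row satisfies local accuracy: base value + sum of contributions equals
#' the model prediction.
#'
#' @param fit Result of [train_gbm()] (or an xgb.Booster).
#' @param features Feature matrix to explain.
#' @return Numeric matrix (`nrow(features)` x 33): 32 feature columns plus
#'   `BIAS`.
#' @export
shap_values <- function(fit, features) {
  model <- if (inherits(fit, "xgb.Booster")) fit else fit$model
  stats::predict(model, xgboost::xgb.DMatrix(features), predcontrib = TRUE)
}

#' Average feature contribution, present minus absent
#'
#' `delta_shap(feature) = mean SHAP over genotypes where the feature is
#' present - mean over genotypes where it is absent`.
#'
#' @param fit Result of [train_gbm()].
#' @param features Feature matrix (typically the full genotype space).
#' @param shap Optional precomputed [shap_values()] matrix.
#' @return Data frame with `feature`, `site`, `base`, `delta_shap`,
#'   `n_present`; features constant across genotypes give `NA`.
#' @export
delta_shap <- function(fit, features, shap = NULL) {
  if (is.null(shap)) shap <- shap_values(fit, features)
  nm <- colnames(features)
  out <- lapply(seq_along(nm), function(j) {
    present <- features[, j] == 1
    ds <- if (!any(present) || all(present)) NA_real_ else
      mean(shap[present, j]) - mean(shap[!present, j])
    data.frame(feature = nm[j],
               base = substr(nm[j], 1L, 1L),
               site = as.integer(substring(nm[j], 2L)),
               delta_shap = ds, n_present = sum(present))
  })
  do.call(rbind, out)
}

#' Gain share of a site region with a permutation null
#'
#' Observed share of total model gain attributable to features of the given
#' sites, compared with the null distribution obtained by randomly
#' shuffling the per-feature gains across all 32 site/nucleotide features
#' (features the model never split on carry gain 0).
#'
#' @param fit Result of [train_gbm()].
#' @param sites Sites defining the region (default 18:21).
#' @param n_shuffles Number of random shuffles (default 100).
#' @param seed RNG seed for the shuffles.
#' @return List with `observed`, `null_mean`, `ci` (2.5/97.5 percentiles),
#'   `p_greater` (permutation tail), and the per-feature `gains`.
#' @export
gain_share_test <- function(fit, sites = 18:21, n_shuffles = 100L, seed = 1L) {
  imp <- xgboost::xgb.importance(model = fit$model)
  gains <- stats::setNames(rep(0, length(fit$feature_names)),
                           fit$feature_names)
  gains[imp$Feature] <- imp$Gain
  total <- sum(gains)
  if (total <= 0) stop("model has zero total gain")
  region <- as.integer(substring(names(gains), 2L)) %in% sites
  observed <- sum(gains[region]) / total
  set.seed(seed)
  null_share <- vapply(seq_len(n_shuffles), function(i) {
    sum(sample(gains)[region]) / total
  }, numeric(1L))
  list(observed = observed, null_mean = mean(null_share),
       ci = stats::quantile(null_share, c(0.025, 0.975)),
       p_greater = (sum(null_share >= observed) + 1) / (n_shuffles + 1),
       gains = gains)
}

#' Leave-one-replicate-out prediction accuracy
#'
#' For each replicate r, the response (pooled log2 fold-change) is
#' recomputed from the remaining replicates, a model is trained on the
#' training split of that response, and accuracy is the Spearman
#' correlation between the model's held-out predictions and replicate r's
#' own single-replicate fold-change.
#'
#' @param counts Count matrix (genotype x sample).
#' @param sheet [sample_sheet()].
#' @param temperature Condition to analyse.
#' @param config [attr_config()].
#' @param pseudocount Pseudocount for fold-changes.
#' @return List with `per_replicate` (named numeric) and `mean_rho`.
#' @export
leave_one_replicate_out <- function(counts, sheet, temperature = "30",
                                    config = attr_config(),
                                    pseudocount = 0.5) {
  sh <- sheet[sheet$temperature == as.character(temperature), , drop = FALSE]
  reps <- sort(unique(sh$replicate))
  if (length(reps) < 3L) stop("need at least 3 replicates")
  pre_ids <- vapply(reps, function(r)
    sh$sample[sh$replicate == r & sh$selection == "pre"][1L], character(1L))
  post_ids <- vapply(reps, function(r)
    sh$sample[sh$replicate == r & sh$selection == "post"][1L], character(1L))
  X <- one_hot_features(rownames(counts))
  rho <- vapply(seq_along(reps), function(k) {
    train_fc <- log2_foldchange(counts[, pre_ids[-k], drop = FALSE],
                                counts[, post_ids[-k], drop = FALSE],
                                pseudocount = pseudocount)
    test_fc <- log2_foldchange(counts[, pre_ids[k], drop = FALSE],
                               counts[, post_ids[k], drop = FALSE],
                               pseudocount = pseudocount)
    fit <- train_gbm(X, train_fc, config)
    stats::cor(fit$pred_test, test_fc[fit$test_idx], method = "spearman")
  }, numeric(1L))
  names(rho) <- paste0("rep", reps)
  list(per_replicate = rho, mean_rho = mean(rho))
}
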