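## Diversity metrics, distribution-of-fitness-effects summaries, and simple
## fitness correlates.

#' Shannon diversity of a genotype pool
#'
#' `H = -sum(p log p)` over nonzero proportions, computed with
#' `vegan::diversity`. Natural log by default.
#'
#' @param counts Nonnegative count vector (or matrix with samples in
#'   columns, returning one value per column).
#' @param base Logarithm base (default `exp(1)`).
#' @return Numeric vector of diversities.
#' @export
shannon <- function(counts, base = exp(1)) {
  if (is.matrix(counts)) {
    if (any(colSums(counts) <= 0)) stop("zero total count in a sample")
    return(vegan::diversity(t(counts), index = "shannon", base = base))
  }
  if (sum(counts) <= 0) stop("zero total count")
  unname(vegan::diversity(counts, index = "shannon", base = base))
}

#' Bray-Curtis dissimilarity
#'
#' `BC = sum |x - y| / sum (x + y)`, in `[0, 1]`; 1 indicates maximum
#' dissimilarity (disjoint supports). For a matrix, returns the full
#' pairwise `dist` via `vegan::vegdist`.
#'
#' @param x Count vector, or matrix with samples in columns.
#' @param y Second count vector (ignored for matrix input).
#' @return A single dissimilarity, or a `dist` object for matrix input.
#' @export
bray_curtis <- function(x, y = NULL) {
  if (is.matrix(x)) {
    return(vegan::vegdist(t(x), method = "bray"))
  }
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  if (sum(x) + sum(y) <= 0) stop("both vectors are all-zero")
  as.numeric(vegan::vegdist(rbind(x, y), method = "bray"))
}

## moment-based skewness and (non-excess) kurtosis
moment_skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  mean((x - m)^3) / mean((x - m)^2)^1.5
}

moment_kurtosis <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  mean((x - m)^4) / mean((x - m)^2)^2
}

#' Summary of the distribution of fitness effects
#'
#' Moment statistics of the fitness distribution plus a two-component
#' Gaussian mixture fit on log fitness (via `mclust`) as a bimodality
#' summary: component means, standard deviations and weights, and whether
#' the two modes are well separated (mean difference exceeding twice each
#' component standard deviation).
#'
#' @param f Numeric vector of relative fitness values (`NA` and
#'   nonpositive values are dropped for the log-scale mixture).
#' @param breaks Histogram breaks (passed to [hist()], not plotted).
#' @return List with `n`, `mean`, `median`, `skewness`, `kurtosis`
#'   (non-excess), `histogram`, and `mixture` (means/sds/weights on log
#'   fitness, plus `ashman_d` and `bimodal`, true when Ashman's D > 2).
#' @export
dfe_summary <- function(f, breaks = 50) {
  stopifnot(sum(is.finite(f)) >= 2)
  fv <- f[is.finite(f)]
  h <- graphics::hist(fv, breaks = breaks, plot = FALSE)
  lf <- log(fv[fv > 0])
  mix <- NULL
  if (length(lf) >= 10) {
    mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller
    fit <- mclust::Mclust(lf, G = 2, modelNames = "V", verbose = FALSE)
    if (is.null(fit)) {
      fit <- mclust::Mclust(lf, G = 2, modelNames = "E", verbose = FALSE)
    }
    if (!is.null(fit)) {
      mu <- as.numeric(fit$parameters$mean)
      sd <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
      if (length(sd) == 1L) sd <- rep(sd, 2L)
      pro <- as.numeric(fit$parameters$pro)
      ord <- order(mu)
      ## Ashman's D: component separation relative to within-component spread
      D <- abs(diff(mu)) / sqrt(mean(sd^2))
      mix <- list(means = mu[ord], sds = sd[ord], weights = pro[ord],
                  ashman_d = D, bimodal = D > 2)
    }
  }
  list(n = length(fv), mean = mean(fv), median = stats::median(fv),
       skewness = moment_skewness(fv), kurtosis = moment_kurtosis(fv),
       histogram = h, mixture = mix)
}

#' Fitness summarised by Hamming distance from a reference
#'
#' @param fitness [fitness_table()] or data frame with `genotype` and `f`.
#' @param reference Reference genotype (default master).
#' @return Data frame per distance `d`: `n`, `median`, `q25`, `q75`.
#' @export
fitness_by_hamming <- function(fitness, reference = MASTER_GENOTYPE) {
  f <- if (!is.null(fitness$f)) fitness$f else fitness$w
  d <- hamming(fitness$genotype, reference)
  sp <- split(f, d)
  out <- data.frame(
    d = as.integer(names(sp)),
    n = vapply(sp, function(x) sum(is.finite(x)), integer(1L)),
    median = vapply(sp, function(x) stats::median(x, na.rm = TRUE), numeric(1L)),
    q25 = vapply(sp, function(x) unname(stats::quantile(x, 0.25, na.rm = TRUE)),
                 numeric(1L)),
    q75 = vapply(sp, function(x) unname(stats::quantile(x, 0.75, na.rm = TRUE)),
                 numeric(1L))
  )
  rownames(out) <- NULL
  out[order(out$d), ]
}

#' Number of G or C bases among the eight variable sites
#'
#' @param g Character vector of genotypes.
#' @return Integer vector in `[0, 8]`.
#' @export
gc_count <- function(g) {
  m <- gt_base_matrix(g)
  as.integer(rowSums(m == "G" | m == "C"))
}

#' Spearman correlations between fitness and simple features
#'
#' Rank correlation (midranks for ties) between fitness and each supplied
#' feature, e.g. GC count or forced-helix free energy.
#'
#' @param fitness Numeric fitness vector.
#' @param features Named list or data frame of numeric features, same
#'   length as `fitness`.
#' @return Data frame with `feature`, `rho`, `n`; constant features give
#'   `NA` with a note in the `note` column.
#' @export
feature_correlates <- function(fitness, features) {
  features <- as.data.frame(features)
  out <- lapply(names(features), function(nm) {
    x <- features[[nm]]
    keep <- is.finite(fitness) & is.finite(x)
    if (stats::sd(x[keep]) == 0) {
      return(data.frame(feature = nm, rho = NA_real_, n = sum(keep),
                        note = "constant feature"))
    }
    data.frame(feature = nm,
               rho = stats::cor(fitness[keep], x[keep], method = "spearman"),
               n = sum(keep), note = "")
  })
  do.call(rbind, out)
}
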