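## Count-to-fitness estimation: wildtype-normalised per-replicate log
## fold-changes combined by inverse-variance weighting, with a
## median-of-ratios normalised pooled log2 fold-change alongside.

#' Median-of-ratios size factors
#'
#' Per-sample scaling factors computed as the median, over genotypes with
#' nonzero counts in every sample, of the ratio of the sample's count to the
#' genotype's geometric mean across samples. Falls back to total-count
#' normalisation (with a warning) when no genotype is shared by all samples.
#'
#' @param counts Integer matrix (genotype x sample).
#' @return Numeric vector of positive factors, one per column.
#' @export
size_factors <- function(counts) {
  all_nz <- rowSums(counts == 0L) == 0L
  if (!any(all_nz)) {
    warning("no genotype observed in all samples; ",
            "falling back to total-count normalisation")
    tot <- colSums(counts)
    return(tot / exp(mean(log(tot))))
  }
  m <- counts[all_nz, , drop = FALSE]
  log_gm <- rowMeans(log(m))
  apply(m, 2L, function(col) exp(stats::median(log(col) - log_gm)))
}

#' Per-replicate wildtype-normalised log fitness
#'
#' For replicate `r` and genotype `g`,
#' `s_r(g) = log[(n_post(g)+c) / (n_post(master)+c)] -
#'           log[(n_pre(g)+c) / (n_pre(master)+c)]`,
#' with Poisson error propagation
#' `var_r(g) = sum of 1/(n+c)` over the four counts involved.
#'
#' @param pre,post Integer matrices (genotype x replicate), equal dimensions
#'   and matching columns.
#' @param master Row name or index of the master genotype (default: the
#'   master sequence).
#' @param pseudocount Added to every count (default 0.5).
#' @return List with matrices `s` and `var` (genotype x replicate).
#' @export
replicate_fitness <- function(pre, post, master = MASTER_GENOTYPE,
                              pseudocount = 0.5) {
  if (!all(dim(pre) == dim(post))) stop("pre/post replicate structure differs")
  im <- if (is.character(master)) match(gt_format(master), rownames(pre)) else master
  if (is.na(im)) stop("master genotype not found in count table")
  c0 <- pseudocount
  s <- log((post + c0) / rep((post[im, ] + c0), each = nrow(post))) -
    log((pre + c0) / rep((pre[im, ] + c0), each = nrow(pre)))
  v <- 1 / (post + c0) + 1 / (pre + c0) +
    rep(1 / (post[im, ] + c0) + 1 / (pre[im, ] + c0), each = nrow(pre))
  list(s = s, var = v)
}

#' Combine replicate fitness estimates
#'
#' Error-weighted combination: `s = sum(w_r s_r) / sum(w_r)` with
#' `w_r = 1/var_r`; the nominal standard error `1/sqrt(sum w_r)` is inflated
#' by the between-replicate dispersion factor
#' `max(1, chi^2/(R-1))` when replicate scatter exceeds the Poisson
#' expectation. Fitness is `exp(s)` rescaled so the master is exactly 1.
#'
#' @param rep_fit List from [replicate_fitness()].
#' @param master Row identifying the master genotype for rescaling.
#' @return Data frame with `s`, `se`, `f` (relative fitness, master = 1) and
#'   `dispersion`; genotypes with no finite-variance replicate are `NA`
#'   (unestimable).
#' @export
combine_replicates <- function(rep_fit, master = MASTER_GENOTYPE) {
  s_r <- rep_fit$s
  w_r <- 1 / rep_fit$var
  bad <- !is.finite(s_r) | !is.finite(w_r)
  w_r[bad] <- 0
  s_r[bad] <- 0
  wsum <- rowSums(w_r)
  nrep <- rowSums(w_r > 0)
  s <- rowSums(w_r * s_r) / wsum
  chi2 <- rowSums(w_r * (s_r - s)^2)
  disp <- ifelse(nrep > 1L, pmax(1, chi2 / pmax(nrep - 1L, 1L)), 1)
  se <- sqrt(disp / wsum)
  s[nrep == 0L] <- NA_real_
  se[nrep == 0L] <- NA_real_
  im <- if (is.character(master)) match(gt_format(master), rownames(s_r)) else master
  s0 <- s[im]
  data.frame(genotype = rownames(s_r), s = s - s0, se = se,
             f = exp(s - s0), dispersion = disp)
}

#' Two-sided significance of fitness differences with BH adjustment
#'
#' z-test of `s/se` against zero, Benjamini-Hochberg adjusted across all
#' tested genotypes.
#'
#' @param s,se Numeric vectors of combined log fitness and standard error.
#' @return Data frame with `p` and `p_adj`.
#' @export
test_differential <- function(s, se) {
  z <- s / se
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(p = p, p_adj = stats::p.adjust(p, method = "BH"))
}

#' Pooled, size-factor-normalised log2 fold-change
#'
#' log2 of the ratio of pooled normalised post-selection to pre-selection
#' counts (with pseudocount), the differential-abundance style companion to
#' the wildtype-normalised fitness estimate.
#'
#' @param pre,post Integer matrices (genotype x replicate).
#' @param sf Size factors for `cbind(pre, post)` (default: computed).
#' @param pseudocount Added to pooled normalised counts (default 0.5).
#' @return Numeric vector of log2 fold-changes.
#' @export
log2_foldchange <- function(pre, post, sf = NULL, pseudocount = 0.5) {
  if (is.null(sf)) sf <- size_factors(cbind(pre, post))
  k <- ncol(pre)
  pre_n <- sweep(pre, 2L, sf[seq_len(k)], "/")
  post_n <- sweep(post, 2L, sf[k + seq_len(ncol(post))], "/")
  log2((rowMeans(post_n) + pseudocount) / (rowMeans(pre_n) + pseudocount))
}

#' Estimate fitness for one condition of an experiment
#'
#' End-to-end estimation from a count table and sample sheet: selects the
#' pre/post columns of one temperature, computes per-replicate
#' wildtype-normalised fitness, combines replicates with inverse-variance
#' weights, and attaches pooled log2 fold-changes and BH-adjusted
#' significance. Genotypes with zero counts across all pre-selection
#' samples are reported with `NA` fitness (missing), not fitness 0.
#'
#' @param counts Integer matrix (genotype x sample).
#' @param sheet [sample_sheet()] describing the columns.
#' @param temperature Condition to analyse (default `"30"`).
#' @param pseudocount Pseudocount (default 0.5).
#' @return A `fitness_table` data frame: `genotype`, `f`, `log2FC`, `s`,
#'   `se`, `p`, `p_adj`, `n_pre`, `n_post`, `condition`.
#' @export
fitness_table <- function(counts, sheet, temperature = "30",
                          pseudocount = 0.5) {
  sel <- sheet$temperature == as.character(temperature)
  if (!any(sel)) stop("no samples at temperature ", temperature)
  sh <- sheet[sel, , drop = FALSE]
  reps <- sort(unique(sh$replicate))
  pre_ids <- vapply(reps, function(r)
    sh$sample[sh$replicate == r & sh$selection == "pre"][1L], character(1L))
  post_ids <- vapply(reps, function(r)
    sh$sample[sh$replicate == r & sh$selection == "post"][1L], character(1L))
  if (anyNA(pre_ids) || anyNA(post_ids)) {
    stop("each replicate needs one pre and one post sample")
  }
  pre <- counts[, pre_ids, drop = FALSE]
  post <- counts[, post_ids, drop = FALSE]
  rf <- replicate_fitness(pre, post, pseudocount = pseudocount)
  comb <- combine_replicates(rf)
  tst <- test_differential(comb$s, comb$se)
  out <- data.frame(
    genotype = rownames(counts),
    f = comb$f, log2FC = log2_foldchange(pre, post, pseudocount = pseudocount),
    s = comb$s, se = comb$se, p = tst$p, p_adj = tst$p_adj,
    n_pre = rowSums(pre), n_post = rowSums(post),
    condition = paste0(temperature, "C")
  )
  missing <- out$n_pre == 0L
  out$f[missing] <- NA_real_
  out$s[missing] <- NA_real_
  class(out) <- c("fitness_table", "data.frame")
  out
}
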