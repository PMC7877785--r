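## Pairwise epistasis, region-partitioned epistasis, the correlation of
## fitness effects gamma(d), and the helix mirror test.

#' Pairwise epistasis on the log10 scale
#'
#' `epsilon = log10(f_master * f_m12 / (f_m1 * f_m2))`, with fitness
#' relative to the master (master = 1). Positive values indicate the double
#' mutant is fitter than the multiplicative expectation. Records with any
#' nonpositive or missing fitness are undefined (`NA`), never clipped.
#'
#' @param f_master,f_m1,f_m2,f_m12 Fitness of the reference, the two single
#'   mutants and the double mutant (vectorised).
#' @return Numeric vector of epsilon values.
#' @export
pairwise_epsilon <- function(f_master, f_m1, f_m2, f_m12) {
  ok <- is.finite(f_master) & is.finite(f_m1) & is.finite(f_m2) &
    is.finite(f_m12) & f_master > 0 & f_m1 > 0 & f_m2 > 0 & f_m12 > 0
  out <- rep(NA_real_, length(ok))
  out[ok] <- log10(f_master[ok] * f_m12[ok] / (f_m1[ok] * f_m2[ok]))
  out
}

## internal: fitness lookup by bare genotype key; accepts estimated tables
## (column f) and true landscapes (column w)
fitness_lookup <- function(fitness) {
  f <- if (!is.null(fitness$f)) fitness$f else fitness$w
  if (is.null(f)) stop("fitness data needs an 'f' (or 'w') column")
  stats::setNames(f, gt_parse(fitness$genotype))
}

#' Pairwise epistasis map for all double mutants of a reference
#'
#' Enumerates every site pair and allele pair two mutations away from the
#' reference (`C(8,2) * 9 = 252` records when the table is complete) and
#' computes epsilon for each. Records are classed by the location of the
#' two mutated sites: both within N2..N5 (`within_2_5`), both within
#' N18..N21 (`within_18_21`), or one in each (`cross_helix`).
#'
#' @param fitness Data frame with `genotype` and `f` (master fitness 1).
#' @param reference Reference genotype (default master).
#' @return Data frame with one row per (site pair, allele pair): `site1`,
#'   `to1`, `site2`, `to2`, `mutation1`, `mutation2`, `f_m1`, `f_m2`,
#'   `f_m12`, `epsilon`, `class`; attribute `summary` holds the mean and
#'   the fraction positive among defined records. Missing genotypes are
#'   skipped (NA epsilon).
#' @export
epistasis_map_d2 <- function(fitness, reference = MASTER_GENOTYPE) {
  lut <- fitness_lookup(fitness)
  ref <- gt_parse(reference)
  f_ref <- unname(lut[ref])
  refb <- strsplit(ref, "")[[1L]]
  alts <- lapply(seq_len(8L), function(i) setdiff(GT_ALPHABET, refb[i]))
  rows <- list()
  for (i in 1:7) for (j in (i + 1):8) {
    cls <- if (j <= 4L) "within_2_5" else if (i >= 5L) "within_18_21" else
      "cross_helix"
    for (a in alts[[i]]) for (b in alts[[j]]) {
      g1 <- refb; g1[i] <- a
      g2 <- refb; g2[j] <- b
      g12 <- g1; g12[j] <- b
      k1 <- paste0(g1, collapse = "")
      k2 <- paste0(g2, collapse = "")
      k12 <- paste0(g12, collapse = "")
      rows[[length(rows) + 1L]] <- data.frame(
        site1 = GENOTYPE_SITES[i], to1 = a,
        site2 = GENOTYPE_SITES[j], to2 = b,
        mutation1 = paste0(refb[i], GENOTYPE_SITES[i], a),
        mutation2 = paste0(refb[j], GENOTYPE_SITES[j], b),
        f_m1 = unname(lut[k1]), f_m2 = unname(lut[k2]),
        f_m12 = unname(lut[k12]), class = cls
      )
    }
  }
  out <- do.call(rbind, rows)
  out$epsilon <- pairwise_epsilon(rep(f_ref, nrow(out)), out$f_m1, out$f_m2,
                                  out$f_m12)
  def <- out$epsilon[is.finite(out$epsilon)]
  attr(out, "summary") <- list(n = length(def), mean = mean(def),
                               frac_positive = mean(def > 0))
  out
}

#' Region-partitioned pairwise epistasis
#'
#' Splits the double-mutant epistasis map into its three site classes and
#' compares the class distributions with rank-sum (Wilcoxon) tests. With a
#' complete table the classes hold 54 (within N2..N5), 54 (within
#' N18..N21) and 144 (cross-helix) records.
#'
#' @inheritParams epistasis_map_d2
#' @return List with `records` (the map), `by_class` (named list of epsilon
#'   vectors), `medians`, and `tests` (pairwise Wilcoxon p-values).
#' @export
partitioned_epistasis <- function(fitness, reference = MASTER_GENOTYPE) {
  rec <- epistasis_map_d2(fitness, reference)
  by_class <- split(rec$epsilon, rec$class)
  by_class <- lapply(by_class, function(x) x[is.finite(x)])
  cmb <- utils::combn(names(by_class), 2L)
  tests <- apply(cmb, 2L, function(pair) {
    stats::wilcox.test(by_class[[pair[1L]]], by_class[[pair[2L]]])$p.value
  })
  names(tests) <- apply(cmb, 2L, paste, collapse = "_vs_")
  list(records = rec, by_class = by_class,
       medians = vapply(by_class, stats::median, numeric(1L)), tests = tests)
}

#' Correlation of fitness effects at Hamming distance d
#'
#' For every single mutation `m` (site, replacement base) and every
#' background `g` at Hamming distance `d` from the reference that carries
#' the reference base at `m`'s site, the effect of `m` is
#' `s_m(g) = log f(g + m) - log f(g)`. `gamma(d)` is the Pearson
#' correlation between `s_m(reference)` and `s_m(g)` over all such
#' (mutation, background) pairs. `gamma(0) = 1` by construction; additive
#' (in log) landscapes give `gamma(d) = 1` at every distance.
#'
#' @param fitness Data frame with `genotype` and `f`.
#' @param reference Reference genotype (default master).
#' @param d Hamming distance(s) in `[0, 7]` (default `0:7`).
#' @return Data frame with `d`, `gamma`, `n_pairs`; `gamma` is `NA` when
#'   fewer than 3 valid pairs exist.
#' @export
gamma_correlation <- function(fitness, reference = MASTER_GENOTYPE, d = 0:7) {
  lut <- fitness_lookup(fitness)
  lf <- log(lut)
  lf[!is.finite(lf)] <- NA_real_
  ref <- gt_parse(reference)
  refb <- strsplit(ref, "")[[1L]]
  keys <- names(lf)
  dist <- hamming(keys, ref)
  base_m <- gt_base_matrix(keys)
  out <- lapply(d, function(dd) {
    stopifnot(dd >= 0L, dd <= 7L)
    xs <- numeric(0)
    ys <- numeric(0)
    for (i in seq_len(8L)) {
      bg <- which(dist == dd & base_m[, i] == refb[i])
      if (!length(bg)) next
      for (b in setdiff(GT_ALPHABET, refb[i])) {
        mref <- refb; mref[i] <- b
        s_ref <- unname(lf[paste0(mref, collapse = "")] - lf[ref])
        mut_keys <- keys[bg]
        substr(mut_keys, i, i) <- b
        s_bg <- unname(lf[mut_keys] - lf[keys[bg]])
        xs <- c(xs, rep(s_ref, length(s_bg)))
        ys <- c(ys, s_bg)
      }
    }
    keep <- is.finite(xs) & is.finite(ys)
    n <- sum(keep)
    g <- if (n < 3L || stats::sd(xs[keep]) == 0 || stats::sd(ys[keep]) == 0) {
      if (n >= 3L && isTRUE(all.equal(xs[keep], ys[keep]))) 1 else NA_real_
    } else {
      stats::cor(xs[keep], ys[keep])
    }
    data.frame(d = dd, gamma = g, n_pairs = n)
  })
  do.call(rbind, out)
}

#' Mirror test of helix-strand symmetry
#'
#' Correlates the fitness of genotypes with the fitness of their mirror
#' images across the helix axis, restricted to genotypes whose mirror is at
#' the same Hamming distance `d` from the reference. Each unordered
#' (genotype, mirror) pair is counted once and self-mirror genotypes are
#' excluded. A mirror-symmetric landscape gives rho = 1; strongly
#' asymmetric constraint gives low rho.
#'
#' @param fitness Data frame with `genotype` and `f`.
#' @param reference Reference genotype (default master).
#' @param d Hamming distance required of both genotype and mirror (default
#'   4). Because the reference and its mirror differ at all eight sites, a
#'   genotype at distance `d` has its mirror at distance at least `8 - d`,
#'   so the comparison set is nonempty only for `d >= 4`.
#' @return List with `rho` (Spearman), `p`, `n` (pairs); `rho` is `NA` when
#'   `n < 3`.
#' @export
mirror_test <- function(fitness, reference = MASTER_GENOTYPE, d = 4L) {
  lut <- fitness_lookup(fitness)
  keys <- names(lut)
  mk <- mirror(keys)
  dist_g <- hamming(keys, reference)
  dist_m <- hamming(mk, reference)
  keep <- dist_g == d & dist_m == d & keys != mk & mk %in% keys &
    keys < mk  # unordered pairs once
  fx <- unname(lut[keys[keep]])
  fy <- unname(lut[mk[keep]])
  ok <- is.finite(fx) & is.finite(fy)
  n <- sum(ok)
  if (n < 3L) return(list(rho = NA_real_, p = NA_real_, n = n))
  ct <- suppressWarnings(stats::cor.test(fx[ok], fy[ok], method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n)
}
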