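## Ground-truth two-state fitness model for synthetic experiments.
##
## Molecular fitness of an intron genotype is modelled as the product of
## three constraints observed in the real system: the P1ex helix must form
## but not be too stable (a stability band: too weak and splice sites are
## not aligned, too strong and the helix cannot dissociate to let P10 form);
## P10 pairing with the 3' exon is beneficial (logistic in P10 stability);
## and cytosines at both N2 and N21 disturb splice-site geometry (a
## multiplicative defect).

#' Parameters of the two-state fitness model
#'
#' Stabilities are in kcal/mol on the scale `-dG` of the forced-helix
#' energies, so larger means more stable.
#'
#' * `theta_lo`, `theta_hi`, `tau`: edges and softness of the P1ex stability
#'   band. Defaults (-20, 0, 1) place the master (P1ex stability -11.8) well
#'   inside the band, fully mismatched helices (about -34) below it, and
#'   perfect Watson-Crick helices (up to +5.1) above it.
#' * `theta10`, `tau10`: midpoint and scale of the logistic P10 benefit.
#'   Default midpoint -8 sits mid-range of the 21-value P10 spectrum
#'   (-22.6 to +6.6), so losing two or more P10 pairs is strongly deleterious.
#' * `delta`: multiplicative fitness factor applied when N2 = C and N21 = C
#'   (splice-site geometry defect), default 0.1.
#' * `sigma`: standard deviation of lognormal genotype-level noise.
#' * `theta_hi_offset_37`: added to `theta_hi` at 37 deg C, encoding the
#'   milder excess-stability penalty when kinetic traps are easier to
#'   escape (default +2 kcal/mol).
#'
#' @param w0 Baseline fitness scale (rescaled away in the final landscape).
#' @param theta_lo,theta_hi,tau,theta10,tau10,delta,sigma,theta_hi_offset_37
#'   See above.
#' @return A list of model parameters.
#' @export
two_state_params <- function(w0 = 1, theta_lo = -20, theta_hi = 0, tau = 1,
                             theta10 = -8, tau10 = 1, delta = 0.1,
                             sigma = 0.2, theta_hi_offset_37 = 2) {
  stopifnot(tau > 0, tau10 > 0, delta > 0, delta <= 1, sigma >= 0,
            theta_lo < theta_hi)
  as.list(environment())
}

logistic <- function(x) 1 / (1 + exp(-x))

#' Two-state true fitness of genotypes
#'
#' Evaluates the generative fitness model for given P1ex/P10 energies:
#' `w = w0 * band(s1) * logistic((s10 - theta10)/tau10) * geom * noise`,
#' where `s1 = -dG_P1ex`, `s10 = -dG_P10`,
#' `band(x) = logistic((x - theta_lo)/tau) * (1 - logistic((x - theta_hi)/tau))`,
#' and `geom = delta` when the genotype has cytosines at both N2 and N21.
#'
#' @param g Character vector of genotypes.
#' @param dg_p1ex,dg_p10 Free energies (kcal/mol) of the forced P1ex and P10
#'   helices for `g` (computed if omitted).
#' @param params [two_state_params()].
#' @param temperature `"30C"` or `"37C"` (raises the upper band edge).
#' @param z Optional standard-normal deviates for the lognormal noise (one
#'   per genotype); default none (`sigma` ignored). Supply pre-drawn values
#'   for reproducible noisy landscapes.
#' @return Numeric vector of unscaled fitness values (`>= 0`).
#' @export
two_state_fitness <- function(g, dg_p1ex = NULL, dg_p10 = NULL,
                              params = two_state_params(),
                              temperature = c("30C", "37C"), z = NULL) {
  temperature <- match.arg(temperature)
  if (is.null(dg_p1ex)) dg_p1ex <- forced_helix_energy(g, p1ex_helix())
  if (is.null(dg_p10)) dg_p10 <- forced_helix_energy(g, p10_helix())
  s1 <- -dg_p1ex
  s10 <- -dg_p10
  th_hi <- params$theta_hi +
    if (temperature == "37C") params$theta_hi_offset_37 else 0
  band <- logistic((s1 - params$theta_lo) / params$tau) *
    (1 - logistic((s1 - th_hi) / params$tau))
  p10 <- logistic((s10 - params$theta10) / params$tau10)
  bm <- gt_base_matrix(g)
  geom <- ifelse(bm[, 1L] == "C" & bm[, 8L] == "C", params$delta, 1)
  w <- params$w0 * band * p10 * geom
  if (!is.null(z)) {
    stopifnot(length(z) == length(w))
    w <- w * exp(params$sigma * z)
  }
  w
}

#' Ground-truth fitness landscape
#'
#' Builds the complete true-fitness ledger for a genotype set under the
#' two-state model, rescaled so the master genotype has fitness exactly 1.
#'
#' @param genotypes Character vector (default: the full 4^8 space).
#' @param params [two_state_params()].
#' @param temperature `"30C"` or `"37C"`.
#' @param seed Integer seed for the lognormal genotype noise; `NULL` (with
#'   `sigma = 0` implied) for a noise-free landscape.
#' @param model [energy_model()].
#' @return A `true_landscape` data frame with columns `genotype`, `d`
#'   (Hamming distance to the master), `dg_p1ex`, `dg_p10`, `w` (relative
#'   fitness, master = 1) and the component factors `band`, `p10`, `geom`.
#' @export
true_landscape <- function(genotypes = enumerate_genotypes(),
                           params = two_state_params(),
                           temperature = "30C", seed = NULL,
                           model = energy_model()) {
  dg1 <- forced_helix_energy(genotypes, p1ex_helix(), model)
  dg10 <- forced_helix_energy(genotypes, p10_helix(), model)
  z <- NULL
  if (!is.null(seed) && params$sigma > 0) {
    set.seed(as.integer(seed))
    z <- stats::rnorm(length(genotypes))
  }
  w <- two_state_fitness(genotypes, dg1, dg10, params, temperature, z)
  key <- gt_parse(genotypes)
  im <- match(gt_parse(MASTER_GENOTYPE), key)
  wm <- if (is.na(im)) {
    ## subset without the master: rescale by its noise-free fitness
    two_state_fitness(MASTER_GENOTYPE, params = params,
                      temperature = temperature)
  } else {
    w[im]
  }
  if (wm <= 0) stop("master fitness is not positive; bad parameters")
  th_hi <- params$theta_hi +
    if (temperature == "37C") params$theta_hi_offset_37 else 0
  s1 <- -dg1
  out <- data.frame(
    genotype = gt_format(genotypes),
    d = hamming(genotypes),
    dg_p1ex = dg1, dg_p10 = dg10,
    band = logistic((s1 - params$theta_lo) / params$tau) *
      (1 - logistic((s1 - th_hi) / params$tau)),
    p10 = logistic((-dg10 - params$theta10) / params$tau10),
    geom = ifelse(substr(key, 1L, 1L) == "C" & substr(key, 8L, 8L) == "C",
                  params$delta, 1),
    w = w / wm
  )
  class(out) <- c("true_landscape", "data.frame")
  out
}
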