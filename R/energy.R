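## Nearest-neighbor free energies of the forced P1ex and P10 helices.
##
## Each helix is evaluated as a forced hairpin: a 5' strand, a loop of six
## undefined nucleotides, and a 3' strand, with every rung of the helix
## paired regardless of whether the bases can actually pair. Energies are
## stored internally as integers in units of 0.01 kcal/mol so that counting
## unique values across a genotype space is exact and platform-independent.

PAIR_TYPES <- c("CG", "GC", "GU", "UG", "AU", "UA")
## index of the strand-reversed pair type (CG<->GC, GU<->UG, AU<->UA)
PAIR_REV <- c(2L, 1L, 4L, 3L, 6L, 5L)

#' Nearest-neighbor helix energy model
#'
#' Loads the Turner 2004 stack and hairpin-initiation parameters shipped with
#' the package and combines them with the model's policy terms:
#'
#' * stacking free energy for each adjacent pair of canonical
#'   (Watson-Crick or G.U wobble) rungs, looked up in the published 6x6
#'   stack table;
#' * zero stacking across any rung forced into a non-canonical pair, plus a
#'   flat `noncanonical_penalty` per such rung (forced pairing of
#'   incompatible bases is heavily destabilising);
#' * a terminal A-U penalty at every end of every contiguous canonical helix
#'   segment (a non-canonical rung interrupts the helix, exposing new ends);
#' * hairpin initiation for the six undefined loop nucleotides, with a
#'   closing-G.C adjustment (`closing_gc`) mirroring the mismatch term that
#'   loop evaluation applies against undefined bases.
#'
#' The `noncanonical_penalty` default of 7.10 kcal/mol is the package's
#' calibrated value: it makes fully mismatched helices the least stable in
#' the spectrum and reproduces the reference unique-energy counts of the
#' P1ex and P10 spaces (211 and 21; see the methods vignette).
#'
#' @param stacks_file,loops_file Parameter TSVs (defaults: Turner 2004
#'   tables shipped in `extdata`).
#' @param noncanonical_penalty Free energy (kcal/mol) added per forced
#'   non-canonical rung.
#' @param temperature Temperature (deg C) at which the free energies are
#'   tabulated (37 for the shipped set); metadata only.
#' @return An `energy_model` list with integer (0.01 kcal/mol) components
#'   `stacks` (6x6 matrix), `hairpin` (named vector by loop length),
#'   `terminal_au`, `closing_gc`, `noncanonical`, `temperature`.
#' @export
energy_model <- function(stacks_file = NULL, loops_file = NULL,
                         noncanonical_penalty = 7.10, temperature = 37) {
  if (is.null(stacks_file)) {
    stacks_file <- system.file("extdata", "turner2004_stacks.tsv",
                               package = "intronscape", mustWork = TRUE)
  }
  if (is.null(loops_file)) {
    loops_file <- system.file("extdata", "turner2004_loops.tsv",
                              package = "intronscape", mustWork = TRUE)
  }
  st <- utils::read.delim(stacks_file, check.names = FALSE)
  stacks <- as.matrix(st[, PAIR_TYPES])
  rownames(stacks) <- st$pair
  stacks <- round(stacks[PAIR_TYPES, PAIR_TYPES] * 100)
  storage.mode(stacks) <- "integer"
  ## reading the stack from the other strand swaps row and column in this
  ## layout, so strand-reversal symmetry is plain matrix symmetry
  if (!isSymmetric(unname(stacks))) {
    stop("stack table is not symmetric under strand reversal")
  }
  lo <- utils::read.delim(loops_file)
  val <- stats::setNames(as.integer(round(lo$value * 100)), lo$parameter)
  hp_idx <- grep("^hairpin_", names(val))
  hairpin <- val[hp_idx]
  names(hairpin) <- sub("^hairpin_", "", names(hairpin))
  structure(list(
    stacks = stacks,
    hairpin = hairpin,
    terminal_au = unname(val["terminal_au"]),
    closing_gc = unname(val["closing_gc"]),
    noncanonical = as.integer(round(noncanonical_penalty * 100)),
    temperature = temperature
  ), class = "energy_model")
}

#' Forced-helix specifications for P1ex and P10
#'
#' A helix spec describes a forced hairpin: `strand5` and `strand3` are
#' written 5' to 3' and rung `i` pairs `strand5[i]` with
#' `strand3[n + 1 - i]`. Entries are either fixed RNA bases (`"A"`, `"C"`,
#' `"G"`, `"U"`) or site references (`"N2"` ... `"N21"`) resolved from each
#' genotype. The intervening loop is six undefined nucleotides.
#'
#' `p1ex_helix()` forces the four-rung P1ex pairing N2-N21, N3-N20, N4-N19,
#' N5-N18. `p10_helix()` forces the six-rung helix formed after 5' cleavage,
#' in which intron positions 15-20 (fixed A15, C16, G17 plus variable
#' N18-N20) pair with the first six bases of the 3' exon (GGUCGU); N21 sits
#' outside this helix, next to the splice site.
#'
#' @return A `helix_spec` list with `bracket`, `strand5`, `strand3`,
#'   `loop_len`.
#' @export
p1ex_helix <- function() {
  structure(list(
    bracket = "((((......))))",
    strand5 = c("N2", "N3", "N4", "N5"),
    strand3 = c("N18", "N19", "N20", "N21"),
    loop_len = 6L
  ), class = "helix_spec")
}

#' @rdname p1ex_helix
#' @export
p10_helix <- function() {
  structure(list(
    bracket = "((((((......))))))",
    strand5 = c("G", "G", "U", "C", "G", "U"),
    strand3 = c("A", "C", "G", "N18", "N19", "N20"),
    loop_len = 6L
  ), class = "helix_spec")
}

## internal: resolve one strand entry to a vector of RNA bases (one/genotype)
resolve_strand <- function(entry, base_mat) {
  if (grepl("^N[0-9]+$", entry)) {
    site <- as.integer(sub("^N", "", entry))
    col <- site_to_col(site)
    if (is.na(col)) stop("helix spec references unknown site ", entry)
    chartr("T", "U", base_mat[, col])
  } else {
    if (!entry %in% c("A", "C", "G", "U")) stop("unknown base '", entry, "'")
    rep(entry, nrow(base_mat))
  }
}

## internal: pair-type code per rung: 1..6 canonical, 0 non-canonical
pair_type_code <- function(b5, b3) {
  m <- match(paste0(b5, b3), PAIR_TYPES)
  m[is.na(m)] <- 0L
  m
}

#' Free energy of a forced helix
#'
#' Evaluates the nearest-neighbor free energy of the forced hairpin described
#' by `spec` for each genotype. Deterministic; exact in units of
#' 0.01 kcal/mol.
#'
#' @param g Character vector of genotypes (any length, including the full
#'   enumerated space).
#' @param spec A [p1ex_helix()] or [p10_helix()] specification.
#' @param model An [energy_model()].
#' @return Numeric vector of free energies (kcal/mol).
#' @export
forced_helix_energy <- function(g, spec = p1ex_helix(), model = energy_model()) {
  bm <- gt_base_matrix(g)
  n <- length(spec$strand5)
  s5 <- lapply(spec$strand5, resolve_strand, base_mat = bm)
  s3 <- lapply(spec$strand3, resolve_strand, base_mat = bm)
  ## rung i pairs strand5[i] with strand3[n+1-i]; codes: ngenotype x nrung
  codes <- vapply(seq_len(n), function(i) {
    pair_type_code(s5[[i]], s3[[n + 1L - i]])
  }, integer(nrow(bm)))
  if (nrow(bm) == 1L) codes <- matrix(codes, nrow = 1L)

  e <- rep(model$hairpin[[as.character(spec$loop_len)]], nrow(bm))
  ## stacking between adjacent canonical rungs:
  ## stack(i -> i+1) = stacks[type_i, rev(type_{i+1})]
  for (i in seq_len(n - 1L)) {
    a <- codes[, i]
    b <- codes[, i + 1L]
    ok <- a > 0L & b > 0L
    if (any(ok)) {
      e[ok] <- e[ok] + model$stacks[cbind(a[ok], PAIR_REV[b[ok]])]
    }
  }
  ## non-canonical penalty and per-segment terminal A-U penalties
  nc <- codes == 0L
  e <- e + as.integer(rowSums(nc)) * model$noncanonical
  au <- codes == 5L | codes == 6L
  left_end <- cbind(TRUE, nc[, -n, drop = FALSE])  # rung starts a segment
  right_end <- cbind(nc[, -1L, drop = FALSE], TRUE)  # rung ends a segment
  e <- e + as.integer(rowSums(au & left_end) + rowSums(au & right_end)) *
    model$terminal_au
  ## closing-pair adjustment against the undefined loop
  closing_gc <- codes[, n] == 1L | codes[, n] == 2L
  e <- e + ifelse(closing_gc, model$closing_gc, 0L)
  unname(e) / 100
}

#' Unique-energy spectrum of a genotype space
#'
#' Distinct forced-helix free energies and their multiplicities over a set of
#' genotypes, counted exactly (integer representation). Across all 4^8
#' genotypes the P1ex helix has 211 unique values; across all 4^4 right-half
#' genotypes the P10 helix has 21.
#'
#' @param g Character vector of genotypes (e.g. [enumerate_genotypes()]).
#' @inheritParams forced_helix_energy
#' @return Data frame with columns `dg` (kcal/mol, ascending: most stable
#'   first) and `n` (multiplicity); multiplicities sum to `length(g)`.
#' @export
unique_energy_spectrum <- function(g, spec = p1ex_helix(),
                                   model = energy_model()) {
  e <- forced_helix_energy(g, spec, model)
  tab <- table(factor(round(e * 100)))
  dg <- as.integer(names(tab)) / 100
  ord <- order(dg)
  data.frame(dg = dg[ord], n = as.integer(tab)[ord])
}

#' Stability rank bins
#'
#' Ranks forced-helix energies by increasing stability (decreasing free
#' energy) and partitions the unique values into `n_bins` near-equal groups
#' of unique values, so tied energies always share a bin. Bin 1 is the least
#' stable. Forced non-canonical rungs carry large penalties, so fully
#' mismatched genotypes always occupy the lowest-stability bins.
#'
#' @param dg Numeric vector of free energies (kcal/mol) per genotype.
#' @param n_bins Number of bins (default 10, as used for the P1ex axis of
#'   the stability landscape). If `n_bins` exceeds the number of unique
#'   values, each unique value gets its own bin (identity binning).
#' @return Integer vector of bin indices (1 = least stable), with attribute
#'   `rank` (stability rank of each genotype's unique value, 1 = least
#'   stable) and `n_unique`.
#' @export
stability_rank_bins <- function(dg, n_bins = 10L) {
  stopifnot(n_bins >= 1L)
  key <- as.integer(round(dg * 100))
  u <- sort(unique(key), decreasing = TRUE)  # least stable (highest dG) first
  rank <- match(key, u)
  n_u <- length(u)
  n_bins <- min(as.integer(n_bins), n_u)
  bin_of_rank <- as.integer(ceiling(seq_len(n_u) * n_bins / n_u))
  out <- bin_of_rank[rank]
  attr(out, "rank") <- rank
  attr(out, "n_unique") <- n_u
  out
}

#' Median-fitness landscape over two stability axes
#'
#' Cross-tabulates genotypes by their P1ex and P10 stability bins and
#' reports the median fitness in each cell, reproducing the two-axis
#' stability landscape view. Empty cells are `NA`, never zero-filled.
#'
#' @param fitness Numeric vector of fitness values per genotype.
#' @param p1ex_bins,p10_bins Integer bin assignments per genotype (see
#'   [stability_rank_bins()]).
#' @return Numeric matrix (P1ex bins x P10 bins) of median fitness, with an
#'   `n` attribute holding the per-cell genotype counts.
#' @export
landscape_surface <- function(fitness, p1ex_bins, p10_bins) {
  stopifnot(length(fitness) == length(p1ex_bins),
            length(fitness) == length(p10_bins))
  b1 <- max(p1ex_bins)
  b10 <- max(p10_bins)
  med <- matrix(NA_real_, b1, b10,
                dimnames = list(p1ex = seq_len(b1), p10 = seq_len(b10)))
  cnt <- matrix(0L, b1, b10)
  idx <- split(seq_along(fitness),
               list(factor(p1ex_bins, seq_len(b1)),
                    factor(p10_bins, seq_len(b10))))
  for (key in names(idx)) {
    ii <- idx[[key]]
    if (!length(ii)) next
    kk <- as.integer(strsplit(key, ".", fixed = TRUE)[[1L]])
    med[kk[1L], kk[2L]] <- stats::median(fitness[ii])
    cnt[kk[1L], kk[2L]] <- length(ii)
  }
  attr(med, "n") <- cnt
  med
}
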