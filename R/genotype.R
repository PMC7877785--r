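## Genotype space: encoding, enumeration and combinatorics of the variable
## sites N2..N5 / N18..N21 of the Tet-119(C20A) P1ex region.

#' Master (wild-type) genotype of the selection experiment
#'
#' The eight variable bases of the Tet-119(C20A) master sequence, written as
#' `"LLLL-RRRR"` where the left block is N2..N5 and the right block is
#' N18..N21 (DNA alphabet).
#'
#' @format A length-1 character vector, `"AGGT-ACAT"`.
#' @export
MASTER_GENOTYPE <- "AGGT-ACAT"

#' Intron site labels of the eight variable positions
#'
#' Variable positions use the intron's 1-based numbering: sites 2-5 form the
#' left half and sites 18-21 the right half of the P1ex helix.
#'
#' @format Integer vector of length 8.
#' @export
GENOTYPE_SITES <- c(2:5, 18:21)

GT_ALPHABET <- c("A", "C", "G", "T")

#' Parse genotype strings
#'
#' Accepts the canonical `"LLLL-RRRR"` text form with or without the hyphen
#' and returns the bare 8-base string over `{A,C,G,T}`. `U` is accepted on
#' input (RNA display form) and converted to `T`.
#'
#' @param x Character vector of genotype strings.
#' @return Character vector of 8-base genotype strings (no hyphen).
#' @export
gt_parse <- function(x) {
  x <- toupper(gsub("-", "", x, fixed = TRUE))
  x <- chartr("U", "T", x)
  bad <- nchar(x) != 8L | grepl("[^ACGT]", x)
  if (any(bad)) {
    stop("invalid genotype(s): ", paste(utils::head(x[bad], 5L), collapse = ", "),
         "; expected 8 bases over {A,C,G,T} as 'LLLL-RRRR'")
  }
  x
}

#' Format genotypes in canonical text form
#'
#' @param x Character vector of genotype strings (with or without hyphen).
#' @param rna Display as RNA (`T` shown as `U`)? Formatting only; genotypes
#'   are stored as DNA throughout.
#' @return Character vector in `"LLLL-RRRR"` form.
#' @export
gt_format <- function(x, rna = FALSE) {
  x <- gt_parse(x)
  out <- paste0(substr(x, 1L, 4L), "-", substr(x, 5L, 8L))
  if (rna) out <- chartr("T", "U", out)
  out
}

## internal: genotype vector -> 8-column character matrix of bases
gt_base_matrix <- function(x) {
  x <- gt_parse(x)
  matrix(unlist(strsplit(x, ""), use.names = FALSE), ncol = 8L, byrow = TRUE)
}

#' Enumerate the complete genotype space
#'
#' Returns all `alphabet_size^n_sites` genotypes in lexicographic order
#' (A < C < G < T). For the default 8 sites this is the full 4^8 = 65,536
#' P1ex/P10 genotype space of the experiment.
#'
#' @param n_sites Number of variable sites (default 8; at most 12).
#' @param alphabet_size Number of bases per site, 1-4 (prefix of A,C,G,T).
#' @return Character vector of bare genotype strings in lexicographic order.
#' @export
enumerate_genotypes <- function(n_sites = 8L, alphabet_size = 4L) {
  n_sites <- as.integer(n_sites)
  alphabet_size <- as.integer(alphabet_size)
  stopifnot(n_sites >= 1L, alphabet_size >= 1L, alphabet_size <= 4L)
  if (n_sites > 12L) {
    stop("n_sites = ", n_sites, " exceeds the enumeration guard (12 sites; ",
         "4^12 = 16.7M genotypes)")
  }
  ab <- GT_ALPHABET[seq_len(alphabet_size)]
  ## expand.grid varies the first factor fastest; reverse for lexicographic order
  g <- expand.grid(rev(rep(list(ab), n_sites)), stringsAsFactors = FALSE)
  do.call(paste0, rev(g))
}

#' Hamming distance between genotypes
#'
#' Number of variable sites at which two genotypes differ, i.e. the number of
#' mutational steps separating them. Vectorised over `g1` (and `g2` if given).
#'
#' @param g1 Character vector of genotypes.
#' @param g2 Single genotype or vector the same length as `g1`
#'   (default: the master sequence).
#' @return Integer vector of distances in `[0, 8]`.
#' @export
hamming <- function(g1, g2 = MASTER_GENOTYPE) {
  m1 <- gt_base_matrix(g1)
  m2 <- gt_base_matrix(g2)
  if (nrow(m2) == 1L && nrow(m1) > 1L) m2 <- m2[rep(1L, nrow(m1)), , drop = FALSE]
  if (nrow(m1) != nrow(m2)) stop("g1 and g2 lengths differ")
  as.integer(rowSums(m1 != m2))
}

#' Mirror a genotype across the P1ex helix axis
#'
#' Reflects the genotype across the helix axis under the P1ex pairing scheme
#' (2,21),(3,20),(4,19),(5,18): the new left block is the old right block
#' reversed, and vice versa, so that each base moves to the site of its
#' pairing partner. The operation is an involution and preserves Hamming
#' distances between genotypes.
#'
#' @param g Character vector of genotypes.
#' @return Character vector of mirrored genotypes (bare form).
#' @export
mirror <- function(g) {
  m <- gt_base_matrix(g)
  out <- m[, c(8L, 7L, 6L, 5L, 4L, 3L, 2L, 1L), drop = FALSE]
  apply(out, 1L, paste0, collapse = "")
}

#' P1ex pairing scheme
#'
#' The established master/wildtype pairing pattern of the P1ex helix:
#' N2-N21, N3-N20, N4-N19, N5-N18. `wobble_policy` controls how G.T (G.U in
#' RNA) pairs are classified by [pair_profile()]: counted as their own class
#' (default), counted together with the weak A.T class, or treated as
#' non-pairing.
#'
#' @param wobble_policy One of `"separate_class"`, `"count_as_weak"`,
#'   `"exclude"`.
#' @return A `pairing_scheme` list with elements `pairs` (4x2 integer matrix
#'   of site labels) and `wobble_policy`.
#' @export
p1ex_scheme <- function(wobble_policy = c("separate_class", "count_as_weak",
                                          "exclude")) {
  wobble_policy <- match.arg(wobble_policy)
  structure(list(
    pairs = cbind(site5 = 2:5, site3 = 21:18),
    wobble_policy = wobble_policy
  ), class = "pairing_scheme")
}

## internal: site label -> column index in the 8-column base matrix
site_to_col <- function(site) match(site, GENOTYPE_SITES)

## internal: classify a base pair (two uppercase DNA bases)
## -> "strong" (G.C), "weak" (A.T), "wobble" (G.T), "none"
classify_pair <- function(a, b) {
  p <- paste0(a, b)
  out <- rep("none", length(p))
  out[p %in% c("GC", "CG")] <- "strong"
  out[p %in% c("AT", "TA")] <- "weak"
  out[p %in% c("GT", "TG")] <- "wobble"
  out
}

#' Base-pairing profile of a genotype under a pairing scheme
#'
#' Classifies each scheme pair as strong (G.C), weak (A.T), wobble (G.T) or
#' unpaired, assuming base-pairing follows the master/wildtype pattern.
#' Wobble pairs are reassigned according to the scheme's `wobble_policy`.
#'
#' @param g Character vector of genotypes.
#' @param scheme A [p1ex_scheme()] (or compatible) pairing scheme.
#' @return Data frame with columns `genotype`, `strong`, `weak`, `wobble`,
#'   `unpaired`; rows sum to the number of scheme pairs.
#' @export
pair_profile <- function(g, scheme = p1ex_scheme()) {
  m <- gt_base_matrix(g)
  i5 <- site_to_col(scheme$pairs[, 1L])
  i3 <- site_to_col(scheme$pairs[, 2L])
  cls <- vapply(seq_along(i5), function(k) {
    classify_pair(m[, i5[k]], m[, i3[k]])
  }, character(nrow(m)))
  if (nrow(m) == 1L) cls <- matrix(cls, nrow = 1L)
  if (scheme$wobble_policy == "count_as_weak") {
    cls[cls == "wobble"] <- "weak"
  } else if (scheme$wobble_policy == "exclude") {
    cls[cls == "wobble"] <- "none"
  }
  data.frame(
    genotype = gt_format(g),
    strong   = as.integer(rowSums(cls == "strong")),
    weak     = as.integer(rowSums(cls == "weak")),
    wobble   = as.integer(rowSums(cls == "wobble")),
    unpaired = as.integer(rowSums(cls == "none"))
  )
}

#' Single mutations that complete the P1ex helix
#'
#' Scans all 24 single-nucleotide substitutions of `g` and returns those whose
#' product forms a fully Watson-Crick helix under the scheme (no unpaired
#' positions, no wobble pairs). For the master sequence these are exactly G3T
#' and A20C, the only two mutations capable of generating a helix with four
#' paired bases.
#'
#' @param g A single genotype.
#' @param scheme Pairing scheme (default [p1ex_scheme()]).
#' @return Data frame with columns `site`, `from`, `to`, `mutation` (e.g.
#'   `"G3T"`), `genotype` (the mutant); zero rows if no substitution completes
#'   the helix. If `g` itself is already fully Watson-Crick paired the result
#'   carries attribute `already_paired = TRUE`.
#' @export
full_pairing_mutants <- function(g, scheme = p1ex_scheme()) {
  g <- gt_parse(g)
  stopifnot(length(g) == 1L)
  is_full <- function(x) {
    pp <- pair_profile(x, scheme)
    pp$unpaired == 0L && pp$wobble == 0L
  }
  bases <- strsplit(g, "")[[1L]]
  res <- list()
  for (i in seq_len(8L)) {
    for (b in setdiff(GT_ALPHABET, bases[i])) {
      mut <- bases
      mut[i] <- b
      mg <- paste0(mut, collapse = "")
      if (is_full(mg)) {
        res[[length(res) + 1L]] <- data.frame(
          site = GENOTYPE_SITES[i], from = bases[i], to = b,
          mutation = paste0(bases[i], GENOTYPE_SITES[i], b),
          genotype = gt_format(mg)
        )
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(site = integer(), from = character(), to = character(),
               mutation = character(), genotype = character())
  attr(out, "already_paired") <- is_full(g)
  out
}

#' Apply a single-site substitution
#'
#' @param g Character vector of genotypes.
#' @param site Intron site label (one of 2-5, 18-21).
#' @param base Replacement base (DNA).
#' @return Mutated genotypes (bare form).
#' @export
substitute_site <- function(g, site, base) {
  m <- gt_base_matrix(g)
  m[, site_to_col(site)] <- base
  apply(m, 1L, paste0, collapse = "")
}
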