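# Constructed fitness landscapes over the complete genotype space, used as
# analytic oracles for the epistasis/statistics modules.

# Multiplicative landscape: w(g) = prod_i e_i(g_i), site effects seeded,
# rescaled so the master has fitness 1. Log-additive, hence epsilon = 0 for
# every double mutant and gamma(d) = 1 at every distance.
make_multiplicative_landscape <- function(seed = 1, genotypes = enumerate_genotypes()) {
  set.seed(seed)
  eff <- matrix(exp(stats::rnorm(32, sd = 0.7)), 4, 8,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  m <- matrix(unlist(strsplit(gt_parse(genotypes), ""), use.names = FALSE),
              ncol = 8, byrow = TRUE)
  lw <- rowSums(vapply(1:8, function(i) log(eff[m[, i], i]),
                       numeric(length(genotypes))))
  w <- exp(lw)
  w <- w / w[match(gt_parse(MASTER_GENOTYPE), gt_parse(genotypes))]
  data.frame(genotype = gt_format(genotypes), f = w)
}

# Ceiling landscape: a multiplicative landscape (some beneficial site
# effects) truncated at the master fitness 1. Capping can only raise a
# double mutant relative to the multiplicative expectation, so epsilon >= 0
# everywhere.
make_capped_landscape <- function(seed = 2) {
  ml <- make_multiplicative_landscape(seed)
  ml$f <- pmin(ml$f, 1)
  ml
}

# Mirror-symmetric landscape: fitness depends only on the unordered
# {g, mirror(g)} orbit.
make_mirror_symmetric_landscape <- function(seed = 3) {
  g <- enumerate_genotypes()
  set.seed(seed)
  score <- stats::setNames(stats::rnorm(length(g)), g)
  w <- exp(score[g] + score[mirror(g)])
  data.frame(genotype = gt_format(g), f = unname(w))
}

# i.i.d. house-of-cards landscape: fitness of every genotype drawn
# independently.
make_random_landscape <- function(seed = 4) {
  g <- enumerate_genotypes()
  set.seed(seed)
  data.frame(genotype = gt_format(g), f = exp(stats::rnorm(length(g))))
}

# Write a small FASTQ file (optionally gzipped) from explicit records.
write_test_fastq <- function(seqs, quals, file) {
  con <- if (grepl("\\.gz$", file)) gzfile(file, "wb") else file(file, "wb")
  writeLines(paste(paste0("@read", seq_along(seqs)), seqs, "+", quals,
                   sep = "\n"), con)
  close(con)
  file
}
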