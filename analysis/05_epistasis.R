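#!/usr/bin/env Rscript

# Epistasis structure around the master genotype: the pairwise map of all
# double mutants, region-partitioned epsilon, the correlation of fitness
# effects gamma(d), and the helix mirror test.

library(intronscape)

ft <- read.delim("results/fitness_30C.tsv")

em <- epistasis_map_d2(ft)
sm <- attr(em, "summary")
cat(sprintf("pairwise epistasis (d = 2): %d records, mean epsilon %.3f, %.0f%% positive\n",
            sm$n, sm$mean, 100 * sm$frac_positive))
write.table(em, "results/epistasis_d2.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

pe <- partitioned_epistasis(ft)
cat("class means:",
    paste(sprintf("%s %.3f", names(pe$by_class),
                  vapply(pe$by_class, mean, numeric(1))), collapse = ", "),
    "\n")
cat("rank-sum p (within_18_21 vs within_2_5):",
    signif(pe$tests[["within_18_21_vs_within_2_5"]], 3), "\n")

## gamma(d) on the estimated table (well-covered backgrounds only) and on
## the noise-free landscape
cov <- ft$n_pre / 6 >= 50
gm_est <- gamma_correlation(ft[cov, ], d = 0:2)
gm_true <- gamma_correlation(true_landscape(), d = 0:7)
gm_true$source <- "true_landscape"
gm_est$source <- "estimated"
gm <- rbind(gm_est, gm_true)
print(gm)
write.table(gm, "results/gamma.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

mt <- mirror_test(ft, d = 4)
cat(sprintf("mirror test (d = 4): rho = %.2f, p = %.2f, N = %d\n",
            mt$rho, mt$p, mt$n))
cat("wrote results/epistasis_d2.tsv, results/gamma.tsv\n")
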