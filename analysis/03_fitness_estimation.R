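#!/usr/bin/env Rscript

# Estimate per-genotype relative fitness from the simulated counts at each
# temperature and validate the estimates against the ground truth.

library(intronscape)

counts_df <- read.delim("results/counts.tsv", check.names = FALSE)
counts <- as.matrix(counts_df[, -1])
rownames(counts) <- counts_df$genotype
sheet <- read.delim("results/sample_sheet.tsv",
                    colClasses = c(temperature = "character"))

for (temp in c("30", "37")) {
  ft <- fitness_table(counts, sheet, temperature = temp)
  truth <- read.delim(sprintf("results/truth_%sC.tsv", temp))
  w <- truth$w[match(ft$genotype, truth$genotype)]
  covered <- ft$n_pre / 6 >= 50
  rho <- cor(ft$f[covered], w[covered], method = "spearman")
  sig <- !is.na(ft$p_adj) & ft$n_pre > 0
  cat(sprintf("%sC: rho(f, true w) = %.3f on %d covered genotypes; %.1f%% significantly depleted, %.2f%% enriched (p_adj < 0.05)\n",
              temp, rho, sum(covered),
              100 * mean(ft$p_adj[sig] < 0.05 & ft$s[sig] < 0, na.rm = TRUE),
              100 * mean(ft$p_adj[sig] < 0.05 & ft$s[sig] > 0, na.rm = TRUE)))
  write.table(ft, sprintf("results/fitness_%sC.tsv", temp), sep = "\t",
              quote = FALSE, row.names = FALSE)
}

# fitness estimates correlate between temperatures (the milder 37C ceiling
# preserves ranks)
f30 <- read.delim("results/fitness_30C.tsv")
f37 <- read.delim("results/fitness_37C.tsv")
both <- f30$n_pre / 6 >= 50 & f37$n_pre / 6 >= 50
cat(sprintf("rho(f_30C, f_37C) = %.3f on %d genotypes\n",
            cor(f30$f[both], f37$f[both], method = "spearman"), sum(both)))
cat("wrote results/fitness_30C.tsv, results/fitness_37C.tsv\n")
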