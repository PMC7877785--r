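#!/usr/bin/env Rscript

# Diversity and distribution-of-fitness-effects summaries of the simulated
# experiment: Shannon diversity before/after selection, Bray-Curtis
# structure across replicates and conditions, DFE bimodality, fitness by
# Hamming distance, and simple correlates.

library(intronscape)

counts_df <- read.delim("results/counts.tsv", check.names = FALSE)
counts <- as.matrix(counts_df[, -1])
rownames(counts) <- counts_df$genotype
sheet <- read.delim("results/sample_sheet.tsv",
                    colClasses = c(temperature = "character"))
ft <- read.delim("results/fitness_30C.tsv")

## Shannon diversity per sample
H <- shannon(counts)
div <- data.frame(sheet[, c("sample", "replicate", "selection", "temperature")],
                  shannon = as.numeric(H))
write.table(div, "results/diversity.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
agg <- aggregate(shannon ~ selection + temperature, div, mean)
print(agg)

## Bray-Curtis: within-condition vs between-condition (30C)
s30 <- sheet[sheet$temperature == "30", ]
bc <- as.matrix(bray_curtis(counts[, s30$sample]))
pre <- s30$sample[s30$selection == "pre"]
post <- s30$sample[s30$selection == "post"]
within <- c(bc[pre, pre][upper.tri(bc[pre, pre])],
            bc[post, post][upper.tri(bc[post, post])])
between <- as.vector(bc[pre, post])
cat(sprintf("Bray-Curtis at 30C: mean within-condition %.3f, between %.3f\n",
            mean(within), mean(between)))

## DFE of covered genotypes
covered <- ft$n_pre / 6 >= 10
s <- dfe_summary(ft$f[covered])
cat(sprintf("DFE (n = %d): skewness %.2f, kurtosis %.2f; mixture means %.2f/%.2f (log f), weights %.2f/%.2f, Ashman D = %.2f -> bimodal: %s\n",
            s$n, s$skewness, s$kurtosis, s$mixture$means[1],
            s$mixture$means[2], s$mixture$weights[1], s$mixture$weights[2],
            s$mixture$ashman_d, s$mixture$bimodal))

## fitness by Hamming distance (well-covered genotypes)
fb <- fitness_by_hamming(ft[ft$n_pre / 6 >= 50, ])
print(fb)
write.table(fb, "results/fitness_by_hamming.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

## correlates: GC count and P1ex stability
energies <- read.delim("results/helix_energies.tsv")
stopifnot(identical(energies$genotype, ft$genotype))
fc <- feature_correlates(ft$f, list(gc_count = gc_count(ft$genotype),
                                    dg_p1ex = energies$dg_p1ex,
                                    dg_p10 = energies$dg_p10))
print(fc)
write.table(fc, "results/correlates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

## two-axis stability landscape (median estimated fitness per bin cell)
surf <- landscape_surface(ft$f, energies$p1ex_bin, energies$p10_bin)
write.table(as.data.frame(surf), "results/stability_landscape.tsv",
            sep = "\t", quote = FALSE, row.names = TRUE)
cat("wrote results/diversity.tsv, fitness_by_hamming.tsv, correlates.tsv, stability_landscape.tsv\n")
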