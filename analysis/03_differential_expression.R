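#!/usr/bin/env Rscript

# Stage 3 — quasi-likelihood F-tests for the two contrasts of the design:
# derived vs progenitor (KM vs W) and back-selected vs derived (ZERO vs KM).
# Fewer DEGs in the second contrast than in the first is the expected
# signature when most derived-strain changes persist only partially.

suppressPackageStartupMessages(library(comprev))

data_dir <- "scratch/analysis/data"
res_dir <- "results/analysis"
dir.create(res_dir, recursive = TRUE, showWarnings = FALSE)

counts <- read_counts(file.path(data_dir, "counts.tsv"))
samples <- read_samples(file.path(data_dir, "samples.tsv"), counts)

de_km_w <- qlf_test(counts, samples, "W", "KM")
de_zero_km <- qlf_test(counts, samples, "KM", "ZERO")
write_results(de_km_w, file.path(data_dir, "de_km_w.tsv"))
write_results(de_zero_km, file.path(data_dir, "de_zero_km.tsv"))

n1 <- sum(!is.na(de_km_w$p) & de_km_w$p < 0.05)
n2 <- sum(!is.na(de_zero_km$p) & de_zero_km$p < 0.05)
cat("Tested genes:", sum(de_km_w$tested), "(KM vs W),",
    sum(de_zero_km$tested), "(ZERO vs KM)\n")
cat("DEGs at p < 0.05: KM vs W =", n1, "; ZERO vs KM =", n2, "\n")
deg_summary <- data.frame(contrast = c("KM_vs_W", "ZERO_vs_KM"),
                          n_tested = c(sum(de_km_w$tested), sum(de_zero_km$tested)),
                          n_deg_p05 = c(n1, n2))
write_results(deg_summary, file.path(res_dir, "deg_counts.tsv"))
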