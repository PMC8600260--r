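#!/usr/bin/env Rscript

# Stage 5 — set-level analyses on the KM-vs-W DEG lists (p < 0.05, 1.5-fold):
# the two-contrast Venn partition and one-sided Fisher over-representation
# of up/down DEGs over a gene-set collection. The collection is built here
# from the simulation itself: two sets seeded from truly up- and
# down-regulated genes (which the analysis should flag) and three random
# sets (which it should not).

suppressPackageStartupMessages(library(comprev))

data_dir <- "scratch/analysis/data"
res_dir <- "results/analysis"
dir.create(res_dir, recursive = TRUE, showWarnings = FALSE)

de_km_w <- read_results(file.path(data_dir, "de_km_w.tsv"))
de_zero_km <- read_results(file.path(data_dir, "de_zero_km.tsv"))
for (col in c("logFC", "p", "fdr")) {
  de_km_w[[col]] <- suppressWarnings(as.numeric(de_km_w[[col]]))
  de_zero_km[[col]] <- suppressWarnings(as.numeric(de_zero_km[[col]]))
}
de_km_w$tested <- as.logical(de_km_w$tested)
truth <- read_results(file.path(data_dir, "truth.tsv"))
truth$beta <- as.numeric(truth$beta)
truth$is_de <- as.logical(truth$is_de)

degs_a <- select_degs(de_km_w, 0.05, 1.5)
degs_b <- select_degs(de_zero_km, 0.05, 1.5)
vn <- venn(list(KM_vs_W = degs_a$gene, ZERO_vs_KM = degs_b$gene))
write_results(data.frame(region = names(vn), count = as.integer(vn)),
              file.path(res_dir, "venn.tsv"))
cat("Venn partition of DEG sets (p<0.05, >1.5-fold):\n")
print(vn)

set.seed(2)
up_true <- truth$gene[truth$is_de & truth$beta > 0]
down_true <- truth$gene[truth$is_de & truth$beta < 0]
sets <- list(
  up_module = sample(up_true, min(40, length(up_true))),
  down_module = sample(down_true, min(40, length(down_true))),
  random_a = sample(truth$gene, 40),
  random_b = sample(truth$gene, 40),
  random_c = sample(truth$gene, 40))
gmt <- file.path(data_dir, "synthetic_sets.gmt")
writeLines(vapply(names(sets), function(nm)
  paste(c(nm, "synthetic module", sets[[nm]]), collapse = "\t"),
  character(1)), gmt)

enr <- deg_gsea_lite(de_km_w, read_gmt(gmt), p_threshold = 0.05, min_fold = 1.5)
write_results(enr[, setdiff(names(enr), "members_by_logfc")],
              file.path(res_dir, "enrichment_km_w.tsv"))
cat("\nEnrichment over the DEG universe (one-sided Fisher):\n")
print(enr[, c("set", "n_up_overlap", "n_down_overlap", "p_up", "p_down",
              "direction_call")], digits = 3)
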