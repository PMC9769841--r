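#!/usr/bin/env Rscript
# Screen metadata factors for interference with community composition.
# Discrete factors (binary, minority level in > 10 samples): random forests
# predict the factor from PC scores over every (n, p) grid cell; a factor
# interferes when test AUC > 0.5 in at least 80% of splits somewhere on
# the grid, and its interfering PCs are those with positive training MDA
# in at least 80% of splits. Continuous covariates (age): identity-link
# Poisson GLM on all n PC scores with backward AIC elimination; retained
# PCs with p < 0.05 interfere.

library(pcdenoise)

seed <- 20260923L
clr_df <- read.delim("results/preprocess/clr.tsv", check.names = FALSE)
clr <- clr_matrix(as.matrix(clr_df[-1]), corrected = FALSE)
rownames(clr) <- clr_df$sample_id
metadata <- read.delim("results/study/metadata.tsv", check.names = FALSE)
metadata <- metadata[match(rownames(clr), metadata$sample_id), ]

grid <- grid_params(profile = "quick", seed = seed)
pcs_by_n <- pca_grid(clr, grid$n_values)

results <- list()
for (f in eligible_discrete_factors(metadata)) {
  results[[f]] <- identify_discrete_interference(pcs_by_n, metadata[[f]],
                                                 grid, factor_name = f)
  cat(sprintf("discrete %-16s interfering=%s (max positive-AUC rate %.2f)\n",
              f, results[[f]]$is_interfering,
              max(results[[f]]$cells$positive_auc_rate)))
}
for (f in intersect("age", names(metadata))) {
  results[[f]] <- identify_continuous_interference_grid(
    pcs_by_n, metadata[[f]], grid, factor_name = f)
  cat(sprintf("continuous %-14s interfering=%s\n", f,
              results[[f]]$is_interfering))
}

dir.create("results/confound", showWarnings = FALSE, recursive = TRUE)
cells <- do.call(rbind, lapply(results, function(ir)
  cbind(factor = ir$factor, kind = ir$kind, ir$cells)))
write.table(cells, "results/confound/interference.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
pc_sets <- lapply(results, function(ir)
  lapply(ir$interfering_pcs, as.integer))
jsonlite::write_json(pc_sets, "results/confound/interfering_pcs.json",
                     auto_unbox = FALSE)

for (f in names(results)) {
  ir <- results[[f]]
  if (ir$is_interfering) {
    ve <- ir$cells$variance_explained
    cat(sprintf("  %s: variance explained by interfering PCs %.2f-%.2f\n",
                f, min(ve, na.rm = TRUE), max(ve, na.rm = TRUE)))
  }
}
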