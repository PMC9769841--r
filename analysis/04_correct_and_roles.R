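#!/usr/bin/env Rscript
# Assess PC-regression correction for every interfering factor, the "all"
# combination, and the "none" negative control. Per grid cell, interfering
# PCs are regressed out of the CLR matrix and case/control random-forest
# AUC is compared before vs after correction on shared train/test splits;
# the signed fold change of median AUC and a Wilcoxon p-value summarize
# each cell. Pooling per-cell medians assigns each factor a noise (AUC
# rises), disease (AUC falls) or indeterminate role, and the correction
# used downstream is selected (highest fold change for noise factors, else
# the best-AUC uncorrected rerun).

library(pcdenoise)

seed <- 20260923L
clr_df <- read.delim("results/preprocess/clr.tsv", check.names = FALSE)
clr <- clr_matrix(as.matrix(clr_df[-1]), corrected = FALSE)
rownames(clr) <- clr_df$sample_id
metadata <- read.delim("results/study/metadata.tsv", check.names = FALSE)
metadata <- metadata[match(rownames(clr), metadata$sample_id), ]
labels <- as.integer(metadata$group != "control")

grid <- grid_params(profile = "quick", seed = seed)
pcs_by_n <- pca_grid(clr, grid$n_values)

# re-derive the interference screens (same seed as 03, hence identical)
interference <- list()
for (f in eligible_discrete_factors(metadata))
  interference[[f]] <- identify_discrete_interference(
    pcs_by_n, metadata[[f]], grid, factor_name = f)
for (f in intersect("age", names(metadata)))
  interference[[f]] <- identify_continuous_interference_grid(
    pcs_by_n, metadata[[f]], grid, factor_name = f)
interfering <- names(Filter(function(ir) ir$is_interfering, interference))
cat("interfering factors:", paste(interfering, collapse = ", "), "\n")

cache <- new.env(parent = emptyenv())
assessments <- list()
for (f in interfering)
  assessments[[f]] <- assess_correction(clr, labels, pcs_by_n,
                                        interference[f], grid,
                                        factor_set = f,
                                        before_cache = cache)
if (length(interfering) > 1)
  assessments[["all"]] <- assess_correction(clr, labels, pcs_by_n,
                                            interference[interfering],
                                            grid, factor_set = "all",
                                            before_cache = cache)
assessments[["none"]] <- assess_correction(clr, labels, pcs_by_n, list(),
                                           grid, factor_set = "none",
                                           before_cache = cache)

dir.create("results/correct", showWarnings = FALSE, recursive = TRUE)
cells <- do.call(rbind, lapply(assessments, function(a)
  cbind(factor_set = a$factor_set, a$cells)))
write.table(cells, "results/correct/auc_changes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
roles <- lapply(assessments, function(a)
  list(role = a$role, overall_fold = a$overall_fold,
       overall_p = a$overall_p))
jsonlite::write_json(roles, "results/correct/roles.json",
                     auto_unbox = TRUE, digits = NA)

for (f in names(assessments))
  cat(sprintf("  %-16s role=%-13s overall fold=%+.3f p=%.3g\n", f,
              assessments[[f]]$role, assessments[[f]]$overall_fold,
              assessments[[f]]$overall_p))

single <- assessments[setdiff(names(assessments), c("all", "none"))]
selection <- select_correction(single, clr, labels, pcs_by_n,
                               interference, grid)
jsonlite::write_json(selection[c("factor_set", "n", "p", "pc_set",
                                 "corrected", "criterion")],
                     "results/correct/selection.json",
                     auto_unbox = TRUE, digits = NA)
write.table(data.frame(sample_id = rownames(selection$matrix),
                       unclass(selection$matrix), check.names = FALSE),
            "results/correct/clr_selected.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("selected: factor_set=%s n=%d p=%.1f corrected=%s (criterion %.4f)\n",
            selection$factor_set, selection$n, selection$p,
            selection$corrected, selection$criterion))
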