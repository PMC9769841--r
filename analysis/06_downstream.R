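#!/usr/bin/env Rscript
# Downstream evaluation of the correction: ANOSIM and NMDS on Euclidean
# (Aitchison) distances before vs after correction; differential clinical
# indexes (Wilcoxon + Benjamini-Hochberg); random-forest diagnostic models
# on selected clinical indexes, indicator genera, and both combined; and
# linear (Levenberg-Marquardt) fits between indicator genera and clinical
# indexes.

library(pcdenoise)

seed <- 20260923L
read_mat <- function(path, corrected) {
  df <- read.delim(path, check.names = FALSE)
  m <- clr_matrix(as.matrix(df[-1]), corrected = corrected)
  rownames(m) <- df$sample_id
  m
}
before <- read_mat("results/preprocess/clr.tsv", FALSE)
after <- read_mat("results/correct/clr_selected.tsv", TRUE)
metadata <- read.delim("results/study/metadata.tsv", check.names = FALSE)
metadata <- metadata[match(rownames(before), metadata$sample_id), ]
labels <- as.integer(metadata$group != "control")
ind <- read.delim("results/indicators/indicators.tsv")
sel_genera <- ind$genus[ind$selected]
clin_cols <- intersect(c("CK", "Hb", "TG"), names(metadata))
clin <- metadata[clin_cols]

dir.create("results/evaluate", showWarnings = FALSE, recursive = TRUE)

an_before <- anosim_clr(before, labels, nperm = 999, seed = seed)
an_after <- anosim_clr(after, labels, nperm = 999, seed = seed + 1L)
nm_before <- nmds_clr(before, seed = seed)
nm_after <- nmds_clr(after, seed = seed + 1L)
jsonlite::write_json(
  list(anosim = list(before = an_before, after = an_after),
       nmds_stress = list(before = nm_before$stress,
                          after = nm_after$stress)),
  "results/evaluate/community_tests.json", auto_unbox = TRUE, digits = NA)
cat(sprintf("ANOSIM before: R=%.4f p=%.3g | after: R=%.4f p=%.3g\n",
            an_before$R, an_before$p, an_after$R, an_after$p))
cat(sprintf("NMDS stress before %.3f, after %.3f\n",
            nm_before$stress, nm_after$stress))

diffs <- differential_clinical_indexes(clin, labels)
write.table(diffs, "results/evaluate/clinical_differential.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
sel_idx <- diffs$index[diffs$selected]
cat("differential clinical indexes (BH-adjusted p < 0.05):",
    if (length(sel_idx)) paste(sel_idx, collapse = ", ") else "none", "\n")

models <- list()
if (length(sel_idx))
  models$clinical <- diagnostic_model(clin[sel_idx], labels, reps = 50,
                                      seed = seed, ntree = 200)
if (length(sel_genera))
  models$indicators <- diagnostic_model(
    unclass(after)[, sel_genera, drop = FALSE], labels, reps = 50,
    seed = seed, ntree = 200)
if (length(sel_idx) && length(sel_genera))
  models$combined <- diagnostic_model(
    cbind(clin[sel_idx], unclass(after)[, sel_genera, drop = FALSE]),
    labels, reps = 50, seed = seed, ntree = 200)
if (length(models)) {
  jsonlite::write_json(lapply(models, `[[`, "auc"),
                       "results/evaluate/diagnostic_auc.json",
                       auto_unbox = TRUE, digits = NA)
  roc_tab <- do.call(rbind, lapply(names(models), function(nm)
    cbind(model = nm, models[[nm]]$roc)))
  write.table(roc_tab, "results/evaluate/roc_points.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (nm in names(models))
    cat(sprintf("diagnostic AUC (%s): %.3f\n", nm, models[[nm]]$auc))
}

if (length(sel_genera)) {
  pairs <- expand.grid(genus = sel_genera, index = clin_cols,
                       stringsAsFactors = FALSE)
  cors <- correlate_indicator_clinical(after, clin, pairs)
  write.table(cors, "results/evaluate/correlations.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
  sig <- cors[cors$p < 0.05, ]
  cat(sprintf("indicator-clinical fits: %d pairs, %d with p < 0.05\n",
              nrow(cors), nrow(sig)))
  if (nrow(sig))
    for (i in seq_len(nrow(sig)))
      cat(sprintf("  %s ~ %s: slope %+.2f (r=%+.2f, p=%.2g)\n",
                  sig$index[i], sig$genus[i], sig$slope[i], sig$r[i],
                  sig$p[i]))
}
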