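#' Regress PC scores out of a CLR matrix
#'
#' Each genus column is regressed (ordinary least squares, with intercept)
#' on the supplied PC score columns; the residual matrix is the corrected
#' CLR table used downstream. With zero score columns this reduces to
#' per-genus mean centering.
#'
#' @param clr A \code{\link{clr_matrix}}.
#' @param pc_scores Samples x j matrix of PC scores (j may be 0); rows must
#'   align with \code{clr}.
#' @return A corrected \code{clr_matrix} (residuals).
#' @export
regress_out_pcs <- function(clr, pc_scores) {
  x <- unclass(as.matrix(clr))
  if (is.null(pc_scores) || NCOL(pc_scores) == 0) {
    res <- sweep(x, 2, colMeans(x))
  } else {
    p <- as.matrix(pc_scores)
    if (nrow(p) != nrow(x))
      stop("PC score rows do not align with CLR rows")
    design <- cbind(intercept = 1, p)
    qrd <- qr(design)
    if (qrd$rank < ncol(design)) {
      keep <- qrd$pivot[seq_len(qrd$rank)]
      message("dropping ", ncol(design) - qrd$rank,
              " collinear PC column(s)")
      qrd <- qr(design[, keep, drop = FALSE])
    }
    res <- qr.resid(qrd, x)
  }
  dimnames(res) <- dimnames(x)
  clr_matrix(res, corrected = TRUE,
             provenance = paste0(attr(clr, "provenance"),
                                 " | regressed ", NCOL(pc_scores), " PCs"))
}

#' Case/control classification AUC over repeated splits
#'
#' Random forests on genus-level CLR features over \code{reps} stratified
#' train/test splits. Splits are derived deterministically from \code{seed},
#' so calling with identical seed on corrected and uncorrected matrices
#' reuses identical splits and AUC differences reflect the correction only.
#'
#' @param features A \code{\link{clr_matrix}} (or numeric matrix).
#' @param labels Binary 0/1 case indicator.
#' @param p Training fraction per class.
#' @param reps Number of splits.
#' @param seed Integer seed.
#' @param ntree Trees per forest (default 500).
#' @param importance If TRUE, training-set mean-decrease-accuracy vectors
#'   are collected and attached as attribute \code{"mda"} (features x reps).
#' @return Numeric vector of test AUCs, length \code{reps}.
#' @export
case_control_auc <- function(features, labels, p, reps, seed = 1L,
                             ntree = 500, importance = FALSE) {
  x <- unclass(as.matrix(features))
  stopifnot(all(labels %in% c(0, 1)), sum(labels == 1) > 0,
            sum(labels == 0) > 0)
  splits <- .make_splits(labels, p, reps, .subseed(seed, 77))
  aucs <- numeric(reps)
  mda <- if (importance) matrix(NA_real_, ncol(x), reps,
                                dimnames = list(colnames(x), NULL))
  for (r in seq_len(reps)) {
    res <- .rf_split_auc(x, labels, splits[[r]], ntree,
                         .subseed(seed, 77, r), importance = importance)
    aucs[r] <- res$auc
    if (importance) mda[, r] <- res$mda
  }
  if (importance) attr(aucs, "mda") <- mda
  aucs
}

#' Signed fold change and significance of an AUC shift
#'
#' If the median AUC after correction is at least the median before, the
#' fold change is \code{median(after)/median(before)}; otherwise it is
#' \code{-median(before)/median(after)}, so its magnitude is always >= 1 and
#' its sign reports the direction. Significance is a two-sided Wilcoxon
#' comparison of the two AUC samples (rank-sum by default; a paired variant
#' is available since before/after runs share splits here).
#'
#' @param before,after Equal-length AUC vectors.
#' @param paired Use the signed-rank (paired) test (default FALSE).
#' @return List with \code{fold_change} and \code{wilcoxon_p}.
#' @export
auc_change <- function(before, after, paired = FALSE) {
  stopifnot(length(before) == length(after))
  mb <- stats::median(before)
  ma <- stats::median(after)
  if (mb == 0 || ma == 0) stop("zero median AUC")
  fold <- if (ma >= mb) ma / mb else -(mb / ma)
  p <- suppressWarnings(
    stats::wilcox.test(after, before, paired = paired)$p.value)
  if (is.nan(p)) p <- 1
  list(fold_change = fold, wilcoxon_p = p)
}

#' Assess the effect of correcting one factor set across the grid
#'
#' For every grid cell where the factor set's interfering PCs were
#' identified, the PCs are regressed out of the CLR matrix and case/control
#' AUC is measured before and after correction with shared splits.
#'
#' @param clr The uncorrected \code{\link{clr_matrix}}.
#' @param labels Binary 0/1 case indicator.
#' @param pcs_by_n Named list from \code{\link{pca_grid}}.
#' @param interference List of \code{interference_result}s for the factors
#'   in the set (their per-cell PC sets are unioned).
#' @param grid A \code{\link{grid_params}}.
#' @param factor_set Label for the corrected set (e.g. a factor name,
#'   \code{"all"}, or \code{"none"} for the negative-control rerun that
#'   regresses zero PCs).
#' @param before_cache Optional environment caching before-correction AUC
#'   vectors by cell, shared across factor sets.
#' @param alpha Significance level for the role call.
#' @return A \code{correction_assessment}: \code{cells} data frame (n, p,
#'   median AUC before/after, fold_change, wilcoxon_p), per-cell AUC
#'   vectors, \code{role}, \code{overall_fold} and \code{overall_p}.
#' @export
assess_correction <- function(clr, labels, pcs_by_n, interference, grid,
                              factor_set = "factor",
                              before_cache = NULL, alpha = 0.05) {
  cells <- expand.grid(n = grid$n_values, p = grid$p_values,
                       KEEP.OUT.ATTRS = FALSE)
  is_none <- identical(factor_set, "none")
  if (!is_none) {
    qual <- Reduce(`|`, lapply(interference, function(ir) ir$cells$qualifies))
    keep <- which(qual)
    if (!length(keep))
      stop("no grid cell qualifies for factor set '", factor_set, "'")
  } else {
    keep <- seq_len(nrow(cells))
  }
  cells <- cells[keep, , drop = FALSE]
  rownames(cells) <- NULL
  cells$median_before <- NA_real_
  cells$median_after <- NA_real_
  cells$fold_change <- NA_real_
  cells$wilcoxon_p <- NA_real_
  auc_before <- auc_after <- vector("list", nrow(cells))
  pc_sets <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    ci <- keep[i]
    n <- cells$n[i]
    p <- cells$p[i]
    pcs <- pcs_by_n[[as.character(n)]]
    pc_set <- if (is_none) integer() else
      sort(unique(unlist(lapply(interference, function(ir)
        ir$interfering_pcs[[ci]]))))
    pc_sets[[i]] <- pc_set
    cell_seed <- .subseed(grid$seed, 3, n, round(100 * p))
    key <- sprintf("n%d_p%g", n, p)
    before <- if (!is.null(before_cache) &&
                  !is.null(before_cache[[key]])) {
      before_cache[[key]]
    } else {
      b <- case_control_auc(clr, labels, p, grid$reps, cell_seed,
                            grid$ntree)
      if (!is.null(before_cache)) before_cache[[key]] <- b
      b
    }
    corrected <- regress_out_pcs(clr, pcs$scores[, pc_set, drop = FALSE])
    after <- case_control_auc(corrected, labels, p, grid$reps, cell_seed,
                              grid$ntree)
    ch <- auc_change(before, after)
    cells$median_before[i] <- stats::median(before)
    cells$median_after[i] <- stats::median(after)
    cells$fold_change[i] <- ch$fold_change
    cells$wilcoxon_p[i] <- ch$wilcoxon_p
    auc_before[[i]] <- before
    auc_after[[i]] <- after
  }
  out <- structure(list(factor_set = factor_set, cells = cells,
                        pc_sets = pc_sets, auc_before = auc_before,
                        auc_after = auc_after),
                   class = "correction_assessment")
  role <- assign_factor_role(out, alpha)
  out$role <- role$role
  out$overall_fold <- role$overall_fold
  out$overall_p <- role$overall_p
  out
}

#' Assign a noise or disease role to a corrected factor set
#'
#' Per-cell median AUCs before vs after correction are pooled across all
#' grid cells and compared with a two-sided Wilcoxon rank test; because
#' before/after runs share split seeds within each cell, the cells form
#' natural pairs and the signed-rank (paired) test is used by default. A
#' significant increase marks the factor as noise-associated (its
#' compositional footprint obscured the case/control signal); a significant
#' decrease marks it disease-associated (its footprint carried the
#' signal); otherwise the role is indeterminate.
#'
#' @param assessment A \code{correction_assessment}.
#' @param alpha Significance level (default 0.05).
#' @param paired Use the signed-rank test across cells (default TRUE); set
#'   FALSE for the unpaired rank-sum comparison.
#' @return List with \code{role} (\code{"noise"}, \code{"disease"} or
#'   \code{"indeterminate"}), \code{overall_fold} and \code{overall_p}.
#' @export
assign_factor_role <- function(assessment, alpha = 0.05, paired = TRUE) {
  mb <- assessment$cells$median_before
  ma <- assessment$cells$median_after
  p <- suppressWarnings(stats::wilcox.test(ma, mb, paired = paired)$p.value)
  if (is.nan(p)) p <- 1
  omb <- stats::median(mb)
  oma <- stats::median(ma)
  fold <- if (oma >= omb) oma / omb else -(omb / oma)
  role <- if (p < alpha && oma > omb) "noise"
  else if (p < alpha && oma < omb) "disease"
  else "indeterminate"
  list(role = role, overall_fold = fold, overall_p = p)
}

#' Select the correction used for indicator analysis
#'
#' If at least one factor was called noise, only the noise factors are
#' corrected and the grid cell with the highest fold change (ties: smaller
#' n, then smaller p) supplies the corrected matrix. Otherwise a second,
#' independent uncorrected classification pass is run and the cell with the
#' highest median AUC is selected, with the uncorrected matrix.
#'
#' @param assessments Named list of single-factor
#'   \code{correction_assessment}s (names are factor names).
#' @param clr The uncorrected \code{\link{clr_matrix}}.
#' @param labels Binary 0/1 case indicator.
#' @param pcs_by_n Named list from \code{\link{pca_grid}}.
#' @param interference Named list of \code{interference_result}s aligned
#'   with \code{assessments}.
#' @param grid A \code{\link{grid_params}}.
#' @return List with \code{factor_set}, \code{n}, \code{p}, \code{pc_set},
#'   \code{corrected} (logical), \code{matrix} (the CLR matrix to use
#'   downstream) and \code{criterion} (fold change or median AUC attained).
#' @export
select_correction <- function(assessments, clr, labels, pcs_by_n,
                              interference, grid) {
  roles <- vapply(assessments, function(a) a$role, character(1))
  noise_factors <- names(assessments)[roles == "noise"]
  if (length(noise_factors)) {
    cache <- new.env(parent = emptyenv())
    joint <- if (length(noise_factors) == 1) assessments[[noise_factors]]
    else assess_correction(clr, labels, pcs_by_n,
                           interference[noise_factors], grid,
                           factor_set = paste(noise_factors,
                                              collapse = "&"),
                           before_cache = cache)
    cells <- joint$cells
    ord <- order(-cells$fold_change, cells$n, cells$p)
    best <- ord[1]
    pcs <- pcs_by_n[[as.character(cells$n[best])]]
    pc_set <- joint$pc_sets[[best]]
    mat <- regress_out_pcs(clr, pcs$scores[, pc_set, drop = FALSE])
    return(list(factor_set = joint$factor_set, n = cells$n[best],
                p = cells$p[best], pc_set = pc_set, corrected = TRUE,
                matrix = mat, criterion = cells$fold_change[best]))
  }
  # all roles disease/indeterminate: second uncorrected pass, pick best AUC
  cells <- expand.grid(n = grid$n_values, p = grid$p_values,
                       KEEP.OUT.ATTRS = FALSE)
  cells$median_auc <- NA_real_
  for (i in seq_len(nrow(cells))) {
    aucs <- case_control_auc(clr, labels, cells$p[i], grid$reps,
                             .subseed(grid$seed, 9, cells$n[i],
                                      round(100 * cells$p[i])),
                             grid$ntree)
    cells$median_auc[i] <- stats::median(aucs)
  }
  ord <- order(-cells$median_auc, cells$n, cells$p)
  best <- ord[1]
  list(factor_set = "none", n = cells$n[best], p = cells$p[best],
       pc_set = integer(), corrected = FALSE, matrix = clr,
       criterion = cells$median_auc[best])
}
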