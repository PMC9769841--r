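#' Configure a full pipeline run
#'
#' Exactly one input source: a \code{\link{simulation_config}} (synthetic
#' study) or a list \code{files = list(counts=, metadata=)} of TSV paths.
#'
#' @param synthetic A \code{simulation_config}, or NULL.
#' @param files List with \code{counts} and \code{metadata} paths, or NULL.
#' @param grid A \code{\link{grid_params}}.
#' @param depth Rarefaction depth (default 10000).
#' @param pseudocount CLR pseudocount (default 1).
#' @param min_count,min_samples Low-abundance filter parameters.
#' @param continuous_factors Metadata columns screened as continuous
#'   confounders (default: continuous confounders of the synthetic config).
#' @param clinical_indexes Metadata columns treated as clinical indexes
#'   (default: clinical specs of the synthetic config).
#' @param alpha Significance level used throughout (default 0.05).
#' @param nperm Permutations for indicator and ANOSIM tests (default 999).
#' @param out_dir Output directory.
#' @param seed Global seed.
#' @return A \code{pipeline_config}.
#' @export
pipeline_config <- function(synthetic = NULL, files = NULL,
                            grid = grid_params(profile = "quick"),
                            depth = 10000, pseudocount = 1,
                            min_count = 10, min_samples = 2,
                            continuous_factors = NULL,
                            clinical_indexes = NULL,
                            alpha = 0.05, nperm = 999,
                            out_dir = "results/pipeline", seed = 1L) {
  if (is.null(synthetic) == is.null(files))
    stop("exactly one of 'synthetic' or 'files' must be given")
  if (!is.null(files)) {
    stopifnot(!is.null(files$counts), !is.null(files$metadata))
    for (f in unlist(files)) if (!file.exists(f))
      stop("input file not found: ", f)
  }
  if (is.null(continuous_factors) && !is.null(synthetic))
    continuous_factors <- vapply(
      Filter(function(cf) cf$kind == "continuous", synthetic$confounders),
      function(cf) cf$name, character(1))
  if (is.null(clinical_indexes) && !is.null(synthetic))
    clinical_indexes <- vapply(synthetic$clinical_specs,
                               function(sp) sp$index_name, character(1))
  structure(list(synthetic = synthetic, files = files, grid = grid,
                 depth = depth, pseudocount = pseudocount,
                 min_count = min_count, min_samples = min_samples,
                 continuous_factors = continuous_factors %||% character(),
                 clinical_indexes = clinical_indexes %||% character(),
                 alpha = alpha, nperm = nperm, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full confounder-denoising analysis
#'
#' Executes preprocess, PCA per n, confounder screening (eligible discrete
#' factors by random forest, continuous covariates by identity-link Poisson
#' GLM), correction assessment per interfering factor plus the "all"
#' combination and the "none" negative control, correction selection,
#' indicator analysis, and the downstream evaluations (alpha diversity,
#' ANOSIM/NMDS before vs after correction, differential clinical indexes,
#' diagnostic models, indicator-clinical correlations). All intermediate
#' tables are written under \code{out_dir} together with a manifest of
#' seeds, parameters and output checksums sufficient to re-run
#' bit-identically.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return Invisibly, a result bundle (list of all stage outputs).
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "input"
  res <- list(config = config)
  on.exit(
    if (!identical(stage, "done"))
      message("pipeline aborted at stage '", stage,
              "'; partial outputs kept in ", config$out_dir),
    add = TRUE)

  if (!is.null(config$synthetic)) {
    study <- generate_study(config$synthetic)
    counts <- study$counts
    metadata <- study$metadata
    res$truth <- study$truth
  } else {
    counts <- read_count_table(config$files$counts)
    metadata <- utils::read.delim(config$files$metadata,
                                  check.names = FALSE)
  }
  labels <- as.integer(metadata$group != "control")

  stage <- "preprocess"
  prep <- preprocess_counts(counts, config$min_count, config$min_samples,
                            config$depth, config$pseudocount,
                            seed = .subseed(config$seed, 11))
  keep <- match(rownames(prep$clr), metadata$sample_id)
  metadata <- metadata[keep, , drop = FALSE]
  labels <- labels[keep]
  res$counts <- prep$counts
  res$clr <- prep$clr
  write_count_table(prep$counts, file.path(config$out_dir,
                                           "counts_rarefied.tsv"))
  .write_tsv(data.frame(sample_id = rownames(prep$clr),
                        unclass(prep$clr), check.names = FALSE),
             file.path(config$out_dir, "clr.tsv"))

  stage <- "decompose"
  grid <- config$grid
  pcs_by_n <- pca_grid(prep$clr, grid$n_values)
  res$pcs_by_n <- pcs_by_n

  stage <- "confound"
  interference <- list()
  disc <- eligible_discrete_factors(metadata)
  for (f in disc)
    interference[[f]] <- identify_discrete_interference(
      pcs_by_n, metadata[[f]], grid, factor_name = f)
  for (f in config$continuous_factors)
    interference[[f]] <- identify_continuous_interference_grid(
      pcs_by_n, metadata[[f]], grid, config$alpha, factor_name = f)
  res$interference <- interference
  interfering <- names(Filter(function(ir) ir$is_interfering,
                              interference))
  cells_out <- do.call(rbind, lapply(interference, function(ir)
    cbind(factor = ir$factor, kind = ir$kind, ir$cells)))
  if (!is.null(cells_out))
    .write_tsv(cells_out, file.path(config$out_dir, "interference.tsv"))

  stage <- "correct"
  cache <- new.env(parent = emptyenv())
  assessments <- list()
  for (f in interfering)
    assessments[[f]] <- assess_correction(
      prep$clr, labels, pcs_by_n, interference[f], grid,
      factor_set = f, before_cache = cache, alpha = config$alpha)
  if (length(interfering) > 1)
    assessments[["all"]] <- assess_correction(
      prep$clr, labels, pcs_by_n, interference[interfering], grid,
      factor_set = "all", before_cache = cache, alpha = config$alpha)
  assessments[["none"]] <- assess_correction(
    prep$clr, labels, pcs_by_n, list(), grid, factor_set = "none",
    before_cache = cache, alpha = config$alpha)
  res$assessments <- assessments
  assess_out <- do.call(rbind, lapply(assessments, function(a)
    cbind(factor_set = a$factor_set, a$cells)))
  .write_tsv(assess_out, file.path(config$out_dir, "auc_changes.tsv"))
  roles <- lapply(assessments, function(a)
    list(role = a$role, overall_fold = a$overall_fold,
         overall_p = a$overall_p))
  jsonlite::write_json(roles, file.path(config$out_dir, "roles.json"),
                       auto_unbox = TRUE, digits = NA)

  stage <- "select"
  single <- assessments[setdiff(names(assessments), c("all", "none"))]
  selection <- select_correction(single, prep$clr, labels, pcs_by_n,
                                 interference, grid)
  res$selection <- selection
  jsonlite::write_json(selection[c("factor_set", "n", "p", "pc_set",
                                   "corrected", "criterion")],
                       file.path(config$out_dir, "selection.json"),
                       auto_unbox = TRUE, digits = NA)

  stage <- "indicators"
  ind <- indicator_analysis(selection$matrix, labels, config$nperm,
                            seed = .subseed(config$seed, 21),
                            alpha = config$alpha)
  sel_genera <- ind$genus[ind$selected]
  if (length(sel_genera)) {
    mda <- extract_indicator_mda(selection$matrix, labels, sel_genera,
                                 selection$p, grid$reps,
                                 seed = .subseed(config$seed, 22),
                                 ntree = grid$ntree)
    ind$median_mda <- attr(mda, "median")[match(ind$genus,
                                                rownames(mda))]
  } else {
    ind$median_mda <- NA_real_
  }
  res$indicators <- ind
  .write_tsv(ind, file.path(config$out_dir, "indicators.tsv"))

  stage <- "evaluate"
  res$alpha_diversity <- alpha_diversity(prep$counts)
  .write_tsv(res$alpha_diversity,
             file.path(config$out_dir, "alpha_diversity.tsv"))
  res$anosim <- list(
    before = anosim_clr(prep$clr, labels, config$nperm,
                        .subseed(config$seed, 31)),
    after = anosim_clr(selection$matrix, labels, config$nperm,
                       .subseed(config$seed, 32)))
  res$nmds <- list(
    before = nmds_clr(prep$clr, seed = .subseed(config$seed, 33)),
    after = nmds_clr(selection$matrix, seed = .subseed(config$seed, 34)))
  jsonlite::write_json(
    list(anosim = res$anosim,
         nmds_stress = list(before = res$nmds$before$stress,
                            after = res$nmds$after$stress)),
    file.path(config$out_dir, "community_tests.json"),
    auto_unbox = TRUE, digits = NA)

  clinical_cols <- intersect(config$clinical_indexes, names(metadata))
  if (length(clinical_cols)) {
    clin <- metadata[clinical_cols]
    res$clinical <- differential_clinical_indexes(clin, labels,
                                                  config$alpha)
    .write_tsv(res$clinical,
               file.path(config$out_dir, "clinical_differential.tsv"))
    sel_idx <- res$clinical$index[res$clinical$selected]
    models <- list()
    if (length(sel_idx))
      models$clinical <- diagnostic_model(clin[sel_idx], labels,
                                          reps = grid$reps,
                                          seed = .subseed(config$seed, 41),
                                          ntree = grid$ntree)
    if (length(sel_genera))
      models$indicators <- diagnostic_model(
        unclass(selection$matrix)[, sel_genera, drop = FALSE], labels,
        reps = grid$reps, seed = .subseed(config$seed, 42),
        ntree = grid$ntree)
    if (length(sel_idx) && length(sel_genera))
      models$combined <- diagnostic_model(
        cbind(clin[sel_idx],
              unclass(selection$matrix)[, sel_genera, drop = FALSE]),
        labels, reps = grid$reps, seed = .subseed(config$seed, 43),
        ntree = grid$ntree)
    res$diagnostic <- models
    if (length(models))
      jsonlite::write_json(lapply(models, function(mo) mo$auc),
                           file.path(config$out_dir,
                                     "diagnostic_auc.json"),
                           auto_unbox = TRUE, digits = NA)
    if (length(sel_genera)) {
      pairs <- expand.grid(genus = sel_genera, index = clinical_cols,
                           stringsAsFactors = FALSE)
      res$correlations <- correlate_indicator_clinical(selection$matrix,
                                                       clin, pairs)
      if (nrow(res$correlations))
        .write_tsv(res$correlations,
                   file.path(config$out_dir, "correlations.tsv"))
    }
  }

  stage <- "manifest"
  outputs <- sort(setdiff(list.files(config$out_dir), "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("pcdenoise")),
    seed = config$seed,
    grid = config$grid[c("n_values", "p_values", "reps",
                         "auc_rate_threshold", "mda_rate_threshold",
                         "ntree", "seed")],
    preprocessing = config[c("depth", "pseudocount", "min_count",
                             "min_samples")],
    alpha = config$alpha, nperm = config$nperm,
    input = if (!is.null(config$synthetic)) "synthetic" else "files",
    selection = selection[c("factor_set", "n", "p", "corrected")],
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(config$out_dir, outputs))),
      outputs)))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  stage <- "done"
  invisible(res)
}
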