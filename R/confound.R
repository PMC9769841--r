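#' Grid parameters for the confounder screen
#'
#' The screen evaluates every combination of PC count \code{n} and training
#' fraction \code{p}, with \code{reps} random train/test splits per cell.
#' A discrete factor is called interfering when the fraction of splits with
#' test AUC > 0.5 reaches \code{auc_rate_threshold} in at least one cell;
#' its interfering PCs are those with a positive training-set mean decrease
#' in accuracy in at least \code{mda_rate_threshold} of splits.
#'
#' @param n_values PC counts (default 5..30).
#' @param p_values Training fractions (default 0.5, 0.6, 0.7).
#' @param reps Splits per cell (default 100).
#' @param auc_rate_threshold Positive-AUC-rate cut (default 0.8).
#' @param mda_rate_threshold MDA-positivity rate cut (default 0.8).
#' @param ntree Random-forest trees per fit (default 500).
#' @param seed Integer seed.
#' @param profile \code{"full"} for the full grid, \code{"quick"} for a
#'   reduced desk-scale grid (n in {5,10,15}, 25 reps, 120 trees).
#' @return A \code{grid_params} object.
#' @export
grid_params <- function(n_values = 5:30, p_values = c(0.5, 0.6, 0.7),
                        reps = 100, auc_rate_threshold = 0.8,
                        mda_rate_threshold = 0.8, ntree = 500, seed = 1L,
                        profile = NULL) {
  if (!is.null(profile)) {
    profile <- match.arg(profile, c("full", "quick"))
    if (profile == "quick") {
      n_values <- c(5L, 10L, 15L)
      reps <- 25
      ntree <- 120
    }
  }
  stopifnot(all(p_values > 0 & p_values < 1), reps >= 1,
            auc_rate_threshold > 0, auc_rate_threshold <= 1,
            mda_rate_threshold > 0, mda_rate_threshold <= 1)
  structure(list(n_values = as.integer(n_values), p_values = p_values,
                 reps = as.integer(reps),
                 auc_rate_threshold = auc_rate_threshold,
                 mda_rate_threshold = mda_rate_threshold,
                 ntree = as.integer(ntree), seed = as.integer(seed)),
            class = "grid_params")
}

#' Discrete factors eligible for the random-forest screen
#'
#' A binary factor is eligible when its minority level occurs in more than
#' \code{min_count} samples, so both classes support AUC estimation.
#'
#' @param metadata Data frame of per-sample metadata.
#' @param factors Candidate column names; default: every 0/1 column other
#'   than identifiers.
#' @param min_count Minimum minority-class size that must be exceeded
#'   (default 10).
#' @return Character vector of eligible factor names.
#' @export
eligible_discrete_factors <- function(metadata, factors = NULL,
                                      min_count = 10) {
  if (is.null(factors)) {
    is_binary <- vapply(metadata, function(x)
      is.numeric(x) && all(x %in% c(0, 1)), logical(1))
    factors <- setdiff(names(metadata)[is_binary],
                       c("sample_id", "group"))
  }
  keep <- character()
  for (f in factors) {
    x <- metadata[[f]]
    if (!all(x %in% c(0, 1)))
      stop("factor '", f, "' is not binary 0/1")
    minority <- min(sum(x == 1), sum(x == 0))
    if (minority > min_count) keep <- c(keep, f)
  }
  keep
}

#' Screen a discrete factor for interference with community composition
#'
#' For every (n, p) grid cell, random forests are trained on PC scores to
#' predict the factor over \code{reps} stratified splits. The factor is
#' interfering when the positive-AUC rate (fraction of splits with test
#' AUC > 0.5) reaches the threshold in at least one cell; within qualifying
#' cells the interfering PCs are those whose training mean decrease in
#' accuracy is positive in at least the MDA-rate threshold of splits.
#'
#' @param pcs_by_n Named list of \code{\link{pca_scores}} results keyed by
#'   \code{n} (see \code{\link{pca_grid}}).
#' @param factor_values Binary 0/1 vector aligned with the score rows.
#' @param grid A \code{\link{grid_params}}.
#' @param factor_name Name used in reporting.
#' @return An \code{interference_result}: list with \code{factor},
#'   \code{kind}, \code{cells} (data frame: n, p, positive_auc_rate,
#'   variance_explained, qualifies), \code{interfering_pcs} (list per cell)
#'   and \code{is_interfering}.
#' @export
identify_discrete_interference <- function(pcs_by_n, factor_values, grid,
                                           factor_name = "factor") {
  stopifnot(inherits(grid, "grid_params"),
            all(factor_values %in% c(0, 1)))
  cells <- expand.grid(n = grid$n_values, p = grid$p_values,
                       KEEP.OUT.ATTRS = FALSE)
  cells$positive_auc_rate <- NA_real_
  cells$variance_explained <- NA_real_
  cells$qualifies <- FALSE
  pc_sets <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    n <- cells$n[ci]
    p <- cells$p[ci]
    pcs <- pcs_by_n[[as.character(n)]]
    if (is.null(pcs)) stop("no decomposition provided for n = ", n)
    splits <- .make_splits(factor_values, p, grid$reps,
                           .subseed(grid$seed, n, round(100 * p)))
    aucs <- numeric(grid$reps)
    mda_pos <- integer(pcs$n)
    for (r in seq_len(grid$reps)) {
      res <- .rf_split_auc(pcs$scores, factor_values, splits[[r]],
                           grid$ntree,
                           .subseed(grid$seed, n, round(100 * p), r),
                           importance = TRUE)
      aucs[r] <- res$auc
      mda_pos <- mda_pos + (res$mda > 0)
    }
    cells$positive_auc_rate[ci] <- mean(aucs > 0.5)
    if (cells$positive_auc_rate[ci] >= grid$auc_rate_threshold) {
      cells$qualifies[ci] <- TRUE
      pc_sets[[ci]] <-
        which(mda_pos >= grid$mda_rate_threshold * grid$reps)
      cells$variance_explained[ci] <-
        variance_explained_by(pcs, pc_sets[[ci]])
    } else {
      pc_sets[[ci]] <- integer()
    }
  }
  structure(list(factor = factor_name, kind = "discrete", cells = cells,
                 interfering_pcs = pc_sets,
                 is_interfering = any(cells$qualifies)),
            class = "interference_result")
}

# Poisson identity-link GLM fit with safe starting values; falls back to a
# fit anchored by an offset at the covariate minimum when the identity link
# cannot hold positivity.
.poisson_identity_fit <- function(y, X) {
  dat <- data.frame(y = y, X)
  vars <- colnames(X)
  form <- stats::reformulate(vars, "y")
  fit <- tryCatch(
    stats::glm(form, data = dat, family = stats::poisson("identity"),
               start = c(mean(y), rep(0, length(vars)))),
    error = function(e) NULL)
  if (is.null(fit)) {
    message("identity-link Poisson fit failed; refitting with offset at ",
            "the covariate minimum")
    dat$off <- rep(min(y), length(y))
    form <- stats::as.formula(paste(
      "y ~ 0 + offset(off) +", paste(vars, collapse = " + ")))
    fit <- stats::glm(form, data = dat,
                      family = stats::poisson("identity"),
                      start = rep(0, length(vars)))
  }
  fit
}

# Backward AIC elimination for the identity-link Poisson model. stats::step
# cannot forward starting values to the identity-link refits, so the
# elimination loop is explicit: drop the term whose removal lowers AIC most,
# until no removal improves AIC.
.backward_aic_poisson <- function(y, X) {
  vars <- colnames(X)
  current <- .poisson_identity_fit(y, X[, vars, drop = FALSE])
  repeat {
    if (length(vars) == 0) break
    aics <- vapply(vars, function(v) {
      keep <- setdiff(vars, v)
      f <- if (length(keep))
        tryCatch(.poisson_identity_fit(y, X[, keep, drop = FALSE]),
                 error = function(e) NULL)
      else
        tryCatch(stats::glm(y ~ 1, family = stats::poisson("identity"),
                            start = mean(y)),
                 error = function(e) NULL)
      if (is.null(f)) Inf else stats::AIC(f)
    }, numeric(1))
    best <- which.min(aics)
    if (aics[best] < stats::AIC(current)) {
      drop_var <- vars[best]
      vars <- setdiff(vars, drop_var)
      current <- if (length(vars))
        .poisson_identity_fit(y, X[, vars, drop = FALSE])
      else
        stats::glm(y ~ 1, family = stats::poisson("identity"),
                   start = mean(y))
    } else break
  }
  list(fit = current, vars = vars)
}

#' Screen a continuous covariate for interference via a Poisson GLM
#'
#' The covariate (rounded to integer, e.g. age or BMI) is regressed on all
#' \code{n} PC scores with an identity-link Poisson GLM; backward AIC
#' elimination is applied, and PCs retained with coefficient p-values below
#' \code{alpha} are the interfering PCs.
#'
#' @param pcs A \code{\link{pca_scores}} result.
#' @param values Strictly positive covariate vector.
#' @param alpha Significance level (default 0.05).
#' @param factor_name Name used in reporting.
#' @return An \code{interference_result} with \code{glm_pvalues} for the
#'   retained PCs, \code{interfering_pcs}, \code{variance_explained} and
#'   \code{is_interfering}.
#' @export
identify_continuous_interference <- function(pcs, values, alpha = 0.05,
                                             factor_name = "covariate") {
  stopifnot(inherits(pcs, "pc_decomposition"))
  if (any(values <= 0))
    stop("continuous covariate must be strictly positive")
  y <- round(values)
  X <- as.data.frame(pcs$scores)
  sel <- .backward_aic_poisson(y, X)
  pvals <- numeric(0)
  if (length(sel$vars)) {
    coefs <- summary(sel$fit)$coefficients
    rows <- intersect(sel$vars, rownames(coefs))
    pvals <- coefs[rows, "Pr(>|z|)"]
    names(pvals) <- rows
  }
  interfering <- sort(match(names(pvals)[pvals < alpha],
                            colnames(pcs$scores)))
  structure(list(factor = factor_name, kind = "continuous",
                 glm_pvalues = pvals,
                 interfering_pcs = interfering,
                 variance_explained = variance_explained_by(pcs,
                                                            interfering),
                 is_interfering = length(interfering) > 0),
            class = "interference_result")
}

#' Continuous-covariate screen across the n grid
#'
#' Refits \code{\link{identify_continuous_interference}} at every \code{n},
#' mirroring the per-cell treatment of discrete factors (continuous factors
#' do not involve \code{p}).
#'
#' @inheritParams identify_discrete_interference
#' @param values Strictly positive covariate vector.
#' @param alpha Significance level.
#' @return An \code{interference_result} with per-\code{n} cells; the
#'   \code{interfering_pcs} list is keyed like \code{cells} rows (one row
#'   per n, replicated across p values for grid alignment).
#' @export
identify_continuous_interference_grid <- function(pcs_by_n, values, grid,
                                                  alpha = 0.05,
                                                  factor_name = "covariate") {
  per_n <- lapply(grid$n_values, function(n)
    identify_continuous_interference(pcs_by_n[[as.character(n)]], values,
                                     alpha, factor_name))
  names(per_n) <- as.character(grid$n_values)
  cells <- expand.grid(n = grid$n_values, p = grid$p_values,
                       KEEP.OUT.ATTRS = FALSE)
  pc_sets <- vector("list", nrow(cells))
  cells$positive_auc_rate <- NA_real_
  cells$variance_explained <- NA_real_
  cells$qualifies <- FALSE
  for (ci in seq_len(nrow(cells))) {
    res <- per_n[[as.character(cells$n[ci])]]
    pc_sets[[ci]] <- res$interfering_pcs
    cells$variance_explained[ci] <- res$variance_explained
    cells$qualifies[ci] <- res$is_interfering
  }
  structure(list(factor = factor_name, kind = "continuous", cells = cells,
                 interfering_pcs = pc_sets, per_n = per_n,
                 is_interfering = any(cells$qualifies)),
            class = "interference_result")
}
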