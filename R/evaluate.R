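#' Alpha diversity: richness and Pielou's evenness
#'
#' Richness is the number of genera with count > 0; Pielou's J is Shannon
#' entropy (natural log, on proportions, via \code{vegan::diversity})
#' divided by \code{log(richness)}. J is NA when richness <= 1.
#'
#' @param counts A rarefied \code{\link{genus_count_table}}.
#' @return Data frame with \code{sample_id}, \code{richness},
#'   \code{pielou}.
#' @export
alpha_diversity <- function(counts) {
  m <- unclass(as.matrix(counts))
  richness <- rowSums(m > 0)
  H <- vegan::diversity(m, index = "shannon")
  J <- ifelse(richness > 1, H / log(richness), NA_real_)
  data.frame(sample_id = rownames(m), richness = richness, pielou = J,
             row.names = NULL, stringsAsFactors = FALSE)
}

# ANOSIM R from a dist object and group labels.
.anosim_r <- function(r, within) {
  M <- length(r)
  (mean(r[!within]) - mean(r[within])) / (M / 2)
}

#' Analysis of similarity on Euclidean CLR distances
#'
#' ANOSIM on the Euclidean distances between CLR rows (the Aitchison
#' distance): R contrasts mean between-group vs within-group distance
#' ranks, ~0 under no structure and near 1 for complete separation. The
#' permutation p-value is exact (full enumeration of label assignments)
#' when the number of distinct assignments is at most \code{exhaustive_max},
#' otherwise estimated from \code{nperm} random permutations.
#'
#' @param matrix A \code{\link{clr_matrix}}.
#' @param labels Binary 0/1 group labels.
#' @param nperm Random permutations (default 999).
#' @param seed Integer seed.
#' @param exhaustive_max Enumeration bound (default 10000 assignments).
#' @return List with \code{R}, \code{p} and \code{exact} (logical).
#' @export
anosim_clr <- function(matrix, labels, nperm = 999, seed = 1L,
                       exhaustive_max = 10000) {
  x <- unclass(as.matrix(matrix))
  stopifnot(sum(labels == 1) >= 2, sum(labels == 0) >= 2)
  d <- stats::dist(x)
  if (max(d) == min(d)) return(list(R = 0, p = 1, exact = TRUE))
  r <- rank(d)
  m <- nrow(x)
  pair_i <- pair_j <- integer(0)
  for (i in seq_len(m - 1)) {
    pair_i <- c(pair_i, rep(i, m - i))
    pair_j <- c(pair_j, (i + 1):m)
  }
  within_for <- function(lab) lab[pair_i] == lab[pair_j]
  R_obs <- .anosim_r(r, within_for(labels))
  n1 <- sum(labels == 1)
  if (choose(m, n1) <= exhaustive_max) {
    combos <- utils::combn(m, n1)
    R_all <- apply(combos, 2, function(idx) {
      lab <- integer(m)
      lab[idx] <- 1L
      .anosim_r(r, within_for(lab))
    })
    p <- mean(R_all >= R_obs - 1e-12)
    return(list(R = R_obs, p = p, exact = TRUE))
  }
  set.seed(seed)
  ge <- 0L
  for (b in seq_len(nperm)) {
    lp <- sample(labels)
    if (.anosim_r(r, within_for(lp)) >= R_obs - 1e-12) ge <- ge + 1L
  }
  list(R = R_obs, p = (1 + ge) / (1 + nperm), exact = FALSE)
}

#' Nonmetric multidimensional scaling of CLR distances
#'
#' Kruskal stress-1 NMDS of the Euclidean (Aitchison) distances, via
#' \code{vegan::monoMDS} from a metric-scaling start.
#'
#' @param matrix A \code{\link{clr_matrix}} (or a \code{dist}).
#' @param k Target dimensionality (default 2; must be < number of samples).
#' @param seed Integer seed.
#' @param maxit Maximum iterations (default 500).
#' @return List with \code{coordinates} (samples x k) and \code{stress}.
#' @export
nmds_clr <- function(matrix, k = 2, seed = 1L, maxit = 500) {
  d <- if (inherits(matrix, "dist")) matrix else
    stats::dist(unclass(as.matrix(matrix)))
  m <- attr(d, "Size")
  stopifnot(k < m)
  set.seed(seed)
  fit <- vegan::monoMDS(d, k = k, model = "global", maxit = maxit)
  if (isTRUE(fit$icause == 1L))
    warning("NMDS hit the iteration cap (", maxit,
            "); best configuration returned")
  list(coordinates = fit$points, stress = fit$stress)
}

#' Differential clinical indexes between cases and controls
#'
#' Two-sided Wilcoxon rank-sum per index, Benjamini-Hochberg adjustment
#' across all tested indexes; an index is selected when its adjusted p is
#' below \code{alpha}.
#'
#' @param clinical Data frame of per-sample clinical index values (missing
#'   values allowed).
#' @param labels Binary 0/1 case indicator.
#' @param alpha Selection cut on the adjusted p (default 0.05).
#' @return Data frame with \code{index}, \code{wilcoxon_p},
#'   \code{bh_adjusted_p}, \code{selected}.
#' @export
differential_clinical_indexes <- function(clinical, labels, alpha = 0.05) {
  keep <- character()
  pvals <- numeric()
  for (nm in names(clinical)) {
    v <- clinical[[nm]]
    if (!is.numeric(v)) next
    ok1 <- sum(!is.na(v[labels == 1]))
    ok0 <- sum(!is.na(v[labels == 0]))
    if (ok1 < 2 || ok0 < 2) {
      message("index ", nm, " lacks values in one group; excluded")
      next
    }
    pvals <- c(pvals, suppressWarnings(
      stats::wilcox.test(v[labels == 1], v[labels == 0])$p.value))
    keep <- c(keep, nm)
  }
  if (!length(keep)) stop("no testable clinical index")
  adj <- stats::p.adjust(pvals, method = "BH")
  data.frame(index = keep, wilcoxon_p = pvals, bh_adjusted_p = adj,
             selected = adj < alpha, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Random-forest diagnostic model with pooled ROC
#'
#' Repeated stratified splits (fraction \code{p} for training); test-set
#' class probabilities are pooled across repetitions into a single ROC
#' curve with trapezoidal AUC (via \pkg{pROC}).
#'
#' @param features Numeric matrix or data frame of predictors (selected
#'   clinical indexes, indicator genus CLR values, or both).
#' @param labels Binary 0/1 case indicator.
#' @param reps Number of splits (default 100).
#' @param p Training fraction (default 0.7).
#' @param seed Integer seed.
#' @param ntree Trees per forest (default 500).
#' @return List with \code{roc} (data frame fpr/tpr) and \code{auc}.
#' @export
diagnostic_model <- function(features, labels, reps = 100, p = 0.7,
                             seed = 1L, ntree = 500) {
  x <- as.matrix(features)
  if (ncol(x) == 0) stop("empty feature set")
  if (anyNA(x)) {
    drop <- stats::complete.cases(x)
    x <- x[drop, , drop = FALSE]
    labels <- labels[drop]
  }
  splits <- .make_splits(labels, p, reps, .subseed(seed, 5))
  scores <- numeric(0)
  truth <- integer(0)
  for (r in seq_len(reps)) {
    train <- splits[[r]]
    test <- setdiff(seq_along(labels), train)
    set.seed(.subseed(seed, 5, r))
    fit <- randomForest::randomForest(x[train, , drop = FALSE],
                                      factor(labels[train],
                                             levels = c(0, 1)),
                                      ntree = ntree)
    scores <- c(scores, stats::predict(fit, x[test, , drop = FALSE],
                                       type = "prob")[, "1"])
    truth <- c(truth, labels[test])
  }
  roc <- pROC::roc(truth, scores, quiet = TRUE, direction = "<",
                   levels = c(0, 1))
  list(roc = data.frame(fpr = rev(1 - roc$specificities),
                        tpr = rev(roc$sensitivities)),
       auc = as.numeric(pROC::auc(roc)))
}

#' Linear correlation between indicator genera and clinical indexes
#'
#' Straight-line fits of index on genus CLR value via damped least squares
#' (Levenberg-Marquardt, \code{minpack.lm::nlsLM}; for a linear model the
#' iteration converges to the ordinary least-squares solution). Reports the
#' slope, Pearson r, and the two-sided t-test p-value on the slope.
#'
#' @param matrix The selected \code{\link{clr_matrix}}.
#' @param clinical Data frame of clinical index values.
#' @param pairs Data frame with columns \code{genus} and \code{index}.
#' @return Data frame with \code{genus}, \code{index}, \code{slope},
#'   \code{r}, \code{p}, \code{n}; pairs with a constant predictor or fewer
#'   than 3 complete observations are skipped with a message.
#' @export
correlate_indicator_clinical <- function(matrix, clinical, pairs) {
  xmat <- unclass(as.matrix(matrix))
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    gname <- pairs$genus[i]
    iname <- pairs$index[i]
    j <- match(gname, colnames(xmat))
    if (is.na(j)) stop("unknown genus: ", gname)
    xv <- xmat[, j]
    yv <- clinical[[iname]]
    ok <- !is.na(xv) & !is.na(yv)
    if (sum(ok) < 3) {
      message("pair ", gname, " / ", iname, ": fewer than 3 complete ",
              "observations; skipped")
      next
    }
    xv <- xv[ok]; yv <- yv[ok]
    if (stats::var(xv) == 0) {
      message("pair ", gname, " / ", iname, ": constant predictor; skipped")
      next
    }
    df <- data.frame(x = xv, y = yv)
    start <- unname(stats::coef(stats::lm(y ~ x, df)))
    fit <- minpack.lm::nlsLM(y ~ a + b * x, data = df,
                             start = list(a = start[1], b = start[2]))
    sm <- summary(fit)$coefficients
    rows[[length(rows) + 1]] <- data.frame(
      genus = gname, index = iname, slope = sm["b", "Estimate"],
      r = stats::cor(xv, yv), p = sm["b", "Pr(>|t|)"], n = length(xv),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}
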