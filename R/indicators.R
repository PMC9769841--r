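# Indicator-genus analysis on (corrected) CLR values. Corrected CLR values
# can be negative, so every genus column is min-shifted to non-negative
# values before the specificity/fidelity statistic is computed; the shift
# is order-preserving and removes any additive constant.

.min_shift <- function(v) v - min(v)

# Core IndVal-style statistic for one genus and one side.
.indval_stat <- function(v, labels, side_is_case) {
  vp <- .min_shift(v)
  g1 <- vp[if (side_is_case) labels == 1 else labels == 0]
  g2 <- vp[if (side_is_case) labels != 1 else labels != 0]
  m1 <- mean(g1)
  m2 <- mean(g2)
  if (m1 + m2 == 0) return(NA_real_)
  A <- m1 / (m1 + m2)
  B <- mean(g1 > 0)
  sqrt(A * B)
}

#' Indicator value of a genus for one group
#'
#' The classic indicator value: \code{sqrt(A * B)} where A (specificity) is
#' the group's share of the mean min-shifted abundance and B (fidelity) is
#' the fraction of group samples where the genus is present (min-shifted
#' value > 0). 1 means exclusive to and ubiquitous in the group.
#'
#' @param matrix A \code{\link{clr_matrix}} (corrected or not).
#' @param labels Binary 0/1 case indicator.
#' @param genus Genus name or column index.
#' @param side \code{"case"} or \code{"control"}.
#' @return The statistic in [0, 1], or NA (with a message) for a genus
#'   constant across all samples.
#' @export
indicator_value <- function(matrix, labels, genus,
                            side = c("case", "control")) {
  side <- match.arg(side)
  x <- unclass(as.matrix(matrix))
  j <- if (is.character(genus)) match(genus, colnames(x)) else genus
  if (is.na(j)) stop("unknown genus: ", genus)
  v <- x[, j]
  if (max(v) == min(v)) {
    message("genus ", genus, " is constant; indicator value undefined")
    return(NA_real_)
  }
  .indval_stat(v, labels, side == "case")
}

#' Permutation test of an indicator value
#'
#' The observed statistic is the maximum over the two sides; under each
#' label permutation the side is re-chosen as the maximizing group, and
#' \code{perm_p = (1 + #\{perm stat >= observed\}) / (1 + nperm)}.
#'
#' @inheritParams indicator_value
#' @param nperm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return List with \code{stat}, \code{side} and \code{perm_p}.
#' @export
indicator_permutation_test <- function(matrix, labels, genus, nperm = 999,
                                       seed = 1L) {
  stopifnot(nperm >= 99)
  x <- unclass(as.matrix(matrix))
  j <- if (is.character(genus)) match(genus, colnames(x)) else genus
  v <- x[, j]
  if (max(v) == min(v))
    return(list(stat = NA_real_, side = NA_character_, perm_p = 1))
  s_case <- .indval_stat(v, labels, TRUE)
  s_ctrl <- .indval_stat(v, labels, FALSE)
  obs <- max(s_case, s_ctrl)
  side <- if (s_case >= s_ctrl) "case" else "control"
  set.seed(seed)
  ge <- 0L
  for (b in seq_len(nperm)) {
    lp <- sample(labels)
    sp <- max(.indval_stat(v, lp, TRUE), .indval_stat(v, lp, FALSE))
    if (sp >= obs - 1e-12) ge <- ge + 1L
  }
  list(stat = obs, side = side, perm_p = (1 + ge) / (1 + nperm))
}

#' One-tailed Welch test of a group's CLR elevation
#'
#' Tests whether the side group's mean CLR value exceeds the other group's
#' (Welch two-sample t, alternative "greater").
#'
#' @inheritParams indicator_value
#' @return One-tailed p-value. With zero variance in both groups the means
#'   are compared exactly and p is 0 or 1.
#' @export
one_tailed_location_test <- function(matrix, labels, genus,
                                     side = c("case", "control")) {
  side <- match.arg(side)
  x <- unclass(as.matrix(matrix))
  j <- if (is.character(genus)) match(genus, colnames(x)) else genus
  g1 <- x[if (side == "case") labels == 1 else labels == 0, j]
  g2 <- x[if (side == "case") labels != 1 else labels != 0, j]
  stopifnot(length(g1) >= 2, length(g2) >= 2)
  if (stats::var(g1) == 0 && stats::var(g2) == 0)
    return(if (mean(g1) > mean(g2)) 0 else 1)
  stats::t.test(g1, g2, alternative = "greater")$p.value
}

#' Extract random-forest importances of indicator genera
#'
#' Reruns the case/control classification at the selected (n, p) cell with
#' importance recording and returns each indicator genus's training-set
#' mean-decrease-accuracy vector across the repeated splits.
#'
#' @param features The selected \code{\link{clr_matrix}}.
#' @param labels Binary 0/1 case indicator.
#' @param genera Character vector of indicator genus names.
#' @param p Training fraction of the selected cell.
#' @param reps Number of splits.
#' @param seed Integer seed (use the selected cell's seed to reproduce the
#'   classification run).
#' @param ntree Trees per forest.
#' @return Matrix genera x reps of MDA values, plus attribute
#'   \code{"median"} (per-genus median MDA).
#' @export
extract_indicator_mda <- function(features, labels, genera, p, reps,
                                  seed = 1L, ntree = 500) {
  x <- unclass(as.matrix(features))
  missing <- setdiff(genera, colnames(x))
  if (length(missing))
    stop("genera absent from feature set: ",
         paste(missing, collapse = ", "))
  aucs <- case_control_auc(x, labels, p, reps, seed, ntree,
                           importance = TRUE)
  mda <- attr(aucs, "mda")[genera, , drop = FALSE]
  attr(mda, "median") <- apply(mda, 1, stats::median)
  mda
}

#' Full indicator screen over all genera
#'
#' @inheritParams indicator_permutation_test
#' @param alpha Significance cut on the permutation p (default 0.05).
#' @return Data frame with one row per testable genus: \code{genus},
#'   \code{side}, \code{stat}, \code{perm_p}, \code{t_p},
#'   \code{effect_direction} (sign of the case-minus-control mean CLR
#'   difference) and \code{selected}.
#' @export
indicator_analysis <- function(matrix, labels, nperm = 999, seed = 1L,
                               alpha = 0.05) {
  x <- unclass(as.matrix(matrix))
  rows <- list()
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    if (max(v) == min(v)) {
      message("skipping constant genus ", colnames(x)[j])
      next
    }
    pt <- indicator_permutation_test(matrix, labels, j, nperm,
                                     .subseed(seed, j))
    tp <- one_tailed_location_test(matrix, labels, j, pt$side)
    rows[[length(rows) + 1]] <- data.frame(
      genus = colnames(x)[j], side = pt$side, stat = pt$stat,
      perm_p = pt$perm_p, t_p = tp,
      effect_direction = sign(mean(v[labels == 1]) -
                                mean(v[labels == 0])),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$selected <- out$perm_p < alpha
  out
}
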