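#' Principal-component scores of a CLR matrix
#'
#' PCA of the column-centered (per-genus) CLR matrix via SVD; columns are
#' not scaled since CLR already puts genera on a common log scale. Scores
#' are the projections of samples onto the top-\code{n} right singular
#' directions; explained variances are the eigenvalues of the sample
#' covariance.
#'
#' @param clr A \code{\link{clr_matrix}}.
#' @param n Number of PCs to retain (the confounder screen walks a grid of
#'   \code{n} values).
#' @return A \code{pc_decomposition}: list with \code{n}, \code{scores}
#'   (samples x n), \code{explained} (length n, non-increasing),
#'   \code{loadings} (genera x n) and \code{center} (per-genus means).
#' @export
pca_scores <- function(clr, n) {
  x <- unclass(as.matrix(clr))
  m <- nrow(x)
  rank_max <- min(m - 1L, ncol(x))
  if (n < 1 || n > rank_max)
    stop("n must be between 1 and ", rank_max,
         " (min of samples-1 and genera)")
  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  sv <- svd(xc, nu = n, nv = n)
  scores <- sv$u %*% diag(sv$d[seq_len(n)], n, n)
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(n)))
  explained <- sv$d[seq_len(n)]^2 / (m - 1)
  loadings <- sv$v
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(n)))
  structure(list(n = as.integer(n), scores = scores, explained = explained,
                 loadings = loadings, center = center),
            class = "pc_decomposition")
}

#' Fraction of PC variance attributable to a subset of PCs
#'
#' \code{sum(explained[subset]) / sum(explained[1:n])}: the "variance
#' explained by interfering PCs" summary used to quantify how much of the
#' community structure a confounding factor accounts for.
#'
#' @param pcs A \code{\link{pca_scores}} result.
#' @param subset Integer PC indices (may be empty).
#' @return A fraction in [0, 1].
#' @export
variance_explained_by <- function(pcs, subset) {
  stopifnot(inherits(pcs, "pc_decomposition"))
  subset <- as.integer(subset)
  if (length(subset) && (min(subset) < 1 || max(subset) > pcs$n))
    stop("subset must lie within 1..", pcs$n)
  if (!length(subset)) return(0)
  sum(pcs$explained[subset]) / sum(pcs$explained)
}

#' PCA decompositions for a grid of PC counts
#'
#' @param clr A \code{\link{clr_matrix}}.
#' @param n_values Integer vector of PC counts.
#' @return Named list of \code{pc_decomposition}, keyed by \code{n}.
#' @export
pca_grid <- function(clr, n_values) {
  out <- lapply(n_values, function(n) pca_scores(clr, n))
  names(out) <- as.character(n_values)
  out
}
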