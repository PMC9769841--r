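#' Construct a genus count table
#'
#' @param counts Non-negative integer matrix, samples in rows, genera in
#'   columns. Row and column names are the sample and genus identifiers.
#' @return A \code{genus_count_table} (an integer matrix with class
#'   attribute).
#' @export
genus_count_table <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("S%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("genus_%03d", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("duplicate sample or genus identifiers")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  class(counts) <- c("genus_count_table", class(counts))
  counts
}

#' Read / write genus count tables as TSV
#'
#' Rows are samples, columns genera; the first column holds sample ids.
#' @param path File path.
#' @return \code{read_count_table}: a \code{\link{genus_count_table}}.
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  genus_count_table(as.matrix(df))
}

#' @rdname read_count_table
#' @param table A \code{genus_count_table}.
#' @export
write_count_table <- function(table, path) {
  df <- data.frame(sample_id = rownames(table),
                   unclass(table)[, , drop = FALSE],
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter low-abundance genus counts
#'
#' Cells below \code{min_count} are zeroed, then genera with nonzero counts
#' in fewer than \code{min_samples} samples are removed. Samples are never
#' dropped.
#'
#' @param table A \code{\link{genus_count_table}}.
#' @param min_count Counts strictly below this are set to 0 (default 10).
#' @param min_samples Minimum number of samples a genus must remain present
#'   in (default 2).
#' @return The filtered \code{genus_count_table}.
#' @export
filter_low_abundance <- function(table, min_count = 10, min_samples = 2) {
  stopifnot(inherits(table, "genus_count_table"))
  m <- unclass(table)
  m[m < min_count] <- 0L
  keep <- colSums(m > 0) >= min_samples
  if (!any(keep))
    stop("no genus survives low-abundance filtering")
  genus_count_table(m[, keep, drop = FALSE])
}

#' Rarefy samples to an even sequencing depth
#'
#' Reads are subsampled without replacement to exactly \code{depth} per
#' sample; samples with fewer total reads are dropped with a message.
#' Subsampling is delegated to \code{\link[vegan]{rrarefy}}.
#'
#' @param table A \code{\link{genus_count_table}}.
#' @param depth Target depth (default 10000).
#' @param seed Integer seed.
#' @return A \code{genus_count_table} whose rows all sum to \code{depth}.
#' @export
rarefy_even_depth <- function(table, depth = 10000, seed = 1L) {
  stopifnot(inherits(table, "genus_count_table"), depth > 0)
  totals <- rowSums(table)
  keep <- totals >= depth
  if (!any(keep))
    stop("all samples are below the rarefaction depth ", depth)
  if (any(!keep))
    message("dropping ", sum(!keep), " sample(s) below depth ", depth, ": ",
            paste(rownames(table)[!keep], collapse = ", "))
  sub <- unclass(table)[keep, , drop = FALSE]
  set.seed(seed)
  # the low-abundance filter zeroes counts below 10, so vegan's "smallest
  # count" heuristic warning is expected and uninformative here
  rar <- withCallingHandlers(
    vegan::rrarefy(sub, depth),
    warning = function(w) {
      if (grepl("smallest count", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  genus_count_table(rar)
}

#' Centered log-ratio transform of a count table
#'
#' \code{clr_ij = log(c_ij + pseudocount) - mean_j log(c_ij + pseudocount)},
#' mapping each sample's composition into Aitchison (log-ratio) space where
#' Euclidean distance is the Aitchison distance.
#'
#' @param table A \code{\link{genus_count_table}}.
#' @param pseudocount Added to every cell before the log (default 1); must
#'   be positive when zeros are present.
#' @return A \code{clr_matrix}: numeric matrix with attributes
#'   \code{corrected} (FALSE) and \code{provenance}.
#' @export
clr_transform <- function(table, pseudocount = 1) {
  m <- unclass(as.matrix(table))
  if (pseudocount <= 0 && any(m == 0))
    stop("pseudocount must be positive when zero counts are present")
  lx <- log(m + pseudocount)
  v <- lx - rowMeans(lx)
  clr_matrix(v, corrected = FALSE, provenance = sprintf(
    "clr(pseudocount=%g)", pseudocount))
}

#' Construct a CLR matrix object
#'
#' @param values Numeric samples x genera matrix in log-ratio space.
#' @param corrected Logical; TRUE once PC regression residuals replace the
#'   raw CLR values (rows then no longer sum to zero).
#' @param provenance Character description of the transformations applied.
#' @return A \code{clr_matrix}.
#' @export
clr_matrix <- function(values, corrected = FALSE, provenance = "clr") {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("CLR values must be finite")
  if (!corrected && any(abs(rowSums(values)) > 1e-8))
    stop("uncorrected CLR rows must sum to 0")
  structure(values, corrected = corrected, provenance = provenance,
            class = c("clr_matrix", "matrix", "array"))
}

#' Full preprocessing chain: filter, rarefy, CLR
#'
#' @inheritParams filter_low_abundance
#' @inheritParams rarefy_even_depth
#' @inheritParams clr_transform
#' @return A list with \code{counts} (filtered, rarefied) and \code{clr}.
#' @export
preprocess_counts <- function(table, min_count = 10, min_samples = 2,
                              depth = 10000, pseudocount = 1, seed = 1L) {
  filtered <- filter_low_abundance(table, min_count, min_samples)
  rarefied <- rarefy_even_depth(filtered, depth, seed)
  list(counts = rarefied, clr = clr_transform(rarefied, pseudocount))
}
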