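# Internal helpers shared across modules.

# Derive a reproducible sub-seed from a base seed and integer offsets,
# kept inside 32-bit integer range.
.subseed <- function(seed, ...) {
  off <- c(...)
  s <- as.double(seed)
  for (o in off) s <- (s * 7919 + as.double(o) + 1) %% 2147483587
  as.integer(s) + 1L
}

# Rank-based (Mann-Whitney) AUC of scores for predicting labels == 1.
.auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels != 1]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# Stratified train/test splits: ceil(p * class size) per class for training,
# remainder for testing; resamples if the test set is single-class.
.make_splits <- function(labels, p, reps, seed) {
  idx1 <- which(labels == 1)
  idx0 <- which(labels != 1)
  n1 <- ceiling(p * length(idx1))
  n0 <- ceiling(p * length(idx0))
  if (n1 < 2 || n0 < 2)
    stop("fewer than 2 training samples in a class at p = ", p)
  splits <- vector("list", reps)
  for (r in seq_len(reps)) {
    set.seed(.subseed(seed, r))
    tries <- 0
    repeat {
      train <- c(sample(idx1, n1), sample(idx0, n0))
      test <- setdiff(seq_along(labels), train)
      if (length(unique(labels[test])) == 2) break
      tries <- tries + 1
      if (tries > 100) stop("could not draw a two-class test set")
    }
    splits[[r]] <- train
  }
  splits
}

# Run one random-forest train/test split; returns test AUC and, optionally,
# the training-set mean decrease in accuracy per feature.
.rf_split_auc <- function(features, labels, train, ntree, seed,
                          importance = FALSE) {
  test <- setdiff(seq_len(nrow(features)), train)
  y <- factor(labels, levels = c(0, 1))
  set.seed(seed)
  fit <- randomForest::randomForest(features[train, , drop = FALSE],
                                    y[train], ntree = ntree,
                                    importance = importance)
  prob <- stats::predict(fit, features[test, , drop = FALSE],
                         type = "prob")[, "1"]
  out <- list(auc = .auc(prob, labels[test]))
  if (importance)
    out$mda <- randomForest::importance(fit, type = 1,
                                        scale = FALSE)[, 1]
  out
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
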