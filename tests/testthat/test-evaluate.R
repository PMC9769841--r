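test_that("alpha diversity matches hand computations", {
  tab <- genus_count_table(rbind(u = c(10L, 10L, 10L, 10L),
                                 d = c(40L, 0L, 0L, 0L),
                                 m = c(10L, 20L, 70L, 0L)))
  div <- alpha_diversity(tab)
  expect_equal(div$richness, c(4, 1, 3))
  expect_equal(div$pielou[1], 1.0, tolerance = 1e-10)
  expect_true(is.na(div$pielou[2]))
  p <- c(0.1, 0.2, 0.7)
  H <- -sum(p * log(p))
  expect_equal(div$pielou[3], H / log(3), tolerance = 1e-10)
})

test_that("ANOSIM R and exact p match exhaustive enumeration on a 6-sample toy", {
  set.seed(71)
  x <- rbind(matrix(rnorm(9, 0, 1), 3, 3),
             matrix(rnorm(9, 2, 1), 3, 3))
  labels <- c(1, 1, 1, 0, 0, 0)
  got <- anosim_clr(clr_matrix(x, corrected = TRUE), labels)
  expect_true(got$exact)
  expect_equal(got$R, anosim_reference(x, labels), tolerance = 1e-12)
  combos <- combn(6, 3)
  R_all <- apply(combos, 2, function(idx) {
    lab <- integer(6); lab[idx] <- 1L
    anosim_reference(x, lab)
  })
  expect_equal(got$p, mean(R_all >= got$R - 1e-12))
})

test_that("ANOSIM R agrees with vegan and behaves at the separated and null limits", {
  set.seed(72)
  x <- rbind(matrix(rnorm(40, 0, 0.05), 10, 4),
             matrix(rnorm(40, 10, 0.05), 10, 4))
  labels <- rep(c(1, 0), each = 10)
  got <- anosim_clr(clr_matrix(x, corrected = TRUE), labels,
                    exhaustive_max = 10)
  expect_gte(got$R, 0.99)
  veg <- vegan::anosim(dist(x), factor(labels), permutations = 99)
  expect_equal(got$R, unname(veg$statistic), tolerance = 1e-10)

  # random labels: R centered near zero over seeds
  Rs <- vapply(1:10, function(s) {
    set.seed(s)
    xr <- matrix(rnorm(12 * 4), 12, 4)
    anosim_clr(clr_matrix(xr, corrected = TRUE),
               sample(rep(c(1, 0), 6)), exhaustive_max = 10,
               nperm = 49, seed = s)$R
  }, numeric(1))
  expect_lt(abs(mean(Rs)), 0.15)
  expect_true(all(Rs >= -1 & Rs <= 1))
})

test_that("NMDS reaches near-zero stress for embeddable configurations", {
  set.seed(73)
  pts <- matrix(rnorm(20), 10, 2)
  got <- nmds_clr(clr_matrix(pts, corrected = TRUE), k = 2, seed = 1)
  expect_lt(got$stress, 0.01)
  expect_equal(dim(got$coordinates), c(10L, 2L))
})

test_that("NMDS stress is close to an independent reference on a 5-point toy", {
  d <- dist(matrix(c(0, 0, 1, 2, 4, 2, 3, 1, 5, 0), 5, 2))
  got <- nmds_clr(d, k = 2, seed = 2)
  ref <- MASS::isoMDS(d, k = 2, trace = FALSE)
  # isoMDS reports percent stress; both should find an essentially perfect
  # embedding of 5 planar points
  expect_lt(got$stress, 0.01)
  expect_lt(ref$stress / 100, 0.01)
  expect_lt(abs(got$stress - ref$stress / 100), 1e-3)
})

test_that("differential clinical index selection follows the BH step-up closed form", {
  # indexes engineered to produce known raw p-values are unnecessary:
  # check the adjustment directly against p.adjust on a fixture plus the
  # known closed form
  raw <- c(0.001, 0.01, 0.02, 0.04, 0.2)
  closed <- c(0.005, 0.025, 1 / 30, 0.05, 0.2)
  expect_equal(p.adjust(raw, "BH"), closed, tolerance = 1e-10)

  set.seed(74)
  labels <- rep(c(1, 0), each = 20)
  clin <- data.frame(a = c(rnorm(20, 3), rnorm(20, 0)),
                     b = rnorm(40),
                     c = rnorm(40))
  res <- differential_clinical_indexes(clin, labels)
  expect_true(res$selected[res$index == "a"])
  expect_true(all(res$bh_adjusted_p >= res$wilcoxon_p - 1e-12))
  # order invariance
  res2 <- differential_clinical_indexes(clin[c("c", "a", "b")], labels)
  expect_equal(sort(res2$index[res2$selected]),
               sort(res$index[res$selected]))
})

test_that("missing-in-one-group indexes are excluded with a message", {
  labels <- rep(c(1, 0), each = 5)
  clin <- data.frame(ok = rnorm(10),
                     gone = c(rep(NA, 5), rnorm(5)))
  expect_message(res <- differential_clinical_indexes(clin, labels),
                 "excluded")
  expect_equal(res$index, "ok")
})

test_that("diagnostic model AUC is calibrated at the null and saturates when separable", {
  set.seed(75)
  labels <- rep(c(0L, 1L), each = 30)
  null_feats <- matrix(rnorm(60 * 4), 60, 4,
                       dimnames = list(NULL, paste0("f", 1:4)))
  m0 <- diagnostic_model(null_feats, sample(labels), reps = 30, seed = 5,
                         ntree = 100)
  expect_lt(abs(m0$auc - 0.5), 0.1)
  roc <- m0$roc
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))

  sep <- cbind(null_feats, sep = ifelse(labels == 1, 4, -4))
  m1 <- diagnostic_model(sep, labels, reps = 15, seed = 5, ntree = 100)
  expect_equal(m1$auc, 1.0)
  expect_error(diagnostic_model(null_feats[, 0], labels), "empty")
})

test_that("indicator features outperform noise clinical indexes on planted structure", {
  wins <- vapply(1:5, function(s) {
    cfg <- tiny_config(seed = 400 + s)
    st <- generate_study(cfg)
    prep <- preprocess_counts(st$counts, depth = 10000, seed = 1)
    md <- st$metadata[match(rownames(prep$clr), st$metadata$sample_id), ]
    labels <- as.integer(md$group != "control")
    ind_feats <- unclass(prep$clr)[, cfg$disease_genera, drop = FALSE]
    set.seed(s)
    clin_feats <- matrix(rnorm(nrow(prep$clr) * 3), ncol = 3,
                         dimnames = list(NULL, c("c1", "c2", "c3")))
    a_ind <- diagnostic_model(ind_feats, labels, reps = 15, seed = s,
                              ntree = 100)$auc
    a_cli <- diagnostic_model(clin_feats, labels, reps = 15, seed = s,
                              ntree = 100)$auc
    a_ind > a_cli
  }, logical(1))
  expect_gte(sum(wins), 5 * 0.9)
})

test_that("linear indicator-clinical fits recover slopes, nulls and exact lines", {
  set.seed(76)
  x <- matrix(rnorm(100 * 2), 100, 2,
              dimnames = list(NULL, c("gA", "gB")))
  mat <- clr_matrix(x, corrected = TRUE)
  clin <- data.frame(exact = 2 * x[, 1] + 1,
                     noisy = 1.5 * x[, 2] + rnorm(100, 0, 1),
                     null = rnorm(100))
  pairs <- data.frame(genus = c("gA", "gB", "gA"),
                      index = c("exact", "noisy", "null"),
                      stringsAsFactors = FALSE)
  res <- correlate_indicator_clinical(mat, clin, pairs)
  expect_equal(res$slope[1], 2, tolerance = 1e-8)
  expect_equal(res$r[1], 1, tolerance = 1e-8)
  expect_lt(res$p[1], 1e-8)
  se2 <- summary(lm(clin$noisy ~ x[, 2]))$coefficients[2, 2]
  expect_lt(abs(res$slope[2] - 1.5), 3 * se2)
  expect_gt(res$p[3], 0.001)
})

test_that("null pairs reach nominal false-positive rates over replicates", {
  hits <- vapply(1:40, function(s) {
    set.seed(500 + s)
    x <- matrix(rnorm(100), 100, 1, dimnames = list(NULL, "g"))
    clin <- data.frame(ix = rnorm(100))
    res <- correlate_indicator_clinical(clr_matrix(x, corrected = TRUE),
                                        clin,
                                        data.frame(genus = "g",
                                                   index = "ix"))
    res$p < 0.05
  }, logical(1))
  expect_lte(sum(hits), 8)  # ~5% of 40, binomial slack
})
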