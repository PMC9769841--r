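test_that("PC regression residuals equal the hat-matrix projection", {
  set.seed(11)
  x <- matrix(rnorm(30 * 12), 30, 12)
  clr <- clr_matrix(x - rowMeans(x))
  p <- matrix(rnorm(30 * 3), 30, 3)
  got <- regress_out_pcs(clr, p)
  # independent oracle: epsilon = (I - D (D'D)^-1 D') X with intercept
  D <- cbind(1, p)
  H <- D %*% solve(t(D) %*% D) %*% t(D)
  ref <- (diag(30) - H) %*% unclass(clr)
  expect_equal(unclass(got), ref, tolerance = 1e-8, ignore_attr = TRUE)
  # residual columns orthogonal to every regressed score column
  cors <- abs(cor(unclass(got), p))
  expect_lt(max(cors), 1e-8)
  expect_true(attr(got, "corrected"))
})

test_that("regressing zero PCs mean-centers each genus", {
  set.seed(12)
  x <- matrix(rnorm(10 * 4), 10, 4)
  clr <- clr_matrix(x - rowMeans(x))
  got <- regress_out_pcs(clr, NULL)
  expect_equal(unclass(got), sweep(unclass(clr), 2, colMeans(clr)),
               ignore_attr = TRUE)
})

test_that("a matrix spanned by the regressed score vanishes", {
  set.seed(13)
  s <- rnorm(15)
  w <- rnorm(6)
  clr <- clr_matrix(outer(s, w), corrected = TRUE)
  got <- regress_out_pcs(clr, matrix(s))
  expect_lt(max(abs(got)), 1e-8)
})

test_that("collinear PC columns are dropped with a message", {
  set.seed(14)
  x <- matrix(rnorm(20 * 5), 20, 5)
  clr <- clr_matrix(x - rowMeans(x))
  p <- matrix(rnorm(20), 20, 1)
  expect_message(got <- regress_out_pcs(clr, cbind(p, p)), "collinear")
  ref <- regress_out_pcs(clr, p)
  expect_equal(as.numeric(got), as.numeric(ref), tolerance = 1e-10)
})

test_that("signed AUC fold change follows the stated formula on both branches", {
  up <- auc_change(rep(0.50, 9), rep(0.55, 9))
  expect_equal(up$fold_change, 1.1)
  down <- auc_change(rep(0.55, 9), rep(0.50, 9))
  expect_equal(down$fold_change, -1.1)
  same <- auc_change(c(0.6, 0.7, 0.8), c(0.6, 0.7, 0.8))
  expect_equal(same$fold_change, 1.0)
  expect_equal(same$wilcoxon_p, 1.0)
})

test_that("auc_change is antisymmetric under before/after swap", {
  set.seed(15)
  a <- runif(20, 0.4, 0.9)
  b <- runif(20, 0.4, 0.9)
  f1 <- auc_change(a, b)
  f2 <- auc_change(b, a)
  # medians differ, so the sign branch flips and magnitude is preserved
  expect_equal(f1$fold_change, -f2$fold_change)
  expect_equal(f1$wilcoxon_p, f2$wilcoxon_p)
})

test_that("case/control AUC is near 0.5 for label-independent features and 1 for separable ones", {
  set.seed(16)
  x <- matrix(rnorm(60 * 8), 60, 8)
  colnames(x) <- paste0("g", 1:8)
  labels <- rep(c(0L, 1L), 30)
  aucs <- case_control_auc(clr_matrix(x, corrected = TRUE), labels,
                           p = 0.6, reps = 30, seed = 3, ntree = 100)
  expect_lt(abs(mean(aucs) - 0.5), 0.06)

  # one perfectly separating feature
  x2 <- x
  x2[, 1] <- ifelse(labels == 1, 5 + runif(60), -5 - runif(60))
  aucs2 <- case_control_auc(clr_matrix(x2, corrected = TRUE), labels,
                            p = 0.6, reps = 10, seed = 3, ntree = 100)
  expect_true(all(aucs2 == 1))
})

test_that("before/after runs with the same seed reuse identical splits", {
  set.seed(17)
  x <- matrix(rnorm(40 * 6), 40, 6)
  labels <- rep(c(0L, 1L), 20)
  a1 <- case_control_auc(clr_matrix(x, corrected = TRUE), labels,
                         0.5, 5, seed = 9, ntree = 50)
  a2 <- case_control_auc(clr_matrix(x, corrected = TRUE), labels,
                         0.5, 5, seed = 9, ntree = 50)
  expect_identical(a1, a2)
})

test_that("role assignment separates clear increases, decreases and null shifts", {
  mk <- function(mb, ma) {
    structure(list(cells = data.frame(median_before = mb,
                                      median_after = ma)),
              class = "correction_assessment")
  }
  up <- assign_factor_role(mk(seq(0.60, 0.64, length.out = 9),
                              seq(0.70, 0.74, length.out = 9)))
  expect_equal(up$role, "noise")
  expect_gt(up$overall_fold, 1)
  down <- assign_factor_role(mk(seq(0.70, 0.74, length.out = 9),
                                seq(0.60, 0.64, length.out = 9)))
  expect_equal(down$role, "disease")
  expect_lt(down$overall_fold, -1)
  same <- assign_factor_role(mk(rep(0.7, 9), rep(0.7, 9)))
  expect_equal(same$role, "indeterminate")
})

test_that("select_correction picks argmax fold for noise factors with deterministic ties", {
  # construct two fake assessments; only roles and cells are consulted for
  # the argmax when a single noise factor is present
  cells <- data.frame(n = c(5L, 26L), p = c(0.5, 0.6),
                      median_before = c(0.6, 0.6),
                      median_after = c(0.612, 0.66),
                      fold_change = c(1.02, 1.10),
                      wilcoxon_p = c(0.2, 0.001))
  set.seed(18)
  x <- matrix(rnorm(30 * 8), 30, 8)
  clr <- clr_matrix(x - rowMeans(x))
  scores26 <- matrix(rnorm(30 * 2), 30, 2)
  fake <- structure(list(factor_set = "f", cells = cells,
                         pc_sets = list(1L, 1:2), role = "noise"),
                    class = "correction_assessment")
  pcs_by_n <- list(`5` = list(scores = matrix(rnorm(30), 30, 1)),
                   `26` = list(scores = scores26))
  sel <- select_correction(list(f = fake), clr,
                           rep(c(0L, 1L), 15), pcs_by_n, list(), NULL)
  expect_equal(sel$n, 26L)
  expect_equal(sel$p, 0.6)
  expect_true(sel$corrected)
  expect_equal(sel$factor_set, "f")

  # tie in fold change: smaller n, then smaller p
  fake$cells$fold_change <- c(1.10, 1.10)
  sel2 <- select_correction(list(f = fake), clr,
                            rep(c(0L, 1L), 15), pcs_by_n, list(), NULL)
  expect_equal(sel2$n, 5L)
})

test_that("with no noise factor the second uncorrected pass picks the best-AUC cell", {
  set.seed(19)
  x <- matrix(rnorm(40 * 10), 40, 10)
  labels <- rep(c(0L, 1L), 20)
  x[, 1] <- x[, 1] + 2 * labels
  clr <- clr_matrix(x, corrected = TRUE)
  fake <- structure(list(factor_set = "f", cells = data.frame(),
                         role = "disease"),
                    class = "correction_assessment")
  grid <- grid_params(n_values = c(5L, 6L), p_values = 0.5, reps = 4,
                      ntree = 50, seed = 2)
  sel <- select_correction(list(f = fake), clr, labels, list(), list(),
                           grid)
  expect_equal(sel$factor_set, "none")
  expect_false(sel$corrected)
  expect_identical(unclass(sel$matrix), unclass(clr))
  expect_true(sel$criterion > 0.5)
})
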