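test_that("same config and seed give byte-identical studies", {
  cfg <- tiny_config(seed = 41)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(unclass(s1$counts), unclass(s2$counts))
  expect_identical(s1$metadata, s2$metadata)
})

test_that("counts conserve the drawn depths and respect the depth floor", {
  cfg <- tiny_config(seed = 42)
  st <- generate_study(cfg)
  expect_true(all(rowSums(st$counts) >= 10000))
  expect_equal(nrow(st$counts), cfg$m_case + cfg$m_control)
  expect_equal(ncol(st$counts), cfg$g)
})

test_that("zero-effect configuration leaves all genera balanced between groups", {
  cfg <- simulation_config(m_case = 60, m_control = 60, g = 20,
                          disease_genera = integer(), disease_effect = 0,
                          baseline_log_abundance = rep(0, 20),
                          overdispersion_sd = 0,
                          depth_mean = 20000, depth_sd = 0, seed = 43)
  st <- generate_study(cfg)
  rel <- sweep(unclass(st$counts), 1, rowSums(st$counts), "/")
  case <- st$metadata$group != "control"
  # every genus has expected proportion 1/20 in both groups; multinomial
  # SE of the group mean proportion
  p0 <- 1 / 20
  se <- sqrt(p0 * (1 - p0) / 20000 / 60)
  diffs <- abs(colMeans(rel[case, ]) - colMeans(rel[!case, ]))
  expect_true(all(diffs < 3 * sqrt(2) * se * 3))
  expect_gt(mean(diffs < 3 * sqrt(2) * se), 0.9)
})

test_that("planted CLR shift matches a latent-model Monte-Carlo oracle", {
  g <- 40
  cfg <- simulation_config(m_case = 100, m_control = 100, g = g,
                           disease_genera = 1:10, disease_effect = 2,
                           baseline_log_abundance = rep(0, g),
                           overdispersion_sd = 0.5,
                           depth_mean = 20000, depth_sd = 0, seed = 44)
  st <- generate_study(cfg)
  clr <- clr_transform(st$counts)
  case <- st$metadata$group != "control"
  got <- mean(colMeans(clr[case, 1:10]) - colMeans(clr[!case, 1:10]))

  # oracle: direct 10000-draw simulation of the latent model (no pipeline
  # code): lambda -> multinomial counts -> clr of one genus block
  set.seed(991)
  ndraw <- 10000
  shift <- function(is_case) {
    lam <- rep(0, g)
    if (is_case) lam[1:10] <- 2
    lam <- lam + rnorm(g, 0, 0.5)
    p <- exp(lam) / sum(exp(lam))
    cts <- rmultinom(1, 20000, p)[, 1]
    lx <- log(cts + 1)
    mean((lx - mean(lx))[1:10])
  }
  case_draws <- replicate(ndraw / 2, shift(TRUE))
  ctrl_draws <- replicate(ndraw / 2, shift(FALSE))
  oracle <- mean(case_draws) - mean(ctrl_draws)
  se <- sqrt(var(case_draws) / (ndraw / 2) + var(ctrl_draws) / (ndraw / 2)) +
    sqrt(2 * var(clr[, 1]) / 100)
  expect_lt(abs(got - oracle), 2 * (se + 0.02))
})

test_that("doubling the disease effect increases the mean CLR difference", {
  mean_shift <- function(effect, seed) {
    cfg <- simulation_config(m_case = 40, m_control = 40, g = 30,
                             disease_genera = 1:5, disease_effect = effect,
                             baseline_log_abundance = rep(0, 30),
                             overdispersion_sd = 0.8,
                             depth_mean = 15000, depth_sd = 0, seed = seed)
    st <- generate_study(cfg)
    clr <- clr_transform(st$counts)
    case <- st$metadata$group != "control"
    mean(abs(colMeans(clr[case, 1:5]) - colMeans(clr[!case, 1:5])))
  }
  wins <- sum(vapply(1:5, function(s)
    mean_shift(2, s) > mean_shift(1, s), logical(1)))
  expect_gte(wins, 4)
})

test_that("noise confounders stay independent of the case label", {
  pvals <- vapply(1:20, function(s) {
    cfg <- tiny_config(seed = s, confounders = list(
      confounder_spec("f", "discrete", prevalence = 0.5,
                      affected_genera = 5:8, effect_size = 1,
                      role = "noise")))
    st <- generate_study(cfg)
    suppressWarnings(chisq.test(table(st$metadata$f,
                                      st$metadata$group))$p.value)
  }, numeric(1))
  # roughly uniform over seeds (chi-square p-values are discrete, so ties
  # are expected; the KS statistic is still informative)
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("confounder spec invariants are enforced", {
  expect_error(confounder_spec("f", "discrete", prevalence = 0.5,
                               role = "noise", case_association = 0.2),
               "case_association")
  expect_error(confounder_spec("f", "discrete", prevalence = 1.2,
                               role = "noise"), "prevalence")
  expect_error(simulation_config(10, 10, 20, disease_genera = 1:3,
                                 confounders = list(
                                   confounder_spec("f", "discrete",
                                                   prevalence = 0.4,
                                                   affected_genera = 2:5,
                                                   role = "noise"))),
               "share genera")
  expect_error(simulation_config(10, 10, 20, depth_mean = 5000),
               "at least 10000")
})

test_that("clinical indexes recover their generating slope by OLS", {
  cfg <- simulation_config(m_case = 100, m_control = 100, g = 30,
                           disease_genera = 1:5, disease_effect = 1,
                           baseline_log_abundance = rep(0, 30),
                           overdispersion_sd = 1,
                           clinical_specs = list(
                             list(index_name = "ix", linked_genus = 3,
                                  slope = 1.5, noise_sd = 1)),
                           seed = 46)
  st <- generate_study(cfg)
  clr <- clr_transform(st$counts)
  fit <- lm(st$metadata$ix ~ clr[, 3])
  est <- coef(summary(fit))[2, ]
  expect_lt(abs(est["Estimate"] - 1.5), 3 * est["Std. Error"])

  # noiseless limit: exact recovery
  cfg$clinical_specs[[1]]$noise_sd <- 0
  st0 <- generate_study(cfg)
  clr0 <- clr_transform(st0$counts)
  expect_equal(unname(coef(lm(st0$metadata$ix ~ clr0[, 3]))[2]), 1.5,
               tolerance = 1e-8)
})

test_that("null clinical slope is not significant in most replicates", {
  hits <- vapply(1:20, function(s) {
    cfg <- tiny_config(seed = s, clinical_specs = list(
      list(index_name = "ix", linked_genus = 2, slope = 0, noise_sd = 1)))
    st <- generate_study(cfg)
    clr <- clr_transform(st$counts)
    coef(summary(lm(st$metadata$ix ~ clr[, 2])))[2, 4] < 0.05
  }, logical(1))
  # true rate 5%: allow ~3 binomial SE above 1/20
  expect_lte(sum(hits), 4)
})

test_that("study round-trips through plain-text files", {
  dir <- tempfile()
  st <- generate_study(tiny_config(seed = 47))
  write_study(st, dir)
  counts2 <- read_count_table(file.path(dir, "counts.tsv"))
  expect_equal(unclass(counts2), unclass(st$counts))
  md2 <- read.delim(file.path(dir, "metadata.tsv"))
  expect_equal(md2$group, st$metadata$group)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$disease_genera, st$truth$disease_genera)
})
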