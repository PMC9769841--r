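# Shared fixtures: small synthetic studies built in code.

# Tiny study for fast deterministic tests.
tiny_config <- function(seed = 1L, ...) {
  args <- list(m_case = 20, m_control = 20, g = 30,
               disease_genera = 1:4, disease_effect = 2,
               baseline_log_abundance = rep(0, 30),
               overdispersion_sd = 0.8,
               depth_mean = 15000, depth_sd = 500,
               seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simulation_config, args)
}

# A random count table with a fixed seed.
random_count_table <- function(m = 50, g = 30, seed = 1L, max_count = 60) {
  set.seed(seed)
  genus_count_table(matrix(rpois(m * g, max_count / 3), m, g))
}

# Independent two-pass reference for the low-abundance filter.
filter_reference <- function(counts, min_count = 10, min_samples = 2) {
  x <- unclass(as.matrix(counts))
  out <- x
  for (i in seq_len(nrow(x)))
    for (j in seq_len(ncol(x)))
      if (x[i, j] < min_count) out[i, j] <- 0L
  present <- integer(ncol(x))
  for (j in seq_len(ncol(x)))
    present[j] <- sum(out[, j] > 0)
  out[, present >= min_samples, drop = FALSE]
}

# Brute-force ANOSIM R from first principles (no shared code with the
# implementation): builds the rank matrix explicitly.
anosim_reference <- function(x, labels) {
  m <- nrow(x)
  d <- as.matrix(dist(x))
  vals <- d[lower.tri(d)]
  r <- rank(vals)
  within <- outer(labels, labels, "==")[lower.tri(d)]
  M <- m * (m - 1) / 2
  (mean(r[!within]) - mean(r[within])) / (M / 2)
}

# Small pipeline configuration exercising every stage in seconds.
small_pipeline_config <- function(out_dir, seed = 1L, with_factor = TRUE) {
  confs <- if (with_factor) list(
    confounder_spec("fac", "discrete", prevalence = 0.5,
                    affected_genera = 11:16, effect_size = 2,
                    role = "noise")) else list()
  sim <- simulation_config(
    m_case = 24, m_control = 24, g = 30, disease_genera = 1:4,
    disease_effect = 2, baseline_log_abundance = rep(0, 30),
    confounders = confs, overdispersion_sd = 0.8,
    depth_mean = 15000, depth_sd = 500,
    clinical_specs = list(list(index_name = "CK", linked_genus = 1,
                               slope = 1.5, noise_sd = 1)),
    seed = seed)
  pipeline_config(synthetic = sim,
                  grid = grid_params(n_values = c(5L, 6L), p_values = 0.5,
                                     reps = 6, ntree = 60, seed = seed),
                  nperm = 99, out_dir = out_dir, seed = seed)
}
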