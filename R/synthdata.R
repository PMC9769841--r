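#' Specify a confounding factor for simulation
#'
#' A confounder perturbs the latent log-abundance of a set of genera and may
#' (role \code{"disease_linked"}) or may not (role \code{"noise"}) be
#' associated with the case/control label.
#'
#' @param name Factor name (metadata column).
#' @param kind \code{"discrete"} (binary 0/1 covariate) or
#'   \code{"continuous"} (Gaussian covariate such as age or BMI).
#' @param prevalence Baseline prevalence of the factor in controls
#'   (discrete only), in (0,1).
#' @param mean,sd Mean and standard deviation of the covariate in controls
#'   (continuous only).
#' @param affected_genera Integer indices of genera whose latent
#'   log-abundance the factor shifts.
#' @param effect_size Additive shift on latent log-abundance per unit of the
#'   covariate; either a scalar or a vector along \code{affected_genera}.
#'   A centered (sign-balanced) vector models a factor that raises some
#'   taxa while suppressing others, leaving the remaining genera's
#'   log-ratios untouched.
#' @param role \code{"noise"} (independent of disease) or
#'   \code{"disease_linked"} (entangled with the case label).
#' @param case_association Excess prevalence (discrete) or mean shift in
#'   units of \code{sd} (continuous) in cases. Must be 0 for noise factors.
#' @return A \code{confounder_spec} object.
#' @export
confounder_spec <- function(name,
                            kind = c("discrete", "continuous"),
                            prevalence = NULL,
                            mean = NULL,
                            sd = NULL,
                            affected_genera = integer(),
                            effect_size = 0,
                            role = c("noise", "disease_linked"),
                            case_association = 0) {
  kind <- match.arg(kind)
  role <- match.arg(role)
  if (role == "noise" && case_association != 0)
    stop("a noise confounder must have case_association = 0")
  if (kind == "discrete") {
    if (is.null(prevalence) || prevalence <= 0 || prevalence >= 1)
      stop("discrete confounder '", name, "' needs prevalence in (0,1)")
    if (prevalence + case_association <= 0 ||
        prevalence + case_association >= 1)
      stop("prevalence + case_association must stay in (0,1)")
  } else {
    if (is.null(mean) || is.null(sd) || sd <= 0)
      stop("continuous confounder '", name, "' needs mean and sd > 0")
  }
  if (length(effect_size) > 1 &&
      length(effect_size) != length(affected_genera))
    stop("effect_size must be scalar or one value per affected genus")
  structure(list(name = name, kind = kind, prevalence = prevalence,
                 mean = mean, sd = sd,
                 affected_genera = as.integer(affected_genera),
                 effect_size = effect_size, role = role,
                 case_association = case_association),
            class = "confounder_spec")
}

#' Configure a synthetic case-control microbiome study
#'
#' Samples are generated from a log-linear latent model: per-sample latent
#' log-abundances receive additive disease and confounder effects plus
#' Gaussian overdispersion, are softmax-transformed to a composition, and
#' counts are drawn multinomially at a Gaussian sequencing depth.
#'
#' @param m_case,m_control Numbers of case and control samples.
#' @param g Number of genera.
#' @param disease_genera Indices of genera carrying the disease effect.
#' @param disease_effect Additive latent log-abundance shift in cases.
#' @param baseline_log_abundance Length-\code{g} baseline; default is a
#'   smooth gradient spanning about 6 natural-log units, mimicking the
#'   dominance structure of stool genus profiles.
#' @param confounders List of \code{\link{confounder_spec}} objects.
#' @param overdispersion_sd SD of per-cell Gaussian noise on the latent
#'   log-abundance (sample-to-sample biological variation).
#' @param depth_mean,depth_sd Sequencing depth distribution; draws are
#'   floored at 10000 reads so every sample survives even-depth rarefaction.
#' @param clinical_specs List of lists with fields \code{index_name},
#'   \code{linked_genus}, \code{slope}, \code{noise_sd} (and optional
#'   \code{intercept}) describing clinical indexes tied to genera.
#' @param seed Integer seed controlling all draws.
#' @return A \code{simulation_config} object.
#' @export
simulation_config <- function(m_case, m_control, g,
                              disease_genera = integer(),
                              disease_effect = 0,
                              baseline_log_abundance = NULL,
                              confounders = list(),
                              overdispersion_sd = 1,
                              depth_mean = 20000, depth_sd = 2000,
                              clinical_specs = list(),
                              seed = 1L) {
  if (is.null(baseline_log_abundance))
    baseline_log_abundance <- seq(3, -3, length.out = g)
  stopifnot(m_case >= 1, m_control >= 1, g >= 2,
            length(baseline_log_abundance) == g,
            overdispersion_sd >= 0, depth_sd >= 0)
  disease_genera <- as.integer(disease_genera)
  if (length(disease_genera) && (min(disease_genera) < 1 ||
                                 max(disease_genera) > g))
    stop("disease_genera must lie in 1..g")
  if (depth_mean < 10000)
    stop("depth_mean must be at least 10000 so rarefaction is feasible")
  for (cf in confounders) {
    stopifnot(inherits(cf, "confounder_spec"))
    if (length(cf$affected_genera) &&
        (min(cf$affected_genera) < 1 || max(cf$affected_genera) > g))
      stop("affected_genera of '", cf$name, "' must lie in 1..g")
    if (cf$role == "noise" &&
        length(intersect(cf$affected_genera, disease_genera)))
      stop("noise confounder '", cf$name,
           "' may not share genera with disease_genera")
  }
  structure(list(m_case = as.integer(m_case),
                 m_control = as.integer(m_control),
                 g = as.integer(g), disease_genera = disease_genera,
                 disease_effect = disease_effect,
                 baseline_log_abundance = baseline_log_abundance,
                 confounders = confounders,
                 overdispersion_sd = overdispersion_sd,
                 depth_mean = depth_mean, depth_sd = depth_sd,
                 clinical_specs = clinical_specs, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default study conditions used throughout the analyses
#'
#' 80 cases + 80 controls, 120 genera, a disease effect of 2 natural-log
#' units on 10 moderately abundant genera, one planted pure-noise discrete
#' confounder, one disease-linked discrete confounder, and three clinical
#' indexes (one null).
#'
#' The noise confounder ("antibiotic_use") switches a block of 40 rare
#' genera between absence and presence: antibiotic-associated taxa that
#' bloom only in exposed subjects. Because the planted effect touches no
#' disease genus and the covariate is independent of the case label, its
#' compositional footprint is orthogonal to the disease axis by
#' construction, but its large presence/absence variance and the read share
#' it claims interfere with case/control classification -- the situation PC
#' correction is meant to repair. The disease-linked confounder
#' ("hypertension") perturbs its own block of abundant genera with an
#' exponent-balanced up/down pattern (so it does not distort total
#' sequencing yield) and is entangled with disease through its elevated
#' prevalence in cases; its compositional footprint therefore carries
#' case/control signal, and regressing it out removes real signal.
#'
#' @param seed Integer seed.
#' @param confounders Optional replacement list of confounder specs.
#' @return A \code{simulation_config}.
#' @export
default_simulation_config <- function(seed = 1L, confounders = NULL) {
  baseline <- rep(0, 120)
  baseline[1:10] <- -1      # disease genera: low-abundance taxa
  baseline[31:70] <- -6     # noise-block taxa: absent unless switched on
  baseline[91:120] <- 1.5   # disease-linked block: abundant taxa
  if (is.null(confounders))
    confounders <- list(
      confounder_spec("antibiotic_use", "discrete", prevalence = 0.5,
                      affected_genera = 31:70, effect_size = 8,
                      role = "noise", case_association = 0),
      confounder_spec("hypertension", "discrete", prevalence = 0.25,
                      affected_genera = 91:120,
                      effect_size = c(rep(1.4, 6), rep(-1.47, 24)),
                      role = "disease_linked", case_association = 0.35))
  simulation_config(
    m_case = 80, m_control = 80, g = 120,
    disease_genera = 1:10, disease_effect = 2,
    baseline_log_abundance = baseline,
    confounders = confounders,
    overdispersion_sd = 2, depth_mean = 20000, depth_sd = 2000,
    clinical_specs = list(
      list(index_name = "CK", linked_genus = 1, slope = 1.5,
           noise_sd = 1, intercept = 100),
      list(index_name = "Hb", linked_genus = 2, slope = -1.2,
           noise_sd = 1, intercept = 14),
      list(index_name = "TG", linked_genus = 3, slope = 0,
           noise_sd = 1, intercept = 1.5)),
    seed = seed)
}

#' Generate a synthetic case-control study
#'
#' @param config A \code{\link{simulation_config}}.
#' @return A \code{synthetic_study}: list with \code{counts} (a
#'   \code{\link{genus_count_table}}), \code{metadata} (data frame with
#'   \code{sample_id}, \code{group}, covariates and clinical indexes) and
#'   \code{truth} (planted disease genera and per-confounder roles).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  m <- config$m_case + config$m_control
  g <- config$g
  is_case <- c(rep(1L, config$m_case), rep(0L, config$m_control))
  sample_ids <- sprintf("S%03d", seq_len(m))
  genus_ids <- sprintf("genus_%03d", seq_len(g))

  covariates <- list()
  for (cf in config$confounders) {
    if (cf$kind == "discrete") {
      pr <- cf$prevalence + cf$case_association * is_case
      if (any(pr <= 0 | pr >= 1))
        stop("effective prevalence outside (0,1) for '", cf$name, "'")
      covariates[[cf$name]] <- stats::rbinom(m, 1L, pr)
    } else {
      mu <- cf$mean + cf$case_association * cf$sd * is_case
      covariates[[cf$name]] <- stats::rnorm(m, mu, cf$sd)
    }
  }

  lambda <- matrix(rep(config$baseline_log_abundance, each = m), m, g)
  if (length(config$disease_genera))
    lambda[, config$disease_genera] <-
      lambda[, config$disease_genera] + config$disease_effect * is_case
  for (cf in config$confounders)
    if (length(cf$affected_genera)) {
      eff <- rep_len(cf$effect_size, length(cf$affected_genera))
      lambda[, cf$affected_genera] <- lambda[, cf$affected_genera] +
        outer(covariates[[cf$name]], eff)
    }
  if (config$overdispersion_sd > 0)
    lambda <- lambda + matrix(stats::rnorm(m * g, 0,
                                           config$overdispersion_sd), m, g)

  depth <- pmax(round(stats::rnorm(m, config$depth_mean, config$depth_sd)),
                10000L)
  if (any(depth <= 0)) stop("non-positive sequencing depth drawn")
  counts <- matrix(0L, m, g, dimnames = list(sample_ids, genus_ids))
  for (i in seq_len(m)) {
    p_i <- exp(lambda[i, ] - max(lambda[i, ]))
    counts[i, ] <- as.integer(stats::rmultinom(1, depth[i], p_i / sum(p_i)))
  }

  metadata <- data.frame(sample_id = sample_ids,
                         group = ifelse(is_case == 1L, "case", "control"),
                         stringsAsFactors = FALSE)
  for (nm in names(covariates)) metadata[[nm]] <- covariates[[nm]]

  truth <- list(
    disease_genera = config$disease_genera,
    confounders = lapply(config$confounders, function(cf)
      list(name = cf$name, role = cf$role, kind = cf$kind,
           affected_genera = cf$affected_genera)))

  study <- structure(list(counts = genus_count_table(counts),
                          metadata = metadata, truth = truth),
                     class = "synthetic_study")
  if (length(config$clinical_specs))
    study <- generate_clinical_indexes(study, config$clinical_specs,
                                       seed = config$seed + 1L)
  study
}

#' Attach genus-linked clinical indexes to a synthetic study
#'
#' Each index is a linear function of the CLR value of one genus plus
#' Gaussian noise, emulating clinical chemistry values that track the
#' abundance of particular community members.
#'
#' @param study A \code{synthetic_study}.
#' @param specs List of lists with \code{index_name}, \code{linked_genus}
#'   (index or genus id), \code{slope}, \code{noise_sd}, optional
#'   \code{intercept} (default 0).
#' @param seed Integer seed.
#' @return The study with clinical columns appended to \code{metadata}.
#' @export
generate_clinical_indexes <- function(study, specs, seed = 1L) {
  stopifnot(inherits(study, "synthetic_study"))
  set.seed(seed)
  clr <- clr_transform(study$counts)
  for (sp in specs) {
    j <- sp$linked_genus
    if (is.character(j)) j <- match(j, colnames(clr))
    if (is.na(j) || j < 1 || j > ncol(clr))
      stop("unknown linked genus for clinical index '", sp$index_name, "'")
    icpt <- if (is.null(sp$intercept)) 0 else sp$intercept
    study$metadata[[sp$index_name]] <-
      icpt + sp$slope * clr[, j] +
      stats::rnorm(nrow(clr), 0, sp$noise_sd)
  }
  study$truth$clinical_specs <- specs
  study
}

#' Write a synthetic study to plain-text files
#'
#' Counts and metadata as tab-separated tables, ground truth as JSON.
#'
#' @param study A \code{synthetic_study}.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "truth.json"))
  write_count_table(study$counts, paths[["counts"]])
  utils::write.table(study$metadata, paths[["metadata"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(study$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
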