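#' Simulate a cohort of gray-matter volumes with an age-dependent signal
#'
#' Each subject's volume is
#' `clip(template + weight_map * (age + bag - age_ref) + noise, 0, 1)`,
#' where `noise` is voxel-wise i.i.d. Gaussian (SD `noise_sd` before
#' smoothing) passed through a Gaussian filter of FWHM `smooth_fwhm` voxels.
#' The optional `bag` vector shifts each subject's *effective* age, planting a
#' ground-truth brain age gap that downstream model recovery can be checked
#' against.
#'
#' @param template Template volume ([make_template()]).
#' @param weight_map Per-voxel age effect ([make_signal_map()]).
#' @param n Number of subjects (>= 2).
#' @param age_range Length-2 numeric; ages are uniform on this range.
#' @param noise_sd Noise SD in GM units (>= 0).
#' @param smooth_fwhm Noise smoothing FWHM in voxels (0 = none).
#' @param age_ref Centering age (years).
#' @param bag Optional per-subject true BAG (years); default all zero.
#' @param seed Integer seed.
#' @param id_prefix Prefix for generated subject IDs.
#' @return A list with elements `volumes` (`bg_volumes`), `age`, and `bag`.
#' @export
simulate_gm_cohort <- function(template, weight_map, n, age_range,
                               noise_sd, smooth_fwhm = 0, age_ref = 75,
                               bag = NULL, seed = 1L, id_prefix = "S") {
  stopifnot(identical(dim(template), dim(weight_map)))
  if (n < 2) abort("n must be >= 2")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (diff(range(age_range)) <= 0) abort("age_range must be non-degenerate")
  set.seed(stage_seed(seed, "gm_cohort"))
  d <- dim(template)
  age <- runif(n, age_range[1], age_range[2])
  if (is.null(bag)) bag <- rep(0, n)
  if (length(bag) != n) abort("bag must have length n")
  data <- array(0, c(d, n))
  for (i in seq_len(n)) {
    eps <- if (noise_sd > 0) {
      gaussian_smooth3d(array(rnorm(prod(d), 0, noise_sd), d), smooth_fwhm)
    } else {
      array(0, d)
    }
    data[, , , i] <- clip01(template + weight_map * (age[i] + bag[i] - age_ref) + eps)
  }
  ids <- sprintf("%s%04d", id_prefix, seq_len(n))
  list(volumes = gm_volumes(data, ids, age), age = age, bag = bag)
}

#' Simulate phenotypes, cognitive status, and site-censored survival
#'
#' Generates the covariate and outcome table the association suite consumes:
#' demographic covariates (sex, 5-level center-race, smoking, education),
#' binary risk factors (hypertension, diabetes), continuous covariates (age,
#' BMI, intracranial volume), a cognitive status (CN/MCI/DEM) drawn from an
#' ordinal-logit model whose linear predictor includes the true BAG, physical
#' function (4-m walk time increasing in BAG; a low-grip-strength flag),
#' prevalent disease indicators with log-odds increasing in BAG, and an
#' exponential survival time whose log-hazard follows the tertile-of-true-BAG
#' hazard ratios in the config, administratively censored at each site's
#' censoring date. Death causes are CNS with probability `p_cns_death`.
#'
#' Covariates are generated independently of the true BAG, so the generating
#' tertile hazard ratios are also the covariate-conditional ones the Cox
#' models estimate.
#'
#' @param true_bag Numeric vector of ground-truth BAG values (years); length
#'   must equal `config$n_target`.
#' @param config A [sim_config()].
#' @param age Optional chronological ages; drawn uniformly on
#'   `config$target_age_range` when omitted.
#' @param subject_id Optional subject identifiers.
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A tibble with one row per subject.
#' @export
simulate_phenotypes <- function(true_bag, config, age = NULL,
                                subject_id = NULL, seed = config$seed) {
  if (!all(is.finite(true_bag))) abort("true_bag must be finite")
  n <- length(true_bag)
  if (n != config$n_target) {
    abort(sprintf("length(true_bag) [%d] must equal config$n_target [%d]",
                  n, config$n_target))
  }
  set.seed(stage_seed(seed, "phenotypes"))
  if (is.null(age)) age <- runif(n, config$target_age_range[1],
                                 config$target_age_range[2])
  if (is.null(subject_id)) subject_id <- sprintf("T%04d", seq_len(n))

  center_race_levels <- c("Forsyth-AA", "Forsyth-W", "Jackson-AA",
                          "Minn-W", "Wash-W")
  center_race <- factor(sample(center_race_levels, n, replace = TRUE,
                               prob = c(0.04, 0.16, 0.27, 0.28, 0.25)),
                        levels = center_race_levels)
  site <- sub("-.*", "", as.character(center_race))
  site[site == "Minn"] <- "Minneapolis"
  site[site == "Wash"] <- "Washington"

  sex <- factor(sample(c("female", "male"), n, TRUE, prob = c(0.605, 0.395)))
  smoking <- factor(sample(c("current", "former", "never"), n, TRUE,
                           prob = c(0.053, 0.477, 0.470)),
                    levels = c("never", "former", "current"))
  education <- factor(sample(c("basic", "intermediate", "advanced"), n, TRUE,
                             prob = c(0.144, 0.407, 0.449)),
                      levels = c("basic", "intermediate", "advanced"))
  hypertension <- rbinom(n, 1, 0.754)
  diabetes <- rbinom(n, 1, 0.30)
  bmi <- pmax(rnorm(n, 28.5, 5.7), 15)
  icv <- rnorm(n, 1400, 130)

  # ordinal cognitive status: latent logistic, thresholds tuned so the
  # marginal class mix is roughly 63/32/5 at the default BAG scale
  latent <- 0.3 * true_bag + rlogis(n)
  cognitive_status <- cut(latent, c(-Inf, 0.67, 3.32, Inf),
                          labels = c("CN", "MCI", "DEM"))

  walk_4m <- pmax(rnorm(n, 4.5 + 0.15 * true_bag, 1), 1.5)
  low_grip <- rbinom(n, 1, stats::plogis(stats::qlogis(0.20) + 0.12 * true_bag))
  chd   <- rbinom(n, 1, stats::plogis(stats::qlogis(0.15) + 0.10 * true_bag))
  stroke <- rbinom(n, 1, stats::plogis(stats::qlogis(0.07) + 0.10 * true_bag))
  afib  <- rbinom(n, 1, stats::plogis(stats::qlogis(0.10) + 0.10 * true_bag))
  heart_failure <- rbinom(n, 1, stats::plogis(stats::qlogis(0.08) + 0.10 * true_bag))

  # survival: exponential with tertile-of-true-BAG hazard ratios, highest
  # tertile is the reference hazard
  tert <- assign_tertiles(true_bag)$label
  log_hr <- c(log(config$hr_lowest), log(config$hr_middle), 0)[tert]
  t_event <- rexp(n, rate = config$baseline_hazard * exp(log_hr))
  bdr <- as.Date(config$baseline_date_range)
  baseline_date <- bdr[1] + runif(n) * as.numeric(bdr[2] - bdr[1])
  censor_date <- as.Date(config$censor_date_by_site[site])
  censor_years <- as.numeric(censor_date - baseline_date) / 365.25
  time <- pmin(t_event, censor_years)
  event <- as.integer(t_event <= censor_years)
  cause <- ifelse(event == 1L,
                  ifelse(runif(n) < config$p_cns_death, "CNS", "nonCNS"),
                  NA_character_)

  tibble::tibble(
    subject_id = as.character(subject_id), age = age, sex = sex,
    center_race = center_race, site = site, smoking = smoking,
    education = education, hypertension = hypertension, diabetes = diabetes,
    bmi = bmi, icv = icv, cognitive_status = cognitive_status,
    walk_4m = walk_4m, low_grip = low_grip, chd = chd, stroke = stroke,
    afib = afib, heart_failure = heart_failure,
    time = time, event = event, cause = cause,
    true_bag = true_bag
  )
}

#' Simulate an aptamer-scale proteomics panel linked to true BAG
#'
#' Analyte values are generated on an additive (log-analyte-like) scale as
#' `gamma_j * true_bag + covariate effects + N(0, 1)` noise, with `gamma_j`
#' non-zero only for `config$n_true_proteins` designated analytes (random
#' sign, magnitude around `config$protein_effect_sd`). A fixed fraction of
#' analytes is flagged as failing quality control.
#'
#' @param true_bag Ground-truth BAG vector.
#' @param covariates Optional data frame with `age` and `sex` columns; when
#'   supplied, analytes get small random age/sex effects (the PWAS adjusts
#'   for them).
#' @param config A [sim_config()].
#' @param subject_id Optional identifiers (default `T0001`...).
#' @param seed Integer seed.
#' @return A `bg_proteomics` object: `values` (subjects x analytes matrix),
#'   `analyte_id`, `qc_pass`, `true_gamma` (named, non-zero entries are the
#'   planted effects), and `log_scale = TRUE`.
#' @export
simulate_proteins <- function(true_bag, covariates = NULL, config,
                              subject_id = NULL, seed = config$seed) {
  n <- length(true_bag)
  m <- config$n_proteins
  set.seed(stage_seed(seed, "proteins"))
  if (is.null(subject_id)) subject_id <- sprintf("T%04d", seq_len(n))
  analyte_id <- sprintf("SOMA%05d", seq_len(m))
  true_idx <- sample.int(m, config$n_true_proteins)
  gamma <- numeric(m)
  gamma[true_idx] <- sample(c(-1, 1), config$n_true_proteins, TRUE) *
    config$protein_effect_sd * runif(config$n_true_proteins, 0.75, 1.25)
  values <- outer(true_bag, gamma) + matrix(rnorm(n * m), n, m)
  if (!is.null(covariates)) {
    if (!is.null(covariates$age)) {
      beta_age <- rnorm(m, 0, 0.01)
      values <- values + outer(covariates$age - mean(covariates$age), beta_age)
    }
    if (!is.null(covariates$sex)) {
      beta_sex <- rnorm(m, 0, 0.1)
      values <- values + outer(as.numeric(covariates$sex == "male"), beta_sex)
    }
  }
  dimnames(values) <- list(subject_id, analyte_id)
  n_fail <- round(config$qc_fail_frac * m)
  qc_pass <- rep(TRUE, m)
  if (n_fail > 0) qc_pass[sample.int(m, n_fail)] <- FALSE
  names(qc_pass) <- analyte_id
  structure(
    list(values = values, analyte_id = analyte_id, qc_pass = qc_pass,
         true_gamma = setNames(gamma, analyte_id), log_scale = TRUE),
    class = "bg_proteomics"
  )
}

#' @export
print.bg_proteomics <- function(x, ...) {
  cat(sprintf("<bg_proteomics> %d subjects x %d analytes (%d QC-pass)\n",
              nrow(x$values), ncol(x$values), sum(x$qc_pass)))
  invisible(x)
}

#' Simulate a complete two-cohort brain-age study
#'
#' One call generating everything downstream modules consume: a template, a
#' planted atrophy weight map, a training cohort (wide age range, standing in
#' for cognitively normal reference subjects) and a target cohort (ages
#' 67-90 by default) of GM volumes, a target phenotype/survival table, and a
#' proteomics panel. Ground truth (weight map, per-subject true BAG, planted
#' analyte effects, generating log hazard ratios) is returned for recovery
#' tests.
#'
#' @param config A [sim_config()].
#' @return A list of class `bg_cohort` with elements `template`,
#'   `weight_map`, `train`, `target`, `pheno`, `proteins`, `ground_truth`,
#'   and `config`.
#' @export
#' @examples
#' cfg <- sim_config(grid_shape = c(12, 12, 12), n_train = 24, n_target = 20,
#'                   n_proteins = 50, n_true_proteins = 5)
#' coh <- simulate_cohort(cfg)
#' coh$pheno
simulate_cohort <- function(config) {
  validate_sim_config(config)
  template <- make_template(config$grid_shape, seed = config$seed)
  weight_map <- make_signal_map(template, config$n_signal_clusters,
                                config$effect_scale, seed = config$seed)
  set.seed(stage_seed(config$seed, "bag_train"))
  bag_train <- rnorm(config$n_train, 0, config$bag_sd)
  set.seed(stage_seed(config$seed, "bag_target"))
  bag_target <- rnorm(config$n_target, 0, config$bag_sd)
  bag_target <- bag_target - mean(bag_target)  # centered by construction
  train <- simulate_gm_cohort(template, weight_map, config$n_train,
                              config$train_age_range, config$noise_sd,
                              config$smooth_fwhm, config$age_ref,
                              bag = bag_train,
                              seed = stage_seed(config$seed, "train"),
                              id_prefix = "A")
  target <- simulate_gm_cohort(template, weight_map, config$n_target,
                               config$target_age_range, config$noise_sd,
                               config$smooth_fwhm, config$age_ref,
                               bag = bag_target,
                               seed = stage_seed(config$seed, "target"),
                               id_prefix = "T")
  pheno <- simulate_phenotypes(bag_target, config, age = target$age,
                               subject_id = target$volumes$subject_id,
                               seed = config$seed)
  proteins <- simulate_proteins(bag_target, covariates = pheno, config,
                                subject_id = target$volumes$subject_id,
                                seed = config$seed)
  structure(
    list(template = template, weight_map = weight_map,
         train = train$volumes, target = target$volumes, pheno = pheno,
         proteins = proteins,
         ground_truth = list(
           weight_map = weight_map, true_bag_train = bag_train,
           true_bag_target = bag_target,
           true_protein_ids = names(which(proteins$true_gamma != 0)),
           true_log_hrs = c(lowest = log(config$hr_lowest),
                            middle = log(config$hr_middle), highest = 0)
         ),
         config = config),
    class = "bg_cohort"
  )
}

#' @export
print.bg_cohort <- function(x, ...) {
  cat("<bg_cohort>\n  train: ")
  print(x$train)
  cat("  target: ")
  print(x$target)
  cat(sprintf("  pheno: %d rows; proteins: %d analytes\n",
              nrow(x$pheno), ncol(x$proteins$values)))
  invisible(x)
}
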