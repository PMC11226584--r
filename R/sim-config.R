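#' Simulation configuration for a synthetic brain-age cohort
#'
#' Bundles every parameter of the synthetic-cohort generator: grid geometry,
#' cohort sizes and age ranges, the planted atrophy signal, imaging noise, the
#' ground-truth BAG scale, the protein panel, tertile hazard ratios, and
#' site-specific administrative censoring.
#'
#' @param grid_shape Integer vector of length 3, voxel dimensions of the
#'   template grid (all >= 8).
#' @param n_train,n_target Training-/target-cohort sizes.
#' @param train_age_range,target_age_range Numeric length-2 vectors, years.
#'   Ages are drawn uniformly on these ranges. The target range defaults to
#'   67-90 (an older community cohort); the training range is wider so the
#'   target is interpolated, mirroring a reference cohort of cognitively
#'   normal adults.
#' @param age_ref Centering constant (years) for the atrophy signal: a subject
#'   at `age_ref` with zero BAG shows the bare template.
#' @param n_signal_clusters Number of spherical atrophy clusters planted in
#'   the template brain.
#' @param effect_scale Peak gray-matter loss per year of (effective) age, in
#'   GM-probability units; must be non-zero, applied with a negative sign.
#' @param noise_sd Voxel-wise Gaussian noise SD (GM units) before smoothing.
#' @param smooth_fwhm Full-width-half-maximum (voxels) of the Gaussian kernel
#'   applied to the noise field; 0 disables smoothing.
#' @param bag_sd SD (years) of the ground-truth brain age gap injected as a
#'   per-subject shift of effective age.
#' @param n_proteins,n_true_proteins Panel size and number of analytes truly
#'   associated with BAG (`n_true_proteins <= n_proteins`).
#' @param protein_effect_sd SD of the non-zero analyte effects, analyte units
#'   per BAG-year.
#' @param qc_fail_frac Fraction of analytes flagged as failing quality
#'   control.
#' @param hr_lowest,hr_middle Generating hazard ratios of the lowest/middle
#'   BAG tertile versus the highest (reference) tertile.
#' @param baseline_hazard Yearly death hazard in the reference (highest BAG)
#'   tertile.
#' @param censor_date_by_site Named character vector mapping site label to an
#'   administrative censoring date (`"YYYY-MM-DD"`).
#' @param baseline_date_range Character length-2, the window of baseline exam
#'   dates subjects are uniformly enrolled over.
#' @param p_cns_death Probability that a death is CNS-related.
#' @param seed Integer seed; every generator output is a deterministic
#'   function of the config and this seed.
#'
#' @return A list of class `bg_sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(grid_shape = c(16, 16, 16), n_train = 40, n_target = 30)
#' cfg$target_age_range
sim_config <- function(grid_shape = c(32L, 32L, 32L),
                       n_train = 300L,
                       n_target = 500L,
                       train_age_range = c(55, 95),
                       target_age_range = c(67, 90),
                       age_ref = 75,
                       n_signal_clusters = 4L,
                       effect_scale = 0.004,
                       noise_sd = 0.05,
                       smooth_fwhm = 2,
                       bag_sd = 3,
                       n_proteins = 400L,
                       n_true_proteins = 33L,
                       protein_effect_sd = 0.15,
                       qc_fail_frac = 407 / 5284,
                       hr_lowest = 0.4,
                       hr_middle = 0.6,
                       baseline_hazard = 0.035,
                       censor_date_by_site = c(
                         Jackson = "2017-12-31", Forsyth = "2019-12-31",
                         Minneapolis = "2019-12-31", Washington = "2019-12-31"
                       ),
                       baseline_date_range = c("2011-06-01", "2013-06-01"),
                       p_cns_death = 0.14,
                       seed = 1L) {
  cfg <- list(
    grid_shape = as.integer(grid_shape), n_train = as.integer(n_train),
    n_target = as.integer(n_target),
    train_age_range = as.numeric(train_age_range),
    target_age_range = as.numeric(target_age_range),
    age_ref = age_ref, n_signal_clusters = as.integer(n_signal_clusters),
    effect_scale = effect_scale, noise_sd = noise_sd,
    smooth_fwhm = smooth_fwhm, bag_sd = bag_sd,
    n_proteins = as.integer(n_proteins),
    n_true_proteins = as.integer(n_true_proteins),
    protein_effect_sd = protein_effect_sd, qc_fail_frac = qc_fail_frac,
    hr_lowest = hr_lowest, hr_middle = hr_middle,
    baseline_hazard = baseline_hazard,
    censor_date_by_site = censor_date_by_site,
    baseline_date_range = baseline_date_range,
    p_cns_death = p_cns_death, seed = as.integer(seed)
  )
  class(cfg) <- "bg_sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$grid_shape) == 3L)
  if (any(cfg$grid_shape < 8L)) {
    abort("grid_shape dimensions must all be >= 8")
  }
  counts <- c(cfg$n_train, cfg$n_target, cfg$n_signal_clusters,
              cfg$n_proteins, cfg$n_true_proteins)
  if (any(counts <= 0L)) abort("all counts in sim_config must be > 0")
  if (cfg$noise_sd <= 0) abort("noise_sd must be > 0")
  if (cfg$effect_scale == 0) abort("effect_scale must be non-zero")
  if (cfg$n_true_proteins > cfg$n_proteins) {
    abort("n_true_proteins must be <= n_proteins")
  }
  if (diff(cfg$train_age_range) <= 0 || diff(cfg$target_age_range) <= 0) {
    abort("age ranges must be non-degenerate (min < max)")
  }
  if (cfg$qc_fail_frac < 0 || cfg$qc_fail_frac >= 1) {
    abort("qc_fail_frac must be in [0, 1)")
  }
  if (cfg$target_age_range[1] < cfg$train_age_range[1] ||
      cfg$target_age_range[2] > cfg$train_age_range[2]) {
    warn(paste("target_age_range extends beyond train_age_range:",
               "brain age transfer will extrapolate"))
  }
  cfg
}

#' @export
print.bg_sim_config <- function(x, ...) {
  cat("<bg_sim_config>\n")
  cat(sprintf("  grid %s | n_train %d | n_target %d (ages %g-%g)\n",
              paste(x$grid_shape, collapse = "x"), x$n_train, x$n_target,
              x$target_age_range[1], x$target_age_range[2]))
  cat(sprintf("  signal: %d clusters, effect %g GM/yr; noise sd %g, fwhm %g\n",
              x$n_signal_clusters, x$effect_scale, x$noise_sd, x$smooth_fwhm))
  cat(sprintf("  proteins: %d (%d true), qc fail %.3f; HRs %g/%g vs ref\n",
              x$n_proteins, x$n_true_proteins, x$qc_fail_frac,
              x$hr_lowest, x$hr_middle))
  invisible(x)
}
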