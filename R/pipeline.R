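#' Estimate brain age gap for a simulated two-cohort study
#'
#' The modelling core of the pipeline: build a brain mask from the template,
#' vectorize both cohorts, fit the elastic-net age model on the training
#' cohort, predict raw ages in both, fit the linear bias correction on the
#' training predictions, and emit the target-cohort BAG table with tertiles.
#'
#' @param cohort A `bg_cohort` from [simulate_cohort()].
#' @param fit A [fit_config()].
#' @param mask_threshold Template threshold for [build_mask()].
#' @return A list of class `bg_bag_fit`: `model`, `bias`, `mask`,
#'   `bag` (target BAG table with tertiles), `bag_train`, `metrics`
#'   (train/target accuracy), `weight_volume`.
#' @export
estimate_bag <- function(cohort, fit = fit_config(), mask_threshold = 0.1) {
  stopifnot(inherits(cohort, "bg_cohort"))
  mask <- build_mask(cohort$template, mask_threshold)
  design_train <- vectorize(cohort$train, mask)
  model <- fit_age_model(design_train, cohort$train$age, fit)
  pred_train <- predict_age(model, design_train)
  bias <- fit_bias_correction(pred_train, cohort$train$age)
  bag_train <- apply_bias_correction(pred_train, cohort$train$age, bias,
                                     cohort$train$subject_id)
  design_target <- vectorize(cohort$target, mask)
  pred_target <- predict_age(model, design_target)
  bag <- apply_bias_correction(pred_target, cohort$target$age, bias,
                               cohort$target$subject_id)
  bag <- add_tertiles(bag)
  metrics <- dplyr::bind_rows(
    dplyr::mutate(evaluate_predictions(pred_train, cohort$train$age),
                  cohort = "train", .before = 1),
    dplyr::mutate(evaluate_predictions(pred_target, cohort$target$age),
                  cohort = "target", .before = 1)
  )
  structure(
    list(model = model, bias = bias, mask = mask, bag = bag,
         bag_train = bag_train, metrics = metrics,
         weight_volume = unvectorize(model$weights, mask)),
    class = "bg_bag_fit"
  )
}

#' @export
print.bg_bag_fit <- function(x, ...) {
  cat("<bg_bag_fit>\n")
  print(x$model)
  print(x$metrics)
  invisible(x)
}

#' Run the full synthetic brain-age study end to end
#'
#' Simulate -> mask/vectorize -> train the elastic-net age model -> predict
#' and bias-correct -> BAG tertiles -> Cox mortality models (all subjects,
#' cognitively normal only, and the cause-specific competing-risk variant)
#' -> LS-mean cognitive-status contrasts -> phenotype regressions -> QC
#' filter and PWAS. Every stage seed derives deterministically from
#' `config$seed`, and all result tables are written as CSV under `out_dir`
#' together with a JSON manifest (config, seeds, versions, file hashes), so
#' a rerun with the same config is byte-identical.
#'
#' @param config A [sim_config()].
#' @param fit A [fit_config()] (its seed is derived from `config$seed`).
#' @param out_dir Output directory; `NULL` skips writing.
#' @param mask_threshold Template threshold for the brain mask.
#' @param lsmeans_covariates Adjustment set for the cognitive-status LS
#'   means (default unadjusted).
#' @param cox_covariates Adjustment set for the Cox models.
#' @param alpha PWAS significance level.
#' @return A list of class `bg_run` with the fitted objects, result tables,
#'   and (when written) file paths.
#' @export
run_full <- function(config = sim_config(),
                     fit = fit_config(seed = stage_seed(config$seed, "fit")),
                     out_dir = NULL, mask_threshold = 0.1,
                     lsmeans_covariates = character(),
                     cox_covariates = c("age", "center_race", "sex",
                                        "smoking", "hypertension",
                                        "education", "diabetes", "icv"),
                     alpha = 0.05) {
  stage <- "simulate"
  res <- tryCatch({
    cohort <- simulate_cohort(config)
    stage <- "train"
    bagfit <- estimate_bag(cohort, fit, mask_threshold)
    stage <- "associate"
    merged <- dplyr::left_join(bagfit$bag,
                               dplyr::select(cohort$pheno, -"age"),
                               by = "subject_id")
    cox_all <- fit_cox(merged, cox_covariates)
    cn <- dplyr::filter(merged, .data$cognitive_status == "CN")
    cox_cn <- fit_cox(cn, cox_covariates)
    cox_cr <- fit_competing_risk_cox(cn, cox_covariates,
                                     event_cause = "nonCNS",
                                     competing_cause = "CNS")
    lsm <- lsmeans_by_group(merged, outcome = "bag",
                            group = "cognitive_status",
                            covariates = lsmeans_covariates)
    phen <- phenotype_assoc(
      merged, phenotypes = c("bmi", "diabetes", "hypertension", "walk_4m",
                             "low_grip", "heart_failure", "afib", "chd",
                             "stroke"))
    stage <- "pwas"
    prot <- qc_filter(cohort$proteins)
    pwas <- run_pwas(bagfit$bag, prot, covariates = merged, alpha = alpha)
    stage <- "report"
    list(cohort = cohort, bagfit = bagfit, bag = bagfit$bag,
         metrics = bagfit$metrics, cox_all = cox_all, cox_cn = cox_cn,
         cox_competing = cox_cr, lsmeans = lsm, phenotype = phen,
         pwas = pwas, pwas_summary = pwas_report(pwas),
         table1 = describe_cohort(cohort$pheno))
  }, error = function(e) {
    abort(sprintf("pipeline failed at stage '%s': %s", stage,
                  conditionMessage(e)), parent = e)
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(
      bag = res$bag, metrics = res$metrics,
      cox_all = tidy(res$cox_all), cox_cn = tidy(res$cox_cn),
      cox_competing = tidy(res$cox_competing),
      lsmeans = res$lsmeans$means, lsmean_contrasts = res$lsmeans$contrasts,
      phenotype_assoc = res$phenotype, pwas = tibble::as_tibble(res$pwas),
      table1 = res$table1
    )
    paths <- character()
    for (nm in names(files)) {
      p <- file.path(out_dir, paste0(nm, ".csv"))
      readr::write_csv(files[[nm]], p)
      paths[nm] <- p
    }
    manifest <- list(
      package_version = as.character(utils::packageVersion("braingap")),
      seed = config$seed,
      config = config[setdiff(names(config), "censor_date_by_site")],
      censor_date_by_site = as.list(config$censor_date_by_site),
      fit = unclass(fit),
      n_mask_voxels = length(res$bagfit$mask$index),
      tertile_boundaries = as.list(attr(res$bag, "tertile_boundaries")),
      file_md5 = as.list(tools::md5sum(unname(paths)))
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    res$paths <- paths
  }
  class(res) <- "bg_run"
  res
}

#' @export
print.bg_run <- function(x, ...) {
  cat("<bg_run>\n")
  print(x$metrics)
  cat("Cox (all participants):\n")
  print(tibble::as_tibble(x$cox_all))
  cat(sprintf("PWAS: %d Bonferroni / %d FDR significant of %d analytes\n",
              sum(x$pwas$bonferroni_significant, na.rm = TRUE),
              sum(x$pwas$fdr_significant, na.rm = TRUE), attr(x$pwas, "m")))
  invisible(x)
}

#' Cohort characteristics stratified by cognitive status
#'
#' A long-format analogue of a baseline-characteristics table: counts and
#' percentages for categorical variables, mean and SD for age and BMI, for
#' the total sample and within each cognitive-status stratum. Empty strata
#' are rendered with `n = 0` rather than dropped.
#'
#' @param pheno Phenotype tibble from [simulate_phenotypes()].
#' @return A tibble with columns `variable`, `level`, `stratum`, `n`,
#'   `pct`, `mean`, `sd`.
#' @export
describe_cohort <- function(pheno) {
  check_df_cols(pheno, c("cognitive_status", "age", "bmi"), "pheno")
  cs <- pheno$cognitive_status
  strata <- c("Total", if (is.factor(cs)) levels(cs) else sort(unique(cs)))
  cat_vars <- intersect(c("sex", "center_race", "education", "smoking",
                          "hypertension", "diabetes"), names(pheno))
  rows <- list()
  for (s in strata) {
    d <- if (s == "Total") pheno else
      pheno[!is.na(pheno$cognitive_status) & pheno$cognitive_status == s, ]
    n_s <- nrow(d)
    rows[[length(rows) + 1]] <- tibble::tibble(
      variable = "N", level = NA_character_, stratum = s, n = n_s,
      pct = NA_real_, mean = NA_real_, sd = NA_real_)
    for (v in cat_vars) {
      lev <- sort(unique(as.character(pheno[[v]])))
      for (l in lev) {
        cnt <- sum(as.character(d[[v]]) == l, na.rm = TRUE)
        rows[[length(rows) + 1]] <- tibble::tibble(
          variable = v, level = l, stratum = s, n = cnt,
          pct = if (n_s > 0) 100 * cnt / n_s else NA_real_,
          mean = NA_real_, sd = NA_real_)
      }
    }
    for (v in c("age", "bmi")) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        variable = v, level = NA_character_, stratum = s, n = n_s,
        pct = NA_real_,
        mean = if (n_s > 0) mean(d[[v]], na.rm = TRUE) else NA_real_,
        sd = if (n_s > 1) sd(d[[v]], na.rm = TRUE) else NA_real_)
    }
  }
  dplyr::bind_rows(rows)
}
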