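#' Fit the linear age-bias correction
#'
#' Raw brain-age predictions show a systematic dependence on chronological
#' age (regression dilution / regression to the mean): young subjects are
#' over-predicted and old subjects under-predicted. The correction regresses
#' the uncorrected gap `predicted_raw - age` on age by ordinary least
#' squares in the training cohort; subtracting the fitted trend removes the
#' age dependence.
#'
#' @param predicted_raw Raw predicted ages (years).
#' @param age Chronological ages (years); needs >= 3 pairs with
#'   non-degenerate variance.
#' @return An object of class `bg_bias_model` with `slope_a`
#'   (dimensionless) and `intercept_b` (years).
#' @export
fit_bias_correction <- function(predicted_raw, age) {
  if (length(predicted_raw) != length(age)) abort("length mismatch")
  if (length(age) < 3L) abort("bias correction needs >= 3 subjects")
  if (var(age) == 0) abort("degenerate age variance: bias fit impossible")
  fit <- lm((predicted_raw - age) ~ age)
  cf <- coef(fit)
  if (any(!is.finite(cf))) abort("bias-correction coefficients are not finite")
  structure(list(slope_a = unname(cf[2]), intercept_b = unname(cf[1]),
                 n = length(age)),
            class = "bg_bias_model")
}

#' @export
print.bg_bias_model <- function(x, ...) {
  cat(sprintf("<bg_bias_model> gap = %.4f * age + %.4f (n = %d)\n",
              x$slope_a, x$intercept_b, x$n))
  invisible(x)
}

#' Apply the bias correction and compute brain age gap
#'
#' `bag = (predicted_raw - age) - (slope_a * age + intercept_b)` and
#' `predicted_age_corrected = age + bag`; the brain age gap is exactly the
#' corrected prediction minus chronological age.
#'
#' @param predicted_raw Raw predicted ages.
#' @param age Chronological ages.
#' @param bias A `bg_bias_model` (fitted on the training cohort).
#' @param subject_id Optional identifiers.
#' @return A tibble with columns `subject_id`, `age`, `pred_raw`,
#'   `pred_corrected`, `bag`.
#' @export
apply_bias_correction <- function(predicted_raw, age, bias,
                                  subject_id = NULL) {
  stopifnot(inherits(bias, "bg_bias_model"))
  if (length(predicted_raw) != length(age)) abort("length mismatch")
  if (is.null(subject_id)) {
    subject_id <- sprintf("S%04d", seq_along(age))
  }
  bag <- (predicted_raw - age) - (bias$slope_a * age + bias$intercept_b)
  tibble::tibble(subject_id = as.character(subject_id), age = age,
                 pred_raw = predicted_raw, pred_corrected = age + bag,
                 bag = bag)
}

#' Prediction-accuracy metrics for an age model
#'
#' Mean absolute error, root-mean-squared error, and the Pearson correlation
#' between predicted and chronological age. When either vector has zero
#' variance the correlation is undefined; it is returned as `NA` with
#' `pearson_defined = FALSE` rather than an arbitrary convention.
#'
#' @param predicted Predicted ages. @param age Chronological ages (>= 2).
#' @return A one-row tibble: `mae`, `rmse`, `pearson_r`, `pearson_defined`.
#' @export
evaluate_predictions <- function(predicted, age) {
  if (length(predicted) != length(age)) abort("length mismatch")
  if (length(age) < 2L) abort("need >= 2 pairs")
  d <- predicted - age
  defined <- sd(predicted) > 0 && sd(age) > 0
  tibble::tibble(
    mae = mean(abs(d)), rmse = sqrt(mean(d^2)),
    pearson_r = if (defined) stats::cor(predicted, age) else NA_real_,
    pearson_defined = defined
  )
}
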