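#' @export
ggplot2::autoplot

#' @export
generics::tidy

#' @export
generics::glance

#' Cross-validation curve of an age model
#'
#' Mean CV error against lambda for each repeat, with the selected (averaged)
#' lambda marked.
#'
#' @param object A `bg_age_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bg_age_model <- function(object, ...) {
  ggplot2::ggplot(object$cv_curve,
                  ggplot2::aes(x = log(.data$lambda), y = .data$mean_err,
                               group = .data$repeat_id)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_vline(xintercept = log(object$lambda_selected),
                        linetype = 2, color = "firebrick") +
    ggplot2::labs(x = expression(log(lambda)), y = "mean CV error (years^2)",
                  title = "Repeated cross-validation curves",
                  subtitle = sprintf("selected lambda = %.4g (%s rule)",
                                     object$lambda_selected,
                                     object$selection_rule)) +
    ggplot2::theme_minimal()
}

#' Predicted versus chronological age
#'
#' @param bag_table A BAG table from [apply_bias_correction()].
#' @param corrected Plot corrected (default) or raw predictions.
#' @return A ggplot object.
#' @export
plot_predicted_age <- function(bag_table, corrected = TRUE) {
  ycol <- if (corrected) "pred_corrected" else "pred_raw"
  ggplot2::ggplot(bag_table,
                  ggplot2::aes(x = .data$age, y = .data[[ycol]])) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "chronological age (years)",
                  y = sprintf("%s predicted age (years)",
                              if (corrected) "bias-corrected" else "raw")) +
    ggplot2::theme_minimal()
}

#' Forest plot of tertile hazard ratios
#'
#' @param object A `bg_cox` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bg_cox <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$tertile <- factor(d$tertile, levels = c("lowest", "middle", "highest"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$hazard_ratio, y = .data$tertile)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "hazard ratio (vs highest BAG tertile)", y = NULL) +
    ggplot2::theme_minimal()
}

#' LS means with confidence intervals by group
#'
#' @param object A `bg_lsmeans` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bg_lsmeans <- function(object, ...) {
  ggplot2::ggplot(object$means,
                  ggplot2::aes(x = .data$group, y = .data$lsmean)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high), width = 0.15) +
    ggplot2::labs(x = NULL, y = "least-squares mean BAG (years)") +
    ggplot2::theme_minimal()
}
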