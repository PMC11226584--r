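#' Construct a proteomics container
#'
#' @param values Subjects x analytes numeric matrix; rownames are subject
#'   IDs, colnames analyte IDs.
#' @param qc_pass Logical vector, one flag per analyte (default all pass).
#' @param log_scale Whether values are already on a log-like additive scale.
#' @return A `bg_proteomics` object.
#' @export
proteomics <- function(values, qc_pass = rep(TRUE, ncol(values)),
                       log_scale = FALSE) {
  stopifnot(is.matrix(values))
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("ANALYTE%05d", seq_len(ncol(values)))
  }
  if (anyDuplicated(colnames(values))) abort("analyte IDs must be unique")
  if (length(qc_pass) != ncol(values)) {
    abort("qc_pass must have one flag per analyte")
  }
  structure(list(values = values, analyte_id = colnames(values),
                 qc_pass = setNames(qc_pass, colnames(values)),
                 true_gamma = NULL, log_scale = log_scale),
            class = "bg_proteomics")
}

#' Filter a proteomics panel to QC-passing analytes
#'
#' @param prot A `bg_proteomics` object.
#' @return The panel restricted to `qc_pass` columns; the retained count is
#'   reported via `message()`.
#' @export
qc_filter <- function(prot) {
  stopifnot(inherits(prot, "bg_proteomics"))
  keep <- which(prot$qc_pass)
  if (length(keep) == 0L) abort("no analytes pass QC")
  out <- prot
  out$values <- prot$values[, keep, drop = FALSE]
  out$analyte_id <- prot$analyte_id[keep]
  out$qc_pass <- prot$qc_pass[keep]
  if (!is.null(prot$true_gamma)) out$true_gamma <- prot$true_gamma[keep]
  message(sprintf("QC filter: %d of %d analytes retained",
                  length(keep), length(prot$qc_pass)))
  out
}

transform_analytes <- function(x, transform) {
  n <- sum(is.finite(x))
  switch(transform,
    raw = x,
    standardize = (x - mean(x, na.rm = TRUE)) / sd(x, na.rm = TRUE),
    log2 = {
      if (any(x <= 0, na.rm = TRUE)) {
        abort("log2 transform requires strictly positive analyte values")
      }
      lx <- log2(x)
      (lx - mean(lx, na.rm = TRUE)) / sd(lx, na.rm = TRUE)
    },
    rank = {
      r <- qnorm((rank(x, na.last = "keep") - 0.5) / n)
      r / sd(r, na.rm = TRUE)
    }
  )
}

#' Proteome-wide association scan of the brain age gap
#'
#' Per analyte, an ordinary-least-squares model of BAG on the (transformed,
#' per-analyte standardized) analyte value plus adjustment covariates; all
#' analytes share the covariate set, so the covariate projection is computed
#' once and applied by Frisch-Waugh-Lovell residualization (numerically
#' identical to per-analyte `lm()` fits, verified in the test suite).
#' Multiplicity control: Bonferroni at `alpha / m` and Benjamini-Hochberg
#' step-up FDR at `alpha`, with `m` the number of analytes actually tested.
#'
#' @param bag Data frame with `subject_id` and a `bag` column (a BAG table),
#'   or a named numeric vector of BAG values.
#' @param prot A `bg_proteomics` (run [qc_filter()] first).
#' @param covariates Data frame with `subject_id` plus adjustment columns.
#' @param covariate_cols Which covariate columns to adjust for; default the
#'   full adjustment set (age, sex, center-race, smoking, hypertension,
#'   education, diabetes, intracranial volume).
#' @param alpha Significance level for both decision rules.
#' @param transform Analyte preprocessing: `"auto"` (standardize when the
#'   panel is already log-scale, else log2 then standardize), `"log2"`,
#'   `"standardize"`, `"rank"` (rank-based inverse normal), or `"raw"`.
#' @return A tibble of class `bg_pwas`, one row per analyte: `analyte_id`,
#'   `beta` (BAG-years per SD of analyte), `stderr`, `p_value`,
#'   `bonferroni_significant`, `fdr_significant`, `n_used`; attributes `m`,
#'   `alpha`, `transform`.
#' @export
run_pwas <- function(bag, prot, covariates,
                     covariate_cols = c("age", "sex", "center_race",
                                        "smoking", "hypertension",
                                        "education", "diabetes", "icv"),
                     alpha = 0.05,
                     transform = c("auto", "standardize", "log2", "rank",
                                   "raw")) {
  stopifnot(inherits(prot, "bg_proteomics"))
  transform <- match.arg(transform)
  if (transform == "auto") {
    transform <- if (isTRUE(prot$log_scale)) "standardize" else "log2"
  }
  if (is.data.frame(bag)) {
    check_df_cols(bag, c("subject_id", "bag"), "bag")
    bag_v <- setNames(bag$bag, bag$subject_id)
  } else {
    bag_v <- bag
  }
  ids <- rownames(prot$values)
  if (is.null(names(bag_v)) || is.null(ids)) {
    abort("subject IDs are required on both BAG values and the panel")
  }
  check_df_cols(covariates, c("subject_id", covariate_cols), "covariates")
  common <- intersect(intersect(names(bag_v), ids), covariates$subject_id)
  unmatched <- setdiff(union(names(bag_v), ids), common)
  if (length(common) == 0L) {
    abort(sprintf("no subjects align across inputs; unmatched: %s",
                  paste(head(unmatched, 5), collapse = ", ")))
  }
  y <- unname(bag_v[common])
  X <- prot$values[common, , drop = FALSE]
  cv <- covariates[match(common, covariates$subject_id), covariate_cols,
                   drop = FALSE]
  cc <- stats::complete.cases(cv) & is.finite(y)
  y <- y[cc]; X <- X[cc, , drop = FALSE]; cv <- cv[cc, , drop = FALSE]
  Z <- stats::model.matrix(~ ., data = cv)
  n <- length(y)
  q <- qr(Z)
  if (n < ncol(Z) + 10L) {
    abort(sprintf("need >= 10 more subjects (%d) than model parameters (%d)",
                  n, ncol(Z)))
  }
  Xt <- apply(X, 2, transform_analytes, transform = transform)
  ry <- qr.resid(q, y)
  ryy <- sum(ry^2)
  df <- n - ncol(Z) - 1L

  fit_one <- function(xj) {
    ok <- is.finite(xj)
    if (!all(ok)) {
      # per-analyte complete-case refit
      if (sum(ok) < ncol(Z) + 2L) return(c(NA, NA, NA, sum(ok)))
      qi <- qr(Z[ok, , drop = FALSE])
      ryi <- qr.resid(qi, y[ok])
      rxi <- qr.resid(qi, xj[ok])
      sxx <- sum(rxi^2)
      if (sxx < 1e-12) return(c(NA, NA, NA, sum(ok)))
      b <- sum(rxi * ryi) / sxx
      rss <- sum(ryi^2) - b^2 * sxx
      dfi <- sum(ok) - ncol(Z) - 1L
      se <- sqrt(rss / dfi / sxx)
      return(c(b, se, 2 * stats::pt(-abs(b / se), dfi), sum(ok)))
    }
    rx <- qr.resid(q, xj)
    sxx <- sum(rx^2)
    if (sxx < 1e-12) return(c(NA, NA, NA, n))
    b <- sum(rx * ry) / sxx
    rss <- ryy - b^2 * sxx
    se <- sqrt(rss / df / sxx)
    c(b, se, 2 * stats::pt(-abs(b / se), df), n)
  }
  res <- t(apply(Xt, 2, fit_one))
  skipped <- sum(is.na(res[, 1]))
  if (skipped > 0) {
    message(sprintf("%d analyte(s) skipped (degenerate after adjustment)", skipped))
  }
  tested <- !is.na(res[, 3])
  m <- sum(tested)
  p_bonf <- p_bh <- rep(NA_real_, nrow(res))
  p_bonf[tested] <- p.adjust(res[tested, 3], method = "bonferroni")
  p_bh[tested] <- p.adjust(res[tested, 3], method = "BH")
  res <- unname(res)
  out <- tibble::tibble(
    analyte_id = colnames(prot$values),
    beta = res[, 1], stderr = res[, 2], p_value = res[, 3],
    bonferroni_significant = !is.na(p_bonf) & p_bonf <= alpha,
    fdr_significant = !is.na(p_bh) & p_bh <= alpha,
    n_used = as.integer(res[, 4])
  )
  class(out) <- c("bg_pwas", class(out))
  attr(out, "m") <- m
  attr(out, "alpha") <- alpha
  attr(out, "transform") <- transform
  attr(out, "n") <- n
  out
}

#' Summarize a PWAS into a sorted table and volcano coordinates
#'
#' @param result A `bg_pwas` tibble.
#' @param alpha Significance level for the threshold lines (defaults to the
#'   scan's).
#' @return A list of class `bg_pwas_report`: `table` (sorted by p-value)
#'   and `volcano` (per-analyte effect size and `-log10 p`), plus
#'   `bonferroni_line` and `fdr_line` (`-log10 p` thresholds; the FDR line
#'   is the largest p-value passed by the step-up rule, `NA` when nothing
#'   passes).
#' @export
pwas_report <- function(result, alpha = attr(result, "alpha") %||% 0.05) {
  stopifnot(inherits(result, "bg_pwas"), nrow(result) > 0)
  m <- attr(result, "m")
  tab <- dplyr::arrange(tibble::as_tibble(result), .data$p_value)
  volcano <- dplyr::mutate(
    dplyr::filter(tab, !is.na(.data$p_value)),
    neg_log10_p = -log10(.data$p_value)
  )
  fdr_pass <- result$p_value[result$fdr_significant]
  structure(
    list(table = tab, volcano = volcano,
         bonferroni_line = -log10(alpha / m),
         fdr_line = if (length(fdr_pass)) -log10(max(fdr_pass)) else NA_real_,
         alpha = alpha, m = m),
    class = "bg_pwas_report"
  )
}

#' @export
print.bg_pwas_report <- function(x, ...) {
  cat(sprintf(
    "<bg_pwas_report> m = %d analytes, alpha = %g; %d Bonferroni / %d FDR hits\n",
    x$m, x$alpha, sum(x$table$bonferroni_significant, na.rm = TRUE),
    sum(x$table$fdr_significant, na.rm = TRUE)))
  print(head(x$table, 10))
  invisible(x)
}

#' Volcano plot of a PWAS
#'
#' Effect size against `-log10 p` with horizontal Bonferroni (red) and
#' FDR (green) threshold lines.
#'
#' @param object A `bg_pwas_report` (or `bg_pwas`, summarized on the fly).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bg_pwas_report <- function(object, ...) {
  p <- ggplot2::ggplot(object$volcano,
                       ggplot2::aes(x = .data$beta, y = .data$neg_log10_p)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$bonferroni_significant),
                        alpha = 0.6, show.legend = FALSE) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey40",
                                           `TRUE` = "firebrick")) +
    ggplot2::geom_hline(yintercept = object$bonferroni_line,
                        color = "red", linetype = 2) +
    ggplot2::labs(x = "BAG-years per SD of analyte",
                  y = expression(-log[10](p)),
                  title = "Proteome-wide associations with brain age gap")
  if (is.finite(object$fdr_line)) {
    p <- p + ggplot2::geom_hline(yintercept = object$fdr_line,
                                 color = "darkgreen", linetype = 3)
  }
  p + ggplot2::theme_minimal()
}

#' @rdname autoplot.bg_pwas_report
#' @export
autoplot.bg_pwas <- function(object, ...) {
  autoplot.bg_pwas_report(pwas_report(object), ...)
}
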