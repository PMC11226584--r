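#' Stratify values into tertiles
#'
#' Boundaries are the empirical 1/3 and 2/3 quantiles. Labels follow the
#' closed-outer convention `t1 <= q1 < t2 < q2 <= t3`: values exactly at the
#' lower boundary go to tertile 1 and values exactly at the upper boundary
#' to tertile 3.
#'
#' @param x Numeric vector with >= 3 finite values.
#' @return A list of class `bg_tertiles`: integer `label` (1/2/3) and
#'   `boundaries` (`q1`, `q2`).
#' @export
#' @examples
#' assign_tertiles(1:9)$label
assign_tertiles <- function(x) {
  if (sum(is.finite(x)) < 3L) abort("need >= 3 finite values")
  q <- unname(quantile(x, c(1, 2) / 3, na.rm = TRUE))
  label <- ifelse(x <= q[1], 1L, ifelse(x >= q[2], 3L, 2L))
  counts <- tabulate(label, 3L)
  if (any(counts == 0L)) {
    abort(sprintf(
      "tertile boundaries collide (q1 = %g, q2 = %g): group sizes %s",
      q[1], q[2], paste(counts, collapse = "/")))
  }
  structure(list(label = label, boundaries = c(q1 = q[1], q2 = q[2])),
            class = "bg_tertiles")
}

#' Add a BAG tertile column to a table
#'
#' @param data A data frame. @param col Column to stratify (default `bag`).
#' @return `data` with an integer `tertile` column; boundaries in
#'   `attr(, "tertile_boundaries")`.
#' @export
add_tertiles <- function(data, col = "bag") {
  check_df_cols(data, col, "data")
  tt <- assign_tertiles(data[[col]])
  data$tertile <- tt$label
  attr(data, "tertile_boundaries") <- tt$boundaries
  data
}

tertile_factor <- function(tertile, reference = c("highest", "lowest")) {
  reference <- match.arg(reference)
  lev <- if (reference == "highest") c(3L, 2L, 1L) else c(1L, 2L, 3L)
  factor(tertile, levels = lev,
         labels = c("highest", "middle", "lowest")[match(lev, 3:1)])
}

cox_formula <- function(covariates) {
  rhs <- paste(c(".tertile", covariates), collapse = " + ")
  stats::as.formula(paste("survival::Surv(time, event) ~", rhs))
}

#' Cox proportional-hazards model of mortality by BAG tertile
#'
#' Fits a partial-likelihood Cox model with tertile indicator variables (the
#' highest — oldest-brain — tertile as reference by default) plus adjustment
#' covariates, Efron tie handling, and Wald 95% confidence intervals.
#' Complete cases only; the number of excluded rows is recorded.
#'
#' @param data Data frame with columns `time` (years, > 0), `event` (0/1),
#'   `tertile` (1/2/3), and any covariates.
#' @param covariates Character vector of covariate column names.
#' @param reference `"highest"` (default) or `"lowest"` tertile as the
#'   reference level.
#' @return A tibble of class `bg_cox` with one row per tertile
#'   (`hazard_ratio`, `ci_low`, `ci_high`, `p_value`; reference row fixed at
#'   1) and attributes `n`, `n_events`, `n_competing`, `n_excluded`,
#'   `model` (the underlying `coxph` fit).
#' @export
fit_cox <- function(data, covariates = character(), reference = "highest") {
  check_df_cols(data, c("time", "event", "tertile", covariates), "data")
  used <- c("time", "event", "tertile", covariates)
  cc <- stats::complete.cases(data[used])
  n_excluded <- sum(!cc)
  d <- data[cc, used, drop = FALSE]
  if (any(d$time <= 0)) abort("survival times must be > 0")
  d$.tertile <- tertile_factor(d$tertile, reference)
  if (min(table(d$.tertile[d$event == 1])) < 1L) {
    warn("a tertile stratum has no events; estimates may be unstable")
  }
  fit <- survival::coxph(cox_formula(covariates), data = d, ties = "efron")
  if (any(abs(coef(fit)) > 15)) {
    warn("extreme Cox coefficients: possible monotone likelihood (separation)")
  }
  sm <- summary(fit)
  terms <- grep("^\\.tertile", rownames(sm$coefficients), value = TRUE)
  est <- sm$coefficients[terms, , drop = FALSE]
  ci <- sm$conf.int[terms, , drop = FALSE]
  ref_label <- if (reference == "highest") "highest" else "lowest"
  res <- tibble::tibble(
    tertile = c(ref_label, sub("^\\.tertile", "", terms)),
    hazard_ratio = c(1, unname(est[, "exp(coef)"])),
    ci_low = c(NA, unname(ci[, "lower .95"])),
    ci_high = c(NA, unname(ci[, "upper .95"])),
    p_value = c(NA, unname(est[, "Pr(>|z|)"]))
  )
  class(res) <- c("bg_cox", class(res))
  attr(res, "n") <- nrow(d)
  attr(res, "n_events") <- sum(d$event)
  attr(res, "n_competing") <- 0L
  attr(res, "n_excluded") <- n_excluded
  attr(res, "model") <- fit
  res
}

#' Cause-specific competing-risk Cox model
#'
#' Cause-specific hazard analysis: deaths from the competing cause are
#' censored at their event time, otherwise the model is identical to
#' [fit_cox()]. With zero competing events it reduces to [fit_cox()]
#' exactly.
#'
#' @inheritParams fit_cox
#' @param event_cause Cause analyzed as the event (matched against the
#'   `cause` column).
#' @param competing_cause Cause treated as competing (censored).
#' @return As [fit_cox()]; `n_competing` counts censored competing deaths.
#' @export
fit_competing_risk_cox <- function(data, covariates = character(),
                                   event_cause = "nonCNS",
                                   competing_cause = "CNS",
                                   reference = "highest") {
  check_df_cols(data, c("cause"), "data")
  competing <- data$event == 1 &
    !is.na(data$cause) & data$cause == competing_cause
  d <- data
  d$event <- ifelse(competing, 0L, d$event)
  n_competing <- sum(competing, na.rm = TRUE)
  if (n_competing == 0L) {
    message("no competing events: cause-specific model reduces to fit_cox")
  }
  res <- fit_cox(d, covariates, reference)
  attr(res, "n_competing") <- n_competing
  res
}

#' @export
print.bg_cox <- function(x, ...) {
  cat(sprintf("<bg_cox> n = %d, events = %d, competing = %d (excluded %d)\n",
              attr(x, "n"), attr(x, "n_events"), attr(x, "n_competing"),
              attr(x, "n_excluded")))
  print(tibble::as_tibble(x))
  invisible(x)
}

#' @export
tidy.bg_cox <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.bg_cox <- function(x, ...) {
  tibble::tibble(n = attr(x, "n"), n_events = attr(x, "n_events"),
                 n_competing = attr(x, "n_competing"),
                 n_excluded = attr(x, "n_excluded"))
}

#' Least-squares means of BAG across groups
#'
#' Fits `outcome ~ group + covariates` and reports model-adjusted group
#' means: predictions at covariates fixed to their sample means, with
#' categorical covariates weighted by their observed proportions. Pairwise
#' contrasts come with standard errors and unadjusted p-values. With no
#' covariates the LS means are exactly the raw group means.
#'
#' @param data Data frame. @param outcome Outcome column (default `"bag"`).
#' @param group Grouping column (factor or coercible).
#' @param covariates Character vector of adjustment columns (default none).
#' @param conf_level Confidence level for the mean CIs.
#' @return A list of class `bg_lsmeans`: `means` (group, n, lsmean, stderr,
#'   ci_low, ci_high) and `contrasts` (contrast, difference, stderr,
#'   p_value), plus the underlying `lm` fit.
#' @export
lsmeans_by_group <- function(data, outcome = "bag", group,
                             covariates = character(), conf_level = 0.95) {
  check_df_cols(data, c(outcome, group, covariates), "data")
  d <- data[stats::complete.cases(data[c(outcome, group, covariates)]), ]
  d[[group]] <- factor(d[[group]])
  sizes <- table(d[[group]])
  if (length(sizes) < 2L || any(sizes < 2L)) {
    abort("need >= 2 groups with >= 2 subjects each")
  }
  rhs <- paste(c(group, covariates), collapse = " + ")
  fit <- lm(stats::as.formula(paste(outcome, "~", rhs)), data = d)
  al <- stats::alias(fit)$Complete
  if (!is.null(al)) {
    abort(sprintf("rank-deficient design; aliased terms: %s",
                  paste(rownames(al), collapse = ", ")))
  }
  emm <- emmeans::emmeans(fit, specs = group, weights = "proportional",
                          level = conf_level)
  ms <- as.data.frame(emm)
  means <- tibble::tibble(
    group = as.character(ms[[1]]), n = as.integer(sizes[as.character(ms[[1]])]),
    lsmean = ms$emmean, stderr = ms$SE,
    ci_low = ms$lower.CL, ci_high = ms$upper.CL
  )
  pr <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                        adjust = "none"))
  contrasts <- tibble::tibble(
    contrast = as.character(pr$contrast), difference = pr$estimate,
    stderr = pr$SE, p_value = pr$p.value
  )
  structure(list(means = means, contrasts = contrasts, model = fit),
            class = "bg_lsmeans")
}

#' @export
print.bg_lsmeans <- function(x, ...) {
  cat("<bg_lsmeans>\n")
  print(x$means)
  print(x$contrasts)
  invisible(x)
}

#' @export
tidy.bg_lsmeans <- function(x, ...) x$contrasts

#' @export
glance.bg_lsmeans <- function(x, ...) {
  s <- summary(x$model)
  tibble::tibble(n = sum(x$means$n), n_groups = nrow(x$means),
                 r_squared = s$r.squared, sigma = s$sigma)
}

#' Covariate-adjusted associations between BAG and phenotypes
#'
#' One linear model per phenotype with BAG as the outcome:
#' `bag ~ phenotype + covariates`, reporting the phenotype coefficient with
#' a 95% Wald confidence interval and p-value. Complete cases per model.
#'
#' @param data Data frame containing BAG, phenotypes and covariates.
#' @param phenotypes Character vector of phenotype columns (binary or
#'   continuous).
#' @param bag BAG column name.
#' @param covariates Adjustment set; default age, sex, and center-race.
#' @return A tibble: `phenotype`, `estimate`, `ci_low`, `ci_high`,
#'   `p_value`, `n`.
#' @export
phenotype_assoc <- function(data, phenotypes, bag = "bag",
                            covariates = c("age", "sex", "center_race")) {
  check_df_cols(data, c(bag, phenotypes, covariates), "data")
  purrr::map_dfr(phenotypes, function(ph) {
    d <- data[stats::complete.cases(data[c(bag, ph, covariates)]), ]
    x <- d[[ph]]
    if (length(unique(x[!is.na(x)])) < 2L) {
      abort(sprintf("phenotype '%s' is constant", ph))
    }
    rhs <- paste(c(ph, covariates), collapse = " + ")
    fit <- lm(stats::as.formula(paste(bag, "~", rhs)), data = d)
    sm <- summary(fit)$coefficients
    term <- grep(paste0("^", ph), rownames(sm), value = TRUE)[1]
    ci <- confint(fit)[term, ]
    tibble::tibble(phenotype = ph, estimate = unname(sm[term, "Estimate"]),
                   ci_low = unname(ci[1]), ci_high = unname(ci[2]),
                   p_value = unname(sm[term, "Pr(>|t|)"]), n = nrow(d))
  })
}
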