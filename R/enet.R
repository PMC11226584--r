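#' Fitting configuration for the voxel-wise elastic-net age model
#'
#' @param alpha Elastic-net mixing parameter in `[0, 1]` (1 = lasso, 0 =
#'   ridge); default 0.5, an equal blend of the two penalties.
#' @param n_folds Cross-validation folds (default 10).
#' @param n_repeats Number of seeded CV repetitions whose selected lambdas
#'   are averaged (default 5); repeats differ only in the random fold
#'   partition.
#' @param lambda_grid `"auto"` (100 log-spaced values from the data-driven
#'   `lambda_max` down to `1e-3 * lambda_max`) or a strictly decreasing
#'   positive numeric vector.
#' @param selection_rule `"1se"` (largest lambda with CV error within one
#'   standard error of the minimum) or `"min"`.
#' @param lambda_average `"arithmetic"` (mean of the per-repeat lambdas on
#'   the raw scale) or `"log"` (geometric mean).
#' @param standardize Standardize each voxel to mean 0 / SD 1 before fitting
#'   (coefficients are returned on the original scale either way).
#' @param seed Integer seed controlling the fold partitions.
#' @return A list of class `bg_fit_config`.
#' @export
fit_config <- function(alpha = 0.5, n_folds = 10L, n_repeats = 5L,
                       lambda_grid = "auto", selection_rule = c("1se", "min"),
                       lambda_average = c("arithmetic", "log"),
                       standardize = TRUE, seed = 1L) {
  selection_rule <- match.arg(selection_rule)
  lambda_average <- match.arg(lambda_average)
  if (alpha < 0 || alpha > 1) abort("alpha must be in [0, 1]")
  if (n_folds < 2L) abort("n_folds must be >= 2")
  if (n_repeats < 1L) abort("n_repeats must be >= 1")
  if (is.numeric(lambda_grid)) {
    if (any(lambda_grid <= 0) || any(diff(lambda_grid) >= 0)) {
      abort("lambda_grid must be strictly decreasing and positive")
    }
  } else if (!identical(lambda_grid, "auto")) {
    abort('lambda_grid must be "auto" or a decreasing numeric vector')
  }
  structure(list(alpha = alpha, n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats), lambda_grid = lambda_grid,
                 selection_rule = selection_rule,
                 lambda_average = lambda_average,
                 standardize = standardize, seed = as.integer(seed)),
            class = "bg_fit_config")
}

# glmnet internally standardizes the gaussian response by its 1/n SD, which
# rescales the ridge (but not the lasso) part of the penalty. Passing
# lambda * (alpha + s*(1-alpha)) at mixing alpha / (alpha + s*(1-alpha))
# makes glmnet minimize the classical objective of enet_objective() exactly;
# the translation is linear in lambda so one call covers a whole grid.
glmnet_translate <- function(alpha, lambda, y) {
  s <- sd(y) * sqrt((length(y) - 1) / length(y))
  cc <- alpha + s * (1 - alpha)
  list(alpha = alpha / cc, lambda = lambda * cc, scale = cc)
}

# data-driven grid: lambda_max is the smallest penalty shrinking every
# coefficient to zero for the elastic net (alpha > 0) on centered data
auto_lambda_grid <- function(x, y, alpha, n_lambda = 100L, min_ratio = 1e-3) {
  yc <- y - mean(y)
  lambda_max <- max(abs(crossprod(x, yc))) / (nrow(x) * max(alpha, 1e-3))
  exp(seq(log(lambda_max), log(min_ratio * lambda_max), length.out = n_lambda))
}

#' Select lambda by the one-standard-error rule
#'
#' Returns the maximum lambda whose mean cross-validated error is within one
#' standard error of the minimum mean CV error — the most regularized model
#' statistically indistinguishable from the best one.
#'
#' @param cv_curve Data frame with columns `lambda`, `mean_err`, `se`.
#' @return The selected lambda (scalar).
#' @export
#' @examples
#' curve <- data.frame(lambda = c(1, 0.5, 0.1),
#'                     mean_err = c(2.0, 1.6, 1.5), se = c(0.5, 0.3, 0.3))
#' select_lambda_1se(curve)  # 0.5
select_lambda_1se <- function(cv_curve) {
  check_df_cols(cv_curve, c("lambda", "mean_err", "se"), "cv_curve")
  ok <- is.finite(cv_curve$mean_err)
  if (!any(ok)) abort("cv_curve has no finite mean errors")
  cv <- cv_curve[ok, ]
  if (nrow(cv) < 2L) abort("cv_curve needs >= 2 lambda values")
  imin <- which.min(cv$mean_err)
  thr <- cv$mean_err[imin] + cv$se[imin]
  max(cv$lambda[cv$mean_err <= thr])
}

#' Fit the voxel-wise elastic-net brain age model
#'
#' Regresses chronological age on the masked voxel values with an elastic-net
#' penalty. The penalty strength is chosen by repeated cross-validation:
#' for each of `n_repeats` random fold partitions, `n_folds`-fold CV is run
#' over the lambda grid and a lambda selected by the configured rule (1-SE by
#' default); the per-repeat lambdas are averaged and the final model is refit
#' once on all subjects at the averaged lambda. Voxels are standardized
#' internally (constant voxels dropped, logged in the result); returned
#' coefficients and intercept are on the original GM-probability scale.
#'
#' The returned solution satisfies the elastic-net stationarity (KKT)
#' conditions on the standardized scale; the maximal violation is stored in
#' the model (`kkt_violation`) and checked against 1e-5.
#'
#' @param design A `bg_design` from [vectorize()] (or any list with a
#'   numeric `values` matrix plus `voxel_index`).
#' @param ages Numeric outcome vector (years), one per design row; defaults
#'   to `design$age`.
#' @param config A [fit_config()].
#' @return An object of class `bg_age_model`.
#' @export
fit_age_model <- function(design, ages = design$age, config = fit_config()) {
  stopifnot(inherits(config, "bg_fit_config"))
  x <- design$values
  n <- nrow(x)
  if (length(ages) != n) abort("ages must have one value per design row")
  if (any(!is.finite(ages))) abort("ages must be finite")
  if (var(ages) == 0) abort("ages are constant: age model is unidentifiable")
  if (n < 2L * config$n_folds) {
    abort(sprintf(
      "n_subjects (%d) < 2 * n_folds (%d); use n_folds <= %d",
      n, config$n_folds, max(2L, n %/% 2L)))
  }

  # standardize features; drop constant voxels
  mu <- colMeans(x)
  sdv <- sqrt(colSums(sweep(x, 2, mu)^2) / (n - 1))
  keep <- sdv > 1e-10
  n_dropped <- sum(!keep)
  if (config$standardize) {
    xs <- sweep(sweep(x[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], "/")
  } else {
    xs <- x[, keep, drop = FALSE]
  }
  if (ncol(xs) == 0L) abort("all voxels are constant")
  # glmnet requires >= 2 columns; pad single-feature designs with a zero
  # column whose coefficient is discarded afterwards
  padded <- ncol(xs) == 1L
  if (padded) xs <- cbind(xs, 0)

  grid <- if (is.numeric(config$lambda_grid)) config$lambda_grid else
    auto_lambda_grid(xs, ages, config$alpha)
  tr <- glmnet_translate(config$alpha, grid, ages)

  set.seed(config$seed)
  lambda_sel <- numeric(config$n_repeats)
  curves <- vector("list", config$n_repeats)
  for (r in seq_len(config$n_repeats)) {
    foldid <- sample(rep_len(seq_len(config$n_folds), n))
    cv <- glmnet::cv.glmnet(xs, ages, alpha = tr$alpha, lambda = tr$lambda,
                            foldid = foldid, standardize = FALSE,
                            thresh = 1e-10)
    curve <- tibble::tibble(repeat_id = r, lambda = cv$lambda / tr$scale,
                            mean_err = cv$cvm, se = cv$cvsd)
    curves[[r]] <- curve
    lambda_sel[r] <- if (config$selection_rule == "1se") {
      select_lambda_1se(curve)
    } else {
      curve$lambda[which.min(curve$mean_err)]
    }
  }
  lambda_bar <- if (config$lambda_average == "arithmetic") {
    mean(lambda_sel)
  } else {
    exp(mean(log(lambda_sel)))
  }

  # refit on all data at the averaged lambda (warm-started along the path so
  # the solution at lambda_bar is exact, not interpolated)
  path <- sort(unique(c(grid[grid > lambda_bar], lambda_bar * 2^(4:1),
                        lambda_bar)), decreasing = TRUE)
  tr_refit <- glmnet_translate(config$alpha, path, ages)
  fit <- glmnet::glmnet(xs, ages, alpha = tr_refit$alpha,
                        lambda = tr_refit$lambda,
                        standardize = FALSE, thresh = 1e-16, maxit = 10^6)
  # lambda_bar maps to the last path value, so the lookup is exact
  beta_std <- as.numeric(coef(fit, s = min(tr_refit$lambda)))
  a0 <- beta_std[1]
  beta_std <- beta_std[-1]
  if (padded) {
    beta_std <- beta_std[1]
    xs <- xs[, 1, drop = FALSE]
  }
  kkt <- enet_kkt_violation(xs, ages, beta_std, a0, config$alpha, lambda_bar)

  # back-transform to the original feature scale
  weights <- numeric(ncol(x))
  if (config$standardize) {
    weights[keep] <- beta_std / sdv[keep]
    intercept <- a0 - sum(beta_std * mu[keep] / sdv[keep])
  } else {
    weights[keep] <- beta_std
    intercept <- a0
  }

  structure(
    list(weights = weights, intercept = intercept,
         lambda_selected = lambda_bar, lambda_per_repeat = lambda_sel,
         cv_curve = dplyr::bind_rows(curves), alpha = config$alpha,
         lambda_grid = grid, selection_rule = config$selection_rule,
         feature_standardization = list(mean = mu, sd = sdv, kept = keep,
                                        n_dropped = n_dropped,
                                        standardized = config$standardize),
         voxel_index = design$voxel_index, grid_shape = design$grid,
         linearization = "column-major",
         n_train = n, kkt_violation = kkt, seed = config$seed),
    class = "bg_age_model"
  )
}

# max violation of the elastic-net stationarity conditions at (beta, a0)
# on the scale the model was fit on; objective is
# (1/2n)||y - a0 - X b||^2 + lambda * (alpha ||b||_1 + (1-alpha)/2 ||b||_2^2)
enet_kkt_violation <- function(x, y, beta, a0, alpha, lambda) {
  r <- y - a0 - drop(x %*% beta)
  g <- drop(crossprod(x, r)) / nrow(x) - lambda * (1 - alpha) * beta
  nz <- beta != 0
  v_nz <- if (any(nz)) max(abs(g[nz] - lambda * alpha * sign(beta[nz]))) else 0
  v_z <- if (any(!nz)) max(pmax(abs(g[!nz]) - lambda * alpha, 0)) else 0
  max(v_nz, v_z, abs(mean(r)))
}

#' Elastic-net objective value
#'
#' `(1/(2n)) * RSS + lambda * (alpha * ||beta||_1 + (1-alpha)/2 * ||beta||_2^2)`
#' — the penalized least-squares criterion the age model minimizes (intercept
#' unpenalized).
#'
#' @param x Feature matrix. @param y Outcome. @param beta Coefficients.
#' @param a0 Intercept. @param alpha Mixing parameter. @param lambda Penalty.
#' @return Scalar objective value.
#' @export
enet_objective <- function(x, y, beta, a0, alpha, lambda) {
  r <- y - a0 - drop(x %*% beta)
  sum(r^2) / (2 * nrow(x)) +
    lambda * (alpha * sum(abs(beta)) + (1 - alpha) / 2 * sum(beta^2))
}

#' Elastic-net solution at a fixed penalty
#'
#' Low-level fit of the penalized criterion in [enet_objective()] at a single
#' `(alpha, lambda)` with no internal standardization — the building block
#' the cross-validated age model uses, exposed for diagnostics and solver
#' validation.
#'
#' @inheritParams enet_objective
#' @return List with `beta` and `a0`.
#' @export
enet_fixed <- function(x, y, alpha, lambda) {
  padded <- ncol(x) == 1L
  if (padded) x <- cbind(x, 0)
  grid <- sort(unique(c(auto_lambda_grid(x, y, alpha), lambda * 2^(4:1),
                        lambda)), decreasing = TRUE)
  grid <- grid[grid >= lambda]
  tr <- glmnet_translate(alpha, grid, y)
  fit <- glmnet::glmnet(x, y, alpha = tr$alpha, lambda = tr$lambda,
                        standardize = FALSE, thresh = 1e-14,
                        maxit = 10^6)
  cf <- as.numeric(coef(fit, s = min(tr$lambda)))  # exact: last path value
  beta <- cf[-1]
  if (padded) beta <- beta[1]
  list(beta = beta, a0 = cf[1])
}

#' Predict raw brain age for a design matrix
#'
#' `prediction = intercept + sum_k weight_k * value_k`; deterministic, no
#' reindexing — the design's voxel columns must be exactly the model's.
#'
#' @param model A `bg_age_model`.
#' @param design A `bg_design` whose `voxel_index` matches the model's.
#' @return Numeric vector of raw (uncorrected) predicted ages.
#' @export
predict_age <- function(model, design) {
  stopifnot(inherits(model, "bg_age_model"))
  if (!identical(as.integer(design$voxel_index),
                 as.integer(model$voxel_index))) {
    abort("design voxel_index does not match the model's mask (no silent reindexing)")
  }
  drop(design$values %*% model$weights) + model$intercept
}

#' @export
print.bg_age_model <- function(x, ...) {
  cat(sprintf(
    "<bg_age_model> %d voxels (%d non-zero), alpha %g, lambda %.5g (%s rule)\n",
    length(x$weights), sum(x$weights != 0), x$alpha, x$lambda_selected,
    x$selection_rule))
  cat(sprintf("  trained on n = %d; KKT violation %.2e\n",
              x$n_train, x$kkt_violation))
  invisible(x)
}

#' @export
#' @importFrom generics tidy
tidy.bg_age_model <- function(x, ...) {
  nz <- which(x$weights != 0)
  tibble::tibble(voxel_index = x$voxel_index[nz], weight = x$weights[nz])
}

#' @export
#' @importFrom generics glance
glance.bg_age_model <- function(x, ...) {
  tibble::tibble(n_train = x$n_train, n_voxels = length(x$weights),
                 n_nonzero = sum(x$weights != 0), alpha = x$alpha,
                 lambda_selected = x$lambda_selected,
                 kkt_violation = x$kkt_violation)
}
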