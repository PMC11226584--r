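fake_design <- function(x, age = NULL) {
  structure(list(values = x, subject_id = sprintf("S%03d", seq_len(nrow(x))),
                 age = age, voxel_index = seq_len(ncol(x)),
                 grid = c(ncol(x), 1L, 1L)),
            class = "bg_design")
}

test_that("the 1-SE rule returns the documented lambda on enumerable curves", {
  # hand-evaluated: threshold = 1.5 + 0.3 = 1.8 -> eligible {0.5, 0.1} -> 0.5
  curve <- data.frame(lambda = c(1, 0.5, 0.1),
                      mean_err = c(2.0, 1.6, 1.5), se = c(0.5, 0.3, 0.3))
  expect_equal(select_lambda_1se(curve), 0.5)
  # zero SE with error strictly increasing in lambda: the minimizer itself
  curve0 <- data.frame(lambda = c(1, 0.5, 0.1),
                       mean_err = c(3, 2, 1), se = c(0, 0, 0))
  expect_equal(select_lambda_1se(curve0), 0.1)
  # single eligible lambda
  curve1 <- data.frame(lambda = c(1, 0.1), mean_err = c(9, 1), se = c(1, 1))
  expect_equal(select_lambda_1se(curve1), 0.1)
  # exhaustive cross-check against direct enumeration on random curves
  set.seed(4)
  for (i in 1:20) {
    cv <- data.frame(lambda = sort(runif(8), decreasing = TRUE),
                     mean_err = runif(8, 1, 3), se = runif(8, 0, 0.5))
    imin <- which.min(cv$mean_err)
    want <- max(cv$lambda[cv$mean_err <= cv$mean_err[imin] + cv$se[imin]])
    expect_equal(select_lambda_1se(cv), want)
  }
  expect_error(select_lambda_1se(data.frame(lambda = 1:2,
                                            mean_err = c(NaN, NaN),
                                            se = c(1, 1))), "finite")
})

test_that("a perfectly informative feature is recovered at weak penalty", {
  set.seed(1)
  age <- runif(60, 55, 90)
  x <- cbind(age, matrix(0, 60, 5))
  cfg <- fit_config(n_folds = 5, n_repeats = 2, seed = 2,
                    lambda_grid = exp(seq(log(1), log(1e-4), length.out = 60)))
  model <- fit_age_model(fake_design(x), age, cfg)
  pred <- predict_age(model, fake_design(x))
  expect_lt(mean(abs(pred - age)), 0.1)
})

test_that("full shrinkage collapses predictions to the training mean age", {
  set.seed(2)
  x <- matrix(rnorm(40 * 8), 40, 8)
  age <- runif(40, 60, 90)
  sol <- enet_fixed(scale(x), age, alpha = 0.5, lambda = 1e4)
  expect_true(all(sol$beta == 0))
  expect_equal(sol$a0, mean(age), tolerance = 1e-8)
})

test_that("solver solutions match an independent coordinate-descent minimizer", {
  set.seed(7)
  for (i in 1:4) {
    n <- sample(25:50, 1)
    p <- sample(5:20, 1)
    x <- scale(matrix(rnorm(n * p), n, p))
    y <- rnorm(n, 75, 6)
    lambda <- runif(1, 0.05, 1)
    got <- enet_fixed(x, y, alpha = 0.5, lambda = lambda)
    want <- oracle_enet(x, y, alpha = 0.5, lambda = lambda)
    obj_got <- enet_objective(x, y, got$beta, got$a0, 0.5, lambda)
    obj_want <- enet_objective(x, y, want$beta, want$a0, 0.5, lambda)
    expect_equal(obj_got, obj_want, tolerance = 1e-6)
    # solution beats the null model
    expect_lte(obj_got, enet_objective(x, y, numeric(p), mean(y), 0.5, lambda))
  }
})

test_that("fitted age models are deterministic and internally consistent", {
  set.seed(11)
  x <- matrix(rnorm(60 * 30), 60, 30)
  beta_true <- c(rep(2, 3), rep(0, 27))
  age <- 75 + drop(x %*% beta_true) + rnorm(60)
  cfg <- fit_config(n_folds = 5, n_repeats = 3, seed = 5)
  m1 <- fit_age_model(fake_design(x), age, cfg)
  m2 <- fit_age_model(fake_design(x), age, cfg)
  expect_identical(m1$lambda_per_repeat, m2$lambda_per_repeat)
  expect_identical(m1$weights, m2$weights)
  # averaged lambda is the arithmetic mean of the per-repeat selections
  expect_equal(m1$lambda_selected, mean(m1$lambda_per_repeat))
  # KKT stationarity at the returned solution (standardized scale)
  expect_lt(m1$kkt_violation, 1e-5)
  # predictions reproduce the refit in-sample fitted values
  pred <- predict_age(m1, fake_design(x))
  mu <- m1$feature_standardization$mean
  sdv <- m1$feature_standardization$sd
  keep <- m1$feature_standardization$kept
  xs <- sweep(sweep(x[, keep], 2, mu[keep]), 2, sdv[keep], "/")
  beta_std <- (m1$weights * sdv)[keep]
  a0 <- m1$intercept + sum(m1$weights[keep] * mu[keep])
  expect_equal(pred, drop(xs %*% beta_std) + a0, tolerance = 1e-8)
})

test_that("age-model preconditions are enforced", {
  x <- matrix(rnorm(15 * 4), 15, 4)
  expect_error(fit_age_model(fake_design(x), rep(70, 15),
                             fit_config(n_folds = 5)), "constant")
  expect_error(fit_age_model(fake_design(x), runif(15, 60, 80),
                             fit_config(n_folds = 10)), "n_folds")
  m <- fit_age_model(fake_design(cbind(x, x[, 1])), runif(15, 60, 80),
                     fit_config(n_folds = 3, n_repeats = 1, seed = 1))
  des_wrong <- fake_design(x[, 1:4])
  des_wrong$voxel_index <- c(2L, 3L, 4L, 6L)
  expect_error(predict_age(m, des_wrong), "voxel_index")
})

test_that("prediction is the stated affine map", {
  m <- structure(list(weights = c(1, 0, 0), intercept = 50,
                      voxel_index = 1:3), class = "bg_age_model")
  d <- fake_design(matrix(c(20, 5, 7), 1, 3))
  expect_equal(predict_age(m, d), 70)
  m0 <- structure(list(weights = c(0, 0, 0), intercept = 62.5,
                       voxel_index = 1:3), class = "bg_age_model")
  expect_equal(predict_age(m0, fake_design(matrix(rnorm(9), 3, 3))),
               rep(62.5, 3))
})

test_that("accuracy metrics follow their definitions and MAE <= RMSE always", {
  m <- evaluate_predictions(c(71, 69), c(70, 70))
  expect_equal(m$mae, 1)
  expect_equal(m$rmse, 1)
  m2 <- evaluate_predictions(c(70, 70, 73), c(70, 70, 70))
  expect_equal(m2$mae, 1)
  expect_equal(m2$rmse, sqrt(3))
  # degenerate variance flags the correlation instead of inventing one
  m3 <- evaluate_predictions(c(70, 70), c(68, 72))
  expect_false(m3$pearson_defined)
  expect_true(is.na(m3$pearson_r))
  set.seed(3)
  for (i in 1:25) {
    p <- rnorm(20, 75, 5)
    a <- rnorm(20, 75, 5)
    mm <- evaluate_predictions(p, a)
    expect_lte(mm$mae, mm$rmse)
  }
})
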