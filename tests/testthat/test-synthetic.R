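test_that("template volumes are bounded, reproducible, and brain-like", {
  tpl <- make_template(c(32, 32, 32), seed = 1)
  expect_gte(min(tpl), 0)
  expect_lte(max(tpl), 1)
  expect_gt(mean(tpl > 0.1), 0.1)
  expect_identical(tpl, make_template(c(32, 32, 32), seed = 1))
  expect_false(identical(as.numeric(tpl),
                         as.numeric(make_template(c(32, 32, 32), seed = 2))))

  tpl8 <- make_template(c(8, 8, 8), seed = 7)
  expect_equal(attr(tpl8, "brain_frac"), mean(tpl8 > 0.1))
  # brain region occupies a plausible fraction of the grid
  expect_gt(attr(tpl, "brain_frac"), 0.3)
  expect_lt(attr(tpl, "brain_frac"), 0.7)
  expect_error(make_template(c(4, 16, 16)), ">= 8")
})

test_that("signal maps are negative spheres with the requested component count", {
  tpl <- make_template(c(24, 24, 24), seed = 5)
  expect_equal(make_signal_map(tpl, 3, effect_scale = 0, seed = 2),
               array(0, c(24, 24, 24)))
  w <- make_signal_map(tpl, 3, effect_scale = 0.01, seed = 2)
  expect_true(all(w <= 0))
  expect_equal(oracle_components(w != 0), 3L)
  expect_equal(max(abs(w)), 0.01, tolerance = 1e-12)
  # unplaceable request errors with the limit in the message
  expect_error(make_signal_map(tpl, 500, effect_scale = 0.01, seed = 2),
               "non-overlapping")
})

test_that("simulated volumes follow the generating formula voxel-wise", {
  tpl <- make_template(c(12, 12, 12), seed = 3)
  w <- make_signal_map(tpl, 2, effect_scale = 0.01, seed = 3)
  # noiseless subject at the reference age reproduces the template
  coh <- simulate_gm_cohort(tpl, w, n = 2, age_range = c(74.9999, 75.0001),
                            noise_sd = 0, age_ref = 75, seed = 1)
  expect_equal(as.vector(get_volume(coh$volumes, 1)), as.vector(tpl),
               tolerance = 1e-5)
  # noiseless subject 10 years past reference: direct clipped formula
  coh10 <- simulate_gm_cohort(tpl, w, n = 2, age_range = c(84.9999, 85.0001),
                              noise_sd = 0, age_ref = 75, seed = 1)
  expected <- pmin(pmax(as.vector(tpl) + 10 * as.vector(w), 0), 1)
  expect_equal(as.vector(get_volume(coh10$volumes, 1)), expected,
               tolerance = 1e-4)
  expect_error(simulate_gm_cohort(tpl, w, 5, c(60, 80), noise_sd = -1),
               ">= 0")
})

test_that("cohort ages respect the configured range and volumes stay in [0,1]", {
  tpl <- make_template(c(10, 10, 10), seed = 2)
  w <- make_signal_map(tpl, 1, 0.005, seed = 2)
  coh <- simulate_gm_cohort(tpl, w, n = 300, age_range = c(67, 90),
                            noise_sd = 0.05, smooth_fwhm = 2, seed = 4)
  expect_gte(min(coh$age), 67)
  expect_lte(max(coh$age), 90)
  expect_gte(min(coh$volumes$data), 0)
  expect_lte(max(coh$volumes$data), 1)
  expect_false(anyNA(coh$volumes$data))
  expect_false(anyDuplicated(coh$volumes$subject_id) > 0)
})

test_that("phenotype generator enforces site-specific administrative censoring", {
  cfg <- sim_config(n_target = 600, seed = 11)
  set.seed(42)
  bag <- rnorm(600, 0, 3)
  ph <- simulate_phenotypes(bag, cfg, seed = 11)
  expect_equal(nrow(ph), 600)
  # no observed time extends past the site censoring horizon
  bdr <- as.Date(cfg$baseline_date_range)
  for (s in unique(ph$site)) {
    horizon <- as.numeric(as.Date(cfg$censor_date_by_site[s]) - bdr[1]) / 365.25
    expect_lte(max(ph$time[ph$site == s]), horizon)
  }
  # censored records carry no cause; events carry one
  expect_true(all(is.na(ph$cause[ph$event == 0])))
  expect_true(all(!is.na(ph$cause[ph$event == 1])))
  # Jackson horizon is two years shorter than the other sites
  jk <- max(ph$time[ph$site == "Jackson" & ph$event == 0])
  other <- max(ph$time[ph$site != "Jackson" & ph$event == 0])
  expect_lt(jk, other - 1)
  expect_error(simulate_phenotypes(bag[1:10], cfg), "n_target")
})

test_that("cognitive status mix roughly matches the configured class imbalance", {
  cfg <- sim_config(n_target = 4000, seed = 8)
  set.seed(1)
  ph <- simulate_phenotypes(rnorm(4000, 0, 3), cfg, seed = 8)
  mix <- prop.table(table(ph$cognitive_status))
  expect_equal(unname(mix[["CN"]]), 0.63, tolerance = 0.12)
  expect_equal(unname(mix[["MCI"]]), 0.32, tolerance = 0.25)
  expect_lt(mix[["DEM"]], 0.12)
})

test_that("protein panel QC filtering reproduces the aptamer-panel counts", {
  cfg <- sim_config(n_target = 20, n_proteins = 5284, n_true_proteins = 33,
                    seed = 6)
  set.seed(3)
  prot <- simulate_proteins(rnorm(20, 0, 3), covariates = NULL, cfg, seed = 6)
  expect_equal(ncol(prot$values), 5284)
  expect_equal(sum(prot$qc_pass), 4877)
  filtered <- suppressMessages(qc_filter(prot))
  expect_equal(ncol(filtered$values), 4877)
  expect_equal(ncol(filtered$values), sum(prot$qc_pass))
})

test_that("null protein panels are uncorrelated with BAG; planted effects are recovered", {
  cfg0 <- sim_config(n_target = 400, n_proteins = 200, n_true_proteins = 1,
                     protein_effect_sd = 0.15, seed = 21)
  set.seed(5)
  bag <- rnorm(400, 0, 3)
  prot <- simulate_proteins(bag, covariates = NULL, cfg0, seed = 21)
  null_cols <- prot$values[, prot$true_gamma == 0]
  r <- abs(cor(bag, null_cols))
  expect_gte(mean(r < 4 / sqrt(400)), 0.95)

  # single strong analyte: per-analyte OLS recovers the planted slope
  set.seed(9)
  bag2 <- rnorm(1000, 0, 3)
  gamma <- 1
  xj <- gamma * bag2 + rnorm(1000, 0, 0.1)
  expect_equal(unname(coef(lm(xj ~ bag2))[2]), 1, tolerance = 0.03)
})

test_that("full cohort simulation is deterministic given config and seed", {
  cfg <- sim_config(grid_shape = c(10, 10, 10), n_train = 12, n_target = 15,
                    n_signal_clusters = 2, n_proteins = 30,
                    n_true_proteins = 3, seed = 77)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$train$data, b$train$data)
  expect_identical(a$pheno, b$pheno)
  expect_identical(a$proteins$values, b$proteins$values)
  # ground-truth BAG centered in the target cohort by construction
  expect_equal(mean(a$ground_truth$true_bag_target), 0, tolerance = 1e-12)
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(effect_scale = 0), "effect_scale")
  expect_error(sim_config(n_proteins = 10, n_true_proteins = 11),
               "n_true_proteins")
  expect_warning(sim_config(train_age_range = c(70, 80),
                            target_age_range = c(67, 90)), "extrapolate")
})
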