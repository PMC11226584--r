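test_that("tertile assignment partitions values with the printed boundary convention", {
  t9 <- assign_tertiles(1:9)
  expect_equal(t9$label, rep(1:3, each = 3))
  # quantile-threshold oracle on random draws
  set.seed(5)
  x <- rnorm(100)
  tt <- assign_tertiles(x)
  q <- quantile(x, c(1, 2) / 3)
  oracle <- ifelse(x <= q[1], 1L, ifelse(x >= q[2], 3L, 2L))
  expect_identical(tt$label, oracle)
  expect_equal(unname(tt$boundaries), unname(q))
  # every subject gets exactly one label; sizes near n/3 (interpolated
  # boundaries: within 1 of n/3 for untied continuous data)
  expect_equal(sort(unique(tt$label)), 1:3)
  x99 <- rnorm(99)
  expect_true(all(abs(tabulate(assign_tertiles(x99)$label) - 33) <= 1))
  # closed-outer convention at published-style cut-points
  v <- c(-3, -1, -0.75, -0.75, 0, 1.75, 1.75, 2.5, 3)
  tv <- assign_tertiles(v)
  expect_equal(unname(tv$boundaries), c(-0.75, 1.75))
  expect_equal(tv$label[v == -0.75], c(1L, 1L))   # boundary value -> t1
  expect_equal(tv$label[v == 1.75], c(3L, 3L))    # boundary value -> t3
  expect_error(assign_tertiles(rep(1, 10)), "collide")
})

sim_surv <- function(n, hr_low, hr_mid, seed) {
  cfg <- sim_config(n_target = n, hr_lowest = hr_low, hr_middle = hr_mid,
                    seed = seed)
  set.seed(seed)
  bag <- rnorm(n, 0, 3)
  ph <- simulate_phenotypes(bag, cfg, seed = seed)
  add_tertiles(ph, col = "true_bag")
}

test_that("Cox tertile estimates are centred at the null when hazards are equal", {
  reps <- 40
  lhr <- matrix(NA_real_, reps, 2)
  for (r in seq_len(reps)) {
    d <- sim_surv(400, 1, 1, seed = 1000 + r)
    fit <- fit_cox(d, covariates = c("age", "sex"))
    lhr[r, ] <- log(fit$hazard_ratio[match(c("lowest", "middle"),
                                           fit$tertile)])
  }
  for (j in 1:2) {
    mc_se <- sd(lhr[, j]) / sqrt(reps)
    expect_lt(abs(mean(lhr[, j])), 3 * mc_se)
  }
})

test_that("Cox output mirrors the tertile table layout with the highest tertile as reference", {
  d <- sim_surv(800, 0.4, 0.6, seed = 7)
  fit <- fit_cox(d, covariates = c("age", "sex"))
  expect_equal(fit$tertile, c("highest", "middle", "lowest"))
  expect_equal(fit$hazard_ratio[1], 1)
  expect_true(all(fit$ci_low[-1] <= fit$hazard_ratio[-1]))
  expect_true(all(fit$ci_high[-1] >= fit$hazard_ratio[-1]))
  expect_equal(attr(fit, "n") , 800L)
  expect_equal(attr(fit, "n_events"), sum(d$event))
})

test_that("re-referencing tertiles yields reciprocal hazard ratios", {
  d <- sim_surv(600, 0.5, 0.7, seed = 12)
  hi <- fit_cox(d, covariates = c("age", "sex"), reference = "highest")
  lo <- fit_cox(d, covariates = c("age", "sex"), reference = "lowest")
  hr_low_vs_high <- hi$hazard_ratio[hi$tertile == "lowest"]
  hr_high_vs_low <- lo$hazard_ratio[lo$tertile == "highest"]
  expect_equal(hr_low_vs_high, 1 / hr_high_vs_low, tolerance = 1e-8)
})

test_that("with no competing events the cause-specific model reduces to fit_cox", {
  d <- sim_surv(400, 0.5, 0.7, seed = 3)
  d$cause[d$event == 1] <- "nonCNS"
  plain <- fit_cox(d, covariates = c("age", "sex"))
  expect_message(
    cs <- fit_competing_risk_cox(d, covariates = c("age", "sex"),
                                 event_cause = "nonCNS",
                                 competing_cause = "CNS"),
    "reduces")
  expect_equal(tibble::as_tibble(cs), tibble::as_tibble(plain))
  expect_equal(attr(cs, "n_competing"), 0L)
})

test_that("competing-risk bookkeeping matches direct cause tallies", {
  d <- sim_surv(500, 0.5, 0.7, seed = 9)
  cs <- fit_competing_risk_cox(d, covariates = c("age", "sex"),
                               event_cause = "nonCNS",
                               competing_cause = "CNS")
  expect_equal(attr(cs, "n_competing"),
               sum(d$event == 1 & d$cause == "CNS", na.rm = TRUE))
  expect_equal(attr(cs, "n_events"),
               sum(d$event == 1 & d$cause == "nonCNS", na.rm = TRUE))
})

test_that("unadjusted LS means equal raw group means exactly", {
  set.seed(2)
  d <- tibble::tibble(bag = rnorm(60), grp = rep(c("a", "b", "c"), 20))
  ls <- lsmeans_by_group(d, outcome = "bag", group = "grp")
  raw <- tapply(d$bag, d$grp, mean)
  expect_equal(ls$means$lsmean, as.numeric(raw[ls$means$group]),
               tolerance = 1e-12)
  # pairwise differences equal differences of the two LS means
  for (i in seq_len(nrow(ls$contrasts))) {
    parts <- strsplit(ls$contrasts$contrast[i], " - ")[[1]]
    expect_equal(ls$contrasts$difference[i],
                 ls$means$lsmean[ls$means$group == parts[1]] -
                   ls$means$lsmean[ls$means$group == parts[2]],
                 tolerance = 1e-10)
  }
})

test_that("covariate-adjusted LS means match a normal-equations oracle", {
  set.seed(8)
  d <- tibble::tibble(
    grp = rep(c("CN", "MCI", "DEM"), each = 4),
    x = rnorm(12),
    bag = rnorm(12) + c(rep(0, 4), rep(1, 4), rep(3, 4))
  )
  ls <- lsmeans_by_group(d, outcome = "bag", group = "grp",
                         covariates = "x")
  orc <- oracle_lsmeans(d, "bag", "grp", "x")
  expect_equal(setNames(ls$means$lsmean, ls$means$group)[names(orc$means)],
               orc$means, tolerance = 1e-10)
  for (i in seq_len(nrow(ls$contrasts))) {
    parts <- strsplit(ls$contrasts$contrast[i], " - ")[[1]]
    want <- orc$contrast(parts[1], parts[2])
    expect_equal(ls$contrasts$difference[i], unname(want["est"]),
                 tolerance = 1e-10)
    expect_equal(ls$contrasts$stderr[i], unname(want["se"]),
                 tolerance = 1e-10)
  }
  expect_error(lsmeans_by_group(d[1:5, ], outcome = "bag", group = "grp"),
               ">= 2")
})

test_that("phenotype regressions reject the null at the nominal rate", {
  reps <- 1000
  n <- 150
  hits <- logical(reps)
  for (r in seq_len(reps)) {
    set.seed(30000 + r)
    d <- data.frame(
      age = runif(n, 67, 90), sex = factor(sample(c("f", "m"), n, TRUE)),
      center_race = factor(sample(letters[1:5], n, TRUE)),
      pheno = rnorm(n), bag = rnorm(n, 0, 3)
    )
    res <- phenotype_assoc(d, phenotypes = "pheno")
    hits[r] <- res$p_value < 0.05
  }
  expect_equal(mean(hits), 0.05, tolerance = 0.02 / 0.05)  # 5% +/- 2 points
})

test_that("phenotype regressions recover a planted group shift", {
  set.seed(4)
  n <- 2000
  diabetes <- rbinom(n, 1, 0.3)
  d <- tibble::tibble(
    age = runif(n, 67, 90), sex = factor(sample(c("f", "m"), n, TRUE)),
    center_race = factor(sample(letters[1:5], n, TRUE)),
    diabetes = diabetes,
    bag = 0.9 * diabetes + rnorm(n, 0, 3)
  )
  res <- phenotype_assoc(d, phenotypes = "diabetes")
  expect_gte(res$estimate, 0.7)
  expect_lte(res$estimate, 1.1)
  expect_true(res$ci_low <= res$estimate & res$estimate <= res$ci_high)
  d$const <- 1
  expect_error(phenotype_assoc(d, phenotypes = "const"), "constant")
})
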