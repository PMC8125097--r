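test_that("constant values give a degenerate median fit with zero loss", {
  ages <- seq(20, 80, length.out = 25)
  expect_error(fit_median_curve(rep(3.5, 25), ages), "spread")
  # the raw solver on constant data: intercept log(c), zero age terms
  fit <- fit_pinball(cbind(1, (ages / 100)^3, (ages / 100)^4), log(rep(3.5, 25)))
  expect_equal(unname(fit$coefficients[1]), log(3.5), tolerance = 1e-8)
  expect_equal(unname(fit$coefficients[2:3]), c(0, 0), tolerance = 1e-6)
  expect_lt(fit$loss, 1e-8)
})

test_that("median fit matches the combinatorial interpolation oracle on tiny instances", {
  set.seed(21)
  for (rep in 1:12) {
    n <- sample(3:6, 1)
    ages <- runif(n, 18, 90)
    y <- rnorm(n, 3, 0.5)
    # two free parameters (intercept + cubic term)
    X <- cbind(1, (ages / 100)^3)
    mine <- fit_pinball(X, y)
    oracle <- oracle_median_fit(X, y)
    expect_lte(mine$loss, oracle$loss + 1e-5)
    expect_gte(mine$loss, oracle$loss - 1e-5)
  }
  # three free parameters on 4-6 points
  for (rep in 1:8) {
    n <- sample(4:6, 1)
    ages <- runif(n, 18, 90)
    y <- rnorm(n, 3, 0.5)
    X <- cbind(1, (ages / 100)^3, (ages / 100)^4)
    mine <- fit_pinball(X, y)
    oracle <- oracle_median_fit(X, y)
    expect_lte(mine$loss, oracle$loss + 1e-5)
    expect_gte(mine$loss, oracle$loss - 1e-5)
  }
})

test_that("at tau = 0.5 about half the residuals are non-positive", {
  set.seed(5)
  n <- 501
  ages <- runif(n, 18, 83)
  v <- exp(3 + 0.5 * (ages / 100)^3 + rnorm(n, 0, 0.2))
  m <- fit_median_curve(v, ages)
  resid <- log(v) - predict_log_median(m, ages)
  expect_lt(abs(mean(resid <= 0) - 0.5), 3 / n)
})

test_that("standardization round-trips and is unit-variance on its own fit", {
  set.seed(11)
  n <- 1000
  ages <- runif(n, 18, 83)
  v <- exp(3.7 + 0.8 * (ages / 100)^3 - 0.5 * (ages / 100)^4 +
             rnorm(n, 0, 0.1))
  m <- fit_median_curve(v, ages, index_name = "bmi")
  z <- standardize(m, v, ages)
  expect_equal(sd(z), 1, tolerance = 1e-6)
  back <- inverse_standardize(m, z, ages)
  expect_lt(max(abs(back - v) / v), 1e-9)
  # a value on the fitted median has z = 0
  expect_equal(standardize(m, exp(predict_log_median(m, 50)), 50), 0)
  expect_error(standardize(m, -1, 50), "positive")
})

test_that("log-scale noise rescaling scales residual_scale and preserves z-ranks", {
  set.seed(13)
  n <- 400
  ages <- runif(n, 18, 83)
  eps <- rnorm(n, 0, 0.1)
  base_log <- 3.7 + 0.8 * (ages / 100)^3 - 0.5 * (ages / 100)^4
  k <- 2.5
  m1 <- fit_median_curve(exp(base_log + eps), ages)
  m2 <- fit_median_curve(exp(base_log + k * eps), ages)
  expect_equal(m2$residual_scale / m1$residual_scale, k, tolerance = 0.05)
  stratum <- abs(ages - 50) < 5
  z1 <- standardize(m1, exp(base_log + eps)[stratum], ages[stratum])
  z2 <- standardize(m2, exp(base_log + k * eps)[stratum], ages[stratum])
  expect_equal(order(z1), order(z2))
})

test_that("within a single-age stratum, AUC on z equals AUC on raw values", {
  set.seed(17)
  n <- 300
  ages <- c(runif(n, 18, 83), rep(55, 100))
  v <- exp(3.5 + 0.6 * (ages / 100)^3 + rnorm(length(ages), 0, 0.15))
  m <- fit_median_curve(v, ages)
  slice <- ages == 55
  labels <- rbinom(sum(slice), 1, plogis(scale(log(v[slice]))))
  if (length(unique(labels)) == 2L) {
    z <- standardize(m, v[slice], ages[slice])
    expect_equal(roc_curve(z, labels)$auc, roc_curve(v[slice], labels)$auc,
                 tolerance = 1e-12)
  }
})

test_that("threshold curves back-transform z* and respond monotonically to it", {
  set.seed(19)
  n <- 500
  ages <- runif(n, 18, 83)
  v <- exp(3.7 + 0.8 * (ages / 100)^3 - 0.5 * (ages / 100)^4 +
             rnorm(n, 0, 0.1))
  m <- fit_median_curve(v, ages, index_name = "bmi")
  grid <- 18:83
  tc0 <- threshold_curve(m, 0, grid, cohort_ages = ages)
  expect_equal(tc0$curve$cutoff, exp(predict_log_median(m, grid)))
  tc1 <- threshold_curve(m, 0.5, grid, cohort_ages = ages)
  tc2 <- threshold_curve(m, 1.0, grid, cohort_ages = ages)
  expect_true(all(tc2$curve$cutoff > tc1$curve$cutoff))
  expect_true(all(tc1$curve$cutoff > tc0$curve$cutoff))
  expect_true(all(tc2$curve$cutoff > 0))
  expect_gt(tc2$mean_cutoff, tc1$mean_cutoff)
  expect_error(threshold_curve(m, 0.5, numeric(0)), "empty")
})

test_that("the model serializes to JSON and restores losslessly", {
  set.seed(23)
  ages <- runif(120, 18, 83)
  v <- exp(3.2 + 0.4 * (ages / 100)^3 + rnorm(120, 0, 0.1))
  m <- fit_median_curve(v, ages, index_name = "wthr")
  path <- tempfile(fileext = ".json")
  age_reference_to_json(m, path)
  m2 <- age_reference_from_json(path)
  expect_equal(m2$coefficients, m$coefficients)
  expect_equal(m2$residual_scale, m$residual_scale)
  expect_equal(standardize(m2, v[1:5], ages[1:5]),
               standardize(m, v[1:5], ages[1:5]))
})

test_that("input screening: short series, non-positive values, out-of-range ages", {
  expect_error(fit_median_curve(exp(rnorm(5)), runif(5, 20, 60)), "10 subjects")
  expect_error(fit_median_curve(c(rep(2, 19), -1), runif(20, 20, 60)), "positive")
  expect_error(fit_median_curve(rep(2, 20) + runif(20), runif(20, 5, 17)),
               "ages")
})
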