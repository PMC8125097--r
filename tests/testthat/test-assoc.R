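test_that("pearson and partial correlation basics", {
  x <- rnorm(50)
  expect_equal(pearson_r(x, x)$r, 1)
  expect_error(pearson_r(x, rep(1, 50)), "variance")
  expect_error(pearson_r(x[1:3], x[1:3]), "at least 4")
})

test_that("partial correlation equals the OLS residual-vector oracle to 1e-10", {
  set.seed(73)
  for (i in 1:20) {
    n <- 60
    z <- rnorm(n)
    x <- 0.5 * z + rnorm(n)
    y <- -0.3 * z + 0.4 * x + rnorm(n)
    pp <- partial_pearson(x, y, z)
    rx <- resid(lm(x ~ z)); ry <- resid(lm(y ~ z))
    expect_equal(pp$r, cor(rx, ry), tolerance = 1e-10)
  }
})

test_that("partial correlation with a constant covariate reduces to plain Pearson", {
  set.seed(79)
  x <- rnorm(40); y <- rnorm(40)
  expect_equal(partial_pearson(x, y, rep(2, 40))$r, pearson_r(x, y)$r,
               tolerance = 1e-12)
})

test_that("partial correlation recovers a known population value", {
  set.seed(83)
  n <- 10000
  z <- rnorm(n)
  # construct (x, y) with partial correlation 0.3 given z
  x <- 0.6 * z + sqrt(1 - 0.36) * rnorm(n)
  e <- rnorm(n)
  y <- 0.6 * z + sqrt(1 - 0.36) * (0.3 * scale(resid(lm(x ~ z))) +
                                     sqrt(1 - 0.09) * scale(e))
  pp <- partial_pearson(x, as.numeric(y), z)
  expect_lte(abs(pp$r - 0.3), 0.03)
})

test_that("Fisher transformation and the correlated-correlation test", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  expect_error(fisher_z(1), "< 1")
  # equal correlations: z = 0, p = 1 whatever the competitors' correlation
  for (rab in c(-0.3, 0, 0.6)) {
    ct <- compare_correlated(0.4, 0.4, rab, 100)
    expect_equal(ct$z, 0); expect_equal(ct$p, 1)
  }
  # antisymmetry in the two competing correlations
  a <- compare_correlated(0.5, 0.3, 0.4, 200)
  b <- compare_correlated(0.3, 0.5, 0.4, 200)
  expect_equal(a$z, -b$z)
  expect_error(compare_correlated(0.5, 0.3, 0.4, 5), "n >= 10")
})

test_that("standardized beta: identity fit, affine invariance, CI width", {
  set.seed(89)
  x <- rnorm(200)
  sb <- suppressWarnings(standardized_beta(x, x))  # perfect fit: lm warns
  expect_equal(sb$beta_std, 1, tolerance = 1e-12)
  expect_equal(sb$r2, 1, tolerance = 1e-12)

  z <- rnorm(200)
  y <- 0.4 * x + 0.3 * z + rnorm(200)
  sb1 <- standardized_beta(y, x, z)
  sb2 <- standardized_beta(5 + 3 * y, -2 + 0.5 * x, z)
  expect_equal(sb1$beta_std, sb2$beta_std, tolerance = 1e-10)
  expect_error(standardized_beta(y, x, x), "collinear")

  # a weak association at the study's sample size: CI width ~0.1
  set.seed(97)
  n <- 1528
  age <- rnorm(n)
  pred <- rnorm(n)
  out <- 0.19 * pred + 0.2 * age + rnorm(n, 0, sqrt(1 - 0.19^2))
  sb3 <- standardized_beta(out, pred, age)
  expect_lte(abs(sb3$beta_std - 0.19), 0.05)
  expect_lte(abs(unname(sb3$ci_hi - sb3$ci_lo) - 0.09), 0.05)
})

test_that("Welch t and ANOVA/Bonferroni behave on null and degenerate input", {
  a <- c(1, 2, 3, 4)
  tt <- welch_t(a, a)
  expect_equal(tt$t, 0); expect_equal(tt$p, 1)
  expect_error(welch_t(a, 2), "n >= 2")

  set.seed(101)
  g <- list(a = rnorm(30, 5), b = rnorm(30, 5), c = rnorm(30, 5))
  ab <- anova_bonferroni(g)
  expect_true(ab$p > 0.001)
  expect_true(all(ab$pairwise$p_adj <= 1))
  expect_equal(nrow(ab$pairwise), 3L)
  # Bonferroni: adjusted p = min(1, 3 * raw p) for three pairs
  raw <- pairwise.t.test(unlist(g), rep(names(g), each = 30),
                         p.adjust.method = "none")$p.value
  expect_equal(sort(ab$pairwise$p_adj),
               sort(pmin(1, 3 * raw[!is.na(raw)])), tolerance = 1e-12)
  expect_error(anova_bonferroni(list(a = 1, b = rnorm(5))), "n >= 2")
})

test_that("two-sample t-test holds its nominal type-I error", {
  set.seed(103)
  reps <- 2000
  p <- replicate(reps, welch_t(rnorm(25), rnorm(25))$p)
  expect_lte(abs(mean(p < 0.05) - 0.05), 0.015)
})

test_that("outlier screen excludes exactly the planted extremes, single pass", {
  set.seed(107)
  x <- rnorm(1528)
  x <- x[abs(x - mean(x)) / sd(x) < 4]       # clean base
  vals <- c(x, 8, -9)                        # two planted extremes
  ids <- as.character(seq_along(vals))
  sc <- screen_outliers(vals, ids)
  expect_setequal(sc$excluded_ids, as.character(c(length(vals) - 1L, length(vals))))
  expect_equal(length(sc$retained), length(vals) - 2L)
  # nothing within 2 SD is ever excluded
  sc2 <- screen_outliers(rnorm(100) * 0.5)
  expect_length(sc2$excluded_ids, 0L)
  expect_warning(screen_outliers(rep(3, 10)), "zero standard deviation")
})

test_that("KS lognormality screen is calibrated and detects gross departures", {
  set.seed(109)
  ps <- replicate(50, lognormality_ks(rlnorm(1000, 3, 0.4))$p)
  expect_gte(mean(ps > 0.05), 0.90)
  # heavily bimodal data fail clearly
  bim <- c(rlnorm(500, 1, 0.05), rlnorm(500, 4, 0.05))
  kt <- lognormality_ks(bim)
  expect_lt(kt$p, 0.01)
  expect_gte(kt$D, 0); expect_lte(kt$D, 1)
  expect_error(lognormality_ks(c(-1, rlnorm(30))), "positive")
  expect_error(lognormality_ks(rlnorm(10)), "at least 20")
})
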