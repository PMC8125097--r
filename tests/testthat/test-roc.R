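test_that("ROC handles perfect separation and all-tied scores", {
  r <- roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$auc, 1.0)
  r2 <- roc_curve(rep(2, 10), rep(c(0, 1), 5))
  expect_equal(r2$auc, 0.5)
  expect_error(roc_curve(1:4, c(1, 1, 1, 1)), "positive and one negative")
  expect_error(roc_curve(c(1, Inf, 3), c(0, 1, 1)), "finite")
})

test_that("AUC equals the tie-corrected Mann-Whitney statistic to 1e-12", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(20:60, 1)
    scores <- sample(1:12, n, replace = TRUE) + rbinom(n, 1, 0.5) * 0.5
    labels <- rbinom(n, 1, 0.45)
    if (length(unique(labels)) < 2L) next
    r <- roc_curve(scores, labels)
    expect_equal(r$auc, oracle_auc(scores, labels), tolerance = 1e-13)
  }
})

test_that("AUC and DeLong variance agree with pROC on random data", {
  set.seed(37)
  for (i in 1:5) {
    n <- 150
    labels <- rbinom(n, 1, 0.5)
    scores <- rnorm(n, labels)
    r <- roc_curve(scores, labels)
    pr <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
    expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
    expect_equal(r$auc_var, pROC::var(pr), tolerance = 1e-12)
  }
})

test_that("DeLong variance is close to the jackknife estimate", {
  set.seed(41)
  labels <- rbinom(100, 1, 0.5)
  scores <- rnorm(100, 0.8 * labels)
  r <- roc_curve(scores, labels)
  jk <- oracle_jackknife_auc_var(scores, labels)
  expect_equal(r$auc_var, jk, tolerance = 0.10)
})

test_that("paired DeLong test: identical scores give delta 0 and p 1", {
  set.seed(43)
  labels <- rbinom(80, 1, 0.5)
  scores <- rnorm(80, labels)
  cmp <- delong_paired_test(scores, scores, labels)
  expect_equal(cmp$delta_auc, 0)
  expect_equal(cmp$p, 1)
  expect_error(delong_paired_test(scores[-1], scores, labels), "same subjects")
})

test_that("paired DeLong test agrees with pROC's on correlated scores", {
  set.seed(47)
  n <- 200
  labels <- rbinom(n, 1, 0.5)
  shared <- rnorm(n)
  a <- labels + shared + rnorm(n)
  b <- 0.8 * labels + shared + rnorm(n)
  cmp <- delong_paired_test(a, b, labels)
  pr <- pROC::roc.test(pROC::roc(labels, a, quiet = TRUE, direction = "<"),
                       pROC::roc(labels, b, quiet = TRUE, direction = "<"),
                       method = "delong", paired = TRUE)
  expect_equal(unname(cmp$z), unname(pr$statistic), tolerance = 1e-10)
  expect_equal(cmp$p, pr$p.value, tolerance = 1e-10)
})

test_that("Youden cutoff matches the exhaustive scan and its conventions", {
  set.seed(53)
  for (i in 1:25) {
    n <- 50
    scores <- round(rnorm(n, rbinom(n, 1, 0.5)), 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2L) next
    y <- youden_cutoff(scores, labels)
    o <- oracle_youden(scores, labels)
    expect_equal(y$cutoff, o$cutoff)
    expect_equal(y$J, o$J)
  }
  # perfect separation: J = 1 at the smallest positive-class score
  y <- youden_cutoff(c(1, 2, 5, 6), c(0, 0, 1, 1))
  expect_equal(y$J, 1)
  expect_equal(y$cutoff, 5)
  # uninformative scores: J near 0
  set.seed(59)
  y0 <- youden_cutoff(rnorm(2000), rbinom(2000, 1, 0.5))
  expect_lt(y0$J, 0.1)
})

test_that("AUC is invariant under strictly increasing transforms of the score", {
  set.seed(61)
  labels <- rbinom(120, 1, 0.5)
  scores <- exp(rnorm(120, 0.5 * labels))
  a1 <- roc_curve(scores, labels)$auc
  expect_equal(roc_curve(log(scores), labels)$auc, a1, tolerance = 1e-14)
  expect_equal(roc_curve(scores^3, labels)$auc, a1, tolerance = 1e-14)
  expect_equal(roc_curve(100 + 2 * scores, labels)$auc, a1, tolerance = 1e-14)
})

test_that("diagnostic metrics satisfy the Bayes identities", {
  set.seed(67)
  for (i in 1:20) {
    se <- runif(1, 0.05, 0.95); sp <- runif(1, 0.05, 0.95)
    pi <- runif(1, 0.1, 0.9)
    m <- diagnostic_metrics(se, sp, pi)
    expect_equal(m$ppv * m$flagged_fraction, se * pi, tolerance = 1e-14)
    expect_equal(m$npv, sp * (1 - pi) / (sp * (1 - pi) + (1 - se) * pi))
    expect_equal(m$plr, se / (1 - sp))
    expect_equal(m$nlr, (1 - se) / sp)
  }
  # uninformative operating point
  m <- diagnostic_metrics(0.5, 0.5, 0.3)
  expect_equal(m$plr, 1); expect_equal(m$nlr, 1); expect_equal(m$ppv, 0.3)
  # degenerate specificities are signalled, not silent
  expect_warning(m1 <- diagnostic_metrics(0.5, 1, 0.3), "infinite")
  expect_true(is.infinite(m1$plr))
  expect_warning(m0 <- diagnostic_metrics(0.5, 0, 0.3), "infinite")
  expect_true(is.infinite(m0$nlr))
  expect_error(diagnostic_metrics(0.5, 0.5, 0), "prevalence")
})

test_that("evaluate_index recovers generator truth and covers the null", {
  d <- small_cohort(n = 5000, seed = 101)
  comp <- classify_mets(d)
  wthr <- d$waist / d$height
  m <- fit_median_curve(wthr, d$age, index_name = "wthr")
  ev <- evaluate_index(wthr, d$age, comp$mets, m)
  expect_lte(abs(ev$roc$auc - 0.66), 0.05)
  expect_lte(abs(ev$metrics$flagged_empirical - ev$metrics$flagged_fraction),
             0.05)
  expect_true(all(ev$thresholds$curve$cutoff > 0))
})

test_that("an independent score's AUC CI covers 0.5 at roughly nominal rate", {
  set.seed(71)
  cover <- logical(400)
  for (i in seq_along(cover)) {
    labels <- rbinom(150, 1, 0.5)
    if (length(unique(labels)) < 2L) { cover[i] <- TRUE; next }
    r <- roc_curve(rnorm(150), labels)
    cover[i] <- r$auc_ci95[1] <= 0.5 && r$auc_ci95[2] >= 0.5
  }
  expect_gte(mean(cover), 0.93)
})
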