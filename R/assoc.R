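#' Pearson and age-partial correlation
#'
#' `pearson_r()` wraps the standard product-moment test. `partial_pearson()`
#' removes a single covariate from both variables through the closed-form
#' identity r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2)),
#' with the p-value from the t distribution on n - 3 df. A covariate with
#' zero variance contributes nothing and the partial correlation reduces to
#' the plain one.
#'
#' @param x,y numeric vectors.
#' @param covariate numeric vector to partial out.
#' @return list with `r`, `p`, `n` (and `df`).
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 4L) stop("need at least 4 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       df = unname(ct$parameter))
}

#' @rdname pearson_r
#' @export
partial_pearson <- function(x, y, covariate) {
  stopifnot(length(x) == length(y), length(x) == length(covariate))
  n <- length(x)
  if (n < 4L) stop("need at least 4 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  if (stats::sd(covariate) == 0) {
    out <- pearson_r(x, y)
    return(list(r = out$r, p = out$p, n = n, df = n - 2L))
  }
  r_xy <- stats::cor(x, y)
  r_xz <- stats::cor(x, covariate)
  r_yz <- stats::cor(y, covariate)
  r <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  df <- n - 3L
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df), n = n, df = df)
}

#' Fisher's r-to-z transformation
#'
#' @param r correlation(s), |r| < 1.
#' @return atanh(r).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1")
  atanh(r)
}

#' Compare two correlated (overlapping) correlations
#'
#' Tests whether one shared variable correlates equally with two competing
#' variables measured on the same subjects, using Fisher-transformed
#' correlations in the Meng-Rosenthal-Rubin form for overlapping
#' correlations: the test statistic accounts for the correlation `r_ab`
#' between the two competitors.
#'
#' @param r_xa,r_xb correlations of the shared variable with competitors a
#'   and b.
#' @param r_ab correlation between the competitors.
#' @param n shared sample size (>= 10).
#' @return tibble with `r_xa`, `r_xb`, `r_ab`, `z`, `p`.
#' @export
compare_correlated <- function(r_xa, r_xb, r_ab, n) {
  if (any(abs(c(r_xa, r_xb, r_ab)) >= 1)) stop("|r| must be < 1")
  if (n < 10L) stop("need n >= 10")
  rbar2 <- (r_xa^2 + r_xb^2) / 2
  f <- min((1 - r_ab) / (2 * (1 - rbar2)), 1)
  h <- (1 - f * rbar2) / (1 - rbar2)
  z <- (atanh(r_xa) - atanh(r_xb)) * sqrt((n - 3) / (2 * (1 - r_ab) * h))
  tibble::tibble(r_xa = r_xa, r_xb = r_xb, r_ab = r_ab,
                 z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Age-adjusted standardized regression coefficient
#'
#' Least-squares fit of the z-scored outcome on the z-scored predictor plus
#' a covariate (age by default): the predictor coefficient is then the
#' standardized beta, invariant to affine rescaling of outcome and
#' predictor. Returns the coefficient, its 95% CI, and the model R^2.
#'
#' @param outcome,predictor,covariate numeric vectors of equal length.
#' @return tibble with `beta_std`, `ci_lo`, `ci_hi`, `r2`, `n`.
#' @export
standardized_beta <- function(outcome, predictor, covariate = NULL) {
  n <- length(outcome)
  stopifnot(length(predictor) == n)
  if (n < 10L) stop("need at least 10 observations")
  zo <- as.numeric(scale(outcome))
  zp <- as.numeric(scale(predictor))
  if (is.null(covariate)) {
    fit <- stats::lm(zo ~ zp)
  } else {
    stopifnot(length(covariate) == n)
    if (stats::sd(covariate) > 0 && abs(stats::cor(predictor, covariate)) > 0.999) {
      stop("predictor and covariate are collinear")
    }
    zc <- as.numeric(scale(covariate))
    fit <- stats::lm(zo ~ zp + zc)
  }
  ci <- stats::confint(fit)["zp", ]
  tibble::tibble(beta_std = unname(stats::coef(fit)["zp"]),
                 ci_lo = ci[1], ci_hi = ci[2],
                 r2 = summary(fit)$r.squared, n = n)
}

#' Welch two-sample t-test
#'
#' @param a,b numeric vectors, each with at least 2 observations.
#' @return list with `t`, `p`, `df`, `mean_a`, `mean_b`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  tt <- stats::t.test(a, b)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       mean_a = mean(a), mean_b = mean(b))
}

#' One-way ANOVA with Bonferroni-adjusted pairwise comparisons
#'
#' Standard one-way ANOVA across groups followed by pairwise t-tests with
#' Bonferroni correction (each pairwise p multiplied by the number of
#' pairs, capped at 1).
#'
#' @param groups named list of numeric vectors, each with n >= 2.
#' @return list with `F`, `p`, and `pairwise` (tibble of `group_a`,
#'   `group_b`, `p_adj`).
#' @export
anova_bonferroni <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(lengths(groups) < 2L)) stop("each group needs n >= 2")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  fit <- stats::aov(values ~ g)
  s <- summary(fit)[[1]]
  pw <- stats::pairwise.t.test(values, g, p.adjust.method = "bonferroni")
  idx <- which(!is.na(pw$p.value), arr.ind = TRUE)
  pairwise <- tibble::tibble(
    group_a = rownames(pw$p.value)[idx[, 1]],
    group_b = colnames(pw$p.value)[idx[, 2]],
    p_adj = pw$p.value[idx]
  )
  list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1], pairwise = pairwise)
}

#' Outlier screen at a standard-deviation-score cutoff
#'
#' Single-pass screen: records whose value lies more than `cutoff` SDs from
#' the mean are excluded. The screen is applied once, with no re-iteration
#' after exclusion. A zero SD yields no exclusions and a warning.
#'
#' @param values numeric vector, n >= 3.
#' @param ids identifiers (default positional).
#' @param cutoff standard-deviation-score threshold (default 4.5).
#' @return list with `retained` (values), `retained_ids`, `excluded_ids`,
#'   `sd_scores`.
#' @export
screen_outliers <- function(values, ids = as.character(seq_along(values)),
                            cutoff = 4.5) {
  if (length(values) < 3L) stop("need at least 3 values")
  stopifnot(length(ids) == length(values))
  s <- stats::sd(values)
  if (s == 0) {
    warning("zero standard deviation; no outliers excluded")
    return(list(retained = values, retained_ids = ids,
                excluded_ids = character(0),
                sd_scores = rep(0, length(values))))
  }
  z <- abs(values - mean(values)) / s
  keep <- z <= cutoff
  list(retained = values[keep], retained_ids = ids[keep],
       excluded_ids = ids[!keep], sd_scores = z)
}

#' Kolmogorov-Smirnov screen for lognormality
#'
#' Tests log-transformed values against a normal distribution with mean and
#' SD estimated from the same data. Note the usual caveat: with estimated
#' parameters the asymptotic KS p-value is conservative (a
#' Lilliefors-corrected p would be smaller); the uncorrected form is the
#' default here and suffices as a screening diagnostic.
#'
#' @param values positive values, n >= 20.
#' @return list with `D`, `p`.
#' @export
lognormality_ks <- function(values) {
  if (length(values) < 20L) stop("need at least 20 values")
  if (any(values <= 0)) stop("values must be positive")
  lv <- log(values)
  kt <- suppressWarnings(
    stats::ks.test(lv, "pnorm", mean = mean(lv), sd = stats::sd(lv),
                   exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value)
}
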