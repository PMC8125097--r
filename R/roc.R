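#' Empirical ROC curve with DeLong confidence interval
#'
#' Builds the empirical ROC curve of a continuous score against a binary
#' outcome. The orientation is fixed: a higher score means higher risk, and
#' a subject is test-positive iff score >= threshold. Thresholds are the
#' unique observed score values. The AUC is the trapezoidal area, which for
#' the empirical curve equals the tie-corrected Mann-Whitney statistic
#' (ties count 1/2). The 95% CI uses the DeLong structural-component
#' variance with a normal approximation.
#'
#' @param scores numeric, finite.
#' @param labels binary (0/1 or logical) with at least one positive and one
#'   negative.
#' @param index_name optional label.
#' @return object of class `roc_curve`: `thresholds` (ascending), `sens`,
#'   `spec`, `auc`, `auc_var`, `auc_ci95`, `n_pos`, `n_neg`, and the inputs.
#' @export
roc_curve <- function(scores, labels, index_name = "score") {
  labels <- check_binary_labels(scores, labels)
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  thresholds <- sort(unique(scores))
  sens <- vapply(thresholds, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(neg < t), numeric(1))
  dl <- delong_components(scores, labels)
  ci <- dl$auc + c(-1, 1) * stats::qnorm(0.975) * sqrt(dl$var)
  structure(list(
    index_name = index_name,
    thresholds = thresholds,
    sens = sens,
    spec = spec,
    auc = dl$auc,
    auc_var = dl$var,
    auc_ci95 = pmin(pmax(ci, 0), 1),
    n_pos = length(pos),
    n_neg = length(neg),
    scores = scores,
    labels = labels
  ), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC for %s: AUC = %.3f (95%% CI %.3f-%.3f), %d+/%d-\n",
              x$index_name, x$auc, x$auc_ci95[1], x$auc_ci95[2],
              x$n_pos, x$n_neg))
  invisible(x)
}

check_binary_labels <- function(scores, labels) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  labels <- as.integer(as.logical(labels))
  if (length(labels) != length(scores)) stop("scores and labels differ in length")
  if (anyNA(labels)) stop("labels must be binary (0/1 or logical)")
  if (sum(labels == 1L) == 0L || sum(labels == 0L) == 0L) {
    stop("labels must contain at least one positive and one negative")
  }
  labels
}

# DeLong structural components via midranks: AUC, its variance, and the
# per-subject placement vectors v10 (positives) and v01 (negatives), which
# carry the covariance needed for paired comparisons.
delong_components <- function(scores, labels) {
  x <- scores[labels == 1L]
  y <- scores[labels == 0L]
  m <- length(x)
  n <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  r_x <- rank(x, ties.method = "average")
  r_y <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_x) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_y) / m
  auc <- mean(v10)
  var_auc <- stats::var(v10) / m + stats::var(v01) / n
  list(auc = auc, var = var_auc, v10 = v10, v01 = v01, m = m, n = n)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two scores measured on the same subjects with the
#' same outcome, accounting for their correlation through the DeLong
#' structural components: z = (AUC_a - AUC_b) / sqrt(var_a + var_b -
#' 2 cov_ab), with a two-sided normal p-value.
#'
#' @param scores_a,scores_b score vectors on the same subjects.
#' @param labels shared binary outcome.
#' @param names length-2 labels for the two scores.
#' @return tibble with `index_a`, `index_b`, `auc_a`, `auc_b`, `delta_auc`,
#'   `var_delta`, `z`, `p`.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels,
                               names = c("a", "b")) {
  if (length(scores_a) != length(scores_b)) {
    stop("paired comparison requires the same subjects for both scores")
  }
  labels <- check_binary_labels(scores_a, labels)
  da <- delong_components(scores_a, labels)
  db <- delong_components(scores_b, labels)
  cov_ab <- stats::cov(da$v10, db$v10) / da$m + stats::cov(da$v01, db$v01) / da$n
  delta <- da$auc - db$auc
  var_delta <- da$var + db$var - 2 * cov_ab
  z <- if (delta == 0) 0 else delta / sqrt(max(var_delta, .Machine$double.eps))
  tibble::tibble(
    index_a = names[1], index_b = names[2],
    auc_a = da$auc, auc_b = db$auc,
    delta_auc = delta, var_delta = var_delta,
    z = z, p = 2 * stats::pnorm(-abs(z))
  )
}

#' Youden-optimal cutoff
#'
#' Scans the observed score values and returns the threshold maximizing
#' J = sensitivity + specificity - 1 under the score >= cutoff positivity
#' convention. Ties are broken toward the smallest cutoff (the more
#' sensitive operating point, the natural choice for screening).
#'
#' @inheritParams roc_curve
#' @return list with `cutoff`, `J`, `sensitivity`, `specificity`.
#' @export
youden_cutoff <- function(scores, labels) {
  roc <- roc_curve(scores, labels)
  J <- roc$sens + roc$spec - 1
  i <- which.max(J)  # thresholds ascending: first max = smallest cutoff
  list(cutoff = roc$thresholds[i], J = J[i],
       sensitivity = roc$sens[i], specificity = roc$spec[i])
}

#' Diagnostic metrics at an operating point
#'
#' Predictive values and likelihood ratios implied by a sensitivity,
#' specificity and disease prevalence, via the Bayes identities:
#' PPV = se pi / (se pi + (1-sp)(1-pi)),
#' NPV = sp (1-pi) / (sp (1-pi) + (1-se) pi),
#' PLR = se / (1-sp), NLR = (1-se) / sp, and the flagged fraction
#' (the share of the cohort testing positive) se pi + (1-sp)(1-pi).
#'
#' Degenerate specificity is signalled: sp = 1 makes the PLR infinite and
#' sp = 0 makes the NLR infinite; both raise a warning and return `Inf`.
#'
#' @param se,sp sensitivity and specificity, in \\[0, 1\\].
#' @param prevalence disease prevalence pi in (0, 1).
#' @return tibble with `sensitivity`, `specificity`, `ppv`, `npv`, `plr`,
#'   `nlr`, `flagged_fraction`.
#' @export
diagnostic_metrics <- function(se, sp, prevalence) {
  stopifnot(length(se) == length(sp))
  if (any(se < 0 | se > 1 | sp < 0 | sp > 1)) stop("se and sp must lie in [0, 1]")
  if (any(prevalence <= 0 | prevalence >= 1)) stop("prevalence must lie in (0, 1)")
  if (any(sp == 1)) warning("specificity of 1: positive likelihood ratio is infinite")
  if (any(sp == 0)) warning("specificity of 0: negative likelihood ratio is infinite")
  pi <- prevalence
  tp <- se * pi
  fp <- (1 - sp) * (1 - pi)
  tn <- sp * (1 - pi)
  fn <- (1 - se) * pi
  tibble::tibble(
    sensitivity = se,
    specificity = sp,
    ppv = tp / (tp + fp),
    npv = tn / (tn + fn),
    plr = ifelse(sp == 1, Inf, se / (1 - sp)),
    nlr = ifelse(sp == 0, Inf, (1 - se) / sp),
    flagged_fraction = tp + fp
  )
}

#' Evaluate one index end to end against the MetS label
#'
#' The full per-index pipeline: age-standardize the raw values with a fitted
#' reference model, build the ROC of the standardized score against the
#' outcome, pick the Youden-optimal standardized cutoff z*, compute the
#' diagnostic metrics at that operating point (at the cohort prevalence),
#' and back-transform z* into the age-specific raw-scale threshold curve.
#'
#' @param values raw index values.
#' @param ages ages in years.
#' @param labels binary outcome (MetS).
#' @param model `age_reference_model` fitted for this index.
#' @param age_grid ages at which to tabulate the threshold curve.
#' @return list with `roc`, `youden` (cutoff on the z scale), `metrics`
#'   (one-row tibble, including the empirical flagged fraction
#'   `flagged_empirical`), and `thresholds` (see [threshold_curve()]).
#' @export
evaluate_index <- function(values, ages, labels, model,
                           age_grid = seq(18, 83, by = 1)) {
  z <- standardize(model, values, ages)
  roc <- roc_curve(z, labels, index_name = model$index_name)
  yj <- youden_cutoff(z, labels)
  prevalence <- mean(check_binary_labels(z, labels))
  metrics <- diagnostic_metrics(yj$sensitivity, yj$specificity, prevalence)
  metrics$cutoff_z <- yj$cutoff
  metrics$youden_j <- yj$J
  metrics$flagged_empirical <- mean(z >= yj$cutoff)
  thresholds <- threshold_curve(model, yj$cutoff, age_grid, cohort_ages = ages)
  list(roc = roc, youden = yj, metrics = metrics, thresholds = thresholds)
}
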