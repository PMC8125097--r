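# Independent oracles used across the suite. These deliberately take the
# slow, transparent route (brute force, enumeration) so they cannot share a
# bug with the implementation they check.

# Tie-corrected Mann-Whitney AUC by full pairwise comparison.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Exhaustive Youden scan over observed thresholds (smallest-cutoff ties).
oracle_youden <- function(scores, labels) {
  ts <- sort(unique(scores))
  J <- vapply(ts, function(t) {
    mean(scores[labels == 1] >= t) + mean(scores[labels == 0] < t) - 1
  }, numeric(1))
  list(cutoff = ts[which.max(J)], J = max(J))
}

# Combinatorial quantile-regression oracle: a median-regression solution
# with p free parameters interpolates p data points, so enumerate all
# p-subsets, solve exactly, and keep the minimal pinball loss.
oracle_median_fit <- function(X, y, tau = 0.5) {
  p <- ncol(X)
  best <- list(loss = Inf, coefficients = NULL)
  for (idx in utils::combn(nrow(X), p, simplify = FALSE)) {
    Xi <- X[idx, , drop = FALSE]
    if (abs(det(Xi)) < 1e-10) next
    beta <- solve(Xi, y[idx])
    loss <- sum(metscreen::pinball_loss(y - drop(X %*% beta), tau))
    if (loss < best$loss) best <- list(loss = loss, coefficients = beta)
  }
  best
}

# Jackknife variance of the empirical AUC.
oracle_jackknife_auc_var <- function(scores, labels) {
  n <- length(scores)
  loo <- vapply(seq_len(n), function(i) {
    oracle_auc(scores[-i], labels[-i])
  }, numeric(1))
  (n - 1) / n * sum((loo - mean(loo))^2)
}

# Cohort with an exact number of MetS-positive and -negative subjects.
mk_flagged_cohort <- function(n_pos, n_neg) {
  n <- n_pos + n_neg
  pos <- seq_len(n) <= n_pos
  data.frame(
    id = as.character(seq_len(n)),
    waist = ifelse(pos, 100, 70), sbp = ifelse(pos, 140, 110),
    dbp = ifelse(pos, 90, 70), tg = ifelse(pos, 200, 80),
    hdl = ifelse(pos, 40, 70), glucose = ifelse(pos, 120, 80),
    on_bp_meds = FALSE, on_lipid_meds = FALSE, on_glucose_meds = FALSE
  )
}

# Small default synthetic cohort shared by several tests.
small_cohort <- function(n = 400, seed = 7, ...) {
  metscreen::generate_cohort(metscreen::cohort_config(n = n, seed = seed, ...))
}
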