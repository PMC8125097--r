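#' Pinball (check) loss
#'
#' The asymmetric absolute loss rho_tau(u) = u * (tau - 1[u < 0]), minimized
#' in expectation by the tau-th conditional quantile.
#'
#' @param u numeric residuals.
#' @param tau quantile level in (0, 1).
#' @return numeric vector of losses.
#' @export
pinball_loss <- function(u, tau = 0.5) {
  stopifnot(tau > 0, tau < 1)
  u * (tau - (u < 0))
}

# Linear quantile regression by iteratively reweighted least squares on an
# epsilon-smoothed pinball loss. Weights w_i = a_i / max(|u_i|, eps) with
# a_i = tau for positive residuals and 1 - tau for negative ones make the
# weighted least-squares objective a local quadratic majorant of the pinball
# loss; iterating drives the fit to the quantile-regression solution.
# Returns coefficients, total pinball loss, iteration count and a
# convergence flag (non-convergence is reported, not fatal).
fit_pinball <- function(X, y, tau = 0.5, eps = 1e-6, tol = 1e-8, maxit = 200L) {
  stopifnot(is.matrix(X), nrow(X) == length(y), tau > 0, tau < 1)
  p <- ncol(X)
  beta <- stats::lm.fit(X, y)$coefficients
  beta[is.na(beta)] <- 0
  converged <- FALSE
  total_it <- 0L
  # continuation: shrink the smoothing parameter toward eps so the iterate
  # is not trapped by a poor initial active set
  for (e in unique(sort(c(1e-2, 1e-3, 1e-4, 1e-5, eps), decreasing = TRUE))) {
    if (e < eps) break
    for (it in seq_len(maxit)) {
      total_it <- total_it + 1L
      u <- y - drop(X %*% beta)
      a <- ifelse(u >= 0, tau, 1 - tau)
      w <- a / pmax(abs(u), e)
      fit <- stats::lm.wfit(X, y, w)
      beta_new <- fit$coefficients
      beta_new[is.na(beta_new)] <- 0
      step <- max(abs(beta_new - beta))
      beta <- beta_new
      if (step < tol * (1 + max(abs(beta)))) {
        converged <- TRUE
        break
      }
    }
  }
  loss <- sum(pinball_loss(y - drop(X %*% beta), tau))
  # active-set polish: a quantile-regression solution interpolates p points,
  # so snap to the exact fit through the p smallest-|residual| points when
  # that lowers the loss
  if (nrow(X) >= p) {
    u <- y - drop(X %*% beta)
    idx <- order(abs(u))[seq_len(p)]
    Xi <- X[idx, , drop = FALSE]
    if (abs(det(Xi)) > 1e-12) {
      beta_snap <- solve(Xi, y[idx])
      loss_snap <- sum(pinball_loss(y - drop(X %*% beta_snap), tau))
      if (loss_snap < loss) {
        beta <- beta_snap
        loss <- loss_snap
      }
    }
  }
  list(coefficients = beta,
       loss = loss,
       iterations = total_it,
       converged = converged)
}
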