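#' Fit an age-reference (median) curve for an index
#'
#' Age-standardization of a body-composition index, as an alternative to the
#' LMS growth-curve method: the log of the index is regressed on a
#' polynomial in age by median (tau = 0.5) quantile regression, and the
#' standardized residuals serve as age-adjusted values.
#'
#' The default basis is `{1, a^3, a^4}` with `a = age / age_scale`: cubic
#' and quartic age terms around an intercept. The rescaling (default 100)
#' keeps the design matrix well conditioned (raw age^4 reaches ~5e7 at age
#' 83 and would dominate the columns). A full quartic basis
#' `{1, a, a^2, a^3, a^4}` is available via `basis = "full_quartic"`.
#'
#' The residual scale used for standardization is, by default, the sample SD
#' of the median-fit residuals; `scale_estimator = "iqr"` uses the robust
#' quantile-spread alternative (q0.75 - q0.25) / 1.349.
#'
#' @param values positive index values (raw scale).
#' @param ages ages in years, same length; must lie in [18, 100].
#' @param tau quantile level (default 0.5, the median).
#' @param basis `"cubic_quartic"` (default) or `"full_quartic"`.
#' @param age_scale divisor applied to age before powering (default 100).
#' @param scale_estimator `"sd"` (default) or `"iqr"`.
#' @param index_name optional label carried through to reports.
#' @return an object of class `age_reference_model` with elements
#'   `coefficients` (on the log scale), `basis`, `age_scale`,
#'   `residual_scale`, and `fit_diagnostics` (iterations, converged,
#'   pinball loss).
#' @export
fit_median_curve <- function(values, ages, tau = 0.5,
                             basis = c("cubic_quartic", "full_quartic"),
                             age_scale = 100,
                             scale_estimator = c("sd", "iqr"),
                             index_name = "index") {
  basis <- match.arg(basis)
  scale_estimator <- match.arg(scale_estimator)
  stopifnot(length(values) == length(ages))
  if (length(values) < 10L) stop("need at least 10 subjects to fit a reference curve")
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("index values must be positive and finite")
  }
  if (any(ages < 18) || any(ages > 100)) stop("ages must lie in [18, 100]")

  X <- age_design(ages, basis, age_scale)
  fit <- fit_pinball(X, log(values), tau = tau)
  resid <- log(values) - drop(X %*% fit$coefficients)
  residual_scale <- switch(scale_estimator,
    sd  = stats::sd(resid),
    iqr = diff(stats::quantile(resid, c(0.25, 0.75), names = FALSE)) / 1.349)
  if (!is.finite(residual_scale) || residual_scale <= 1e-12) {
    stop("degenerate residual scale; index values carry no spread")
  }
  structure(list(
    index_name = index_name,
    coefficients = fit$coefficients,
    basis = basis,
    age_scale = age_scale,
    residual_scale = residual_scale,
    scale_estimator = scale_estimator,
    tau = tau,
    fit_diagnostics = list(iterations = fit$iterations,
                           converged = fit$converged,
                           pinball_loss = fit$loss)
  ), class = "age_reference_model")
}

# Design matrix for the age polynomial basis.
age_design <- function(ages, basis, age_scale) {
  a <- ages / age_scale
  X <- switch(basis,
    cubic_quartic = cbind(1, a^3, a^4),
    full_quartic  = cbind(1, a, a^2, a^3, a^4),
    stop("unknown basis: ", basis))
  colnames(X) <- switch(basis,
    cubic_quartic = c("b0", "b3", "b4"),
    full_quartic  = c("b0", "b1", "b2", "b3", "b4"))
  X
}

#' Predicted log-scale median at given ages
#'
#' @param model an `age_reference_model`.
#' @param ages ages in years.
#' @return numeric vector, the fitted median of log(index) at each age.
#' @export
predict_log_median <- function(model, ages) {
  stopifnot(inherits(model, "age_reference_model"))
  drop(age_design(ages, model$basis, model$age_scale) %*% model$coefficients)
}

#' @export
print.age_reference_model <- function(x, ...) {
  cat(sprintf("Age-reference model for %s (tau = %g, basis %s)\n",
              x$index_name, x$tau, x$basis))
  cat("  log-scale coefficients:",
      paste(sprintf("%s = %.5g", names(x$coefficients), x$coefficients),
            collapse = ", "), "\n")
  cat(sprintf("  residual scale (%s): %.5g\n", x$scale_estimator, x$residual_scale))
  cat(sprintf("  converged: %s after %d IRLS iterations (pinball loss %.5g)\n",
              x$fit_diagnostics$converged, x$fit_diagnostics$iterations,
              x$fit_diagnostics$pinball_loss))
  invisible(x)
}

#' Age-adjusted standardized value of an index
#'
#' z = (log(value) - median_fit(age)) / residual_scale. For fixed age this
#' is a strictly increasing transform of the raw value, so within any single
#' age stratum it preserves ranks (and hence ROC curves).
#'
#' @param model an `age_reference_model`.
#' @param value raw index values (> 0).
#' @param age ages in years.
#' @return standardized (dimensionless) values.
#' @export
standardize <- function(model, value, age) {
  stopifnot(inherits(model, "age_reference_model"))
  if (any(!is.finite(value)) || any(value <= 0)) stop("value must be positive")
  (log(value) - predict_log_median(model, age)) / model$residual_scale
}

#' Inverse of [standardize()]
#'
#' @param model an `age_reference_model`.
#' @param z standardized values.
#' @param age ages in years.
#' @return raw-scale index values.
#' @export
inverse_standardize <- function(model, z, age) {
  stopifnot(inherits(model, "age_reference_model"))
  exp(predict_log_median(model, age) + z * model$residual_scale)
}

#' Age-specific raw-scale threshold curve
#'
#' Back-transforms a cutoff chosen on the standardized scale (typically the
#' Youden-optimal z*) into an age-dependent raw-scale threshold:
#' cutoff(age) = exp(median_fit(age) + z* x residual_scale). The mean
#' cutoff over a cohort's observed ages summarizes the curve as a single
#' number comparable across indexes.
#'
#' @param model an `age_reference_model`.
#' @param z_star cutoff on the standardized scale.
#' @param ages age grid (years) for the curve; non-empty.
#' @param cohort_ages optional cohort ages over which to average the
#'   per-subject cutoff (default: the grid itself).
#' @return list with `index_name`, `z_star`, `curve` (tibble of `age`,
#'   `cutoff`) and `mean_cutoff`.
#' @export
threshold_curve <- function(model, z_star, ages, cohort_ages = ages) {
  stopifnot(inherits(model, "age_reference_model"))
  if (length(ages) == 0L) stop("age grid is empty")
  cutoffs <- inverse_standardize(model, z_star, ages)
  list(index_name = model$index_name,
       z_star = z_star,
       curve = tibble::tibble(age = ages, cutoff = cutoffs),
       mean_cutoff = mean(inverse_standardize(model, z_star, cohort_ages)))
}

#' Serialize / restore an age-reference model as JSON
#'
#' @param model an `age_reference_model`.
#' @param path file path; if `NULL`, the JSON string is returned.
#' @return `age_reference_to_json`: the path (or JSON string) invisibly;
#'   `age_reference_from_json`: the restored model.
#' @export
age_reference_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "age_reference_model"))
  payload <- unclass(model)
  payload$coefficients <- as.list(model$coefficients)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}

#' @rdname age_reference_to_json
#' @export
age_reference_from_json <- function(path) {
  payload <- jsonlite::fromJSON(path)
  payload$coefficients <- unlist(payload$coefficients)
  structure(payload, class = "age_reference_model")
}
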