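#' Run the full index-comparison analysis
#'
#' Drives the whole pipeline over a cohort table: computes the six indexes,
#' applies the MetS rule engine, fits an age-reference model per index, and
#' evaluates every index (ROC with DeLong CI, Youden cutoff, diagnostic
#' metrics, age-specific threshold curve) in the whole cohort and in each
#' age stratum, plus pairwise DeLong comparisons of the correlated AUCs and
#' an association report (age-adjusted standardized betas and age-partial
#' correlations of each index with each risk factor).
#'
#' Age strata are half-open intervals `[lo, hi)`; the defaults are 18-44,
#' 45-54 and 55+ years. Strata with fewer than 30 subjects (or a single
#' outcome class) are skipped with a warning. Reference models and Youden
#' cutoffs are fitted within each stratum's own data for stratified rows;
#' the `all` stratum uses the whole cohort.
#'
#' When `out_dir` is given, the report bundle is written there as CSV files
#' (`descriptives_by_mets.csv`, `associations.csv`, `diagnostics.csv`,
#' `auc_comparisons.csv`, `threshold_curves.csv`, `roc_coordinates.csv`,
#' `mets_summary.csv`) plus a JSON `manifest.json` (n, strata, options,
#' package version). Every diagnostics row is audited against the Bayes
#' identities (PPV x flagged fraction = sensitivity x prevalence, and the
#' PPV/NPV/PLR/NLR closed forms) before the bundle is returned.
#'
#' @param data subject table (see [read_subjects()]), or a path to its CSV.
#' @param out_dir optional output directory (created if needed).
#' @param age_strata list of `c(lo, hi)` half-open bounds.
#' @param indexes which index columns to evaluate.
#' @param basis,scale_estimator passed to [fit_median_curve()].
#' @param age_grid ages at which threshold curves are tabulated.
#' @return invisibly, a list of tibbles: `descriptives`, `associations`,
#'   `diagnostics`, `auc_comparisons`, `threshold_curves`,
#'   `roc_coordinates`, `mets_summary`, and the fitted `models` (whole
#'   cohort).
#' @export
run_analyze <- function(data, out_dir = NULL,
                        age_strata = list(c(18, 45), c(45, 55), c(55, Inf)),
                        indexes = index_names(),
                        basis = "cubic_quartic", scale_estimator = "sd",
                        age_grid = seq(18, 83, by = 1)) {
  if (is.character(data)) data <- read_subjects(data)
  data <- validate_subjects(data)
  stopifnot(length(indexes) >= 1L)
  check_strata(age_strata)

  panel <- compute_indexes(data)
  comp <- classify_mets(data)
  labels <- comp$mets
  risk_factors <- c("sbp", "dbp", "hdl", "glucose", "tg")

  strata <- c(list(all = c(18, Inf)),
              stats::setNames(age_strata, vapply(age_strata, stratum_label,
                                                 character(1))))

  diagnostics <- list()
  curves <- list()
  roc_coords <- list()
  comparisons <- list()
  models <- list()

  for (sname in names(strata)) {
    b <- strata[[sname]]
    in_s <- data$age >= b[1] & data$age < b[2]
    if (sum(in_s) < 30L) {
      warning("stratum ", sname, " has fewer than 30 subjects; skipped")
      next
    }
    if (length(unique(labels[in_s])) < 2L) {
      warning("stratum ", sname, " has a single outcome class; skipped")
      next
    }
    evals <- list()
    for (ix in indexes) {
      model <- fit_median_curve(panel[[ix]][in_s], data$age[in_s],
                                basis = basis,
                                scale_estimator = scale_estimator,
                                index_name = ix)
      ev <- evaluate_index(panel[[ix]][in_s], data$age[in_s], labels[in_s],
                           model, age_grid = age_grid)
      evals[[ix]] <- ev
      if (sname == "all") models[[ix]] <- model
      m <- ev$metrics
      diagnostics[[length(diagnostics) + 1L]] <- tibble::tibble(
        stratum = sname, index = ix, n = sum(in_s),
        prevalence = mean(labels[in_s]),
        auc = ev$roc$auc, auc_lo = ev$roc$auc_ci95[1],
        auc_hi = ev$roc$auc_ci95[2],
        sensitivity = m$sensitivity, specificity = m$specificity,
        ppv = m$ppv, npv = m$npv, plr = m$plr, nlr = m$nlr,
        cutoff_z = m$cutoff_z, youden_j = m$youden_j,
        mean_cutoff = ev$thresholds$mean_cutoff,
        flagged_identity = m$flagged_fraction,
        flagged_empirical = m$flagged_empirical
      )
      curves[[length(curves) + 1L]] <- tibble::tibble(
        stratum = sname, index = ix,
        age = ev$thresholds$curve$age, cutoff = ev$thresholds$curve$cutoff)
      roc_coords[[length(roc_coords) + 1L]] <- tibble::tibble(
        stratum = sname, index = ix,
        threshold = ev$roc$thresholds,
        sensitivity = ev$roc$sens, specificity = ev$roc$spec)
    }
    done <- names(evals)
    if (length(done) >= 2L) {
      for (i in seq_len(length(done) - 1L)) {
        for (j in seq((i + 1L), length(done))) {
          za <- standardize_scores(evals[[done[i]]])
          zb <- standardize_scores(evals[[done[j]]])
          cmp <- delong_paired_test(za, zb, labels[in_s],
                                    names = c(done[i], done[j]))
          cmp$stratum <- sname
          comparisons[[length(comparisons) + 1L]] <- cmp
        }
      }
    }
  }

  diagnostics <- do.call(rbind, diagnostics)
  audit_bayes(diagnostics)

  assoc <- list()
  for (ix in indexes) {
    for (rf in risk_factors) {
      sb <- standardized_beta(data[[rf]], panel[[ix]], data$age)
      pr <- partial_pearson(panel[[ix]], data[[rf]], data$age)
      assoc[[length(assoc) + 1L]] <- tibble::tibble(
        index = ix, risk_factor = rf,
        beta_std = sb$beta_std, ci_lo = sb$ci_lo, ci_hi = sb$ci_hi,
        r2 = sb$r2, partial_r = pr$r, partial_p = pr$p)
    }
  }
  assoc <- do.call(rbind, assoc)

  desc <- descriptives_by_mets(data, panel, labels)

  result <- list(
    descriptives = desc,
    associations = assoc,
    diagnostics = diagnostics,
    auc_comparisons = do.call(rbind, comparisons),
    threshold_curves = do.call(rbind, curves),
    roc_coordinates = do.call(rbind, roc_coords),
    mets_summary = cohort_mets_summary(data),
    models = models
  )

  if (!is.null(out_dir)) write_report(result, out_dir, nrow(data), strata,
                                      basis, scale_estimator)
  invisible(result)
}

stratum_label <- function(b) {
  if (is.infinite(b[2])) sprintf("%g+", b[1]) else sprintf("%g-%g", b[1], b[2])
}

check_strata <- function(age_strata) {
  stopifnot(is.list(age_strata), length(age_strata) >= 1L)
  bounds <- do.call(rbind, age_strata)
  o <- order(bounds[, 1])
  bounds <- bounds[o, , drop = FALSE]
  if (any(bounds[, 2] <= bounds[, 1])) stop("empty age stratum")
  if (nrow(bounds) > 1L &&
      any(bounds[-1L, 1] != bounds[-nrow(bounds), 2])) {
    stop("age strata must be non-overlapping and contiguous")
  }
  invisible(bounds)
}

# standardized scores used for an index's ROC within evaluate_index()
standardize_scores <- function(ev) ev$roc$scores

# Bayes-identity self-audit, run on every report before it is returned.
audit_bayes <- function(d, tol = 1e-10) {
  ok <- abs(d$ppv * d$flagged_identity - d$sensitivity * d$prevalence) < tol &
    abs(d$plr - d$sensitivity / (1 - d$specificity)) < tol * pmax(1, d$plr) &
    abs(d$nlr - (1 - d$sensitivity) / d$specificity) < tol
  ok[!is.finite(d$plr)] <- TRUE
  if (!all(ok)) stop("internal error: diagnostic report violates Bayes identities")
  invisible(TRUE)
}

descriptives_by_mets <- function(data, panel, labels) {
  vars <- c("age", "sbp", "dbp", "tg", "hdl", "glucose", "waist",
            "fm_pct", "ffm_pct")
  tab <- cbind(data[vars], panel[index_names()])
  rows <- lapply(names(tab), function(v) {
    x <- tab[[v]]
    tt <- welch_t(x[labels], x[!labels])
    tibble::tibble(
      variable = v,
      mean_all = mean(x), sd_all = stats::sd(x),
      mean_mets_neg = mean(x[!labels]), sd_mets_neg = stats::sd(x[!labels]),
      mean_mets_pos = mean(x[labels]), sd_mets_pos = stats::sd(x[labels]),
      p = tt$p)
  })
  do.call(rbind, rows)
}

write_report <- function(result, out_dir, n, strata, basis, scale_estimator) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) utils::write.csv(x, file.path(out_dir, f), row.names = FALSE)
  w(result$descriptives, "descriptives_by_mets.csv")
  w(result$associations, "associations.csv")
  w(result$diagnostics, "diagnostics.csv")
  w(result$auc_comparisons, "auc_comparisons.csv")
  w(result$threshold_curves, "threshold_curves.csv")
  w(result$roc_coordinates, "roc_coordinates.csv")
  w(result$mets_summary, "mets_summary.csv")
  manifest <- list(
    n = n,
    strata = lapply(unname(strata), function(b) c(lo = b[1], hi = b[2])),
    basis = basis, scale_estimator = scale_estimator,
    package = "metscreen",
    version = as.character(utils::packageVersion("metscreen"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
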