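#' Classify the metabolic-syndrome components
#'
#' Applies the IDF-style component rules to each subject:
#'
#' * central obesity: waist circumference >= 80 cm
#' * high blood pressure: SBP >= 130 mmHg and/or DBP >= 85 mmHg, or
#'   antihypertensive treatment
#' * high triglycerides: TG >= 150 mg/dL, or lipid-lowering treatment
#' * low HDL cholesterol: HDL-C < 50 mg/dL (no medication override)
#' * high fasting glucose: glucose >= 100 mg/dL (5.6 mmol/L), or
#'   antidiabetic treatment
#'
#' The overall label is MetS when at least three of the five components are
#' present. All cutoffs are applied with exactly the printed inclusivity
#' (>=, <) and no tolerance band: an HDL-C of exactly 50 mg/dL is *not* low.
#' Lipid-lowering medication counts toward the triglyceride component only.
#'
#' @param data subject table with `waist`, `sbp`, `dbp`, `tg`, `hdl`,
#'   `glucose` and the three medication flags.
#' @param require_central_obesity if `TRUE`, use the strict IDF variant in
#'   which central obesity is mandatory and two further components are
#'   required. Default `FALSE`: any three of five, the rule used throughout
#'   the analysis.
#' @return tibble with `id`, the five component logicals, `n_components`,
#'   and `mets`.
#' @export
classify_mets <- function(data, require_central_obesity = FALSE) {
  data <- validate_subjects(data,
    require = c("waist", "sbp", "dbp", "tg", "hdl", "glucose",
                "on_bp_meds", "on_lipid_meds", "on_glucose_meds"))
  central_obesity <- data$waist >= 80
  high_bp      <- data$sbp >= 130 | data$dbp >= 85 | as.logical(data$on_bp_meds)
  high_tg      <- data$tg >= 150 | as.logical(data$on_lipid_meds)
  low_hdl      <- data$hdl < 50
  high_glucose <- data$glucose >= 100 | as.logical(data$on_glucose_meds)
  n_components <- central_obesity + high_bp + high_tg + low_hdl + high_glucose
  mets <- if (require_central_obesity) {
    central_obesity & (high_bp + high_tg + low_hdl + high_glucose >= 2L)
  } else {
    n_components >= 3L
  }
  tibble::tibble(
    id = data$id,
    central_obesity = central_obesity,
    high_bp = high_bp,
    high_tg = high_tg,
    low_hdl = low_hdl,
    high_glucose = high_glucose,
    n_components = as.integer(n_components),
    mets = mets
  )
}

#' Cohort-level component and MetS prevalence summary
#'
#' Counts and percentages (one decimal) for each MetS component and for the
#' overall label, across a cohort.
#'
#' @param data subject table (see [classify_mets()]).
#' @param ... passed on to [classify_mets()].
#' @return tibble with columns `measure`, `n_positive`, `n_total`, `pct`.
#' @export
cohort_mets_summary <- function(data, ...) {
  if (!is.data.frame(data) || nrow(data) == 0L) stop("subject table is empty")
  comp <- classify_mets(data, ...)
  measures <- c("central_obesity", "high_bp", "high_tg", "low_hdl",
                "high_glucose", "mets")
  n <- nrow(comp)
  tibble::tibble(
    measure = measures,
    n_positive = unname(vapply(measures, function(m) sum(comp[[m]]), integer(1))),
    n_total = n,
    pct = unname(round(100 * vapply(measures, function(m) mean(comp[[m]]), numeric(1)), 1))
  )
}
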