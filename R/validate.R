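#' @keywords internal
"_PACKAGE"

# Canonical column order for a subject table (the CSV input schema).
subject_columns <- function() {
  c("id", "age", "height", "weight", "waist", "fm_pct", "ffm_pct",
    "sbp", "dbp", "tg", "hdl", "glucose",
    "on_bp_meds", "on_lipid_meds", "on_glucose_meds", "z50")
}

#' Validate a subject table
#'
#' Checks that a cohort table follows the expected schema: one row per
#' subject, the required columns present, anthropometry within plausible
#' adult ranges (age 18-100 years, height 100-220 cm, positive weight and
#' waist), and non-negative analyte concentrations. Fat-mass and
#' fat-free-mass percentages are expected to sum to 100; a mismatch larger
#' than 0.1 points raises a warning (measurement rounding), not an error.
#'
#' @param data data frame of subject records.
#' @param require character vector of columns that must be present and
#'   non-missing; defaults to every column except the optional `z50`.
#' @return `data`, invisibly, with `id` coerced to character.
#' @export
validate_subjects <- function(data, require = setdiff(subject_columns(), "z50")) {
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0L) stop("subject table is empty")
  for (col in require) {
    if (!col %in% names(data)) stop("missing required field: ", col)
    if (anyNA(data[[col]])) stop("missing values in required field: ", col)
  }
  if (!"id" %in% names(data)) data$id <- as.character(seq_len(nrow(data)))
  data$id <- as.character(data$id)

  check_range <- function(col, lo, hi, lo_ok = TRUE, hi_ok = TRUE) {
    if (!col %in% require) return(invisible())
    x <- data[[col]]
    bad <- if (lo_ok) x < lo else x <= lo
    bad <- bad | if (hi_ok) x > hi else x >= hi
    if (any(bad)) {
      stop(sprintf("field %s out of range [%s, %s] for subject(s): %s",
                   col, lo, hi, paste(utils::head(data$id[bad], 5L), collapse = ", ")))
    }
  }
  check_range("age", 18, 100)
  check_range("height", 100, 220, lo_ok = FALSE, hi_ok = FALSE)
  check_range("weight", 0, Inf, lo_ok = FALSE)
  check_range("waist", 0, Inf, lo_ok = FALSE)
  for (col in intersect(c("tg", "hdl", "glucose", "sbp", "dbp"), require)) {
    if (any(data[[col]] < 0)) stop("negative values in field: ", col)
  }
  if (all(c("fm_pct", "ffm_pct") %in% names(data)) &&
      all(c("fm_pct", "ffm_pct") %in% require)) {
    gap <- abs(data$fm_pct + data$ffm_pct - 100)
    if (any(gap > 0.1)) {
      warning(sprintf("fm_pct + ffm_pct deviates from 100 by up to %.3f for %d subject(s)",
                      max(gap), sum(gap > 0.1)))
    }
  }
  for (col in intersect(c("on_bp_meds", "on_lipid_meds", "on_glucose_meds"), require)) {
    if (!all(data[[col]] %in% c(TRUE, FALSE, 0L, 1L))) {
      stop("field ", col, " must be logical (TRUE/FALSE)")
    }
  }
  invisible(data)
}

#' Read a subject table from CSV
#'
#' Reads the standard per-subject CSV schema (header names as in
#' [subject_columns()]); a missing `z50` column is allowed.
#'
#' @param path path to a CSV file.
#' @return a tibble of subject records.
#' @export
read_subjects <- function(path) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("on_bp_meds", "on_lipid_meds", "on_glucose_meds")) {
    if (col %in% names(data)) data[[col]] <- as.logical(data[[col]])
  }
  validate_subjects(data)
  tibble::as_tibble(data)
}
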