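#' Compute the adiposity and body-composition indexes
#'
#' Computes, for every subject, the six indexes compared by the pipeline:
#'
#' * `bmi`  — body mass index, weight (kg) / height (m)^2
#' * `tmi`  — tri-ponderal mass index, weight (kg) / height (m)^3
#' * `wthr` — waist-to-height ratio, WC (cm) / height (cm)
#' * `fmi`  — fat-mass index, fat mass (kg) / height (m)^2 = BMI x FM%/100
#' * `ffmi` — fat-free-mass index, fat-free mass (kg) / height (m)^2
#' * `bmfi` — body-mass fat index, BMI x fat-mass fraction x WC (m), in kg/m
#'
#' The fat-mass percentage enters BMFI as a fraction and waist circumference
#' in metres: that is the only reading under which the index carries its
#' stated unit (kg/m^2 x dimensionless x m = kg/m) and lands on the
#' physiological scale (cohort means near 27 kg/m rather than ~2600).
#'
#' Heights are accepted in centimetres only; conversion to metres is
#' internal.
#'
#' @param data subject table with at least `height`, `weight`, `waist`,
#'   `fm_pct`, `ffm_pct` (and `id`).
#' @return tibble with `id` and the six index columns.
#' @examples
#' compute_indexes(data.frame(id = "a", height = 160, weight = 102.4,
#'                            waist = 120, fm_pct = 50, ffm_pct = 50))
#' @export
compute_indexes <- function(data) {
  data <- validate_subjects(data,
    require = c("height", "weight", "waist", "fm_pct", "ffm_pct"))
  h_m <- data$height / 100
  bmi <- data$weight / h_m^2
  tibble::tibble(
    id   = data$id,
    bmi  = bmi,
    bmfi = bmi * (data$fm_pct / 100) * (data$waist / 100),
    fmi  = bmi * data$fm_pct / 100,
    ffmi = bmi * data$ffm_pct / 100,
    tmi  = data$weight / h_m^3,
    wthr = data$waist / data$height
  )
}

#' Names of the index columns produced by [compute_indexes()], in report order
#' @return character vector of the six index names.
#' @export
index_names <- function() c("bmi", "bmfi", "fmi", "ffmi", "wthr", "tmi")

#' Impedance index
#'
#' The bioimpedance index ZI50 = height (cm)^2 / Z50 (ohm), where Z50 is
#' whole-body impedance measured at 50 kHz. Units: cm^2/ohm.
#'
#' @param height height in cm.
#' @param z50 whole-body impedance at 50 kHz, in ohm; must be positive.
#' @return numeric vector of impedance-index values.
#' @export
impedance_index <- function(height, z50) {
  if (any(!is.finite(z50)) || any(z50 <= 0)) stop("z50 must be positive and finite")
  if (any(!is.finite(height)) || any(height <= 0)) stop("height must be positive and finite")
  height^2 / z50
}
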