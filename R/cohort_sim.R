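#' Configuration for the synthetic cohort generator
#'
#' Assembles (and checks) the parameters of the synthetic-cohort model. The
#' defaults emulate the study population the pipeline is designed for: adult
#' women with obesity, ages 50.8 +/- 14 years truncated to 18-83, BMI >= 30
#' kg/m^2, all centrally obese, with component prevalences high BP 72.3%,
#' high TG 33.4%, low HDL 54.0%, high glucose 33.0%, medication rates
#' 54.5% / 7.9% / 16.7% (antihypertensive / lipid-lowering / antidiabetic),
#' and an index-MetS association calibrated so the waist-to-height ratio
#' discriminates MetS with an AUC near 0.66.
#'
#' The component model is a logistic link on a single standardized adiposity
#' axis (the log waist-to-height ratio) plus standardized age; intercepts
#' are calibrated by bisection at generation time so the realized component
#' prevalences match their targets in expectation.
#'
#' @param n number of subjects.
#' @param seed integer RNG seed.
#' @param age_mean,age_sd,age_range age distribution (truncated normal).
#' @param height_mean,height_sd height distribution, cm.
#' @param bmi_floor,bmi_meanlog,bmi_sdlog shifted-lognormal BMI:
#'   `bmi_floor + Lognormal(bmi_meanlog, bmi_sdlog)`; defaults give mean
#'   ~43.3 and SD ~5.9 kg/m^2 above the 30 kg/m^2 inclusion floor.
#' @param wc_intercept,wc_slope_bmi,wc_slope_height,wc_sd,wc_floor waist
#'   circumference as an affine function of BMI and height (centred at 160
#'   cm) plus noise, floored so every subject is centrally obese.
#' @param fm_mean,fm_sd,fm_range fat-mass percentage (clipped normal);
#'   FFM% = 100 - FM%.
#' @param component_prevalence named targets for the four non-anthropometric
#'   components.
#' @param med_rates named marginal medication rates (medicated subjects are
#'   a subset of the component-positive, so a flag always implies its
#'   component).
#' @param index_slope log-odds slope of each component on the standardized
#'   log-WtHR axis (the association strength; 0 gives a null cohort).
#' @param age_slope log-odds slope on standardized age.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n = 1528L, seed = 1L,
                          age_mean = 50.8, age_sd = 14, age_range = c(18, 83),
                          height_mean = 161.5, height_sd = 6,
                          bmi_floor = 30, bmi_meanlog = 2.5023, bmi_sdlog = 0.4225,
                          wc_intercept = 50.6, wc_slope_bmi = 1.6,
                          wc_slope_height = 0.3, wc_sd = 6, wc_floor = 80.1,
                          fm_mean = 50.8, fm_sd = 5.35, fm_range = c(25, 70),
                          component_prevalence = c(high_bp = 0.723,
                                                   high_tg = 0.334,
                                                   low_hdl = 0.540,
                                                   high_glucose = 0.330),
                          med_rates = c(bp = 0.545, lipid = 0.079,
                                        glucose = 0.167),
                          index_slope = 0.70, age_slope = 1.30) {
  if (n < 1L) stop("n must be at least 1")
  stopifnot(all(component_prevalence > 0), all(component_prevalence < 1),
            all(med_rates > 0), all(med_rates < 1),
            all(c("high_bp", "high_tg", "low_hdl", "high_glucose") %in%
                  names(component_prevalence)),
            all(c("bp", "lipid", "glucose") %in% names(med_rates)))
  if (med_rates[["bp"]] > component_prevalence[["high_bp"]] ||
      med_rates[["lipid"]] > component_prevalence[["high_tg"]] ||
      med_rates[["glucose"]] > component_prevalence[["high_glucose"]]) {
    stop("medication rate exceeds its component prevalence: infeasible")
  }
  structure(as.list(environment()), class = "cohort_config")
}

# Run code with a local, seeded RNG stream; the caller's RNG state is
# untouched.
with_local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Truncated-normal draw by inverse-CDF.
rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, p_hi), mean, sd)
}

# Solve the logistic intercept so mean(plogis(alpha + eta)) hits the target
# prevalence on the given linear predictor; bisection on a wide bracket.
calibrate_intercept <- function(eta, target, lo = -30, hi = 30) {
  f <- function(a) mean(stats::plogis(a + eta)) - target
  if (f(lo) > 0 || f(hi) < 0) stop("prevalence target cannot be bracketed")
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Generate a synthetic cohort
#'
#' Draws a cohort of subject records from the model described in
#' [cohort_config()]: truncated-normal ages, normal heights, shifted
#' lognormal BMI floored at the inclusion criterion, weight back-solved from
#' BMI and height, waist circumference affine in BMI and height (floored so
#' central obesity is universal), clipped-normal fat-mass percentage, and the
#' four non-anthropometric MetS components drawn from logistic models on the
#' standardized log waist-to-height ratio and standardized age, with
#' intercepts calibrated by bisection to the configured prevalences.
#' Medication flags are drawn among component-positive subjects so that a
#' flag always implies its component; continuous risk values (SBP/DBP, TG,
#' HDL-C, glucose) are drawn from truncated distributions on the side of the
#' clinical cutoff consistent with the component indicator, so the rule
#' engine reproduces the generator's labels exactly.
#'
#' @param config a [cohort_config()].
#' @return tibble in the standard subject schema, with a `truth` attribute
#'   recording the generator's latent structure (slopes, calibrated
#'   intercepts, prevalence targets) for recovery tests.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  n <- cfg$n
  with_local_seed(cfg$seed, {
    age <- rtrunc_norm(n, cfg$age_mean, cfg$age_sd,
                       cfg$age_range[1], cfg$age_range[2])
    height <- rtrunc_norm(n, cfg$height_mean, cfg$height_sd, 140, 190)
    bmi <- cfg$bmi_floor + stats::rlnorm(n, cfg$bmi_meanlog, cfg$bmi_sdlog)
    weight <- bmi * (height / 100)^2
    waist <- pmax(cfg$wc_floor,
                  cfg$wc_intercept + cfg$wc_slope_bmi * bmi +
                    cfg$wc_slope_height * (height - 160) +
                    stats::rnorm(n, 0, cfg$wc_sd))
    fm_pct <- pmin(cfg$fm_range[2],
                   pmax(cfg$fm_range[1], stats::rnorm(n, cfg$fm_mean, cfg$fm_sd)))
    ffm_pct <- 100 - fm_pct

    # latent axes: standardized log WtHR (the adiposity signal the
    # components load on) and standardized age
    zw <- as.numeric(scale(log(waist / height)))
    za <- as.numeric(scale(age))
    eta <- cfg$index_slope * zw + cfg$age_slope * za

    prev <- cfg$component_prevalence
    alphas <- vapply(prev, function(p) calibrate_intercept(eta, p), numeric(1))
    draw_comp <- function(alpha) stats::runif(n) < stats::plogis(alpha + eta)
    high_bp <- draw_comp(alphas[["high_bp"]])
    high_tg <- draw_comp(alphas[["high_tg"]])
    low_hdl <- draw_comp(alphas[["low_hdl"]])
    high_glucose <- draw_comp(alphas[["high_glucose"]])

    # medication flags: subsets of the component-positive
    draw_med <- function(comp, rate) {
      p_given <- min(rate / max(mean(comp), 1e-12), 1)
      comp & stats::runif(n) < p_given
    }
    on_bp_meds <- draw_med(high_bp, cfg$med_rates[["bp"]])
    on_lipid_meds <- draw_med(high_tg, cfg$med_rates[["lipid"]])
    on_glucose_meds <- draw_med(high_glucose, cfg$med_rates[["glucose"]])

    # continuous risk values consistent with their component indicator
    sbp <- dbp <- numeric(n)
    neg <- !high_bp
    sbp[neg] <- rtrunc_norm(sum(neg), 125, 12, 90, 130)
    dbp[neg] <- rtrunc_norm(sum(neg), 75, 7, 50, 85)
    med <- high_bp & on_bp_meds
    sbp[med] <- rtrunc_norm(sum(med), 130, 13, 90, 200)
    dbp[med] <- rtrunc_norm(sum(med), 78, 8, 50, 120)
    unc <- high_bp & !on_bp_meds        # untreated: BP itself must qualify
    route_sys <- stats::runif(n) < 0.65
    i <- unc & route_sys
    sbp[i] <- rtrunc_norm(sum(i), 130, 13, 130, 200)
    dbp[i] <- rtrunc_norm(sum(i), 78, 8, 50, 120)
    i <- unc & !route_sys
    sbp[i] <- rtrunc_norm(sum(i), 130, 13, 90, 200)
    dbp[i] <- rtrunc_norm(sum(i), 85, 6, 85, 120)

    tg <- numeric(n)
    neg <- !high_tg
    tg[neg] <- exp(rtrunc_norm(sum(neg), log(105), 0.32, log(30), log(150)))
    med <- high_tg & on_lipid_meds
    tg[med] <- exp(rtrunc_norm(sum(med), log(130), 0.40, log(30), log(600)))
    unc <- high_tg & !on_lipid_meds
    tg[unc] <- exp(rtrunc_norm(sum(unc), log(150), 0.35, log(150), log(800)))

    hdl <- numeric(n)
    hdl[low_hdl] <- rtrunc_norm(sum(low_hdl), 44, 8, 20, 50)
    hdl[!low_hdl] <- rtrunc_norm(sum(!low_hdl), 56, 10, 50, 110)

    glucose <- numeric(n)
    neg <- !high_glucose
    glucose[neg] <- rtrunc_norm(sum(neg), 87, 8, 60, 100)
    med <- high_glucose & on_glucose_meds
    glucose[med] <- rtrunc_norm(sum(med), 115, 35, 60, 350)
    unc <- high_glucose & !on_glucose_meds
    glucose[unc] <- rtrunc_norm(sum(unc), 100, 25, 100, 350)

    z50 <- rtrunc_norm(n, 480, 60, 250, 800)

    cohort <- tibble::tibble(
      id = sprintf("S%05d", seq_len(n)),
      age = age, height = height, weight = weight, waist = waist,
      fm_pct = fm_pct, ffm_pct = ffm_pct,
      sbp = sbp, dbp = dbp, tg = tg, hdl = hdl, glucose = glucose,
      on_bp_meds = on_bp_meds, on_lipid_meds = on_lipid_meds,
      on_glucose_meds = on_glucose_meds, z50 = z50
    )
    attr(cohort, "truth") <- list(
      seed = cfg$seed, n = n,
      index_slope = cfg$index_slope, age_slope = cfg$age_slope,
      component_prevalence = as.list(prev),
      med_rates = as.list(cfg$med_rates),
      calibrated_intercepts = as.list(alphas),
      components = tibble::tibble(high_bp = high_bp, high_tg = high_tg,
                                  low_hdl = low_hdl,
                                  high_glucose = high_glucose)
    )
    cohort
  })
}

#' Deterministic 12-subject rule-engine fixture
#'
#' A hand-written table of twelve subjects covering every decision branch of
#' the MetS rule engine: each component individually decisive, every
#' boundary value (waist 80 / 79.9, SBP 130 / 129, DBP 85 / 84, TG 150 /
#' 149, HDL exactly 50 and 49.9, glucose 100 / 99), and each medication
#' override, both alone and in combination. Expected component labels are
#' attached as `exp_*` columns; exactly 6 of the 12 subjects are MetS
#' positive. The table is built in code and is byte-identical across calls.
#'
#' @return tibble with the subject schema plus `exp_central_obesity`,
#'   `exp_high_bp`, `exp_high_tg`, `exp_low_hdl`, `exp_high_glucose`,
#'   `exp_n_components`, `exp_mets`.
#' @export
fixture_small <- function() {
  base <- tibble::tibble(
    id = sprintf("F%02d", 1:12),
    age = c(40, 52, 35, 60, 45, 30, 55, 48, 62, 50, 70, 58),
    height = 160, weight = 90, fm_pct = 50, ffm_pct = 50, z50 = 500,
    #        1     2    3    4   5    6    7   8   9    10   11  12
    waist = c(79.9, 90, 85, 70, 80, 70, 81, 70, 90, 70, 100, 95),
    sbp   = c(129, 135, 120, 110, 120, 120, 125, 110, 118, 112, 140, 132),
    dbp   = c(84,  80,  80,  70,  80,  85,  80,  70,  75,  70,  90,  70),
    tg    = c(149, 160, 100, 80, 100, 100, 140, 80, 80, 90, 200, 155),
    hdl   = c(50, 55, 60, 70, 60, 60, 49.9, 70, 65, 72, 40, 45),
    glucose = c(99, 90, 90, 80, 90, 90, 100, 80, 105, 80, 120, 90),
    on_bp_meds = c(F, F, F, T, F, F, F, T, F, F, F, F),
    on_lipid_meds = c(F, F, F, T, F, F, F, F, T, F, F, F),
    on_glucose_meds = c(F, F, F, T, F, F, F, F, F, T, F, F)
  )
  expected <- tibble::tibble(
    exp_central_obesity = c(F, T, T, F, T, F, T, F, T, F, T, T),
    exp_high_bp         = c(F, T, F, T, F, T, F, T, F, F, T, T),
    exp_high_tg         = c(F, T, F, T, F, F, F, F, T, F, T, T),
    exp_low_hdl         = c(F, F, F, F, F, F, T, F, F, F, T, T),
    exp_high_glucose    = c(F, F, F, T, F, F, T, F, T, T, T, F)
  )
  expected$exp_n_components <- as.integer(rowSums(expected))
  expected$exp_mets <- expected$exp_n_components >= 3L
  tibble::as_tibble(cbind(base[, c("id", "age", "height", "weight", "waist",
                                   "fm_pct", "ffm_pct", "sbp", "dbp", "tg",
                                   "hdl", "glucose", "on_bp_meds",
                                   "on_lipid_meds", "on_glucose_meds", "z50")],
                          expected))
}

#' Write a simulated cohort (and its generator truth) to disk
#'
#' @param config a [cohort_config()].
#' @param path output CSV path.
#' @param truth_path optional path for a JSON sidecar recording the
#'   generator's latent structure.
#' @return the cohort tibble, invisibly.
#' @export
run_simulate <- function(config, path, truth_path = NULL) {
  cohort <- generate_cohort(config)
  utils::write.csv(cohort, path, row.names = FALSE)
  if (!is.null(truth_path)) {
    truth <- attr(cohort, "truth")
    truth$components <- NULL  # per-subject draws stay in-memory only
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(cohort)
}
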