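#' Salt-to-blood-pressure dose-response parameters
#'
#' Meta-analytic effect of a 3 g/day reduction in dietary salt on systolic
#' blood pressure: 3.6 mmHg (95% CI 2.8-4.4) among hypertensive persons and
#' 1.8 mmHg (95% CI 1.0-2.6) among normotensive persons, with a continuous
#' linear relationship assumed between salt reduction and blood-pressure
#' reduction.
#'
#' @param hypertensive_per3g,normotensive_per3g mmHg reduction per 3 g/day
#'   salt reduction.
#' @param ci_hypertensive,ci_normotensive 95% confidence intervals, used by
#'   the probabilistic sensitivity analysis to parameterize sampling
#'   distributions.
#' @return An object of class `dose_response_params`.
#' @export
dose_response_params <- function(hypertensive_per3g = 3.6,
                                 normotensive_per3g = 1.8,
                                 ci_hypertensive = c(2.8, 4.4),
                                 ci_normotensive = c(1.0, 2.6)) {
  if (hypertensive_per3g < 0 || normotensive_per3g < 0) {
    stop_config("dose-response coefficients must be >= 0")
  }
  if (hypertensive_per3g < normotensive_per3g) {
    stop_config("hypertensive coefficient must be >= normotensive coefficient")
  }
  structure(list(hypertensive_per3g = hypertensive_per3g,
                 normotensive_per3g = normotensive_per3g,
                 ci_hypertensive = ci_hypertensive,
                 ci_normotensive = ci_normotensive),
            class = "dose_response_params")
}

#' Relative-risk equation parameters
#'
#' Log-linear hazard slopes per mmHg of systolic blood-pressure reduction,
#' by endpoint and age band: `RR = exp(-slope * dSBP)`. Default slopes are
#' ln(2)/20 per mmHg (a halving of risk per 20 mmHg) attenuated by 20% per
#' decade of age; they are an approximate, documented default and fully
#' overridable. Also carries the coefficients of the optional age-dependent
#' (optimistic) dose-response variant: dSBP = 0.0598 mmHg per mmol of salt
#' reduced plus 0.0431 mmHg per year of age above 48, with 17.1 mmol sodium
#' per gram of salt.
#'
#' @param slope_mi,slope_stroke Baseline (40-49 band) log-hazard slopes per
#'   mmHg.
#' @param age_attenuation Fractional attenuation of the slope per decade of
#'   age band above 40-49.
#' @param c_mmol,c_age,mmol_per_gram Coefficients of the age-dependent
#'   dose-response variant.
#' @return An object of class `risk_params`.
#' @export
risk_params <- function(slope_mi = log(2) / 20, slope_stroke = log(2) / 20,
                        age_attenuation = 0.2,
                        c_mmol = 0.0598, c_age = 0.0431, mmol_per_gram = 17.1) {
  if (slope_mi < 0 || slope_stroke < 0) stop_config("slopes must be >= 0")
  if (age_attenuation < 0 || age_attenuation >= 1) {
    stop_config("age_attenuation must be in [0, 1)")
  }
  structure(list(slope_mi = slope_mi, slope_stroke = slope_stroke,
                 age_attenuation = age_attenuation,
                 c_mmol = c_mmol, c_age = c_age,
                 mmol_per_gram = mmol_per_gram),
            class = "risk_params")
}

## slope(endpoint, age band), vectorized over age_band
rr_slope <- function(params, endpoint, age_band) {
  base <- switch(endpoint, mi = params$slope_mi, stroke = params$slope_stroke,
                 stop_domain("unknown endpoint: ", endpoint))
  decade <- match(age_band, AGE_BANDS) - 1
  if (anyNA(decade)) stop_domain("unknown age band")
  base * (1 - params$age_attenuation)^decade
}

#' Lagged phase-in of cardiovascular benefit
#'
#' The benefit of a blood-pressure change is not instantaneous: for stroke the
#' full risk reduction phases in linearly over three years; for MI two-thirds
#' of the benefit accrues linearly over the first three years and the
#' remainder linearly over the subsequent seven years.
#'
#' @param stroke_breaks,stroke_fracs,mi_breaks,mi_fracs Piecewise-linear
#'   breakpoints (months since the exposure change) and the cumulative
#'   fraction of full benefit reached at each.
#' @return An object of class `lag_kernel`.
#' @export
lag_kernel <- function(stroke_breaks = c(0, 36), stroke_fracs = c(0, 1),
                       mi_breaks = c(0, 36, 120), mi_fracs = c(0, 2 / 3, 1)) {
  check_kernel <- function(b, f, what) {
    if (length(b) != length(f)) stop_config(what, ": breaks/fracs length mismatch")
    if (f[1] != 0) stop_config(what, ": fraction at 0 months must be 0")
    if (is.unsorted(b, strictly = TRUE) || is.unsorted(f)) {
      stop_config(what, ": breakpoints and fractions must be non-decreasing")
    }
    if (abs(f[length(f)] - 1) > 1e-12) stop_config(what, ": final fraction must be 1")
  }
  check_kernel(stroke_breaks, stroke_fracs, "stroke kernel")
  check_kernel(mi_breaks, mi_fracs, "mi kernel")
  structure(list(stroke = list(breaks = stroke_breaks, fracs = stroke_fracs),
                 mi = list(breaks = mi_breaks, fracs = mi_fracs)),
            class = "lag_kernel")
}

#' Fraction of full benefit realized after a lag
#'
#' @param endpoint `"mi"` or `"stroke"`.
#' @param months_since_change Months elapsed since the exposure change
#'   (vectorized, must be >= 0).
#' @param kernel A [lag_kernel()].
#' @return Fractions in `[0, 1]`; saturates at 1 beyond the final breakpoint.
#' @examples
#' phase_in_fraction("mi", c(0, 36, 120))
#' phase_in_fraction("stroke", 18)
#' @export
phase_in_fraction <- function(endpoint, months_since_change, kernel = lag_kernel()) {
  k <- kernel[[match.arg(endpoint, c("mi", "stroke"))]]
  if (any(months_since_change < 0)) stop_domain("months_since_change must be >= 0")
  stats::approx(k$breaks, k$fracs, xout = months_since_change, rule = 2)$y
}

#' Individual-level blood-pressure reduction from salt reduction
#'
#' Linear in the salt reduction: `(delta_salt / 3) *` the per-3-gram
#' coefficient for the person's hypertension status.
#'
#' @param delta_salt Salt-intake reduction in g/day (>= 0, vectorized).
#' @param hypertensive Logical; `TRUE` for a hypertensive person.
#' @param params A [dose_response_params()].
#' @return Systolic blood-pressure reduction in mmHg.
#' @examples
#' sbp_reduction_individual(3, hypertensive = TRUE)   # 3.6
#' sbp_reduction_individual(3, hypertensive = FALSE)  # 1.8
#' @export
sbp_reduction_individual <- function(delta_salt, hypertensive,
                                     params = dose_response_params()) {
  if (any(delta_salt < 0)) stop_domain("delta_salt must be >= 0")
  coef <- ifelse(hypertensive, params$hypertensive_per3g,
                 params$normotensive_per3g)
  (delta_salt / 3) * coef
}

#' Cohort-average blood-pressure reduction
#'
#' Prevalence-weighted mixture of the hypertensive and normotensive
#' individual effects. The population's blood-pressure distribution is
#' represented by this binary split, which is all the dose-response
#' meta-analysis distinguishes.
#'
#' @param delta_salt Salt-intake reduction in g/day (>= 0).
#' @param prevalence Hypertension prevalence in `[0, 1]` (vectorized).
#' @param params A [dose_response_params()].
#' @return Cohort-mean systolic blood-pressure reduction in mmHg.
#' @examples
#' sbp_reduction_cohort(1, prevalence = 1 / 3)  # 0.8 mmHg per 1 g
#' @export
sbp_reduction_cohort <- function(delta_salt, prevalence,
                                 params = dose_response_params()) {
  if (any(prevalence < 0 | prevalence > 1)) {
    stop_domain("prevalence must be in [0, 1]")
  }
  prevalence * sbp_reduction_individual(delta_salt, TRUE, params) +
    (1 - prevalence) * sbp_reduction_individual(delta_salt, FALSE, params)
}

#' Age-dependent (optimistic) blood-pressure reduction
#'
#' Alternative dose-response used in the "higher salt sensitivity among the
#' elderly" sensitivity analysis: the reduction in systolic pressure is
#' `c_mmol * (delta_salt * mmol_per_gram) + c_age * max(age - 48, 0)` mmHg.
#' The age term is clamped at zero below age 48 (avoiding sign reversal) and
#' the whole effect is gated to zero when `delta_salt` is zero so that a null
#' intervention carries no benefit.
#'
#' @param delta_salt Salt-intake reduction in g/day (>= 0, vectorized).
#' @param age Age in years.
#' @param params A [risk_params()].
#' @return Systolic blood-pressure reduction in mmHg.
#' @export
sbp_reduction_optimistic <- function(delta_salt, age, params = risk_params()) {
  if (any(delta_salt < 0)) stop_domain("delta_salt must be >= 0")
  mag <- params$c_mmol * delta_salt * params$mmol_per_gram +
    params$c_age * pmax(age - 48, 0)
  ifelse(delta_salt > 0, mag, 0)
}

#' Relative risk from a blood-pressure reduction
#'
#' Log-linear in the reduction: `RR = exp(-slope(endpoint, age_band) * dSBP)`,
#' so `RR = 1` at zero reduction and RR is in `(0, 1]` for any non-negative
#' reduction.
#'
#' @param delta_sbp Systolic blood-pressure reduction in mmHg (>= 0,
#'   vectorized).
#' @param endpoint `"mi"` or `"stroke"`.
#' @param age_band One of `"40-49"`, `"50-59"`, `"60-69"`.
#' @param params A [risk_params()].
#' @return Relative risk, dimensionless.
#' @export
rr_from_sbp <- function(delta_sbp, endpoint = c("mi", "stroke"),
                        age_band = "40-49", params = risk_params()) {
  endpoint <- match.arg(endpoint)
  if (any(delta_sbp < 0)) stop_domain("delta_sbp must be >= 0")
  exp(-rr_slope(params, endpoint, age_band) * delta_sbp)
}

#' Per-cohort monthly exposure effects under a scenario
#'
#' The two-stage exposure calculation at monthly resolution. Stage one maps
#' the scenario's achieved salt reduction to each cohort's blood-pressure
#' reduction (prevalence-weighted mixture by default, or the age-dependent
#' variant when `params$sbp_mode == "optimistic"`). Stage two convolves the
#' monthly *increments* of that reduction with the endpoint's lag kernel --
#' each increment's benefit phases in over the following years -- and converts
#' the effective reduction to relative risks. The convolution over increments
#' is order-independent and linear; under a null scenario all relative risks
#' are exactly 1.
#'
#' @param scenario A `salt_scenario`.
#' @param bundle A `salt_bundle` (supplies hypertension prevalence).
#' @param params A [model_params()].
#' @param horizon Inclusive calendar-year range simulated, e.g.
#'   `c(1998, 2050)`.
#' @return An object of class `salt_effect`: matrices (months x 12 cohorts)
#'   `rr_mi`, `rr_stroke`, `dsbp_mi`, `dsbp_stroke`, the monthly achieved
#'   `salt` reduction vector, and the `year` of each month.
#' @export
effective_rr_series <- function(scenario, bundle, params = model_params(),
                                horizon = c(1998, 2050)) {
  stopifnot(inherits(scenario, "salt_scenario"))
  if (horizon[2] < horizon[1]) stop_config("empty horizon")
  if (scenario$start_year < horizon[1]) {
    stop_config("horizon starts after the scenario does")
  }
  n_months <- (horizon[2] - horizon[1] + 1) * 12
  ## calendar time at the start of each month
  t_cal <- horizon[1] + (seq_len(n_months) - 1) / 12
  salt <- salt_trajectory(scenario, t_cal)

  keys <- cohort_keys()
  prev <- align_to_keys(bundle$hypertension, "hypertension")$prevalence
  ages <- AGE_MIDPOINTS[keys$age_band]

  ## cohort dSBP trajectory d[m, c] before lagging
  d <- matrix(0, n_months, nrow(keys))
  for (c in seq_len(nrow(keys))) {
    d[, c] <- if (identical(params$sbp_mode, "optimistic")) {
      sbp_reduction_optimistic(salt, ages[c], params$risk)
    } else {
      sbp_reduction_cohort(salt, prev[c], params$dose)
    }
  }

  out <- list(salt = salt, year = floor(t_cal), months = n_months,
              scenario = scenario)
  for (endpoint in c("mi", "stroke")) {
    frac <- phase_in_fraction(endpoint, 0:(n_months - 1), params$kernel)
    eff <- matrix(0, n_months, nrow(keys))
    for (c in seq_len(nrow(keys))) {
      eff[, c] <- lag_convolve(d[, c], frac)
    }
    slope <- rr_slope(params$risk, endpoint, keys$age_band)
    rr <- exp(-sweep(eff, 2, slope, `*`))
    out[[paste0("dsbp_", endpoint)]] <- eff
    out[[paste0("rr_", endpoint)]] <- rr
  }
  structure(out, class = "salt_effect")
}

## Effective (lagged) dSBP: convolve the monthly increments of the achieved
## reduction with the phase-in fraction evaluated at the elapsed months.
## eff[m] = sum_j inc[j] * frac[m - j]; FFT convolution, O(M log M).
lag_convolve <- function(d, frac) {
  inc <- diff(c(0, d))
  if (all(inc == 0)) return(numeric(length(d)))
  eff <- convolve(inc, rev(frac), type = "open")[seq_along(d)]
  pmax(eff, 0) # guard against FFT round-off producing tiny negatives
}
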