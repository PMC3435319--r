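## Metric aliases: "mi" and "stroke" pool new and recurrent events;
## "cvd_deaths" pools MI and stroke deaths.
metric_series <- function(run, metric) {
  switch(metric,
    mi = run$new_mi + run$recurrent_mi,
    stroke = run$new_stroke + run$recurrent_stroke,
    cvd_deaths = run$mi_deaths + run$stroke_deaths,
    {
      if (!metric %in% c(TALLY_NAMES, "alive")) {
        stop_domain("unknown metric: ", metric)
      }
      run[[metric]]
    }
  )
}

## Month selector for an analysis window [w1, w2): calendar years w1..(w2-1).
window_months <- function(run, window) {
  if (length(window) != 2 || window[2] <= window[1]) {
    stop_domain("window must be an increasing (start, end) year pair")
  }
  idx <- which(run$year >= window[1] & run$year < window[2])
  if (length(idx) == 0) stop_domain("window outside the simulated horizon")
  if (window[1] < run$horizon[1] || window[2] > run$horizon[2] + 1) {
    stop_domain("window outside the simulated horizon")
  }
  idx
}

#' Mean annual events over an analysis window
#'
#' Total events over the half-open window `[window[1], window[2])` divided by
#' the window length in years (the default window covers the 30 intervention
#' years 2013-2042).
#'
#' @param run A `salt_run`.
#' @param metric `"mi"`, `"stroke"`, `"cvd_deaths"`, or any raw tally name.
#' @param window `(start, end)` calendar years, end exclusive.
#' @param by_cohort If `TRUE`, return the per-cohort vector instead of the
#'   overall total.
#' @return Events per year (scalar, or length-12 vector).
#' @export
annual_average <- function(run, metric, window = c(2013, 2043),
                           by_cohort = FALSE) {
  idx <- window_months(run, window)
  mat <- metric_series(run, metric)
  years <- length(idx) / 12
  per_cohort <- colSums(mat[idx, , drop = FALSE]) / years
  if (by_cohort) per_cohort else sum(per_cohort)
}

## Mean alive population over the window (per cohort or overall)
mean_alive <- function(run, window, by_cohort = FALSE) {
  idx <- window_months(run, window)
  per_cohort <- colMeans(run$alive[idx, , drop = FALSE])
  if (by_cohort) per_cohort else sum(per_cohort)
}

#' Annual event rate per 10,000 persons
#'
#' `10,000 * annual events / mean alive population aged 40-69` over the
#' window. The denominator is the modelled alive population (all twelve
#' cohorts, or the cohort's own population when `by_cohort = TRUE`).
#'
#' @inheritParams annual_average
#' @return Events per 10,000 persons per year.
#' @export
rate_per_10k <- function(run, metric, window = c(2013, 2043),
                         by_cohort = FALSE) {
  pop <- mean_alive(run, window, by_cohort)
  if (any(pop <= 0)) stop_domain("alive population is zero in the window")
  10000 * annual_average(run, metric, window, by_cohort) / pop
}

#' Averted events: baseline minus intervention
#'
#' Compares two runs of the same bundle and demographic stream and reports,
#' per cohort and overall, the mean annual events, the annual rates per
#' 10,000, the averted counts and rates (baseline minus intervention), and the
#' percent reduction (averted rate / baseline rate). Overall rows aggregate
#' counts exactly (the per-cohort averted counts sum to the overall row).
#'
#' @param baseline,intervention `salt_run` objects from the same bundle and
#'   horizon.
#' @param window `(start, end)` calendar years, end exclusive.
#' @param metrics Metrics to tabulate.
#' @return A data.frame of class `salt_averted` with one row per cohort and
#'   metric plus `overall` rows.
#' @export
averted <- function(baseline, intervention, window = c(2013, 2043),
                    metrics = c("mi", "stroke", "cvd_deaths")) {
  if (!identical(baseline$horizon, intervention$horizon) ||
      !identical(baseline$cohorts, intervention$cohorts)) {
    stop_domain("baseline and intervention runs must share horizon and cohorts")
  }
  keys <- baseline$cohorts
  rows <- list()
  for (metric in metrics) {
    b_n <- annual_average(baseline, metric, window, by_cohort = TRUE)
    i_n <- annual_average(intervention, metric, window, by_cohort = TRUE)
    b_pop <- mean_alive(baseline, window, by_cohort = TRUE)
    i_pop <- mean_alive(intervention, window, by_cohort = TRUE)
    b_r <- 10000 * b_n / b_pop
    i_r <- 10000 * i_n / i_pop
    cohort_rows <- data.frame(
      keys, metric = metric,
      baseline_annual = b_n, intervention_annual = i_n,
      averted_annual = b_n - i_n,
      baseline_rate_per_10k = b_r, intervention_rate_per_10k = i_r,
      averted_rate_per_10k = b_r - i_r,
      pct_averted = 100 * (b_r - i_r) / b_r
    )
    bo_r <- 10000 * sum(b_n) / sum(b_pop)
    io_r <- 10000 * sum(i_n) / sum(i_pop)
    overall <- data.frame(
      gender = "all", age_band = "all", location = "all", metric = metric,
      baseline_annual = sum(b_n), intervention_annual = sum(i_n),
      averted_annual = sum(b_n) - sum(i_n),
      baseline_rate_per_10k = bo_r, intervention_rate_per_10k = io_r,
      averted_rate_per_10k = bo_r - io_r,
      pct_averted = 100 * (bo_r - io_r) / bo_r
    )
    rows[[metric]] <- rbind(cohort_rows, overall)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "window") <- window
  class(out) <- c("salt_averted", "data.frame")
  out
}

#' Shares of averted events by location and gender
#'
#' Decomposes the per-cohort averted counts of one metric into fractions by
#' urban/rural location and by gender. Shares over each partition sum to 1;
#' with zero total averted events the shares are undefined and reported as
#' `NA` with a warning.
#'
#' @param av A `salt_averted` table.
#' @param metric One metric present in `av`.
#' @return A data.frame with columns `dimension`, `level`, `share`.
#' @export
subgroup_shares <- function(av, metric = "mi") {
  rows <- av[av$metric == metric & av$gender != "all", ]
  if (nrow(rows) == 0) stop_domain("metric not present: ", metric)
  total <- sum(rows$averted_annual)
  share_of <- function(sel) {
    if (total == 0) NA_real_ else sum(rows$averted_annual[sel]) / total
  }
  if (total == 0) warning("zero total averted events: shares undefined")
  data.frame(
    dimension = c("location", "location", "gender", "gender"),
    level = c("urban", "rural", "male", "female"),
    share = c(share_of(rows$location == "urban"),
              share_of(rows$location == "rural"),
              share_of(rows$gender == "male"),
              share_of(rows$gender == "female"))
  )
}

#' Percent change in the intervention/baseline rate ratio between two years
#'
#' The convention behind "% change in rate from 2013 to 2043": the
#' intervention-to-baseline rate ratio is 1 at the intervention start and
#' falls as the benefit phases in; the reported percentage is
#' `100 * (ratio(year_a) - ratio(year_b))`, i.e. how much lower the
#' intervention rate is, relative to baseline, in `year_b` than in `year_a`.
#'
#' @param baseline,intervention `salt_run` objects.
#' @param metric Metric name.
#' @param year_a,year_b Calendar years (both simulated).
#' @param by_cohort If `TRUE`, per-cohort percentages.
#' @return Percent (positive = rates fell relative to baseline).
#' @export
pct_rate_change <- function(baseline, intervention, metric,
                            year_a = 2013, year_b = 2043, by_cohort = FALSE) {
  year_rate <- function(run, yr) {
    r <- 10000 * annual_average(run, metric, c(yr, yr + 1), by_cohort) /
      mean_alive(run, c(yr, yr + 1), by_cohort)
    r
  }
  b_a <- year_rate(baseline, year_a); b_b <- year_rate(baseline, year_b)
  if (any(b_a == 0) || any(b_b == 0)) {
    warning("zero baseline rate: percent change undefined")
    return(if (by_cohort) rep(NA_real_, 12) else NA_real_)
  }
  i_a <- year_rate(intervention, year_a); i_b <- year_rate(intervention, year_b)
  100 * (i_a / b_a - i_b / b_b)
}
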