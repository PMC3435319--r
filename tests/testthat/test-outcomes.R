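## Build a minimal salt_run by hand so outcome arithmetic can be checked
## against closed forms.
synthetic_run <- function(events_per_month, alive_per_cohort,
                          years = 1998:2050, metric = "new_mi") {
  n_months <- length(years) * 12
  zero <- matrix(0, n_months, 12)
  run <- list(new_mi = zero, recurrent_mi = zero, new_stroke = zero,
              recurrent_stroke = zero, mi_deaths = zero, stroke_deaths = zero,
              other_deaths = zero,
              alive = matrix(rep(alive_per_cohort, each = n_months), n_months, 12),
              aged_out = zero, entrants = zero,
              year = rep(years, each = 12), horizon = range(years),
              cohorts = cohort_keys(),
              scenario = scenario_preset("baseline"), demography = TRUE)
  m <- zero
  m[] <- events_per_month
  run[[metric]] <- m
  structure(run, class = "salt_run")
}

test_that("annual averages are events per year over the window", {
  run <- synthetic_run(100, 1e5)
  expect_equal(annual_average(run, "new_mi", c(2013, 2043), by_cohort = TRUE),
               rep(1200, 12))
  expect_equal(annual_average(run, "mi"), 12 * 1200)  # pooled with recurrent
  expect_equal(annual_average(run, "stroke"), 0)
  expect_error(annual_average(run, "mi", c(2043, 2013)), "domain error")
  expect_error(annual_average(run, "mi", c(1950, 1960)), "domain error")
})

test_that("linearly growing events average to the midpoint value", {
  years <- 1998:2050
  n_months <- length(years) * 12
  run <- synthetic_run(0, 1e5, years)
  run$new_mi[] <- seq_len(n_months)  # events = month index, every cohort
  idx <- which(run$year >= 2013 & run$year < 2043)
  midpoint_annual <- mean(range(idx)) * 12  # arithmetic-series identity
  expect_equal(annual_average(run, "new_mi", c(2013, 2043), by_cohort = TRUE)[1],
               midpoint_annual)
})

test_that("rates per 10,000 use the mean alive population", {
  ## constants mirror a published-scale baseline MI rate
  run <- synthetic_run(1969 / 12, 100000 / 12)
  expect_equal(rate_per_10k(run, "new_mi", c(2013, 2043), by_cohort = TRUE)[1],
               10000 * (1969 * 12) / 100000)
  ## per-cohort: one cohort with 1969 events/yr in a population of 100000
  expect_equal(10000 * 1969 / 100000, 196.9)
  run2 <- synthetic_run(1969 / 12, 100000 * 2 / 12)
  expect_equal(rate_per_10k(run2, "new_mi", by_cohort = TRUE)[1],
               rate_per_10k(run, "new_mi", by_cohort = TRUE)[1] / 2)
  expect_equal(rate_per_10k(synthetic_run(0, 1e5), "mi"), 0)
})

test_that("averted metrics subtract intervention from baseline", {
  base <- synthetic_run(200 / 12, 1e5)
  int <- synthetic_run(150 / 12, 1e5)
  av <- averted(base, int, metrics = "new_mi")
  overall <- av[av$gender == "all", ]
  expect_equal(overall$averted_annual, 12 * 50)
  expect_equal(overall$pct_averted, 25)
  ## identical runs avert nothing
  av0 <- averted(base, base, metrics = "new_mi")
  expect_true(all(av0$averted_annual == 0))
  expect_true(all(av0$pct_averted == 0))
})

test_that("averted events decompose exactly across the twelve cohorts", {
  b <- small_bundle()
  base <- run_model(b)
  int3 <- run_model(b, scenario_preset("3g30y"))
  int1 <- run_model(b, scenario_preset("1g30y"))
  av3 <- averted(base, int3)
  for (metric in c("mi", "stroke", "cvd_deaths")) {
    rows <- av3[av3$metric == metric, ]
    expect_equal(sum(rows$averted_annual[rows$gender != "all"]),
                 rows$averted_annual[rows$gender == "all"], tolerance = 1e-12)
  }
  ## count/rate consistency per cohort
  rows <- av3[av3$metric == "mi" & av3$gender != "all", ]
  pop_b <- saltcvd:::mean_alive(base, c(2013, 2043), by_cohort = TRUE)
  pop_i <- saltcvd:::mean_alive(int3, c(2013, 2043), by_cohort = TRUE)
  reconstructed <- rows$baseline_rate_per_10k * pop_b / 1e4 -
    rows$intervention_rate_per_10k * pop_i / 1e4
  expect_equal(reconstructed, rows$averted_annual, tolerance = 1e-9)
  ## deeper reduction averts more in every cohort
  av1 <- averted(base, int1)
  for (metric in c("mi", "stroke", "cvd_deaths")) {
    a3 <- av3$averted_annual[av3$metric == metric & av3$gender != "all"]
    a1 <- av1$averted_annual[av1$metric == metric & av1$gender != "all"]
    expect_true(all(a3 > a1))
  }
})

test_that("subgroup shares partition the averted events", {
  b <- small_bundle()
  base <- run_model(b)
  int <- run_model(b, scenario_preset("3g30y"))
  av <- averted(base, int)
  for (metric in c("mi", "stroke")) {
    sh <- subgroup_shares(av, metric)
    expect_equal(sum(sh$share[sh$dimension == "location"]), 1)
    expect_equal(sum(sh$share[sh$dimension == "gender"]), 1)
    expect_true(all(sh$share >= 0 & sh$share <= 1))
  }
  ## all events in rural cohorts -> rural share 1
  base_s <- synthetic_run(0, 1e5)
  int_s <- synthetic_run(0, 1e5)
  rural <- cohort_keys()$location == "rural"
  base_s$new_mi[, rural] <- 10
  av_r <- averted(base_s, int_s, metrics = "new_mi")
  sh <- subgroup_shares(av_r, "new_mi")
  expect_equal(sh$share[sh$level == "rural"], 1)
  expect_equal(sh$share[sh$level == "urban"], 0)
  ## worked partition: 27 rural / 73 urban
  base_s$new_mi[] <- 0
  base_s$new_mi[, rural] <- 27 / sum(rural) / 12
  base_s$new_mi[, !rural] <- 73 / sum(!rural) / 12
  av_p <- averted(base_s, int_s, metrics = "new_mi")
  sh_p <- subgroup_shares(av_p, "new_mi")
  expect_equal(sh_p$share[sh_p$level == "rural"], 0.27)
  ## zero averted events: undefined shares
  expect_warning(sh0 <- subgroup_shares(averted(int_s, int_s, metrics = "new_mi"),
                                        "new_mi"), "undefined")
  expect_true(all(is.na(sh0$share)))
})

test_that("percent rate change follows the intervention/baseline convention", {
  b <- small_bundle()
  base <- run_model(b)
  ## no intervention effect -> 0%
  expect_equal(pct_rate_change(base, base, "mi"), 0)
  ## constructed 8% reduction: identical in 2013, ratio 0.92 in 2043
  years <- 1998:2050
  n_months <- length(years) * 12
  b_run <- synthetic_run(100, 1e5, years)
  i_run <- synthetic_run(100, 1e5, years)
  i_run$new_mi[b_run$year == 2043, ] <- 92
  expect_equal(pct_rate_change(b_run, i_run, "new_mi"), 8)
})

test_that("with homogeneous RR slopes all cohorts see similar percent declines", {
  b <- calibrated_paper_bundle()
  params <- model_params(risk = risk_params(age_attenuation = 0))
  base <- run_model(b, params = params)
  int <- run_model(b, scenario_preset("3g30y"), params = params)
  pct <- pct_rate_change(base, int, "mi", by_cohort = TRUE)
  expect_true(max(pct) - min(pct) < 3)
  pct_s <- pct_rate_change(base, int, "stroke", by_cohort = TRUE)
  expect_true(max(pct_s) - min(pct_s) < 3)
})
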