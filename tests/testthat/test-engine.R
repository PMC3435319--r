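test_that("annual rates convert to monthly probabilities exponentially", {
  expect_equal(rate_to_monthly_prob(0), 0)
  expect_equal(rate_to_monthly_prob(0.12), 1 - exp(-0.01))
  ## small-rate limit: p ~ rate/12 within 1%
  r <- seq(0.001, 0.1, by = 0.001)
  expect_true(all(abs(rate_to_monthly_prob(r) - r / 12) / (r / 12) < 0.01))
  expect_error(rate_to_monthly_prob(-0.1), "domain error")
})

test_that("competing risks split the cycle probability by cause rates", {
  cs <- competing_split(c(0.03, 0.01))
  p_tot <- 1 - exp(-0.04 / 12)
  expect_equal(cs$total, p_tot)
  expect_equal(cs$per_cause, c(0.75, 0.25) * p_tot)
  expect_equal(sum(cs$per_cause), cs$total)

  eq <- competing_split(c(0.2, 0.2))
  expect_equal(eq$per_cause[1], eq$per_cause[2])
  expect_equal(eq$per_cause[1], eq$total / 2)

  one <- competing_split(0.07)
  expect_equal(one$per_cause, rate_to_monthly_prob(0.07))

  z <- competing_split(c(0, 0))
  expect_equal(z$total, 0)
  expect_equal(z$per_cause, c(0, 0))
})

test_that("a step with zero rates leaves the state unchanged", {
  b <- make_toy_bundle(init = 500)
  st <- new_state_matrix(b)
  out <- step_cohorts(st, 1, b)
  expect_identical(out$state, st)
  expect_true(all(out$tallies == 0))
})

test_that("each monthly step conserves persons exactly", {
  for (seed in 1:5) {
    b <- small_bundle(seed)
    st <- new_state_matrix(b)
    eff <- effective_rr_series(scenario_preset("3g30y"), b)
    total0 <- sum(st)
    for (m in c(1, 50, 200, 400)) {
      out <- step_cohorts(st, m, b, eff)
      expect_equal(sum(out$state), total0, tolerance = 1e-12)
      st <- out$state
      total0 <- sum(st)
    }
  }
})

test_that("two-month dynamics match a hand-built transition-matrix product", {
  fmi <- 0.12; fst <- 0.06; bg <- 0.24; rmi <- 0.6; rst <- 0.3
  cfm <- 0.5; cfs <- 0.4
  b <- make_toy_bundle(first_mi = fmi, first_stroke = fst,
                       recurrent_mi = rmi, recurrent_stroke = rst,
                       cf_mi = cfm, cf_stroke = cfs, background = bg,
                       init = 1000)
  ## oracle: explicit 7x7 transition matrix, states
  ## (well, acute_mi, acute_stroke, post_mi, post_stroke, cvd_death, other_death)
  p3 <- function(r1, r2, r3) {
    tot <- r1 + r2 + r3
    (1 - exp(-tot / 12)) * c(r1, r2, r3) / tot
  }
  pw <- p3(fmi, fst, bg)
  ppm <- p3(rmi, 0, bg)[c(1, 3)]
  pps <- p3(rst, 0, bg)[c(1, 3)]
  Tm <- matrix(0, 7, 7)
  Tm[1, ] <- c(1 - sum(pw), pw[1], pw[2], 0, 0, 0, pw[3])
  Tm[2, ] <- c(0, 0, 0, 1 - cfm, 0, cfm, 0)
  Tm[3, ] <- c(0, 0, 0, 0, 1 - cfs, cfs, 0)
  Tm[4, ] <- c(0, ppm[1], 0, 1 - ppm[1] - ppm[2], 0, 0, ppm[2])
  Tm[5, ] <- c(0, 0, pps[1], 0, 1 - pps[1] - pps[2], 0, pps[2])
  Tm[6, 6] <- 1; Tm[7, 7] <- 1
  s0 <- c(1000, 0, 0, 0, 0, 0, 0)
  s1 <- drop(s0 %*% Tm)
  s2 <- drop(s1 %*% Tm)

  run <- run_model(b, horizon = c(1998, 1998), demography = FALSE)
  ## cohort 1 tallies against the oracle's flows
  expect_equal(run$new_mi[1, 1], s0[1] * pw[1], tolerance = 1e-12)
  expect_equal(run$new_mi[2, 1], s1[1] * pw[1], tolerance = 1e-12)
  expect_equal(run$recurrent_mi[2, 1], s1[4] * ppm[1], tolerance = 1e-12)
  expect_equal(run$mi_deaths[2, 1], s1[2] * cfm, tolerance = 1e-12)
  expect_equal(run$other_deaths[1, 1], s0[1] * pw[3], tolerance = 1e-12)
  ## state after two months: alive mass and the two absorbing states
  expect_equal(run$alive[2, 1], sum(s2[1:5]), tolerance = 1e-9)
  expect_equal(sum(run$mi_deaths[1:2, 1]) + sum(run$stroke_deaths[1:2, 1]),
               s2[6], tolerance = 1e-12)
  expect_equal(sum(run$other_deaths[1:2, 1]), s2[7], tolerance = 1e-12)
})

test_that("aging follows the memoryless band-flow closed form", {
  E <- 1200  # persons per stratum-year entering 40-49
  b <- make_toy_bundle(init = 0, entrants = E)
  run <- run_model(b, horizon = c(1998, 2017))
  e <- E / 12
  m <- seq_len(length(run$year))
  ## W1_m = 120e + (W0 - 120e) * (119/120)^m with W0 = 0
  closed <- 120 * e * (1 - (119 / 120)^m)
  i40 <- which(cohort_keys()$age_band == "40-49")[1]
  expect_equal(run$alive[, i40], closed, tolerance = 1e-9)
  ## convergence toward the 120e steady state
  expect_true(abs(run$alive[length(m), i40] - 120 * e) / (120 * e) < 0.2)

  ## with no entrants the whole age chain drains: 60-69 never grows and ends
  ## below where it started once the upstream bands have thinned
  b2 <- make_toy_bundle(init = 1000, entrants = 0)
  run2 <- run_model(b2, horizon = c(1998, 2002))
  i60 <- which(cohort_keys()$age_band == "60-69")[1]
  a60 <- run2$alive[, i60]
  expect_true(all(diff(a60) <= 0))
  expect_lt(a60[length(a60)], a60[1])
})

test_that("zero effect coefficients reproduce the baseline run exactly", {
  b <- small_bundle()
  base <- run_model(b, scenario_preset("baseline"))
  null_dose <- model_params(dose = dose_response_params(0, 0, c(0, 0), c(0, 0)))
  same <- run_model(b, scenario_preset("3g30y"), null_dose)
  for (nm in c("new_mi", "recurrent_mi", "new_stroke", "recurrent_stroke",
               "mi_deaths", "stroke_deaths", "other_deaths", "alive")) {
    expect_identical(base[[nm]], same[[nm]])
  }
})

test_that("salt reduction lowers cumulative events in every cohort", {
  b <- small_bundle()
  base <- run_model(b, scenario_preset("baseline"))
  int <- run_model(b, scenario_preset("3g30y"))
  expect_true(all(colSums(int$new_mi) <= colSums(base$new_mi)))
  expect_true(all(colSums(int$new_stroke) < colSums(base$new_stroke)))
  expect_true(all(colSums(int$recurrent_mi) < colSums(base$recurrent_mi)))
  expect_true(all(colSums(int$mi_deaths + int$stroke_deaths) <
                  colSums(base$mi_deaths + base$stroke_deaths)))
})

test_that("cross-morbidity switch routes post-event first events", {
  b <- small_bundle()
  on <- run_model(b, params = model_params(cross_morbidity = TRUE),
                  horizon = c(1998, 2010))
  off <- run_model(b, horizon = c(1998, 2010))
  ## with the switch on, post-MI occupants also suffer strokes
  expect_true(sum(on$new_stroke) > sum(off$new_stroke))
  ## conservation still exact
  tot0 <- sum(b$population$initial$initial_size)
  acc <- sum(on$final_state) + sum(on$aged_out) - sum(on$entrants)
  expect_equal(acc, tot0, tolerance = 1e-9 * tot0)
})
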