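test_that("salt trajectory is a capped linear ramp", {
  sc <- scenario(3, 0.1, 2013, 2043)
  expect_equal(salt_trajectory(sc, 2013), 0)
  expect_equal(salt_trajectory(sc, 2028), 1.5)
  expect_equal(salt_trajectory(sc, 2043), 3.0)
  expect_equal(salt_trajectory(sc, 2005), 0)   # before the ramp
  expect_equal(salt_trajectory(sc, 2050), 3.0) # capped at target
  ## continuity and monotonicity on a fine grid
  y <- seq(2010, 2050, by = 1 / 24)
  tr <- salt_trajectory(sc, y)
  expect_true(all(diff(tr) >= 0))
  expect_true(max(abs(diff(tr))) <= 0.1 / 24 + 1e-12)
  expect_error(scenario(3, -0.1), "configuration error")
  expect_error(scenario(3, 0.05, 2013, 2043), "not reachable")
})

test_that("individual dose-response matches the meta-analytic anchors", {
  expect_equal(sbp_reduction_individual(3, TRUE), 3.6, tolerance = 0)
  expect_equal(sbp_reduction_individual(3, FALSE), 1.8, tolerance = 0)
  expect_equal(sbp_reduction_individual(0, TRUE), 0)
  expect_equal(sbp_reduction_individual(1.5, TRUE), 1.8) # linear in salt
  expect_error(sbp_reduction_individual(-1, TRUE), "domain error")
})

test_that("cohort dose-response is the prevalence-weighted mixture", {
  ## 1 g at prevalence 1/3: (1/3)*1.2 + (2/3)*0.6 = 0.8 mmHg
  expect_equal(sbp_reduction_cohort(1, 1 / 3), 0.8)
  expect_equal(sbp_reduction_cohort(3, 1), 3.6)
  expect_equal(sbp_reduction_cohort(3, 0), 1.8)
  ## symmetry at prevalence 1/2
  expect_equal(sbp_reduction_cohort(2, 0.5),
               mean(c(sbp_reduction_individual(2, TRUE),
                      sbp_reduction_individual(2, FALSE))))
  expect_error(sbp_reduction_cohort(1, 1.2), "domain error")
})

test_that("age-dependent dose-response evaluates the published formula", {
  expect_equal(sbp_reduction_optimistic(0, 48), 0)
  expect_equal(sbp_reduction_optimistic(0, 65), 0)  # gated at zero exposure
  expect_equal(sbp_reduction_optimistic(3, 55), 0.0598 * 51.3 + 0.0431 * 7)
  expect_equal(sbp_reduction_optimistic(1, 48), 0.0598 * 17.1)
  expect_equal(sbp_reduction_optimistic(1, 40), 0.0598 * 17.1) # age clamped
})

test_that("relative risk is log-linear in the blood-pressure reduction", {
  expect_equal(rr_from_sbp(0, "mi"), 1)
  expect_equal(rr_from_sbp(20, "mi", params = risk_params(slope_mi = log(2) / 20)),
               0.5)
  ## log-linearity: doubling dSBP squares the RR
  r1 <- rr_from_sbp(3.1, "stroke", "50-59")
  r2 <- rr_from_sbp(6.2, "stroke", "50-59")
  expect_equal(r2, r1^2)
  ## age attenuation: older bands get shallower slopes, hence larger RR
  expect_true(rr_from_sbp(5, "mi", "60-69") > rr_from_sbp(5, "mi", "40-49"))
  expect_equal(rr_from_sbp(5, "mi", "50-59", risk_params(age_attenuation = 0)),
               rr_from_sbp(5, "mi", "40-49", risk_params(age_attenuation = 0)))
  expect_error(rr_from_sbp(5, "renal"), "arg")
})

test_that("lag kernels phase benefit in as specified", {
  expect_equal(phase_in_fraction("stroke", 18), 0.5)
  expect_equal(phase_in_fraction("stroke", 36), 1)
  expect_equal(phase_in_fraction("mi", 36), 2 / 3)
  expect_equal(phase_in_fraction("mi", 120), 1)
  expect_equal(phase_in_fraction("mi", 0), 0)
  expect_equal(phase_in_fraction("mi", 500), 1)  # saturates
  ## piecewise linearity inside the MI segments
  expect_equal(phase_in_fraction("mi", 18), 1 / 3)
  expect_equal(phase_in_fraction("mi", 78), 2 / 3 + (1 / 3) * (42 / 84))
  m <- 0:200
  expect_true(all(diff(phase_in_fraction("mi", m)) >= 0))
  expect_error(lag_kernel(mi_fracs = c(0.1, 2 / 3, 1)), "configuration error")
})

test_that("lagged convolution matches a direct double-loop evaluation", {
  set.seed(3)
  frac <- phase_in_fraction("mi", 0:119)
  for (rep in 1:5) {
    d <- cumsum(runif(120, 0, 0.05)) * rbinom(1, 1, 0.8)
    inc <- diff(c(0, d))
    direct <- vapply(seq_along(d), function(m) {
      sum(inc[seq_len(m)] * frac[m - seq_len(m) + 1])
    }, numeric(1))
    expect_equal(saltcvd:::lag_convolve(d, frac), direct, tolerance = 1e-10)
  }
})

test_that("effective RR series: null scenario, step saturation, monotonicity", {
  b <- small_bundle()
  ## null intervention: RR exactly 1 everywhere
  eff0 <- effective_rr_series(scenario_preset("baseline"), b)
  expect_true(all(eff0$rr_mi == 1) && all(eff0$rr_stroke == 1))

  ## near-instant step to 3 g in the first month of 2013
  step_sc <- scenario(3, 36, 2013, 2043, name = "step")
  eff <- effective_rr_series(step_sc, b)
  jump <- which(eff$salt > 0)[1]
  prev <- b$hypertension$prevalence
  full_dsbp <- sbp_reduction_cohort(3, prev)
  keys <- cohort_keys()
  ## stroke kernel saturates 36 months after the step
  m36 <- jump + 36
  expect_equal(eff$dsbp_stroke[m36, ], full_dsbp, tolerance = 1e-9)
  for (c in c(1, 6, 12)) {
    expect_equal(eff$rr_stroke[m36, c],
                 rr_from_sbp(full_dsbp[c], "stroke", keys$age_band[c]),
                 tolerance = 1e-9)
  }
  ## MI reaches 2/3 of the full effect at 36 months, all of it at 120
  expect_equal(eff$dsbp_mi[m36, ], full_dsbp * 2 / 3, tolerance = 1e-9)
  expect_equal(eff$dsbp_mi[jump + 120, ], full_dsbp, tolerance = 1e-9)

  ## under a non-decreasing ramp the RR series never increases
  eff3 <- effective_rr_series(scenario_preset("3g30y"), b)
  expect_true(all(diff(eff3$rr_mi) <= 1e-12))
  expect_true(all(diff(eff3$rr_stroke) <= 1e-12))
})

test_that("exposure is linear: a 4 g ramp is 4/3 of a 3 g ramp month by month", {
  b <- small_bundle()
  eff3 <- effective_rr_series(scenario_preset("3g30y"), b)
  eff4 <- effective_rr_series(scenario_preset("4g30y"), b)
  expect_equal(eff4$dsbp_mi, eff3$dsbp_mi * 4 / 3, tolerance = 1e-9)
  expect_equal(log(eff4$rr_stroke), log(eff3$rr_stroke) * 4 / 3,
               tolerance = 1e-9)
})
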