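STATE_NAMES <- c("well", "acute_mi", "acute_stroke", "post_mi", "post_stroke",
                 "cvd_death", "other_death")

TALLY_NAMES <- c("new_mi", "recurrent_mi", "new_stroke", "recurrent_stroke",
                 "mi_deaths", "stroke_deaths", "other_deaths")

#' Model run parameters
#'
#' Bundles the exposure-chain parameters and the engine switches:
#' `sbp_mode` selects the cohort dose-response (`"mixture"`:
#' prevalence-weighted hypertensive/normotensive split; `"optimistic"`:
#' age-dependent variant), and `cross_morbidity` (off by default) lets
#' post-MI occupants suffer first strokes and vice versa, using the first-event
#' rates.
#'
#' @param dose A [dose_response_params()].
#' @param risk A [risk_params()].
#' @param kernel A [lag_kernel()].
#' @param sbp_mode `"mixture"` or `"optimistic"`.
#' @param cross_morbidity Logical.
#' @return An object of class `model_params`.
#' @export
model_params <- function(dose = dose_response_params(), risk = risk_params(),
                         kernel = lag_kernel(),
                         sbp_mode = c("mixture", "optimistic"),
                         cross_morbidity = FALSE) {
  structure(list(dose = dose, risk = risk, kernel = kernel,
                 sbp_mode = match.arg(sbp_mode),
                 cross_morbidity = isTRUE(cross_morbidity)),
            class = "model_params")
}

#' Convert an annual rate to a monthly transition probability
#'
#' Standard actuarial conversion for a monthly cycle:
#' `p = 1 - exp(-rate / 12)`.
#'
#' @param annual_rate Events per person-year (>= 0, vectorized).
#' @return Probability in `[0, 1)`.
#' @examples
#' rate_to_monthly_prob(0.12)  # 1 - exp(-0.01)
#' @export
rate_to_monthly_prob <- function(annual_rate) {
  if (any(annual_rate < 0)) stop_domain("annual_rate must be >= 0")
  -expm1(-annual_rate / 12)
}

#' Competing-risks allocation of monthly probabilities
#'
#' Several mutually exclusive causes compete to remove a person from a state
#' within one monthly cycle. The total exit probability is
#' `1 - exp(-sum(rates) / 12)` and each cause receives a share proportional to
#' its rate, so the cause-specific probabilities always sum to the total and
#' never exceed 1.
#'
#' @param cause_rates Numeric vector of annual cause-specific rates (>= 0).
#' @return Named list with `total` (exit probability) and `per_cause`
#'   (probability per cause, same order as `cause_rates`).
#' @examples
#' competing_split(c(0.03, 0.01))
#' @export
competing_split <- function(cause_rates) {
  if (any(cause_rates < 0)) stop_domain("cause rates must be >= 0")
  tot_rate <- sum(cause_rates)
  total <- rate_to_monthly_prob(tot_rate)
  per_cause <- if (tot_rate > 0) total * cause_rates / tot_rate
               else numeric(length(cause_rates))
  list(total = total, per_cause = per_cause)
}

#' Initial state matrix for a bundle
#'
#' @param bundle A `salt_bundle`.
#' @return A 12 x 7 matrix (cohorts x states) with the initial population in
#'   the `well` state and zeros elsewhere.
#' @export
new_state_matrix <- function(bundle) {
  init <- align_to_keys(bundle$population$initial, "population")$initial_size
  m <- matrix(0, nrow = 12, ncol = length(STATE_NAMES),
              dimnames = list(cohort_label(), STATE_NAMES))
  m[, "well"] <- init
  m
}

## Monthly transition probabilities for every cohort at month m.
## All flows are computed from the start-of-month state simultaneously;
## acute states (entered the previous month) resolve fully within the cycle
## to death (case fatality) or the corresponding post-event state.
build_month_probs <- function(rates, rr_mi, rr_stroke, years_elapsed,
                              cross_morbidity = FALSE) {
  tmi <- rates$trend_mi^years_elapsed
  tst <- rates$trend_stroke^years_elapsed
  tbg <- rates$trend_background^years_elapsed
  r_fmi <- rates$first_mi_rate * tmi * rr_mi
  r_fst <- rates$first_stroke_rate * tst * rr_stroke
  r_rmi <- rates$recurrent_mi_rate * tmi * rr_mi
  r_rst <- rates$recurrent_stroke_rate * tst * rr_stroke
  r_bg <- rates$background_mortality_rate * tbg

  share <- function(tot) {
    p <- -expm1(-tot / 12)
    ifelse(tot > 0, p / tot, 0)
  }
  ## well: first MI vs first stroke vs other death
  kw <- share(r_fmi + r_fst + r_bg)
  ## post-MI: recurrent MI (optionally first stroke) vs other death
  x_st <- if (cross_morbidity) r_fst else 0
  kpm <- share(r_rmi + x_st + r_bg)
  ## post-stroke: recurrent stroke (optionally first MI) vs other death
  x_mi <- if (cross_morbidity) r_fmi else 0
  kps <- share(r_rst + x_mi + r_bg)

  list(
    w_mi = r_fmi * kw, w_st = r_fst * kw, w_bg = r_bg * kw,
    pm_mi = r_rmi * kpm, pm_st = x_st * kpm, pm_bg = r_bg * kpm,
    ps_st = r_rst * kps, ps_mi = x_mi * kps, ps_bg = r_bg * kps,
    cf_mi = rates$mi_case_fatality, cf_st = rates$stroke_case_fatality
  )
}

## One synchronous monthly update. `q` is the output of build_month_probs.
## Mass is conserved exactly: every outflow lands in another state.
step_kernel <- function(state, q) {
  W <- state[, "well"]; AM <- state[, "acute_mi"]; AS <- state[, "acute_stroke"]
  PM <- state[, "post_mi"]; PS <- state[, "post_stroke"]

  new_mi <- W * q$w_mi
  new_st <- W * q$w_st
  d_w <- W * q$w_bg
  rec_mi <- PM * q$pm_mi
  cross_st <- PM * q$pm_st
  d_pm <- PM * q$pm_bg
  rec_st <- PS * q$ps_st
  cross_mi <- PS * q$ps_mi
  d_ps <- PS * q$ps_bg
  d_am <- AM * q$cf_mi
  d_as <- AS * q$cf_st

  state[, "well"] <- W - new_mi - new_st - d_w
  state[, "acute_mi"] <- new_mi + rec_mi + cross_mi
  state[, "acute_stroke"] <- new_st + rec_st + cross_st
  state[, "post_mi"] <- PM - rec_mi - cross_st - d_pm + (AM - d_am)
  state[, "post_stroke"] <- PS - rec_st - cross_mi - d_ps + (AS - d_as)
  state[, "cvd_death"] <- state[, "cvd_death"] + d_am + d_as
  state[, "other_death"] <- state[, "other_death"] + d_w + d_pm + d_ps

  if (any(state < -1e-9)) {
    bad <- which(state < -1e-9, arr.ind = TRUE)[1, ]
    stop("internal error: negative count (over-probability) for cohort ",
         rownames(state)[bad[1]], ", state ", STATE_NAMES[bad[2]])
  }
  tallies <- cbind(new_mi = new_mi,
                   recurrent_mi = rec_mi,
                   new_stroke = new_st + cross_st,
                   recurrent_stroke = rec_st,
                   mi_deaths = d_am, stroke_deaths = d_as,
                   other_deaths = d_w + d_pm + d_ps)
  list(state = state, tallies = tallies)
}

#' Advance all cohorts by one monthly step
#'
#' From `well`, competing risks of a first MI, a first stroke (both scaled by
#' the secular trend and the scenario's relative risk) and other-cause death;
#' from the post-event states, recurrence and other-cause death; acute states
#' resolve within the cycle to cardiovascular death (case fatality) or the
#' corresponding post-event state. Mass is conserved exactly (no entrants or
#' aging here; see [age_and_enter()]).
#'
#' @param state A 12 x 7 state matrix (see [new_state_matrix()]).
#' @param month_index 1-based month within the horizon.
#' @param bundle A `salt_bundle`.
#' @param effect A `salt_effect` from [effective_rr_series()], or `NULL` for
#'   relative risks of 1.
#' @param params A [model_params()].
#' @param horizon Inclusive calendar-year range, used to apply annual trends.
#' @return List with the updated `state` and a 12 x 7 `tallies` matrix
#'   (new/recurrent MI and stroke, MI/stroke/other deaths).
#' @export
step_cohorts <- function(state, month_index, bundle, effect = NULL,
                         params = model_params(), horizon = c(1998, 2050)) {
  rates <- align_to_keys(bundle$rates, "rates")
  years_elapsed <- (month_index - 1) %/% 12
  rr_mi <- if (is.null(effect)) rep(1, 12) else effect$rr_mi[month_index, ]
  rr_st <- if (is.null(effect)) rep(1, 12) else effect$rr_stroke[month_index, ]
  q <- build_month_probs(rates, rr_mi, rr_st, years_elapsed,
                         params$cross_morbidity)
  step_kernel(state, q)
}

#' Aging flow and new entrants
#'
#' Ten-year age bands are treated as memoryless: each month a fraction 1/120
#' of every living state's occupants moves to the next age band, and 60-69
#' occupants age out of the model (tracked, not lost). New entrants are added
#' to the `well` state of the 40-49 cohorts of each gender-location group.
#'
#' @param state A 12 x 7 state matrix.
#' @param entrants_month Length-12 vector of persons entering this month
#'   (non-zero only for 40-49 cohorts).
#' @return List with the updated `state` and `aged_out`, a length-12 vector of
#'   persons leaving the model through the top of the 60-69 band this month.
#' @export
age_and_enter <- function(state, entrants_month) {
  i1 <- idx_age(1); i2 <- idx_age(2); i3 <- idx_age(3)
  aged_out <- numeric(nrow(state))
  alive_states <- c("well", "acute_mi", "acute_stroke", "post_mi", "post_stroke")
  for (s in alive_states) {
    mv1 <- state[i1, s] / 120
    mv2 <- state[i2, s] / 120
    mv3 <- state[i3, s] / 120
    state[i1, s] <- state[i1, s] - mv1
    state[i2, s] <- state[i2, s] + mv1 - mv2
    state[i3, s] <- state[i3, s] + mv2 - mv3
    aged_out[i3] <- aged_out[i3] + mv3
  }
  state[i1, "well"] <- state[i1, "well"] + entrants_month[i1]
  list(state = state, aged_out = aged_out)
}

## Monthly entrant matrix (months x 12), aligned to the canonical cohort
## order; annual counts are spread uniformly over the 12 months.
entrants_matrix <- function(bundle, horizon) {
  years <- horizon[1]:horizon[2]
  e <- bundle$population$new_entrants
  missing_years <- setdiff(years, unique(e$year))
  if (length(missing_years) > 0) {
    stop_config("entrants missing for year(s): ",
                paste(missing_years, collapse = ", "))
  }
  keys <- cohort_keys()
  n_months <- length(years) * 12
  m <- matrix(0, n_months, nrow(keys))
  for (c in which(keys$age_band == AGE_BANDS[1])) {
    sel <- e$gender == keys$gender[c] & e$location == keys$location[c]
    annual <- e$count[sel][match(years, e$year[sel])]
    m[, c] <- rep(annual / 12, each = 12)
  }
  m
}

#' Run the Markov cohort model
#'
#' Advances the twelve cohorts through the seven-state model in monthly steps
#' from January of `horizon[1]` through December of `horizon[2]`, applying
#' secular trends (compounded annually, stepped at calendar-year boundaries),
#' the scenario's lagged relative risks, competing risks, and -- unless
#' `demography = FALSE` -- aging between bands and new entrants into the
#' 40-49 band. The run is deterministic (expected-value cohort simulation):
#' identical inputs give bit-identical results, and a zero-reduction scenario
#' reproduces the baseline exactly.
#'
#' @param bundle A `salt_bundle`.
#' @param scenario A `salt_scenario` (default: no change).
#' @param params A [model_params()].
#' @param horizon Inclusive calendar-year range, default 1998-2050 (the 1998
#'   burn-in lets trends act before the 2013 intervention start).
#' @param demography If `FALSE`, disable aging and entrants (closed cohorts).
#' @return An object of class `salt_run`: monthly tally matrices
#'   (months x 12) for new/recurrent MIs and strokes and MI/stroke/other
#'   deaths, the `alive` population, `aged_out` and `entrants` flows, the
#'   final state matrix, and the calendar `year` of each month.
#' @export
run_model <- function(bundle, scenario = scenario_preset("baseline"),
                      params = model_params(), horizon = c(1998, 2050),
                      demography = TRUE) {
  validate_bundle(bundle)
  stopifnot(inherits(scenario, "salt_scenario"))
  n_months <- (horizon[2] - horizon[1] + 1) * 12
  rates <- align_to_keys(bundle$rates, "rates")
  effect <- effective_rr_series(scenario, bundle, params, horizon)

  ## precompute all monthly probabilities as (months x 12) matrices
  yrs <- (seq_len(n_months) - 1) %/% 12
  tpow <- function(tr) t(outer(tr, yrs, `^`))
  Tmi <- tpow(rates$trend_mi); Tst <- tpow(rates$trend_stroke)
  Tbg <- tpow(rates$trend_background)
  R_fmi <- sweep(Tmi, 2, rates$first_mi_rate, `*`) * effect$rr_mi
  R_fst <- sweep(Tst, 2, rates$first_stroke_rate, `*`) * effect$rr_stroke
  R_rmi <- sweep(Tmi, 2, rates$recurrent_mi_rate, `*`) * effect$rr_mi
  R_rst <- sweep(Tst, 2, rates$recurrent_stroke_rate, `*`) * effect$rr_stroke
  R_bg <- sweep(Tbg, 2, rates$background_mortality_rate, `*`)
  share <- function(tot) {
    p <- -expm1(-tot / 12)
    k <- p / tot
    k[tot <= 0] <- 0
    k
  }
  X_st <- if (params$cross_morbidity) R_fst else 0
  X_mi <- if (params$cross_morbidity) R_fmi else 0
  KW <- share(R_fmi + R_fst + R_bg)
  KPM <- share(R_rmi + X_st + R_bg)
  KPS <- share(R_rst + X_mi + R_bg)
  Q <- list(w_mi = R_fmi * KW, w_st = R_fst * KW, w_bg = R_bg * KW,
            pm_mi = R_rmi * KPM, pm_st = X_st * KPM, pm_bg = R_bg * KPM,
            ps_st = R_rst * KPS, ps_mi = X_mi * KPS, ps_bg = R_bg * KPS)
  cf_mi <- rates$mi_case_fatality
  cf_st <- rates$stroke_case_fatality

  entr <- if (demography) entrants_matrix(bundle, horizon) else
    matrix(0, n_months, 12)

  init_state <- new_state_matrix(bundle)
  tallies <- lapply(setNames(TALLY_NAMES, TALLY_NAMES),
                    function(nm) matrix(0, n_months, 12))
  alive <- matrix(0, n_months, 12)
  aged_out <- matrix(0, n_months, 12)

  has_cross <- params$cross_morbidity
  i1 <- idx_age(1); i2 <- idx_age(2); i3 <- idx_age(3)
  W <- init_state[, "well"]
  AM <- AS <- PM <- PS <- DC <- DO <- numeric(12)
  ## inlined step_kernel + age_and_enter, kept in exact arithmetic lockstep
  ## with the exported single-step operations (verified by tests)
  for (m in seq_len(n_months)) {
    new_mi <- W * Q$w_mi[m, ]
    new_st <- W * Q$w_st[m, ]
    d_w <- W * Q$w_bg[m, ]
    rec_mi <- PM * Q$pm_mi[m, ]
    cross_st <- if (has_cross) PM * Q$pm_st[m, ] else 0
    d_pm <- PM * Q$pm_bg[m, ]
    rec_st <- PS * Q$ps_st[m, ]
    cross_mi <- if (has_cross) PS * Q$ps_mi[m, ] else 0
    d_ps <- PS * Q$ps_bg[m, ]
    d_am <- AM * cf_mi
    d_as <- AS * cf_st

    W <- W - new_mi - new_st - d_w
    PM <- PM - rec_mi - cross_st - d_pm + (AM - d_am)
    PS <- PS - rec_st - cross_mi - d_ps + (AS - d_as)
    AM <- new_mi + rec_mi + cross_mi
    AS <- new_st + rec_st + cross_st
    DC <- DC + d_am + d_as
    DO <- DO + d_w + d_pm + d_ps

    tallies$new_mi[m, ] <- new_mi
    tallies$recurrent_mi[m, ] <- rec_mi
    tallies$new_stroke[m, ] <- new_st + cross_st
    tallies$recurrent_stroke[m, ] <- rec_st
    tallies$mi_deaths[m, ] <- d_am
    tallies$stroke_deaths[m, ] <- d_as
    tallies$other_deaths[m, ] <- d_w + d_pm + d_ps

    if (demography) {
      out3 <- numeric(12)
      mv1 <- W[i1] / 120; mv2 <- W[i2] / 120; mv3 <- W[i3] / 120
      W[i1] <- W[i1] - mv1; W[i2] <- W[i2] + mv1 - mv2
      W[i3] <- W[i3] + mv2 - mv3; out3[i3] <- out3[i3] + mv3
      mv1 <- AM[i1] / 120; mv2 <- AM[i2] / 120; mv3 <- AM[i3] / 120
      AM[i1] <- AM[i1] - mv1; AM[i2] <- AM[i2] + mv1 - mv2
      AM[i3] <- AM[i3] + mv2 - mv3; out3[i3] <- out3[i3] + mv3
      mv1 <- AS[i1] / 120; mv2 <- AS[i2] / 120; mv3 <- AS[i3] / 120
      AS[i1] <- AS[i1] - mv1; AS[i2] <- AS[i2] + mv1 - mv2
      AS[i3] <- AS[i3] + mv2 - mv3; out3[i3] <- out3[i3] + mv3
      mv1 <- PM[i1] / 120; mv2 <- PM[i2] / 120; mv3 <- PM[i3] / 120
      PM[i1] <- PM[i1] - mv1; PM[i2] <- PM[i2] + mv1 - mv2
      PM[i3] <- PM[i3] + mv2 - mv3; out3[i3] <- out3[i3] + mv3
      mv1 <- PS[i1] / 120; mv2 <- PS[i2] / 120; mv3 <- PS[i3] / 120
      PS[i1] <- PS[i1] - mv1; PS[i2] <- PS[i2] + mv1 - mv2
      PS[i3] <- PS[i3] + mv2 - mv3; out3[i3] <- out3[i3] + mv3
      W[i1] <- W[i1] + entr[m, i1]
      aged_out[m, ] <- out3
    }
    alive[m, ] <- W + AM + AS + PM + PS
  }
  if (any(c(W, AM, AS, PM, PS) < -1e-9)) {
    stop("internal error: negative count (over-probability)")
  }
  state <- init_state
  state[, "well"] <- W; state[, "acute_mi"] <- AM; state[, "acute_stroke"] <- AS
  state[, "post_mi"] <- PM; state[, "post_stroke"] <- PS
  state[, "cvd_death"] <- DC; state[, "other_death"] <- DO

  structure(c(tallies, list(
    alive = alive, aged_out = aged_out, entrants = entr,
    final_state = state, year = horizon[1] + yrs, horizon = horizon,
    cohorts = cohort_keys(), scenario = scenario,
    initial_population = sum(bundle$population$initial$initial_size),
    demography = demography
  )), class = "salt_run")
}

#' @export
print.salt_run <- function(x, ...) {
  cat(sprintf("<salt_run> scenario %s, %d-%d (%d months)\n",
              x$scenario$name, x$horizon[1], x$horizon[2], length(x$year)))
  cat(sprintf("  cumulative MIs %.4g, strokes %.4g, CVD deaths %.4g\n",
              sum(x$new_mi) + sum(x$recurrent_mi),
              sum(x$new_stroke) + sum(x$recurrent_stroke),
              sum(x$mi_deaths) + sum(x$stroke_deaths)))
  invisible(x)
}

#' Tidy export of a model run
#'
#' @param x A `salt_run`.
#' @param row.names,optional Ignored (S3 signature).
#' @param ... Ignored.
#' @return A long data.frame with columns `year`, `month`, `gender`,
#'   `age_band`, `location`, `metric`, `value`.
#' @export
as.data.frame.salt_run <- function(x, row.names = NULL, optional = FALSE, ...) {
  keys <- x$cohorts
  n_months <- length(x$year)
  metrics <- c(TALLY_NAMES, "alive", "aged_out", "entrants")
  out <- do.call(rbind, lapply(metrics, function(nm) {
    mat <- x[[nm]]
    data.frame(
      year = rep(x$year, times = 12),
      month = rep(rep_len(1:12, n_months), times = 12),
      gender = rep(keys$gender, each = n_months),
      age_band = rep(keys$age_band, each = n_months),
      location = rep(keys$location, each = n_months),
      metric = nm,
      value = as.vector(mat)
    )
  }))
  rownames(out) <- NULL
  out
}
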