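## Individual-level stochastic microsimulation oracle. Individuals within a
## cohort-state are exchangeable and face identical monthly probabilities, so
## sampling their joint transitions as multinomial/binomial counts is an exact
## individual-level simulation, vectorised. All probabilities are recomputed
## here from the annual rates with the standard conversions, independently of
## the engine's precomputation path. No intervention (relative risks = 1).

microsim_probs <- function(bundle, n_months) {
  r <- bundle$rates[match(
    paste(cohort_keys()$gender, cohort_keys()$age_band, cohort_keys()$location),
    paste(bundle$rates$gender, bundle$rates$age_band, bundle$rates$location)
  ), ]
  probs <- vector("list", n_months)
  for (m in seq_len(n_months)) {
    y <- (m - 1) %/% 12
    fmi <- r$first_mi_rate * r$trend_mi^y
    fst <- r$first_stroke_rate * r$trend_stroke^y
    rmi <- r$recurrent_mi_rate * r$trend_mi^y
    rst <- r$recurrent_stroke_rate * r$trend_stroke^y
    bg <- r$background_mortality_rate * r$trend_background^y
    split3 <- function(r1, r2, r3) {
      tot <- r1 + r2 + r3
      p <- 1 - exp(-tot / 12)
      k <- ifelse(tot > 0, p / tot, 0)
      cbind(r1 * k, r2 * k, r3 * k)
    }
    probs[[m]] <- list(
      w = split3(fmi, fst, bg),        # first MI, first stroke, other death
      pm = split3(rmi, 0, bg)[, c(1, 3)],  # recurrence, other death
      ps = split3(rst, 0, bg)[, c(1, 3)],
      cf_mi = r$mi_case_fatality, cf_st = r$stroke_case_fatality
    )
  }
  probs
}

## One stochastic replicate; returns months x metrics tallies summed over
## cohorts. Order of operations mirrors the engine: transitions from the
## start-of-month state, acute resolution, then aging, then entrants.
microsim_replicate <- function(bundle, probs, n_months, entrants_per_month) {
  W <- round(bundle$population$initial$initial_size)
  AM <- AS <- PM <- PS <- integer(12)
  i1 <- 1:12 %in% idx_age(1); i2 <- 1:12 %in% idx_age(2); i3 <- 1:12 %in% idx_age(3)
  out <- matrix(0, n_months, 7,
                dimnames = list(NULL, c("new_mi", "recurrent_mi", "new_stroke",
                                        "recurrent_stroke", "mi_deaths",
                                        "stroke_deaths", "other_deaths")))
  for (m in seq_len(n_months)) {
    p <- probs[[m]]
    new_mi <- new_st <- d_w <- rec_mi <- d_pm <- rec_st <- d_ps <- integer(12)
    for (c in 1:12) {
      if (W[c] > 0) {
        pw <- p$w[c, ]
        draw <- stats::rmultinom(1, W[c], c(pw, 1 - sum(pw)))
        new_mi[c] <- draw[1]; new_st[c] <- draw[2]; d_w[c] <- draw[3]
      }
      if (PM[c] > 0) {
        pp <- p$pm[c, ]
        draw <- stats::rmultinom(1, PM[c], c(pp, 1 - sum(pp)))
        rec_mi[c] <- draw[1]; d_pm[c] <- draw[2]
      }
      if (PS[c] > 0) {
        pp <- p$ps[c, ]
        draw <- stats::rmultinom(1, PS[c], c(pp, 1 - sum(pp)))
        rec_st[c] <- draw[1]; d_ps[c] <- draw[2]
      }
    }
    d_am <- stats::rbinom(12, AM, p$cf_mi)
    d_as <- stats::rbinom(12, AS, p$cf_st)

    W <- W - new_mi - new_st - d_w
    PM <- PM - rec_mi - d_pm + (AM - d_am)
    PS <- PS - rec_st - d_ps + (AS - d_as)
    AM <- new_mi + rec_mi
    AS <- new_st + rec_st

    out[m, ] <- c(sum(new_mi), sum(rec_mi), sum(new_st), sum(rec_st),
                  sum(d_am), sum(d_as), sum(d_w) + sum(d_pm) + sum(d_ps))

    ## aging: each living individual moves up a band w.p. 1/120
    age_state <- function(X) {
      mv1 <- stats::rbinom(12, X, 1 / 120) * i1
      mv2 <- stats::rbinom(12, X, 1 / 120) * i2
      mv3 <- stats::rbinom(12, X, 1 / 120) * i3
      up <- integer(12)
      up[which(i2)] <- mv1[which(i1)]
      up[which(i3)] <- mv2[which(i2)]
      X - mv1 - mv2 - mv3 + up
    }
    W <- age_state(W); AM <- age_state(AM); AS <- age_state(AS)
    PM <- age_state(PM); PS <- age_state(PS)
    W <- W + entrants_per_month * i1
  }
  out
}

microsim_tallies <- function(bundle, n_months, reps, seed, entrants_per_month = 0L) {
  probs <- microsim_probs(bundle, n_months)
  arr <- array(0, dim = c(reps, n_months, 7))
  set.seed(seed)
  for (r in seq_len(reps)) {
    arr[r, , ] <- microsim_replicate(bundle, probs, n_months, entrants_per_month)
  }
  arr
}
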