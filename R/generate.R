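#' Default settings for the synthetic input generator
#'
#' The generator emulates the statistical structure of the stratified input
#' tables the model consumes: event rates that rise steeply with age and are
#' highest among urban men for MI, multiplicative annual time trends, acute
#' case-fatality probabilities, competing background mortality, hypertension
#' prevalence in the 10-40% range (higher urban than rural, rising with age),
#' census-style population sizes with annual new entrants into the 40-49 band,
#' and a mixture of provincial salt-iodization levels including one
#' low-content province. Magnitudes are order-of-magnitude plausible for
#' India's 40-69 population; [calibrate_to_totals()] is the supported route to
#' matching stated aggregate totals.
#'
#' @param population_scale Multiplier applied to all population counts
#'   (cohort sizes, entrants, iodine strata). Use a small value for fast
#'   exploratory runs; event *rates* are unaffected.
#' @return A named list of generator settings, suitable for editing and
#'   passing to [generate_inputs()].
#' @export
default_generator_config <- function(population_scale = 1) {
  list(
    population_scale = population_scale,
    ## annual first-event rates (events/person-year) for the reference cohort
    ## (male, 40-49, urban), with age / gender / location multipliers
    first_mi = list(base = 0.006, age_mult = c(1, 2, 3.4),
                    female_mult = 0.5, rural_mult = 0.6, jitter = 0.06),
    first_stroke = list(base = 0.0012, age_mult = c(1, 2.2, 4),
                        female_mult = 0.75, rural_mult = 1.05, jitter = 0.06),
    ## recurrent-event rates as multiples of the cohort's first-event rate
    recurrent_mult = list(mi = 5, stroke = 4, jitter = 0.05),
    ## probability an acute event is fatal within its month, by age band
    case_fatality = list(mi = c(0.20, 0.24, 0.28),
                         stroke = c(0.28, 0.33, 0.38),
                         female_mult = 0.95, rural_mult = 1.15, jitter = 0.03),
    ## non-MI/non-stroke mortality (deaths/person-year), by age band
    background = list(age = c(0.005, 0.012, 0.030),
                      female_mult = 0.8, rural_mult = 1.2, jitter = 0.05),
    ## multiplicative annual trends (>1 rising, <1 declining)
    trends = list(mi = 1.018, stroke = 1.012, background = 0.985,
                  jitter = 0.004),
    ## initial cohort sizes: totals per age band split by gender and location
    population = list(age_totals = c(85e6, 55e6, 32e6),
                      male_share = 0.515, urban_share = 0.29, jitter = 0.03),
    ## persons entering the 40-49 band per calendar year
    entrants = list(base_total = 7.5e6, growth = 1.015,
                    male_share = 0.515, urban_share = 0.29,
                    years = 1998:2060),
    ## uniform sampling ranges for hypertension prevalence, sorted so
    ## prevalence rises with age within each gender-location group
    hypertension = list(urban = c(0.22, 0.40), rural = c(0.10, 0.26)),
    ## provincial iodized-salt structure; one province is iodized at low
    ## iodine content so salt reduction can push intakes below requirement
    iodine = list(n_provinces = 8, total_population = 1.05e9,
                  salt_mean = c(8.5, 12), salt_sd = c(1.5, 2.5),
                  coverage = c(0.6, 0.95), content = c(20, 35),
                  low_content = c(12, 16), low_province = 4,
                  requirement = 150, requirement_upper = 250)
  )
}

check_range <- function(x, what) {
  if (length(x) != 2 || !is.numeric(x) || anyNA(x)) {
    stop_config(what, " must be a numeric (min, max) pair")
  }
  if (x[1] > x[2]) stop_config(what, ": min > max (", x[1], " > ", x[2], ")")
  invisible(x)
}

validate_generator_config <- function(config) {
  check_range(config$hypertension$urban, "hypertension$urban")
  check_range(config$hypertension$rural, "hypertension$rural")
  for (nm in c("salt_mean", "salt_sd", "coverage", "content", "low_content")) {
    check_range(config$iodine[[nm]], paste0("iodine$", nm))
  }
  if (config$population_scale <= 0) stop_config("population_scale must be > 0")
  jitters <- c(config$first_mi$jitter, config$first_stroke$jitter,
               config$recurrent_mult$jitter, config$case_fatality$jitter,
               config$background$jitter, config$trends$jitter,
               config$population$jitter)
  if (any(jitters < 0)) stop_config("jitter values must be >= 0")
  invisible(config)
}

runif_range <- function(n, range) stats::runif(n, range[1], range[2])

#' Generate a synthetic input bundle
#'
#' Deterministically generates a complete set of model inputs (rate table,
#' population projection, hypertension prevalence, iodine strata) from a seed
#' and a generator configuration. Identical `(seed, config)` pairs yield
#' bit-identical bundles; the caller's RNG state is left untouched.
#'
#' Structural constraints are enforced by construction: first-event rates rise
#' strictly with age within every gender-location group, urban male MI rates
#' are the highest MI rates, and hypertension prevalence rises with age.
#'
#' @param seed Integer seed.
#' @param config Generator settings, see [default_generator_config()].
#' @return An object of class `salt_bundle`: a list with elements `rates`,
#'   `population` (`$initial`, `$new_entrants`), `hypertension`, `iodine` and
#'   `metadata`.
#' @examples
#' b <- generate_inputs(seed = 1)
#' b$rates[, c("gender", "age_band", "location", "first_mi_rate")]
#' @export
generate_inputs <- function(seed, config = default_generator_config()) {
  validate_generator_config(config)
  with_seed(derive_seed(seed), {
    keys <- cohort_keys()
    ai <- match(keys$age_band, AGE_BANDS)
    fem <- keys$gender == "female"
    rur <- keys$location == "rural"
    jit <- function(sd) exp(stats::rnorm(nrow(keys), 0, sd))

    strat_rate <- function(cfg) {
      r <- cfg$base * cfg$age_mult[ai] *
        ifelse(fem, cfg$female_mult, 1) *
        ifelse(rur, cfg$rural_mult, 1) * jit(cfg$jitter)
      enforce_age_increase(r)
    }
    first_mi <- strat_rate(config$first_mi)
    first_stroke <- strat_rate(config$first_stroke)
    rec_cfg <- config$recurrent_mult
    recurrent_mi <- first_mi * rec_cfg$mi * jit(rec_cfg$jitter)
    recurrent_stroke <- first_stroke * rec_cfg$stroke * jit(rec_cfg$jitter)

    cf_cfg <- config$case_fatality
    cf_adj <- ifelse(fem, cf_cfg$female_mult, 1) * ifelse(rur, cf_cfg$rural_mult, 1)
    cf_mi <- pmin(pmax(cf_cfg$mi[ai] * cf_adj * jit(cf_cfg$jitter), 0.01), 0.9)
    cf_stroke <- pmin(pmax(cf_cfg$stroke[ai] * cf_adj * jit(cf_cfg$jitter), 0.01), 0.9)

    bg_cfg <- config$background
    background <- enforce_age_increase(
      bg_cfg$age[ai] * ifelse(fem, bg_cfg$female_mult, 1) *
        ifelse(rur, bg_cfg$rural_mult, 1) * jit(bg_cfg$jitter)
    )

    tr <- config$trends
    rates <- cbind(keys, data.frame(
      first_mi_rate = first_mi,
      first_stroke_rate = first_stroke,
      recurrent_mi_rate = recurrent_mi,
      recurrent_stroke_rate = recurrent_stroke,
      mi_case_fatality = cf_mi,
      stroke_case_fatality = cf_stroke,
      background_mortality_rate = background,
      trend_mi = tr$mi * jit(tr$jitter),
      trend_stroke = tr$stroke * jit(tr$jitter),
      trend_background = tr$background * jit(tr$jitter)
    ))

    pop_cfg <- config$population
    initial <- pop_cfg$age_totals[ai] *
      ifelse(fem, 1 - pop_cfg$male_share, pop_cfg$male_share) *
      ifelse(rur, 1 - pop_cfg$urban_share, pop_cfg$urban_share) *
      jit(pop_cfg$jitter) * config$population_scale
    population <- list(
      initial = cbind(keys, data.frame(initial_size = initial)),
      new_entrants = make_entrants(config)
    )

    ht_cfg <- config$hypertension
    prev <- numeric(nrow(keys))
    for (g in GENDERS) {
      for (loc in LOCATIONS) {
        rows <- which(keys$gender == g & keys$location == loc)
        rows <- rows[order(match(keys$age_band[rows], AGE_BANDS))]
        prev[rows] <- sort(runif_range(3, ht_cfg[[loc]]))
      }
    }
    hypertension <- cbind(keys, data.frame(prevalence = prev))

    iodine <- make_iodine_strata(config)

    bundle <- structure(list(
      rates = rates,
      population = population,
      hypertension = hypertension,
      iodine = iodine,
      metadata = list(seed = seed,
                      generator_version = "saltcvd-0.1.0",
                      population_scale = config$population_scale,
                      calibration = NULL)
    ), class = "salt_bundle")
    validate_bundle(bundle)
    bundle
  })
}

## Guarantee strict increase with age inside each gender-location group
## (consecutive triplets in canonical order), regardless of jitter draws.
enforce_age_increase <- function(x) {
  for (g in seq(1, length(x), by = 3)) {
    x[g + 1] <- max(x[g + 1], x[g] * 1.01)
    x[g + 2] <- max(x[g + 2], x[g + 1] * 1.01)
  }
  x
}

make_entrants <- function(config) {
  e <- config$entrants
  grid <- expand.grid(year = e$years, gender = GENDERS, location = LOCATIONS,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  share <- ifelse(grid$gender == "male", e$male_share, 1 - e$male_share) *
    ifelse(grid$location == "urban", e$urban_share, 1 - e$urban_share)
  grid$count <- e$base_total * e$growth^(grid$year - min(e$years)) * share *
    config$population_scale
  grid[order(grid$year, grid$gender, grid$location), ]
}

make_iodine_strata <- function(config) {
  io <- config$iodine
  n <- io$n_provinces
  w <- stats::rgamma(n, shape = 5)
  content <- runif_range(n, io$content)
  coverage <- runif_range(n, io$coverage)
  low <- min(max(io$low_province, 1), n)
  content[low] <- runif_range(1, io$low_content)
  df <- data.frame(
    province = sprintf("province_%02d", seq_len(n)),
    population = io$total_population * w / sum(w) * config$population_scale,
    salt_mean_g = runif_range(n, io$salt_mean),
    salt_sd_g = runif_range(n, io$salt_sd),
    iodization_coverage = coverage,
    iodine_content_ug_per_g = content,
    requirement_ug = io$requirement,
    requirement_upper_ug = io$requirement_upper
  )
  rownames(df) <- NULL
  df
}

#' Validate an input bundle
#'
#' Checks the structural invariants every run relies on: all twelve cohorts
#' present in each stratified table, non-negative rates, case fatalities and
#' prevalences in `[0, 1]`, positive trend factors, non-negative populations,
#' and entrant counts defined for a contiguous span of years. The same
#' validator runs after generation and after loading from disk.
#'
#' @param bundle A `salt_bundle`.
#' @return Invisibly `TRUE`; errors name the offending table and row.
#' @export
validate_bundle <- function(bundle) {
  if (!inherits(bundle, "salt_bundle")) stop_format("not a salt_bundle object")
  r <- align_to_keys(bundle$rates, "rates")
  rate_cols <- c("first_mi_rate", "first_stroke_rate", "recurrent_mi_rate",
                 "recurrent_stroke_rate", "background_mortality_rate")
  for (cl in rate_cols) {
    if (any(r[[cl]] < 0) || anyNA(r[[cl]])) stop_format("rates: ", cl, " must be >= 0")
  }
  for (cl in c("mi_case_fatality", "stroke_case_fatality")) {
    if (any(r[[cl]] < 0 | r[[cl]] > 1)) stop_format("rates: ", cl, " must be in [0, 1]")
  }
  for (cl in c("trend_mi", "trend_stroke", "trend_background")) {
    if (any(r[[cl]] <= 0)) stop_format("rates: ", cl, " must be > 0")
  }
  p <- align_to_keys(bundle$population$initial, "population")
  if (any(p$initial_size < 0)) stop_format("population: initial_size must be >= 0")
  e <- bundle$population$new_entrants
  if (!all(c("year", "gender", "location", "count") %in% names(e))) {
    stop_format("entrants: missing columns")
  }
  if (any(e$count < 0)) stop_format("entrants: count must be >= 0")
  yrs <- sort(unique(e$year))
  if (!all(diff(yrs) == 1)) stop_format("entrants: years must be contiguous")
  per_year <- table(e$year)
  if (any(per_year != length(GENDERS) * length(LOCATIONS))) {
    stop_format("entrants: every year needs one row per gender x location")
  }
  h <- align_to_keys(bundle$hypertension, "hypertension")
  if (any(h$prevalence < 0 | h$prevalence > 1)) {
    stop_format("hypertension: prevalence must be in [0, 1]")
  }
  io <- bundle$iodine
  need <- c("province", "population", "salt_mean_g", "salt_sd_g",
            "iodization_coverage", "iodine_content_ug_per_g", "requirement_ug")
  if (!all(need %in% names(io))) {
    stop_format("iodine: missing columns: ",
                paste(setdiff(need, names(io)), collapse = ", "))
  }
  if (any(io$iodization_coverage < 0 | io$iodization_coverage > 1)) {
    stop_format("iodine: iodization_coverage must be in [0, 1]")
  }
  if (any(io$iodine_content_ug_per_g < 0) || any(io$population < 0)) {
    stop_format("iodine: contents and populations must be >= 0")
  }
  invisible(TRUE)
}

#' @export
print.salt_bundle <- function(x, ...) {
  cat("<salt_bundle>\n")
  cat(sprintf("  seed: %s  generator: %s\n",
              x$metadata$seed %||% "?", x$metadata$generator_version %||% "?"))
  cat(sprintf("  initial population 40-69: %.3g persons across 12 cohorts\n",
              sum(x$population$initial$initial_size)))
  cat(sprintf("  entrant years: %d-%d\n",
              min(x$population$new_entrants$year),
              max(x$population$new_entrants$year)))
  cat(sprintf("  iodine strata: %d provinces\n", nrow(x$iodine)))
  if (!is.null(x$metadata$calibration)) {
    cat("  calibrated to:",
        paste(names(x$metadata$calibration$targets), "=",
              signif(unlist(x$metadata$calibration$targets), 3),
              collapse = ", "), "\n")
  }
  invisible(x)
}
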