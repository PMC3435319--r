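## Shared fixtures, built in code. Expensive objects are memoised for the
## duration of the test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

## A bundle with a small population (rates unchanged) for fast engine runs.
small_bundle <- function(seed = 1) {
  memo(paste0("small_", seed),
       generate_inputs(seed, default_generator_config(population_scale = 1e-4)))
}

## Bundle calibrated to India-scale aggregate annual totals (8.3M MIs,
## 830k strokes, 2.0M CVD deaths over 2013-2042).
calibrated_paper_bundle <- function() {
  memo("calibrated", {
    b <- generate_inputs(11)
    calibrate_to_totals(b, list(mi = 8.3e6, stroke = 8.3e5, deaths = 2.0e6))
  })
}

## Hand-specified bundle: every cohort gets the same scalar rates, so engine
## arithmetic can be checked against closed forms. Entrants are constant per
## gender-location stratum.
make_toy_bundle <- function(first_mi = 0, first_stroke = 0,
                            recurrent_mi = 0, recurrent_stroke = 0,
                            cf_mi = 0, cf_stroke = 0, background = 0,
                            trend_mi = 1, trend_stroke = 1, trend_background = 1,
                            init = 1000, entrants = 0, prevalence = 0.25,
                            years = 1998:2060) {
  keys <- cohort_keys()
  rates <- cbind(keys, data.frame(
    first_mi_rate = first_mi, first_stroke_rate = first_stroke,
    recurrent_mi_rate = recurrent_mi, recurrent_stroke_rate = recurrent_stroke,
    mi_case_fatality = cf_mi, stroke_case_fatality = cf_stroke,
    background_mortality_rate = background,
    trend_mi = trend_mi, trend_stroke = trend_stroke,
    trend_background = trend_background
  ))
  egrid <- expand.grid(year = years, gender = GENDERS, location = LOCATIONS,
                       stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  egrid$count <- entrants
  io <- data.frame(province = "province_01", population = 1e6,
                   salt_mean_g = 10, salt_sd_g = 2,
                   iodization_coverage = 0.8, iodine_content_ug_per_g = 20,
                   requirement_ug = 150, requirement_upper_ug = 250)
  structure(list(
    rates = rates,
    population = list(initial = cbind(keys, data.frame(initial_size = init)),
                      new_entrants = egrid),
    hypertension = cbind(keys, data.frame(prevalence = prevalence)),
    iodine = io,
    metadata = list(seed = NA, generator_version = "toy")
  ), class = "salt_bundle")
}

## Sum a run's monthly tally across cohorts.
monthly_total <- function(run, metric) rowSums(run[[metric]])
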