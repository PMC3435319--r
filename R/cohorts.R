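GENDERS <- c("male", "female")
AGE_BANDS <- c("40-49", "50-59", "60-69")
LOCATIONS <- c("urban", "rural")

## Midpoint age used when a single representative age per band is needed
## (e.g. the age-dependent dose-response variant).
AGE_MIDPOINTS <- c("40-49" = 45, "50-59" = 55, "60-69" = 65)

#' The twelve modelled cohorts
#'
#' The model stratifies the Indian population aged 40-69 into twelve cohorts
#' defined by gender, ten-year age band and urban/rural location. All input
#' tables and engine outputs are aligned to the row order returned here:
#' age band varies fastest, then gender, then location, so the three age bands
#' of each gender-location group occupy consecutive rows (which is what the
#' aging flow relies on).
#'
#' @return A 12-row data.frame with columns `gender`, `age_band`, `location`.
#' @examples
#' cohort_keys()
#' @export
cohort_keys <- function() {
  k <- expand.grid(
    age_band = AGE_BANDS, gender = GENDERS, location = LOCATIONS,
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  k[, c("gender", "age_band", "location")]
}

cohort_label <- function(keys = cohort_keys()) {
  paste(keys$gender, keys$age_band, keys$location, sep = "/")
}

## Reorder a per-cohort table onto the canonical cohort_keys() row order,
## erroring with the name of the offending cohort if any row is missing.
align_to_keys <- function(df, table_name) {
  keys <- cohort_keys()
  want <- paste(keys$gender, keys$age_band, keys$location)
  if (!all(c("gender", "age_band", "location") %in% names(df))) {
    stop_format(table_name, ": missing cohort key columns (gender, age_band, location)")
  }
  have <- paste(df$gender, df$age_band, df$location)
  idx <- match(want, have)
  if (anyNA(idx)) {
    missing <- cohort_label(keys)[is.na(idx)]
    stop_format(table_name, ": missing cohort row(s): ",
                paste(missing, collapse = ", "))
  }
  out <- df[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Row indices of each age band within the canonical cohort order. Each index
## vector is aligned across the four gender-location groups, so aging moves
## idx_age(1) -> idx_age(2) -> idx_age(3) -> out of the model.
idx_age <- function(band) {
  keys <- cohort_keys()
  which(keys$age_band == AGE_BANDS[band])
}
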