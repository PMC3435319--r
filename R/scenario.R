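#' Define a salt-reduction scenario
#'
#' A scenario is a linear ramp in the per-capita reduction of dietary salt
#' intake: starting at `start_year` the achieved reduction grows by
#' `ramp_g_per_year` each year until it is capped at `target_g`. The main
#' policy scenario is a 3 g/day reduction reached over 30 years (0.1 g/year
#' from 2013 through 2043), the pace historically achieved in Finland.
#'
#' @param target_g Target reduction in g salt/day (>= 0).
#' @param ramp_g_per_year Linear ramp rate in g/day per year; defaults to
#'   `target_g / (end_year - start_year)` so the target is reached exactly at
#'   `end_year`.
#' @param start_year,end_year Calendar years over which the ramp runs.
#' @param name Optional label.
#' @return An object of class `salt_scenario`.
#' @examples
#' sc <- scenario(3)                     # 3 g over 2013-2043
#' salt_trajectory(sc, c(2013, 2028, 2043))
#' @export
scenario <- function(target_g, ramp_g_per_year = NULL,
                     start_year = 2013, end_year = 2043, name = NULL) {
  if (!is.numeric(target_g) || length(target_g) != 1 || target_g < 0) {
    stop_config("target_g must be a single non-negative number")
  }
  if (end_year < start_year) stop_config("end_year must be >= start_year")
  if (is.null(ramp_g_per_year)) {
    ramp_g_per_year <- if (target_g == 0) 0 else target_g / (end_year - start_year)
  }
  if (ramp_g_per_year < 0) stop_config("ramp_g_per_year must be >= 0")
  if (target_g > 0 && ramp_g_per_year * (end_year - start_year) < target_g - 1e-9) {
    stop_config("target not reachable: ramp_g_per_year * duration < target_g")
  }
  structure(list(
    target_g = target_g, ramp_g_per_year = ramp_g_per_year,
    start_year = start_year, end_year = end_year,
    name = name %||% sprintf("%gg_%dy", target_g, end_year - start_year)
  ), class = "salt_scenario")
}

#' Named scenario presets
#'
#' `"baseline"` is the no-change scenario (0 g); `"1g30y"`, `"3g30y"` and
#' `"4g30y"` ramp linearly to 1, 3 and 4 g/day over 2013-2043.
#'
#' @param name One of `"baseline"`, `"1g30y"`, `"3g30y"`, `"4g30y"`.
#' @return A `salt_scenario`.
#' @export
scenario_preset <- function(name = c("baseline", "1g30y", "3g30y", "4g30y")) {
  name <- match.arg(name)
  switch(name,
    baseline = scenario(0, 0, name = "baseline"),
    "1g30y" = scenario(1, name = "1g30y"),
    "3g30y" = scenario(3, 0.1, name = "3g30y"),
    "4g30y" = scenario(4, name = "4g30y")
  )
}

#' Achieved salt reduction at a calendar time
#'
#' Piecewise-linear, continuous trajectory: zero before `start_year`, growing
#' at the ramp rate, capped at the target. `year` may be fractional (the
#' engine evaluates it at monthly resolution) and is vectorized.
#'
#' @param scenario A `salt_scenario`.
#' @param year Calendar year(s), possibly fractional.
#' @return Achieved reduction in g/day, same length as `year`.
#' @export
salt_trajectory <- function(scenario, year) {
  stopifnot(inherits(scenario, "salt_scenario"))
  pmin(pmax(year - scenario$start_year, 0) * scenario$ramp_g_per_year,
       scenario$target_g)
}

#' @export
print.salt_scenario <- function(x, ...) {
  cat(sprintf("<salt_scenario> %s: %g g/day at %g g/yr over %d-%d\n",
              x$name, x$target_g, x$ramp_g_per_year, x$start_year, x$end_year))
  invisible(x)
}
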