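#' Experimental-style time series
#'
#' A GC-count or total-volume time series in days post immunization, of the
#' kind digitized from published histology time courses.
#'
#' @param times_d times in days, strictly increasing.
#' @param values non-negative observations (counts or volume in arbitrary
#'   units).
#' @param kind `"gc_count"` or `"gc_volume"`.
#' @return a data frame of class `experimental_series`.
#' @export
experimental_series <- function(times_d, values,
                                kind = c("gc_count", "gc_volume")) {
  kind <- match.arg(kind)
  stopifnot(length(times_d) == length(values))
  if (any(diff(times_d) <= 0)) stop("times must be strictly increasing")
  if (any(values < 0)) stop("values must be non-negative")
  out <- data.frame(time_days = times_d, value = values, kind = kind)
  class(out) <- c("experimental_series", "data.frame")
  out
}

#' Relative squared-error cost
#'
#' Cost of simulated values `S` with respect to data `E`:
#' `sum(((E - S) / E)^2)`. Zero iff the series match exactly, and invariant
#' under a joint rescaling of data and simulation.
#'
#' @param E data values, all strictly positive.
#' @param S matched simulated values, same length.
#' @return non-negative scalar.
#' @export
cost_relsq <- function(E, S) {
  if (length(E) != length(S)) {
    stop("E and S must have equal length")
  }
  zero <- which(E == 0)
  if (length(zero)) {
    stop("data value at index ", zero[1L],
         " is zero; the relative cost is undefined there")
  }
  sum(((E - S) / E)^2)
}

#' Match a simulated cohort curve to data times
#'
#' Linearly interpolates the simulated mean curve at the data times. Volume
#' curves are normalized to the simulated day-7 value before comparison, the
#' convention under which experimental volume series are reported.
#'
#' @param curves data frame with `time_h` and either `n_gc_mean`/`n_gc` (for
#'   counts) or `volume_mean`/`volume` (for volumes).
#' @param series an [experimental_series()].
#' @return simulated values matched to `series$time_days`.
#' @export
align_series <- function(curves, series) {
  stopifnot(inherits(series, "experimental_series"))
  kind <- series$kind[1L]
  col <- if (kind == "gc_count") {
    intersect(c("n_gc_mean", "n_gc"), names(curves))[1L]
  } else {
    intersect(c("volume_mean", "volume"), names(curves))[1L]
  }
  if (is.na(col)) stop("curves lack a column for kind '", kind, "'")
  t_h <- series$time_days * 24
  if (max(t_h) > max(curves$time_h) || min(t_h) < min(curves$time_h)) {
    stop("data times extend beyond the simulated horizon")
  }
  y <- curves[[col]]
  if (kind == "gc_volume") {
    day7 <- approx(curves$time_h, y, xout = 7 * 24)$y
    if (!is.finite(day7) || day7 == 0) {
      stop("simulated volume at day 7 is zero; cannot normalize")
    }
    y <- y / day7
  }
  approx(curves$time_h, y, xout = t_h)$y
}

#' Score a hypothesis scenario against data
#'
#' Runs the scenario, aligns the across-repeat mean curves to the data
#' times, and returns the combined relative squared-error cost
#' `cost(count) + cost(volume)` with equal weights.
#'
#' @param cfg a [hypothesis_config()].
#' @param E_count GC-count [experimental_series()].
#' @param E_volume GC-volume [experimental_series()] (normalized to day 7).
#' @param repeats cohort repeats entering the mean curve.
#' @param seed master seed.
#' @return list with `cost` (combined), `cost_count`, `cost_volume`, and the
#'   underlying `scenario_result`.
#' @export
score_scenario <- function(cfg, E_count, E_volume, repeats = 10L,
                           seed = 1L) {
  if (repeats < 1L) stop("repeats must be >= 1")
  horizon_h <- max(c(E_count$time_days, E_volume$time_days)) * 24
  times <- seq(0, max(960, horizon_h), by = 6)
  res <- run_scenario(cfg, repeats = repeats, seed = seed, times = times)
  s_count <- align_series(res$curves, E_count)
  s_vol <- align_series(res$curves, E_volume)
  cc <- cost_relsq(E_count$value, s_count)
  cv <- cost_relsq(E_volume$value, s_vol)
  list(cost = cc + cv, cost_count = cc, cost_volume = cv, result = res)
}
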