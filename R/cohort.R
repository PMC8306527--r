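#' Hill-function parameters for GC formation
#'
#' The cumulative number of GCs formed until time `t` is modeled as
#' `N(t) = Nmax * t^n / (T^n + t^n)`: `Nmax` is the maximum number of GCs
#' formed, `T` the time (h) at which half of them have appeared, and `n` the
#' Hill coefficient controlling how switch-like formation is.
#'
#' @param nmax maximum cumulative number of GCs.
#' @param t_half half-maximum time (h).
#' @param n Hill coefficient.
#' @return a list of class `hill_params`.
#' @export
hill_params <- function(nmax, t_half, n) {
  stopifnot(nmax > 0, t_half > 0, n > 0)
  structure(list(nmax = nmax, t_half = t_half, n = n), class = "hill_params")
}

#' Cumulative GC formation
#'
#' @param t time (h), non-negative.
#' @param hp a [hill_params()] object.
#' @return `Nmax * t^n / (T^n + t^n)`.
#' @export
hill_cumulative <- function(t, hp) {
  if (any(t < 0)) stop("t must be non-negative")
  hp$nmax * t^hp$n / (hp$t_half^hp$n + t^hp$n)
}

#' Schedule representative GCs over the formation window
#'
#' The formation window `[0, horizon]` is divided into `n_intervals` equal
#' intervals; one representative GC is simulated per interval and stands for
#' every GC initiated in that interval. The representative's weight is the
#' Hill-function mass of its interval, and its initiation time is drawn from
#' a Gaussian centred on the interval midpoint with standard deviation
#' `jitter_width / 2`, truncated to the interval.
#'
#' @param hp a [hill_params()] object.
#' @param n_intervals number of representative GCs (8 for formation limited
#'   to the initial phase, 15 when formation is extended).
#' @param horizon end of the formation window (h).
#' @param jitter_width width (h) of the Gaussian jitter on initiation times;
#'   0 puts every representative exactly at its interval midpoint.
#' @return a data frame of class `cohort_schedule` with columns `start`,
#'   `end`, `midpoint`, `init_time` (h) and `weight` (GCs represented).
#' @export
build_schedule <- function(hp, n_intervals = 8L, horizon = 288,
                           jitter_width = 24) {
  if (n_intervals < 1L) stop("n_intervals must be >= 1")
  stopifnot(horizon > 0, jitter_width >= 0)
  br <- seq(0, horizon, length.out = n_intervals + 1L)
  start <- br[-length(br)]
  end <- br[-1L]
  mid <- (start + end) / 2
  if (jitter_width > 0) {
    init <- rnorm(n_intervals, mean = mid, sd = jitter_width / 2)
    init <- pmin(pmax(init, start), end)
  } else {
    init <- mid
  }
  weight <- hill_cumulative(end, hp) - hill_cumulative(start, hp)
  out <- data.frame(start = start, end = end, midpoint = mid,
                    init_time = init, weight = weight)
  class(out) <- c("cohort_schedule", "data.frame")
  attr(out, "hill") <- hp
  out
}

#' GC lifetime above the counting threshold
#'
#' The lifetime of a GC is the total time during which its live B-cell count
#' stays strictly above the threshold (100 cells by default). The recorded
#' trace is treated as piecewise constant at the recording cadence; traces
#' that cross the threshold several times contribute the sum of their
#' supra-threshold episodes.
#'
#' @param run a `gc_run`, or a data frame with `time_h` and `live_cells`.
#' @param threshold live-cell count threshold.
#' @return lifetime in hours.
#' @export
gc_lifetime <- function(run, threshold = 100) {
  s <- if (inherits(run, "gc_run")) run$series else run
  stopifnot(threshold >= 0, nrow(s) >= 2L)
  dt_rec <- diff(s$time_h)
  above <- s$live_cells[-nrow(s)] > threshold
  sum(dt_rec[above])
}

#' Run a cohort of representative GCs
#'
#' Simulates one GC per schedule row with its own parameters, founder
#' specification and seed, and attaches the schedule weights and initiation
#' times. Runs are independent, so the result does not depend on execution
#' order.
#'
#' @param params_list list of [gc_params()], one per representative.
#' @param schedule a [build_schedule()] result.
#' @param founders_list list of [founder_spec()], one per representative, or
#'   a single spec recycled for all.
#' @param epitopes an `epitope_panel` shared by all representatives.
#' @param seeds integer vector of per-representative seeds.
#' @return an object of class `cohort_result`: list of runs plus a summary
#'   data frame with `init_time`, `weight`, `lifetime_h` and `plasma`.
#' @export
run_cohort <- function(params_list, schedule, founders_list = NULL,
                       epitopes = default_epitopes(), seeds) {
  n <- nrow(schedule)
  if (length(params_list) != n) {
    stop("need one gc_params per representative (", n, "), got ",
         length(params_list))
  }
  if (length(seeds) != n) {
    stop("need one seed per representative (", n, "), got ", length(seeds))
  }
  if (is.null(founders_list)) founders_list <- founder_spec("random")
  if (inherits(founders_list, "founder_spec")) {
    founders_list <- rep(list(founders_list), n)
  }
  if (length(founders_list) != n) {
    stop("need one founder_spec per representative")
  }
  runs <- vector("list", n)
  for (i in seq_len(n)) {
    runs[[i]] <- run_gc(params_list[[i]], epitopes, founders_list[[i]],
                        seed = seeds[i], init_time = schedule$init_time[i])
  }
  thr <- vapply(params_list, function(p) p$count_threshold, numeric(1))
  summary <- data.frame(
    init_time = schedule$init_time,
    weight = schedule$weight,
    lifetime_h = vapply(seq_len(n),
                        function(i) gc_lifetime(runs[[i]], thr[i]),
                        numeric(1)),
    plasma = vapply(runs, function(r) tail(r$series$cumulative_plasma, 1L),
                    numeric(1)))
  structure(list(runs = runs, schedule = schedule, summary = summary),
            class = "cohort_result")
}

# Interpolate a representative's trace at absolute time t (h post
# immunization). Before initiation and beyond the simulated span the GC
# contributes nothing.
.rep_value <- function(run, column, t_abs) {
  s <- run$series
  t_rel <- t_abs - run$init_time
  out <- numeric(length(t_rel))
  inside <- t_rel >= 0 & t_rel <= max(s$time_h)
  if (any(inside)) {
    out[inside] <- approx(s$time_h, s[[column]], xout = t_rel[inside])$y
  }
  out
}

#' Weighted number of active GCs at a time point
#'
#' Each represented GC behaves identically to its representative, so the
#' active count is the sum of interval weights over representatives whose
#' live-cell count exceeds the threshold at `t`.
#'
#' @param result a `cohort_result`.
#' @param t absolute time(s) (h post immunization).
#' @param threshold live-cell counting threshold.
#' @return weighted active-GC count, one value per `t`.
#' @export
count_active_gcs <- function(result, t, threshold = 100) {
  horizon <- max(vapply(result$runs, function(r)
    r$init_time + max(r$series$time_h), numeric(1)))
  if (any(t < 0)) {
    stop("t must be non-negative")
  }
  vapply(t, function(ti) {
    act <- vapply(result$runs, function(r) {
      .rep_value(r, "live_cells", ti) > threshold
    }, logical(1))
    sum(result$schedule$weight[act])
  }, numeric(1))
}

#' Weighted total GC volume at a time point
#'
#' Sum of the representatives' volume proxies (live-cell counts, arbitrary
#' units) weighted by the number of GCs each represents. Comparisons against
#' experimental volume data are made after normalizing both to their day-7
#' value.
#'
#' @inheritParams count_active_gcs
#' @return total volume in arbitrary units, one value per `t`.
#' @export
total_volume <- function(result, t) {
  if (any(t < 0)) stop("t must be non-negative")
  vapply(t, function(ti) {
    sum(result$schedule$weight *
          vapply(result$runs, .rep_value, numeric(1),
                 column = "volume_proxy", t_abs = ti))
  }, numeric(1))
}

#' Cohort observables on a shared time grid
#'
#' @param result a `cohort_result`.
#' @param times absolute times (h); defaults to a 6-h grid over 40 days.
#' @param threshold live-cell counting threshold.
#' @return data frame with `time_h`, `n_gc`, `volume`.
#' @export
cohort_curves <- function(result, times = seq(0, 960, by = 6),
                          threshold = 100) {
  data.frame(time_h = times,
             n_gc = count_active_gcs(result, times, threshold),
             volume = total_volume(result, times))
}

#' Aggregate repeated cohort simulations
#'
#' @param curve_list list of data frames from [cohort_curves()], one per
#'   repeat (identical time grids).
#' @return data frame with mean and standard deviation of the active-GC
#'   count and total volume at every time point.
#' @export
aggregate_repeats <- function(curve_list) {
  stopifnot(length(curve_list) >= 1L)
  times <- curve_list[[1L]]$time_h
  ngc <- sapply(curve_list, function(d) d$n_gc)
  vol <- sapply(curve_list, function(d) d$volume)
  ngc <- matrix(ngc, nrow = length(times))
  vol <- matrix(vol, nrow = length(times))
  sd0 <- function(x) if (length(x) > 1L) sd(x) else 0
  data.frame(time_h = times,
             n_gc_mean = rowMeans(ngc),
             n_gc_sd = apply(ngc, 1L, sd0),
             volume_mean = rowMeans(vol),
             volume_sd = apply(vol, 1L, sd0))
}

#' @importFrom stats approx rnorm
NULL
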