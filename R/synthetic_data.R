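#' Ground truth for synthetic GC time series
#'
#' Defines a known generating process for experimental-style GC-count and
#' volume series: GCs form according to a Hill function; each GC formed at
#' time `u` lives for `L(u)` hours, where `L` is either a fixed lifetime or
#' a map driven by exponential antigen decay (so that late GCs are
#' short-lived and the cohort's contraction phase is prolonged); observations
#' carry multiplicative lognormal noise.
#'
#' With the decay-driven model the lifetime is
#' `L(u) = lifetime_scale * log1p(A(u) / antigen_half)`, a saturating map
#' from the antigen available at initiation to the time the GC stays above
#' the counting threshold.
#'
#' @param hill a [hill_params()] object.
#' @param lifetime either `list(type = "fixed", L = <hours>)` or
#'   `list(type = "decay", decay = antigen_decay(...), lifetime_scale =
#'   <hours per log unit>, antigen_half = <portions>)`.
#' @param noise_sd standard deviation of the lognormal multiplicative noise.
#' @param times_d sampling times (days), increasing.
#' @param formation_horizon end of the formation window (h).
#' @param count_floor detection floor of the count series: sampling times
#'   whose expected count falls below it are not observable and are dropped.
#' @param volume_floor detection floor of the volume series, as a fraction
#'   of the day-7 value.
#' @return a list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(hill,
                            lifetime = list(type = "fixed", L = 300),
                            noise_sd = 0.15,
                            times_d = c(4, 5, 6, 7, 8, 10, 12, 15, 18, 21,
                                        25, 30, 35),
                            formation_horizon = 288,
                            count_floor = 1,
                            volume_floor = 0.05) {
  stopifnot(inherits(hill, "hill_params"), noise_sd >= 0)
  if (any(diff(times_d) <= 0)) stop("sampling times must be increasing")
  if (!lifetime$type %in% c("fixed", "decay")) {
    stop("lifetime$type must be 'fixed' or 'decay'")
  }
  if (lifetime$type == "decay") {
    if (is.null(lifetime$lifetime_scale)) lifetime$lifetime_scale <- 90
    if (is.null(lifetime$antigen_half)) lifetime$antigen_half <- 130
    stopifnot(inherits(lifetime$decay, "antigen_decay"))
  }
  stopifnot(count_floor >= 0, volume_floor >= 0)
  structure(list(hill = hill, lifetime = lifetime, noise_sd = noise_sd,
                 times_d = times_d, formation_horizon = formation_horizon,
                 count_floor = count_floor, volume_floor = volume_floor),
            class = "synthetic_truth")
}

# Lifetime (h) of a GC formed at time u (h).
.truth_lifetime <- function(truth, u) {
  lt <- truth$lifetime
  if (lt$type == "fixed") {
    rep(lt$L, length(u))
  } else {
    lt$lifetime_scale * log1p(antigen_at_start(u, lt$decay) / lt$antigen_half)
  }
}

# Formation-time grid and Hill mass increments used by the closed-form
# expected curves.
.formation_mass <- function(truth, du = 1) {
  u <- seq(0, truth$formation_horizon - du, by = du)
  dN <- hill_cumulative(u + du, truth$hill) - hill_cumulative(u, truth$hill)
  list(u = u + du / 2, dN = dN)
}

#' Expected active-GC count of a synthetic truth
#'
#' Closed-form expectation: the number of GCs formed at time `u` (Hill mass)
#' that are still alive at `t`, i.e. `u <= t < u + L(u)`, integrated over
#' formation times.
#'
#' @param truth a [synthetic_truth()].
#' @param t_h times (h).
#' @export
expected_count <- function(truth, t_h) {
  fm <- .formation_mass(truth)
  L <- .truth_lifetime(truth, fm$u)
  vapply(t_h, function(t) {
    sum(fm$dN[fm$u <= t & t < fm$u + L])
  }, numeric(1))
}

#' Generate a synthetic GC-count series
#'
#' Expected active counts at the sampling times, multiplied by lognormal
#' noise `exp(rnorm(0, sd))`. Deterministic given the RNG state.
#'
#' @param truth a [synthetic_truth()].
#' @return an [experimental_series()] of kind `"gc_count"`.
#' @export
generate_count_series <- function(truth) {
  mu <- expected_count(truth, truth$times_d * 24)
  keep <- mu >= truth$count_floor  # sub-detection times are not observable
  noise <- exp(rnorm(sum(keep), 0, truth$noise_sd))
  experimental_series(truth$times_d[keep], mu[keep] * noise, "gc_count")
}

#' Generate a synthetic total-volume series
#'
#' Each GC contributes a trapezoidal volume profile: a rapid rise from 0 to a
#' unit plateau over the first quarter of its lifetime (at most 2 days), the
#' plateau while the reaction is fully fed, and from half the lifetime a
#' linear decay that reaches 0 at 1.25 lifetimes - the shape a
#' volume-limited GC traces as antigen availability erodes, including the
#' residual volume it keeps after its cell count drops below the counting
#' threshold. Profiles are summed
#' over the formation mass, normalized to the day-7 value, and multiplied by
#' lognormal noise.
#'
#' @param truth a [synthetic_truth()].
#' @return an [experimental_series()] of kind `"gc_volume"` with value 1 at
#'   day 7 before noise.
#' @export
generate_volume_series <- function(truth) {
  fm <- .formation_mass(truth)
  L <- .truth_lifetime(truth, fm$u)
  vol_at <- function(t) {
    a <- t - fm$u                       # age of each formation slice
    rise <- pmin(0.25 * L, 48)
    fall_from <- 0.5 * L
    fall_end <- 1.25 * L   # residual sub-threshold volume outlives the count
    kern <- ifelse(a < 0 | a >= fall_end, 0,
                   ifelse(a < rise, a / rise,
                          ifelse(a < fall_from, 1,
                                 (fall_end - a) / (fall_end - fall_from))))
    sum(fm$dN * kern)
  }
  t_h <- truth$times_d * 24
  raw <- vapply(t_h, vol_at, numeric(1))
  day7 <- vol_at(7 * 24)
  if (day7 == 0) stop("synthetic volume at day 7 is zero; cannot normalize")
  keep <- raw / day7 >= truth$volume_floor
  noise <- exp(rnorm(sum(keep), 0, truth$noise_sd))
  experimental_series(truth$times_d[keep], raw[keep] / day7 * noise,
                      "gc_volume")
}

#' Recover Hill formation parameters from a rising phase
#'
#' Least-squares fit of the Hill function to the rising phase of a GC-count
#' series, used as a cumulative-formation proxy (deaths are assumed
#' negligible before the peak). The rising phase runs through the last
#' record high of the series, so single noisy dips do not truncate it;
#' because observation noise is multiplicative, the fit minimizes squared
#' residuals on the log scale.
#'
#' @param series an [experimental_series()] of kind `"gc_count"`.
#' @return a [hill_params()] with the fitted `(Nmax, T, n)`.
#' @export
recover_hill <- function(series) {
  stopifnot(inherits(series, "experimental_series"))
  i_peak <- max(which(series$value == cummax(series$value)))
  rising <- series[seq_len(i_peak), , drop = FALSE]
  if (nrow(rising) < 4L) {
    stop("need at least 4 points in the rising phase, got ", nrow(rising))
  }
  t_h <- rising$time_days * 24
  y <- rising$value
  nmax0 <- max(y) * 1.2
  t0 <- t_h[which.min(abs(y - max(y) / 2))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      log(y) ~ log(nmax * t_h^n / (t_half^n + t_h^n)),
      start = list(nmax = nmax0, t_half = t0, n = 2),
      lower = c(nmax = 1e-6, t_half = 1e-6, n = 0.1),
      upper = c(nmax = 100 * nmax0, t_half = 100 * max(t_h), n = 20),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop("Hill fit did not converge: ", conditionMessage(e))
    })
  cf <- coef(fit)
  hill_params(unname(cf["nmax"]), unname(cf["t_half"]), unname(cf["n"]))
}

#' @importFrom stats coef
NULL
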