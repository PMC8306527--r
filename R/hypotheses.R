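#' Exponential antigen decay
#'
#' Free immune complexes are cleared rapidly after immunization, so GCs
#' initiated later trap less antigen. The antigen loaded per FDC for a GC
#' initiated at time `t` is `A(t) = A0 * exp(-k * t)`.
#'
#' @param A0 antigen portions per FDC at the time of immunization.
#' @param k decay rate (1/h).
#' @return a list of class `antigen_decay`.
#' @export
antigen_decay <- function(A0, k) {
  stopifnot(A0 > 0, k >= 0)
  structure(list(A0 = A0, k = k), class = "antigen_decay")
}

#' Antigen-decay parameters fitted to splenic SRBC-response data
#' @export
rao_decay <- function() antigen_decay(20000, 0.026)

#' Antigen-decay parameters fitted to splenic NP-CGG-response data
#' @export
alqahtani_decay <- function() antigen_decay(2000, 0.01)

#' Antigen available to a GC initiated at a given time
#'
#' @param t_init initiation time (h post immunization), non-negative.
#' @param d an [antigen_decay()] object.
#' @return antigen portions per FDC.
#' @export
antigen_at_start <- function(t_init, d) {
  stopifnot(inherits(d, "antigen_decay"), all(t_init >= 0))
  d$A0 * exp(-d$k * t_init)
}

.h_ids <- paste0("H", 1:8)

#' Hypothesis scenario configuration
#'
#' Builds the per-scenario configuration for the eight hypotheses about the
#' origin of GC lifetime variability:
#' \describe{
#'   \item{H1}{identical GCs, formation restricted to the first 12 days.}
#'   \item{H2}{identical GCs, formation extended to day 40.}
#'   \item{H3}{initial antigen decreases exponentially with initiation time.}
#'   \item{H4}{three unrelated epitopes in unequal proportions with
#'     founder-cell specificity varying across GCs; `variant`
#'     `"early_random"` gives early GCs random founders and late GCs
#'     epitope-specific founders, `"early_specific"` the reverse.}
#'   \item{H5}{initial antigen drawn per GC from a Gaussian, independent of
#'     initiation time.}
#'   \item{H6}{antibody feedback masks FDC antigen as plasma output
#'     accumulates.}
#'   \item{H7}{founder-cell influx rate varies across GCs.}
#'   \item{H8}{founder-cell affinity (shape-space distance) varies across
#'     GCs with a single epitope.}
#' }
#'
#' @param id scenario identifier, `"H1"` to `"H8"`.
#' @param base a [gc_params()] shared baseline.
#' @param hill [hill_params()] of GC formation. Defaults: formation mostly
#'   within 12 days for all scenarios except H2, which extends formation to
#'   day 30-40.
#' @param n_intervals number of representative GCs (8; 15 for H2).
#' @param horizon end of the formation window (h).
#' @param jitter_width Gaussian jitter on initiation times (h).
#' @param decay [antigen_decay()] used by H3.
#' @param variant H4 founder-assignment variant, `"early_random"` or
#'   `"early_specific"`.
#' @param epitope_fractions H4 epitope abundances.
#' @param founder_distance shape-space distance of epitope-specific founders
#'   (H4) or the per-GC distances (H8, recycled over representatives).
#' @param antigen_mean,antigen_sd H5 Gaussian for per-GC antigen per FDC,
#'   truncated below at `antigen_min`.
#' @param antigen_min truncation floor of the H5 Gaussian (portions).
#' @param feedback_strength H6 antibody-feedback strength.
#' @param multi_epitope logical; H6 with three epitopes instead of one.
#' @param influx_multipliers H7 per-GC multipliers of the influx rate
#'   (recycled over representatives).
#' @return a list of class `hypothesis_config`.
#' @export
hypothesis_config <- function(id,
                              base = gc_params(),
                              hill = NULL,
                              n_intervals = NULL,
                              horizon = NULL,
                              jitter_width = 24,
                              decay = rao_decay(),
                              variant = c("early_random", "early_specific"),
                              epitope_fractions = c(0.6, 0.3, 0.1),
                              founder_distance = 2L,
                              antigen_mean = 3000,
                              antigen_sd = 1500,
                              antigen_min = 100,
                              feedback_strength = 0.8,
                              multi_epitope = FALSE,
                              influx_multipliers = c(0.5, 0.75, 1, 1.5, 2)) {
  if (!id %in% .h_ids) {
    stop("unknown scenario id '", id, "'; valid ids: ",
         paste(.h_ids, collapse = ", "))
  }
  variant <- match.arg(variant)
  extended <- identical(id, "H2")
  if (is.null(hill)) {
    hill <- if (extended) hill_params(120, 240, 2) else hill_params(120, 96, 2)
  }
  if (is.null(n_intervals)) n_intervals <- if (extended) 15L else 8L
  if (is.null(horizon)) horizon <- if (extended) 960 else 288
  structure(list(id = id, base = base, hill = hill,
                 n_intervals = as.integer(n_intervals), horizon = horizon,
                 jitter_width = jitter_width, decay = decay,
                 variant = variant, epitope_fractions = epitope_fractions,
                 founder_distance = founder_distance,
                 antigen_mean = antigen_mean, antigen_sd = antigen_sd,
                 antigen_min = antigen_min,
                 feedback_strength = feedback_strength,
                 multi_epitope = multi_epitope,
                 influx_multipliers = influx_multipliers),
            class = "hypothesis_config")
}

#' Per-representative parameters for a scenario
#'
#' Expands a [hypothesis_config()] into one [gc_params()] and one
#' [founder_spec()] per representative GC of a schedule, plus the epitope
#' panel shared by the cohort.
#'
#' @param cfg a [hypothesis_config()].
#' @param schedule a [build_schedule()] result with `cfg$n_intervals` rows.
#' @return list with elements `params_list`, `founders_list`, `epitopes`.
#' @export
make_per_gc_params <- function(cfg, schedule) {
  stopifnot(inherits(cfg, "hypothesis_config"))
  n <- nrow(schedule)
  base <- cfg$base
  params_list <- rep(list(base), n)
  founders_list <- rep(list(founder_spec("random")), n)
  epitopes <- default_epitopes()

  if (cfg$id == "H3") {
    ag <- antigen_at_start(schedule$init_time, cfg$decay)
    params_list <- lapply(ag, function(a) update_params(base,
                                                        antigen_per_fdc = a))
  } else if (cfg$id == "H4") {
    epitopes <- three_epitope_panel(cfg$epitope_fractions)
    half <- ceiling(n / 2)
    targets <- rep_len(seq_along(epitopes), n)
    for (i in seq_len(n)) {
      early <- i <= half
      random_here <- (cfg$variant == "early_random") == early
      founders_list[[i]] <- if (random_here) {
        # with three well-separated optima the lattice region >= 5 steps from
        # all of them is dominated by very remote points; a slightly tighter
        # naive shell keeps random founders poorly matched to every epitope
        # without making ignition impossible
        founder_spec("random", min_distance_random = 4)
      } else {
        founder_spec("epitope_specific", target_epitope = targets[i],
                     distance_from_optimum = cfg$founder_distance)
      }
    }
  } else if (cfg$id == "H5") {
    ag <- pmax(rnorm(n, cfg$antigen_mean, cfg$antigen_sd), cfg$antigen_min)
    params_list <- lapply(ag, function(a) update_params(base,
                                                        antigen_per_fdc = a))
  } else if (cfg$id == "H6") {
    if (cfg$multi_epitope) epitopes <- three_epitope_panel()
    params_list <- rep(list(update_params(base,
                                          feedback_strength =
                                            cfg$feedback_strength)), n)
  } else if (cfg$id == "H7") {
    mult <- rep_len(cfg$influx_multipliers, n)
    params_list <- lapply(mult, function(m)
      update_params(base, influx_rate = base$influx_rate * m))
  } else if (cfg$id == "H8") {
    dists <- rep_len(cfg$founder_distance, n)
    founders_list <- lapply(dists, function(d)
      founder_spec("epitope_specific", target_epitope = 1L,
                   distance_from_optimum = d))
  }
  list(params_list = params_list, founders_list = founders_list,
       epitopes = epitopes)
}

#' Run a hypothesis scenario
#'
#' Draws a schedule, expands it into per-GC parameters, simulates the
#' cohort, and repeats. Each repeat redraws the initiation-time jitter and
#' any scenario-level random parameter assignments, emulating independent
#' realizations of the same lymphoid organ.
#'
#' @param cfg a [hypothesis_config()].
#' @param repeats number of independent cohort repeats.
#' @param seed master seed; per-repeat and per-representative seeds are
#'   derived deterministically from it.
#' @param times absolute time grid (h) of the reported curves.
#' @return list of class `scenario_result` with `curves` (mean and sd of the
#'   active-GC count and total volume over repeats), `summaries` (one
#'   per-representative data frame per repeat) and `cfg`.
#' @export
run_scenario <- function(cfg, repeats = 10L, seed = 1L,
                         times = seq(0, 960, by = 6)) {
  if (repeats < 1L) stop("repeats must be >= 1")
  curve_list <- vector("list", repeats)
  summaries <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    set.seed(make_seeds(seed, 1L, stream = r))
    schedule <- build_schedule(cfg$hill, cfg$n_intervals, cfg$horizon,
                               cfg$jitter_width)
    pg <- make_per_gc_params(cfg, schedule)
    seeds <- make_seeds(seed, cfg$n_intervals, stream = 1000L + r)
    res <- run_cohort(pg$params_list, schedule, pg$founders_list,
                      pg$epitopes, seeds)
    curve_list[[r]] <- cohort_curves(res, times,
                                     cfg$base$count_threshold)
    summaries[[r]] <- res$summary
  }
  structure(list(curves = aggregate_repeats(curve_list),
                 summaries = summaries, cfg = cfg),
            class = "scenario_result")
}

.sweepable <- c("recycling_prob", "antigen_per_fdc", "feedback_strength",
                "polarization_threshold", "founder_distance",
                "mutation_prob")

#' Sweep a parameter and report normalized GC lifetimes
#'
#' For each value, simulates `repeats` single GCs, computes the mean
#' lifetime, and normalizes it by the mean lifetime at the reference
#' parameter set, so the reference point maps to 1. The reference and every
#' swept value share the same per-repeat seeds (a paired design: sweeping a
#' value equal to the reference reproduces the reference runs exactly).
#' `founder_distance` is swept through epitope-specific founder positions at
#' the requested shape-space distance; all other names are `gc_params`
#' fields. Raw per-repeat lifetimes are attached as the `"lifetimes"`
#' attribute (one column per value).
#'
#' @param name one of `recycling_prob`, `antigen_per_fdc`,
#'   `feedback_strength`, `polarization_threshold`, `founder_distance`,
#'   `mutation_prob`.
#' @param values parameter values to sweep.
#' @param base reference [gc_params()].
#' @param repeats single-GC repeats per value.
#' @param seed master seed.
#' @return data frame with `parameter`, `value`, `lifetime_mean_h`,
#'   `lifetime_sd_h`, `normalized`.
#' @export
sweep_parameter <- function(name, values, base = gc_params(), repeats = 10L,
                            seed = 1L) {
  if (!name %in% .sweepable) {
    stop("unknown sweep parameter '", name, "'; valid: ",
         paste(.sweepable, collapse = ", "))
  }
  seeds <- make_seeds(seed, repeats, stream = 0L)
  lifetimes <- function(params, founders) {
    vapply(seeds, function(s) {
      gc_lifetime(run_gc(params, founders = founders, seed = s),
                  params$count_threshold)
    }, numeric(1))
  }
  ref_lt <- lifetimes(base, founder_spec("random"))
  ref <- mean(ref_lt)
  if (ref <= 0) stop("reference parameter set yields zero mean lifetime")
  out <- data.frame(parameter = name, value = values,
                    lifetime_mean_h = NA_real_, lifetime_sd_h = NA_real_)
  raw <- matrix(NA_real_, repeats, length(values))
  for (i in seq_along(values)) {
    if (name == "founder_distance") {
      par_i <- base
      fs <- founder_spec("epitope_specific", target_epitope = 1L,
                         distance_from_optimum = values[i])
    } else {
      par_i <- do.call(update_params,
                       c(list(base), setNames(list(values[i]), name)))
      fs <- founder_spec("random")
    }
    lt <- lifetimes(par_i, fs)
    raw[, i] <- lt
    out$lifetime_mean_h[i] <- mean(lt)
    out$lifetime_sd_h[i] <- sd(lt)
  }
  out$normalized <- out$lifetime_mean_h / ref
  attr(out, "reference_lifetime_h") <- ref
  attr(out, "reference_lifetimes") <- ref_lt
  attr(out, "lifetimes") <- raw
  out
}

#' @importFrom stats setNames
NULL
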