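#' Simulate a single germinal center
#'
#' Runs the stochastic agent-based GC engine and returns the recorded time
#' series. The run is deterministic given `seed`: founder positions are
#' pre-sampled and all within-run randomness uses the same RNG stream.
#'
#' @param params a [gc_params()] object.
#' @param epitopes an `epitope_panel`; defaults to a single epitope.
#' @param founders a [founder_spec()]; defaults to random low-affinity
#'   founders.
#' @param seed integer seed for the run.
#' @param init_time initiation time of this GC (h post immunization);
#'   attached to the result and used when the GC is placed in a cohort.
#' @return an object of class `gc_run`: a list with a `series` data frame
#'   (`time_h`, `live_cells`, `volume_proxy`, `cumulative_plasma`,
#'   `antigen_remaining`, `antigen_in_cells`, `antigen_output`,
#'   `antigen_dead`, `antigen_decayed`), per-epitope plasma counts, the
#'   conserved initial
#'   antigen total, founder count, parameters, seed and `init_time`. The
#'   volume proxy is the live B-cell count in arbitrary units.
#' @export
run_gc <- function(params = gc_params(), epitopes = default_epitopes(),
                   founders = founder_spec("random"), seed = 1L,
                   init_time = 0) {
  stopifnot(inherits(params, "gc_params"))
  validate_gc_params(params)
  if (!inherits(epitopes, "epitope_panel")) {
    epitopes <- epitope_panel(epitopes)
  }
  set.seed(as.integer(seed))
  mu <- params$influx_rate * params$influx_duration
  pool_n <- max(16L, ceiling(mu + 10 * sqrt(max(mu, 1)) + 50))
  pool <- sample_founders(founders, epitopes, pool_n)
  raw <- .run_gc_cpp(params, .optima_matrix(epitopes), .fractions(epitopes),
                     pool, .default_bounds)
  series <- data.frame(time_h = raw$time_h,
                       live_cells = raw$live_cells,
                       volume_proxy = raw$live_cells,
                       cumulative_plasma = raw$cumulative_plasma,
                       antigen_remaining = raw$antigen_remaining,
                       antigen_in_cells = raw$antigen_in_cells,
                       antigen_output = raw$antigen_output,
                       antigen_dead = raw$antigen_dead,
                       antigen_decayed = raw$antigen_decayed)
  structure(list(series = series,
                 plasma_by_epitope = raw$plasma_by_epitope,
                 masked_fraction = raw$masked_fraction,
                 initial_antigen = raw$initial_antigen,
                 total_founders = raw$total_founders,
                 params = params, seed = as.integer(seed),
                 init_time = init_time),
            class = "gc_run")
}

#' @export
print.gc_run <- function(x, ...) {
  s <- x$series
  peak <- max(s$live_cells)
  lt <- gc_lifetime(x, x$params$count_threshold)
  cat("<gc_run> ", nrow(s), " records over ", max(s$time_h) / 24, " days\n",
      "  peak live cells: ", peak, "; plasma output: ",
      s$cumulative_plasma[nrow(s)], "\n",
      "  lifetime above ", x$params$count_threshold, " cells: ",
      round(lt / 24, 2), " days; init time: ", round(x$init_time / 24, 2),
      " days\n", sep = "")
  invisible(x)
}

#' Audit antigen conservation of a run
#'
#' At every recorded time, the initial antigen pool must equal the sum of the
#' portions remaining on FDCs, held by live cells, carried out by plasma
#' output, carried away by dead cells, and lost to clearance. Bookkeeping is
#' integer, so the identity is exact.
#'
#' @param run a `gc_run`.
#' @return logical vector, one entry per recorded time.
#' @export
antigen_conserved <- function(run) {
  s <- run$series
  total <- s$antigen_remaining + s$antigen_in_cells + s$antigen_output +
    s$antigen_dead + s$antigen_decayed
  total == run$initial_antigen
}

#' Simulate one Tfh contact group
#'
#' Reference implementation of the selection rule for one group of B cells
#' sharing a Tfh cell over a full contact: at each timestep the Tfh polarizes
#' to the member with the most collected antigen (ties broken uniformly at
#' random), and a member is selected if it accumulated at least
#' `polarization_threshold` hours of polarization by the end of the
#' `tfh_contact_duration` contact.
#'
#' @param antigens portions collected by each B cell in the group.
#' @param params a [gc_params()] (uses `dt`, `tfh_contact_duration`,
#'   `polarization_threshold`).
#' @return logical vector: selected or not, per cell.
#' @export
simulate_tfh_contact <- function(antigens, params = gc_params()) {
  n <- length(antigens)
  stopifnot(n >= 1, all(antigens >= 1))
  steps <- round(params$tfh_contact_duration / params$dt)
  pol <- numeric(n)
  for (s in seq_len(steps)) {
    top <- which(antigens == max(antigens))
    win <- if (length(top) == 1L) top else sample(top, 1L)
    pol[win] <- pol[win] + params$dt
  }
  pol >= params$polarization_threshold - 1e-9
}
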