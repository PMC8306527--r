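# Small parameter sets for fast engine tests: short runs, reduced influx.
fast_params <- function(...) {
  args <- list(duration = 120, record_every = 6)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(gc_params, args)
}

# A hand-built gc_run with a prescribed live-cell trace, for cohort
# arithmetic tests that need exact step traces.
fake_run <- function(times_h, live, init_time = 0, threshold = 100L) {
  series <- data.frame(time_h = times_h, live_cells = live,
                       volume_proxy = live,
                       cumulative_plasma = cumsum(live > 0),
                       antigen_remaining = 0, antigen_in_cells = 0,
                       antigen_output = 0, antigen_dead = 0,
                       antigen_decayed = 0)
  structure(list(series = series, plasma_by_epitope = 0,
                 masked_fraction = 0, initial_antigen = 0,
                 total_founders = 0,
                 params = gc_params(count_threshold = threshold),
                 seed = 0L, init_time = init_time),
            class = "gc_run")
}
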