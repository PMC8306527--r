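# Serialization and seed management. Times are hours internally and days in
# user-facing CSVs (the experimental data are reported in days post
# immunization).

#' Deterministic child seeds
#'
#' Derives a vector of child seeds from a master seed with a splittable
#' integer-mixing scheme, so that adding repeats or representatives never
#' changes the seeds of earlier ones.
#'
#' @param master master seed (integer).
#' @param n number of child seeds.
#' @param stream stream index separating independent uses of the same
#'   master seed.
#' @return integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @export
make_seeds <- function(master, n, stream = 0L) {
  m <- 2147483647
  vapply(seq_len(n), function(i) {
    x <- (as.numeric(master) * 48271 + as.numeric(stream) * 16807 +
            i * 69621) %% m
    x <- (x * 16807) %% m
    as.integer(x + 1)
  }, integer(1))
}

#' Write / read an experimental-style series as CSV
#'
#' Columns `time_days`, `value`, `kind`.
#'
#' @param series an [experimental_series()].
#' @param path file path.
#' @export
write_series_csv <- function(series, path) {
  stopifnot(inherits(series, "experimental_series"))
  write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_days", "value", "kind")
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    stop("series CSV lacks column(s): ", paste(missing, collapse = ", "))
  }
  experimental_series(d$time_days, d$value, d$kind[1L])
}

#' Write a single GC run as CSV plus JSON sidecar
#'
#' The CSV holds the recorded time series; the sidecar records parameters,
#' seed and initiation time so the run can be reproduced exactly.
#'
#' @param run a `gc_run`.
#' @param prefix output path prefix; writes `<prefix>.csv` and
#'   `<prefix>.json`.
#' @export
write_gc_run <- function(run, prefix) {
  stopifnot(inherits(run, "gc_run"))
  csv <- paste0(prefix, ".csv")
  side <- paste0(prefix, ".json")
  write.csv(run$series[, c("time_h", "live_cells", "volume_proxy",
                           "cumulative_plasma", "antigen_remaining")],
            csv, row.names = FALSE)
  jsonlite::write_json(list(params = unclass(run$params), seed = run$seed,
                            init_time = run$init_time,
                            initial_antigen = run$initial_antigen),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, side))
}

#' Write aggregated cohort curves as tidy CSV
#'
#' Columns `time_d`, `n_gc_mean`, `n_gc_sd`, `volume_mean`, `volume_sd`.
#'
#' @param agg output of [aggregate_repeats()] or the `curves` element of a
#'   `scenario_result`.
#' @param path file path.
#' @export
write_cohort_csv <- function(agg, path) {
  out <- data.frame(time_d = agg$time_h / 24,
                    n_gc_mean = agg$n_gc_mean, n_gc_sd = agg$n_gc_sd,
                    volume_mean = agg$volume_mean,
                    volume_sd = agg$volume_sd)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Run manifest
#'
#' Writes a JSON manifest tying a scenario run to its configuration, seeds
#' and output files.
#'
#' @param path output path.
#' @param scenario_id scenario identifier.
#' @param seed master seed.
#' @param files character vector of output paths.
#' @param config optional configuration list echoed into the manifest.
#' @export
write_manifest <- function(path, scenario_id, seed, files, config = NULL) {
  jsonlite::write_json(
    list(scenario = scenario_id, seed = seed,
         version = as.character(utils::packageVersion("gcohort")),
         outputs = files, config = config),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
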