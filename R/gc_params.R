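#' Parameters of a single germinal center simulation
#'
#' Complete parameterization of one GC run. Defaults reproduce the reference
#' reaction: founder B cells enter at 2 cells/h for 96 h and divide 6 times
#' before acquiring a light-zone phenotype; 200 FDCs each carry 3000 antigen
#' portions; unselected LZ cells collect antigen for 0.7 h with a success
#' probability set by BCR affinity and antigen availability; collectors
#' contact one of 250 Tfh cells for 36 min and are selected if they hold the
#' Tfh's polarization for at least 30 min; selected cells divide a number of
#' times determined by the antigen they collected, 72% of divisions being
#' asymmetric with one daughter retaining all antigen; antigen-retaining
#' terminal daughters leave as plasma cells and the rest recycle to the light
#' zone with probability `recycling_prob`.
#'
#' @param dt timestep (h).
#' @param duration simulated span of one GC (h); default 40 days.
#' @param influx_rate founder-cell arrival rate (cells/h).
#' @param influx_duration duration of founder influx (h).
#' @param founder_divisions number of divisions of each founder before it
#'   enters the light zone.
#' @param antigen_per_fdc initial antigen portions loaded per FDC.
#' @param n_fdc number of FDCs.
#' @param n_tfh number of Tfh cells.
#' @param mutation_prob somatic hypermutation probability per division.
#' @param collection_window duration of the antigen-collection phase (h).
#' @param tfh_contact_duration duration of one B-Tfh contact (h; 36 min).
#' @param polarization_threshold minimum accumulated polarized-Tfh time for
#'   selection (h; 30 min). This is the Tfh signal threshold swept in the
#'   lifetime analysis.
#' @param asymmetric_fraction fraction of divisions that are asymmetric.
#' @param recycling_prob probability that a selected, non-antigen-retaining
#'   daughter re-enters the light zone instead of exiting.
#' @param feedback_strength antibody-feedback scaling in `[0, 1]`; 0 disables
#'   epitope masking.
#' @param feedback_K half-saturation constant of the masking function
#'   (affinity-weighted plasma cells).
#' @param max_divisions cap on selection-induced divisions.
#' @param count_threshold live-cell threshold above which a GC is counted as
#'   active.
#' @param gamma width of the Gaussian affinity kernel (lattice units).
#' @param fdc_encounter_rate FDC binding attempts per hour during the
#'   collection phase. Encounters are modeled as per-timestep contact
#'   opportunities; this rate stands in for the migration and dendrite
#'   geometry of a spatially resolved GC.
#' @param availability_K per-FDC antigen load (portions) at which the
#'   probability that an encountered FDC site still presents antigen is 1/2.
#'   Encodes progressive exhaustion of FDC sites as antigen is consumed.
#' @param availability_hill Hill exponent of the site-availability function
#'   `a^h / (a^h + K^h)`; larger values make collection fail more switch-like
#'   as the per-FDC load approaches `availability_K`.
#' @param tfh_signal_prob probability per timestep that the B cell holding a
#'   Tfh's polarization actually receives a productive help signal;
#'   engagement noise that makes the polarization threshold a graded
#'   stringency filter even for uncontested cells.
#' @param fdc_decay_rate exponential clearance rate (1/h) of FDC-held
#'   antigen during the reaction, independent of consumption by B cells.
#'   Free immune complexes are cleared over days to weeks after
#'   immunization; the same first-order loss is applied to the FDC depot, and
#'   it is this clearance that ultimately winds the reaction down.
#' @param gc_capacity spatial carrying capacity of the GC (cells). The
#'   parent lattice model bounds the reaction volume; here survival becomes
#'   density-dependent above this size. 0 disables the bound.
#' @param cycle_mean mean B-cell division cycle time (h).
#' @param cycle_cv coefficient of variation of the cycle time
#'   (gamma-distributed).
#' @param record_every recording cadence of the time series (h).
#' @return a list of class `gc_params`.
#' @export
gc_params <- function(dt = 0.1,
                      duration = 960,
                      influx_rate = 2,
                      influx_duration = 96,
                      founder_divisions = 6L,
                      antigen_per_fdc = 3000,
                      n_fdc = 200L,
                      n_tfh = 250L,
                      mutation_prob = 0.5,
                      collection_window = 0.7,
                      tfh_contact_duration = 0.6,
                      polarization_threshold = 0.5,
                      asymmetric_fraction = 0.72,
                      recycling_prob = 0.8,
                      feedback_strength = 0,
                      feedback_K = 1000,
                      max_divisions = 6L,
                      count_threshold = 100L,
                      gamma = 2.8,
                      fdc_encounter_rate = 8,
                      availability_K = 250,
                      availability_hill = 2,
                      fdc_decay_rate = 0.0115,
                      tfh_signal_prob = 0.8,
                      gc_capacity = 1200,
                      cycle_mean = 7.5,
                      cycle_cv = 0.2,
                      record_every = 6) {
  p <- list(dt = dt, duration = duration, influx_rate = influx_rate,
            influx_duration = influx_duration,
            founder_divisions = as.integer(founder_divisions),
            antigen_per_fdc = antigen_per_fdc, n_fdc = as.integer(n_fdc),
            n_tfh = as.integer(n_tfh), mutation_prob = mutation_prob,
            collection_window = collection_window,
            tfh_contact_duration = tfh_contact_duration,
            polarization_threshold = polarization_threshold,
            asymmetric_fraction = asymmetric_fraction,
            recycling_prob = recycling_prob,
            feedback_strength = feedback_strength, feedback_K = feedback_K,
            max_divisions = as.integer(max_divisions),
            count_threshold = as.integer(count_threshold), gamma = gamma,
            fdc_encounter_rate = fdc_encounter_rate,
            availability_K = availability_K,
            availability_hill = availability_hill,
            fdc_decay_rate = fdc_decay_rate,
            tfh_signal_prob = tfh_signal_prob,
            gc_capacity = gc_capacity,
            cycle_mean = cycle_mean, cycle_cv = cycle_cv,
            record_every = record_every)
  validate_gc_params(p)
  structure(p, class = "gc_params")
}

#' Validate GC parameters
#'
#' @param p a `gc_params` list.
#' @return `p`, invisibly; errors on the first violated constraint.
#' @export
validate_gc_params <- function(p) {
  chk <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
  probs <- c("mutation_prob", "asymmetric_fraction", "recycling_prob",
             "feedback_strength")
  for (nm in probs) {
    chk(p[[nm]] >= 0 && p[[nm]] <= 1, paste0(nm, " must be in [0, 1]"))
  }
  for (nm in c("dt", "duration", "collection_window", "tfh_contact_duration",
               "polarization_threshold", "cycle_mean", "record_every")) {
    chk(p[[nm]] > 0, paste0(nm, " must be > 0"))
  }
  chk(p$collection_window >= p$dt, "collection_window must be >= dt")
  chk(p$tfh_contact_duration >= p$dt, "tfh_contact_duration must be >= dt")
  chk(p$polarization_threshold <= p$tfh_contact_duration + 1e-9,
      "polarization_threshold must be <= tfh_contact_duration")
  chk(p$influx_rate >= 0, "influx_rate must be >= 0")
  chk(p$influx_duration >= 0, "influx_duration must be >= 0")
  chk(p$antigen_per_fdc >= 0, "antigen_per_fdc must be >= 0")
  chk(p$n_fdc >= 1, "n_fdc must be >= 1")
  chk(p$n_tfh >= 1, "n_tfh must be >= 1")
  chk(p$founder_divisions >= 0, "founder_divisions must be >= 0")
  chk(p$max_divisions >= 1, "max_divisions must be >= 1")
  chk(p$count_threshold >= 0, "count_threshold must be >= 0")
  chk(p$gamma > 0, "gamma must be > 0")
  chk(p$fdc_encounter_rate > 0, "fdc_encounter_rate must be > 0")
  chk(p$availability_K >= 0, "availability_K must be >= 0")
  chk(p$availability_hill > 0, "availability_hill must be > 0")
  chk(p$fdc_decay_rate >= 0, "fdc_decay_rate must be >= 0")
  chk(p$tfh_signal_prob > 0 && p$tfh_signal_prob <= 1,
      "tfh_signal_prob must be in (0, 1]")
  chk(p$gc_capacity >= 0, "gc_capacity must be >= 0")
  chk(p$cycle_cv > 0, "cycle_cv must be > 0")
  invisible(p)
}

#' Modify a parameter set
#'
#' Returns a copy of `p` with the named fields replaced and re-validated.
#'
#' @param p a `gc_params` object.
#' @param ... named replacement values.
#' @export
update_params <- function(p, ...) {
  repl <- list(...)
  unknown <- setdiff(names(repl), names(p))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  p[names(repl)] <- repl
  p$founder_divisions <- as.integer(p$founder_divisions)
  p$max_divisions <- as.integer(p$max_divisions)
  validate_gc_params(p)
  structure(p, class = "gc_params")
}

#' Divisions granted by collected antigen
#'
#' Selected B cells divide a number of times determined by the amount of
#' antigen they collected: `min(1 + floor(log2(1 + a)), max_divisions)`.
#' Monotone non-decreasing in antigen, at least 1, capped at `max_divisions`.
#'
#' @param antigen_collected portions collected (>= 1).
#' @param max_divisions cap on the number of divisions.
#' @export
assign_divisions <- function(antigen_collected, max_divisions = 6L) {
  if (any(antigen_collected < 1)) {
    stop("assign_divisions requires antigen_collected >= 1")
  }
  as.integer(pmin(1 + floor(log2(1 + antigen_collected)), max_divisions))
}
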