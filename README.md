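# gcohort

Agent-based simulation of asynchronous germinal center (GC) cohorts in a
primary immune response.

## The problem

After a primary immunization, GCs — the transient structures in which B
cells mutate their receptors and compete for survival signals — appear
asynchronously in a lymphoid organ over days to weeks. Experiments report
organ-level time courses: the number of GCs visible in tissue sections and
the total GC volume. Both are superpositions of many individual reactions
whose individual lifetimes cannot be followed longitudinally. A prolonged
organ-level contraction phase is therefore ambiguous: it can arise from
continued formation of new GCs with similar lifetimes, or from a broad
distribution of individual lifetimes with no late formation at all.

`gcohort` is for modellers and systems immunologists who want to
discriminate such explanations in silico. It provides:

* a stochastic agent-based engine for a single GC (`run_gc()`): Poisson
  founder influx (2 cells/h for 96 h, six founder divisions), somatic
  hypermutation as steps on a 4-D shape-space lattice with Gaussian
  affinity `exp(-d²/Γ²)`, antigen collection from an integer-valued FDC
  depot (3000 portions per FDC on 200 FDCs), competition for polarized
  Tfh-cell help (36-min contacts, 30-min polarization threshold),
  antigen-dependent division numbers, 72% asymmetric divisions with
  antigen retention, plasma-cell output, and recycling;
* a cohort layer (`build_schedule()`, `run_cohort()`) that schedules a few
  *representative* GCs along a Hill formation curve
  `N(t) = Nmax·tⁿ/(Tⁿ+tⁿ)`, weights them to organ scale, and computes the
  active-GC count (100-cell threshold) and total volume over 40 days;
* a scenario catalogue `hypothesis_config("H1")`–`"H8"` (restricted vs
  extended formation; antigen availability decaying with initiation time,
  `A(t) = A0·e^(-kt)`; multi-epitope founder specificity; random parameter
  variation; antibody feedback; founder influx and affinity variation) and
  lifetime sweeps (`sweep_parameter()`);
* a fitting module scoring cohort curves against experimental-style series
  with the relative squared-error cost `Σ((Eᵢ-Sᵢ)/Eᵢ)²`
  (`score_scenario()`);
* a synthetic-data generator with known ground truth
  (`synthetic_truth()`, `generate_count_series()`, `recover_hill()`) so
  scheduling, simulation and fitting are testable end to end without
  external data.

The methods vignette (`vignettes/gcohort-methods.Rmd`) documents the model,
every tunable parameter, and the design decisions of the well-mixed
reduction.

## Worked example

Simulate one reference GC:

```r
library(gcohort)
r <- run_gc(gc_params(), seed = 1)
print(r)
#> <gc_run> 161 records over 40 days
#>   peak live cells: 1203; plasma output: 2516
#>   lifetime above 100 cells: 11.25 days; init time: 0 days
```

The GC expands after founder influx, plateaus near its carrying capacity,
and contracts as the FDC antigen load erodes, staying above the 100-cell
counting threshold for about 11 days and exporting ~2500 plasma cells.

Run the antigen-decay scenario (H3), in which late-initiated GCs trap
exponentially less antigen:

```r
res <- run_scenario(hypothesis_config("H3"), repeats = 5, seed = 42)
res$summaries[[1]]
#>   init_day weight lifetime_d plasma
#> 1     0.53  14.79      17.25  10441
#> 2     2.01  28.41      14.25   4880
#> 3     3.00  23.83      12.00   3641
#> 4     5.44  16.04       5.25    514
#> 5     7.01  10.35       5.00     90
#> 6     8.35   6.78       5.00     17
#> 7     9.79   4.59       5.25      5
#> 8    11.20   3.21       4.75      3
```

Each row is one representative GC: its initiation day, the number of GCs it
stands for (the Hill mass of its interval), its lifetime, and its plasma
output. Early GCs are long-lived (17 days) and dominate output; GCs formed
after day 5 barely ignite — the initiation-time/lifetime correlation and the
early-vs-late output asymmetry that characterize the antigen-decay
hypothesis. The cohort curves peak at ~103 active GCs around day 10.75
before a prolonged contraction driven by the staggered shutdown of early
GCs.

Sweep antigen availability and report lifetimes normalized to the
reference parameter set:

```r
sweep_parameter("antigen_per_fdc", c(1500, 3000, 6000), repeats = 5, seed = 7)
#>   value lifetime_mean_h normalized
#> 1  1500           150.0      0.556
#> 2  3000           270.0      1.000
#> 3  6000           339.6      1.258
```

Halving the FDC antigen load nearly halves GC lifetime; doubling it extends
lifetime by ~26% — antigen availability is a strong lifetime determinant,
in contrast to mutation probability, which moves lifetime only weakly.

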