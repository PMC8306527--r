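---
title: "Simulating cohorts of asynchronous germinal centers: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating cohorts of asynchronous germinal centers: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcohort)
```

## The question the package addresses

After a primary immunization, germinal centers (GCs) appear asynchronously
in a lymphoid organ over days to weeks, and the organ-level time courses
that experiments report — the number of GCs visible in a tissue section and
the total GC volume — are superpositions of many individual reactions whose
individual lifetimes cannot be followed directly. `gcohort` simulates
individual GC reactions with a stochastic agent-based model, schedules
cohorts of such reactions along a Hill-shaped formation curve, and scores
the resulting cohort observables against experimental-style time series
with a relative squared-error cost. The package's scenario catalogue
(`hypothesis_config("H1")` … `"H8"`) expresses competing explanations for a
prolonged organ-level contraction phase: extended formation of new GCs with
similar lifetimes, versus GC-to-GC variability in lifetime caused by
antigen availability, founder-cell composition, antibody feedback, or
initiation-time-independent random parameter variation.

## The single-GC engine

Each GC is a well-mixed population of B-cell agents stepped at `dt = 0.1` h
for 40 simulated days (`run_gc()`, compiled core in `src/gc_engine.cpp`).

**Founders and expansion.** Seeder cells arrive as a Poisson stream at 2
cells/h for 96 h and divide `founder_divisions = 6` times before acquiring
a light-zone phenotype. Division cycle times are gamma distributed with
mean 7.5 h and CV 0.2.

**Shape space and mutation.** A B-cell receptor is a point on a 4-D integer
lattice (axes 0–9). Affinity to an epitope is a Gaussian kernel of
Euclidean distance to the epitope's optimal position,
$a = \exp(-d^2/\Gamma^2)$ with $\Gamma = 2.8$, so a cell on the optimum has
affinity 1 and a naive founder at distance 5 has affinity 0.04. Somatic
hypermutation moves one coordinate by one step with probability 0.5 per
division (out-of-bounds moves are redrawn). Multiple epitopes are
represented as multiple optima whose abundance fractions partition the
antigen pool; at each binding attempt the epitope is drawn with probability
proportional to its remaining portions, and success tests affinity to the
drawn epitope.

**Antigen collection.** Unselected light-zone cells collect antigen from a
shared FDC depot for a 0.7-h window. The depot starts with
`antigen_per_fdc = 3000` portions on each of 200 FDCs, integer-valued
throughout. Encounters are per-timestep contact opportunities
(`fdc_encounter_rate = 8` attempts/h); each attempt succeeds with
probability

$$p = a \cdot \frac{\ell^2}{\ell^2 + K^2} \cdot (1 - s\,m)$$

where $a$ is affinity, $\ell$ the current per-FDC load,
$K = 250$ portions the availability half-saturation
(`availability_K`, Hill exponent `availability_hill = 2`), and $s\,m$ the
antibody-feedback masking term (below). A successful attempt moves one
portion from the pool into the cell. Cells that end the window without any
portion die; the rest seek T follicular helper (Tfh) help.

**Tfh selection.** A collector spends 36 min in contact, sampling one of
250 Tfh cells per timestep; each Tfh polarizes toward the sampled cell with
the most collected antigen (ties uniform), and the polarized cell receives
a productive help signal with probability `tfh_signal_prob = 0.8` per step.
A cell is selected if its accumulated polarized time reaches the 30-min
threshold (`polarization_threshold`, the "Tfh signal threshold" of the
lifetime sweeps); otherwise it dies. The signal-noise term makes the
threshold a graded stringency filter — with 6 polarization opportunities per
contact, an uncontested cell passes a 0.3/0.5/0.58-h threshold with
probability 0.98/0.66/0.26 — rather than a pure tie-breaking rule.

**Division, output, recycling.** Selected cells divide
$\min(1 + \lfloor \log_2(1 + \text{antigen}) \rfloor,\, 6)$ times. 72% of
divisions are asymmetric (one daughter retains all collected antigen; for
symmetric divisions odd portions split ceil/floor to keep the ledger
integer). Antigen-retaining terminal daughters leave as plasma cells;
antigen-free terminal daughters re-enter the light zone with probability
`recycling_prob = 0.8` and otherwise exit.

**Feedback.** When `feedback_strength > 0`, each epitope's masked fraction
is $m = P_w/(P_w + 1000)$ with $P_w$ the affinity-weighted cumulative
plasma output against that epitope; masking only ever grows.

### Two closure mechanisms of the well-mixed reduction

The parent model this engine abstracts is spatially resolved: a 3-D lattice
with chemokine-guided migration, discrete FDC dendrites, and a bounded
reaction volume. Two consequences of space must be restored explicitly in a
well-mixed model, and both are first-class parameters:

* **FDC antigen clearance** (`fdc_decay_rate = 0.0115`/h). Free immune
  complexes are cleared exponentially after immunization — the same
  first-order law that sets the antigen available to late-initiated GCs —
  and the FDC depot inside a running GC is subject to the same loss. In a
  well-mixed pool, consumption alone cannot terminate the reaction
  correctly: population-increasing parameter changes then deplete the pool
  faster and *shorten* lifetime, inverting the selection-stringency
  response. With first-order clearance the termination clock is
  $\sim \ln(A_0/a^*)/k$: longer for larger initial loads, earlier for
  stricter selection (higher viability load $a^*$), and only weakly coupled
  to consumption. Clearance appears as an explicit `antigen_decayed` column
  so the conservation audit stays exact.
* **Carrying capacity** (`gc_capacity = 1200` cells). The lattice bounds
  how many cells a GC holds; here survival becomes density-dependent
  (binomial thinning) above the capacity. Without it, permissive selection
  produces boom-and-crash dynamics in which Tfh-competition crowding during
  the crash erases the population-level advantage that permissiveness
  should confer.

With the default parameter set a reference GC crosses the 100-cell counting
threshold at about day 1.5, plateaus near the capacity, declines as the
antigen load erodes, and holds a mean lifetime of about 11.5–12 days —
between the two cohort-level lifetimes the scenario analyses reproduce
(12.5 days under restricted formation, 10.5 under extended formation, both
within ±2 days). The contact-process rates (`fdc_encounter_rate`,
`availability_K`, `availability_hill`, `fdc_decay_rate`,
`tfh_signal_prob`, `gc_capacity`) were calibrated once against that
lifetime and the directional responses of the parameter sweeps, and then
frozen; they are reported here as package defaults, not fitted per
scenario.

## Cohorts of representative GCs

Cumulative GC formation follows a Hill function
$N(t) = N_\max t^n/(T^n + t^n)$ (`hill_cumulative()`). Because simulating
hundreds of GCs is wasteful, the formation window is split into equal
intervals — 8 when formation is restricted to the first 12 days, 15 when it
extends to day 40 — and one *representative* GC is simulated per interval
(`build_schedule()`), weighted by the Hill mass of its interval and
initiated at a Gaussian-jittered time (sd = 12 h, truncated to the
interval). All GCs of an interval are assumed to behave exactly like their
representative. The default restricted-formation Hill is
$(N_\max, T, n) = (120, 96\,\mathrm{h}, 2)$, which puts 90% of formation
within 12 days and every representative weight in the 1–30 range; the
extended-formation Hill is $(120, 240\,\mathrm{h}, 2)$.

Cohort observables (`cohort_curves()`) are the weighted number of
representatives whose live-cell count exceeds 100 (strictly), and the
weighted sum of volume proxies (live-cell count, arbitrary units; volume
comparisons are always made after normalizing both sides to their day-7
value). A GC's lifetime is the total time its live-cell trace stays above
the threshold, summed over supra-threshold episodes on the 6-h recording
grid. Repeats redraw the schedule jitter and any per-GC random parameters;
`aggregate_repeats()` reports mean ± sd per time point.

## Hypothesis scenarios

`make_per_gc_params()` expands a scenario into per-representative
parameters: H1/H2 share one parameter set and differ only in the formation
schedule; H3 loads each representative with
$A(t_{\text{init}}) = A_0 e^{-k t_{\text{init}}}$ portions per FDC
($A_0 = 20{,}000$, $k = 0.026$/h for the splenic SRBC-style setting;
$A_0 = 2000$, $k = 0.01$/h for the NP-CGG-style setting); H4 uses three
unrelated epitopes at abundances 0.6/0.3/0.1 with founder specificity
assigned by interval (`variant` controls whether the early or the late half
gets random founders; specific founders sit 2 lattice steps from their
target optimum, and H4's random founders use a 4-step naive shell because
the region ≥ 5 steps from all three optima is dominated by very remote
points); H5 draws `antigen_per_fdc` from a Gaussian (mean 3000, sd 1500,
floored at 100) independent of initiation time; H6 enables antibody
feedback; H7 and H8 vary influx rate and founder distance per GC.

`sweep_parameter()` reproduces the lifetime-sensitivity analysis: for each
value of one of {recycling probability, antigen portions, feedback
strength, polarization threshold, founder distance, mutation probability}
it simulates single GCs with seeds shared with the reference set (a paired
design, so the reference value maps to exactly 1.0) and reports mean
lifetimes normalized by the reference mean.

## Fitting

The cost of simulated values $S_i$ against data $E_i$ is
$\sum_i ((E_i - S_i)/E_i)^2$ (`cost_relsq()`), computed on the across-repeat
mean curve after linear interpolation to the data times (`align_series()`);
count and volume costs are added with equal weight (`score_scenario()`),
since the reference analyses report a single combined number. All data
points enter the cost. The relative form is undefined at zero and
hypersensitive to near-zero denominators, which is why the synthetic
generator enforces detection floors (below).

## The synthetic-data generator

Because the experimental series behind the reference analyses are digitized
figures without a deposited accession, `synthetic_truth()` defines a known
generating process for end-to-end testing: GCs form along a Hill curve;
each GC formed at time $u$ lives $L(u)$ hours — either a fixed $L$ or the
saturating antigen-decay map
$L(u) = 90 \cdot \log(1 + A(u)/130)$ hours, whose scale and half-saturation
mirror the engine's own antigen-to-lifetime response; observations carry
multiplicative lognormal noise (sd 0.15 by default). The expected count
curve is the closed-form superposition of formation mass and lifetimes
(`expected_count()`), against which the generator is tested exactly. The
volume kernel is a trapezoid — rise to a unit plateau within a quarter
lifetime (at most 2 days), plateau to half the lifetime, then linear decay
reaching zero at 1.25 lifetimes — mirroring the capped, antigen-eroded
volume trajectory a simulated GC traces, including the residual volume a GC
keeps after its count drops below threshold. Sampling times whose expected
count falls below 1 GC, or whose volume falls below 5% of the day-7 value,
are treated as unobservable and dropped: a histology series neither counts
fractional GCs nor resolves volumes that small, and the relative cost would
otherwise be dominated by them.

`recover_hill()` closes the loop: it fits $(N_\max, T, n)$ to the rising
phase of a count series by least squares on the log scale (the maximum
likelihood choice under the generator's multiplicative noise), truncating
the rising phase at the last record high so single noisy dips do not
shorten it. On noiseless input the recovery is exact; at 15% noise the
median relative errors stay below 10%.

What passing these tests shows — and what it does not. The synthetic series
share the structure of the digitized experimental curves (a rise to a peak
near day 10–12, a contraction whose duration encodes lifetime variability,
day-7-normalized volumes) but none of their measurement pathologies:
digitization error, section-sampling variability, inter-animal variation,
or correlated errors between count and volume from the same sections.
Model-selection results on synthetic targets therefore demonstrate that the
pipeline can discriminate formation-extended from lifetime-variable worlds
at realistic noise, not that any particular hypothesis is true of the
original tissue data.

## Numerical choices and degenerate inputs

* Timestep 0.1 h divides the 36-min contact exactly (6 polarization
  opportunities); the 0.7-h collection window spans 7 steps by clock
  accumulation. Fractional expected attempts per step are Bernoulli-rounded.
* All antigen bookkeeping is integer; the audit
  `initial = remaining + in cells + output + dead + decayed` holds exactly
  at every recorded step (`antigen_conserved()`).
* Ties in Tfh polarization break uniformly at random; a persistent tie
  splits polarized time so that at most one of two tied cells can reach the
  30-min threshold within one contact.
* `antigen_per_fdc = 0` collapses the GC after founder expansion;
  `influx_rate = 0` leaves it empty; an empty founder shell (no lattice
  point at the requested distance) and a polarization threshold exceeding
  the contact duration are rejected at validation.
* Seeds: every run takes a single integer seed; cohort and sweep seeds are
  derived from a master seed by an integer-mixing splittable scheme
  (`make_seeds()`), so enlarging a study never changes earlier runs.

## Problem sizes used by the shipped analyses

The test suite and the acceptance script run cohorts of 8 or 15
representatives with 10 repeats (50 for the random-variation scenario's
repeat-averaged check), 10-seed parameter sweeps, 10 model-selection
batches at 3 repeats per scenario, and 50 replicate recovery fits. A single
reference GC simulates in well under a second, so the full suite completes
in a few minutes on one core. Larger repeat counts sharpen the stochastic
summaries but do not change any qualitative outcome reported here.

## Known limitations

* The engine is deliberately non-spatial: chemokine fields, migration, and
  FDC dendrite geometry are collapsed into contact rates, an availability
  function, a capacity, and a clearance rate. Encounter logic sits behind a
  single interface in the compiled core, so a spatial backend could replace
  it without touching the cohort layer.
* Represented GCs are exact copies of their interval's representative; the
  within-interval variance of real cohorts is therefore understated.
* Memory-cell output, Tfh migration between GCs, and antibody exchange
  between concurrently running GCs (inter-GC coupling) are out of scope.
* The volume proxy is a cell count; experimental volumes are comparable
  only after day-7 normalization, and no attempt is made to model absolute
  GC volume.
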