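Package: gcohort
Title: Agent-Based Simulation of Asynchronous Germinal Center Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic agent-based simulation of germinal center (GC)
    reactions and of cohorts of asynchronously initiated GCs in a lymphoid
    organ after primary immunization. Individual GCs are simulated as
    well-mixed populations of B-cell agents that divide, hypermutate in a
    four-dimensional shape space, collect antigen from follicular dendritic
    cells, and compete for polarized T follicular helper cell signals.
    Cohorts of representative GCs are scheduled with a Hill function,
    weighted to organ scale, and scored against experimental-style time
    series of GC counts and total GC volume with a relative squared-error
    cost. Includes hypothesis scenarios for antigen-availability,
    founder-cell and random parameter variation, parameter sweeps of GC
    lifetime, and a synthetic-data generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
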