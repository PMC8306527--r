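test_that("runs are reproducible from the seed", {
  p <- fast_params()
  r1 <- run_gc(p, seed = 11)
  r2 <- run_gc(p, seed = 11)
  expect_identical(r1$series, r2$series)
  expect_identical(r1$plasma_by_epitope, r2$plasma_by_epitope)
  r3 <- run_gc(p, seed = 12)
  expect_false(identical(r1$series, r3$series))
})

test_that("founder influx is Poisson at 2 cells/h for 96 h", {
  p <- fast_params(antigen_per_fdc = 0)  # no reaction needed, just influx
  founders <- sapply(1:12, function(s) run_gc(p, seed = s)$total_founders)
  # rate x duration = 192; allow 3 standard errors of the mean
  expect_lt(abs(mean(founders) - 192), 3 * sqrt(192 / 12))
  # no arrivals after the influx window: total is fixed by 96 h
  p2 <- fast_params(duration = 240, antigen_per_fdc = 0)
  expect_identical(run_gc(p2, seed = 3)$total_founders,
                   run_gc(fast_params(duration = 100, antigen_per_fdc = 0),
                          seed = 3)$total_founders)
})

test_that("no influx means an empty GC", {
  r <- run_gc(fast_params(influx_rate = 0), seed = 1)
  expect_true(all(r$series$live_cells == 0))
  expect_true(all(r$series$cumulative_plasma == 0))
})

test_that("without antigen the GC collapses after founder expansion", {
  r <- run_gc(gc_params(duration = 480, antigen_per_fdc = 0), seed = 2)
  s <- r$series
  expect_identical(tail(s$live_cells, 1), 0)
  expect_identical(tail(s$cumulative_plasma, 1), 0)
  # founder expansion produced cells before the collapse
  expect_gt(max(s$live_cells), 100)
})

test_that("antigen bookkeeping is conserved exactly at every record", {
  r <- run_gc(fast_params(), seed = 5)
  expect_true(all(antigen_conserved(r)))
  r2 <- run_gc(fast_params(antigen_per_fdc = 400, fdc_decay_rate = 0.05),
               seed = 6)
  expect_true(all(antigen_conserved(r2)))
})

test_that("cumulative outputs are monotone and pools non-increasing", {
  r <- run_gc(fast_params(), seed = 7)
  s <- r$series
  expect_true(all(diff(s$cumulative_plasma) >= 0))
  expect_true(all(diff(s$antigen_remaining) <= 0))
  expect_true(all(diff(s$antigen_output) >= 0))
  expect_true(all(diff(s$antigen_decayed) >= 0))
  expect_true(all(s$live_cells >= 0))
})

test_that("without hypermutation affinity cannot improve", {
  # founders placed on the optimum sustain a reaction; founders placed far
  # from it can never gain affinity when mutation is off, so the GC dies
  # after the founder burst
  eps <- default_epitopes()
  on_opt <- founder_spec("epitope_specific", 1L, distance_from_optimum = 0)
  far <- founder_spec("epitope_specific", 1L, distance_from_optimum = 7)
  p <- gc_params(duration = 480, mutation_prob = 0)
  lt_opt <- gc_lifetime(run_gc(p, eps, on_opt, seed = 8))
  lt_far <- gc_lifetime(run_gc(p, eps, far, seed = 8))
  expect_gt(lt_opt, 7 * 24)
  expect_lt(lt_far, lt_opt / 1.5)
})

test_that("asymmetric divisions concentrate antigen into fewer plasma cells", {
  p <- gc_params(duration = 360)
  sym <- update_params(p, asymmetric_fraction = 0)
  asym <- update_params(p, asymmetric_fraction = 1)
  load_per_pc <- function(par) {
    out <- sapply(1:4, function(s) {
      r <- tail(run_gc(par, seed = s)$series, 1)
      c(r$antigen_output, r$cumulative_plasma)
    })
    sum(out[1, ]) / sum(out[2, ])
  }
  expect_gt(load_per_pc(asym), load_per_pc(sym))
})

test_that("Tfh polarization selects the strongest collector of a contact", {
  p <- gc_params()
  expect_identical(simulate_tfh_contact(5, p), TRUE)
  set.seed(9)
  expect_identical(simulate_tfh_contact(c(10, 1), p), c(TRUE, FALSE))
  # tied cells split the polarization time: at most one of the pair can
  # accumulate the 30 min needed within the 36 min contact
  set.seed(10)
  ties <- replicate(50, simulate_tfh_contact(c(4, 4), p))
  expect_true(all(colSums(ties) <= 1))
  # a permissive threshold lets tied cells through
  relaxed <- update_params(p, polarization_threshold = 0.2)
  set.seed(11)
  loose <- replicate(50, simulate_tfh_contact(c(4, 4), relaxed))
  expect_true(all(colSums(loose) >= 1))
})

test_that("masking by antibody feedback saturates at the half constant", {
  # m = P_w / (P_w + K): the identity the engine's masking uses
  r <- run_gc(fast_params(feedback_strength = 0.9, feedback_K = 50,
                          duration = 240), seed = 12)
  expect_true(all(r$masked_fraction >= 0 & r$masked_fraction < 1))
  # with no output yet, masking is zero
  r0 <- run_gc(fast_params(influx_rate = 0, feedback_strength = 0.9),
               seed = 1)
  expect_identical(r0$masked_fraction, 0)
})
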