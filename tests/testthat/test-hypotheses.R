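test_that("antigen decay evaluates the exponential clearance law", {
  d <- rao_decay()
  expect_identical(antigen_at_start(0, d), 20000)
  expect_equal(antigen_at_start(100, d), 20000 * exp(-2.6))
  nodecay <- antigen_decay(500, 0)
  expect_identical(antigen_at_start(c(0, 240, 960), nodecay),
                   rep(500, 3))
  expect_true(all(diff(antigen_at_start(seq(0, 960, 24), d)) < 0))
})

test_that("scenario expansion follows each hypothesis", {
  set.seed(1)
  sch <- build_schedule(hill_params(120, 96, 3), 8, 288, 24)

  h1 <- make_per_gc_params(hypothesis_config("H1"), sch)
  expect_true(all(sapply(h1$params_list, identical, h1$params_list[[1]])))

  cfg3 <- hypothesis_config("H3")
  h3 <- make_per_gc_params(cfg3, sch)
  ag <- sapply(h3$params_list, `[[`, "antigen_per_fdc")
  expect_equal(ag, antigen_at_start(sch$init_time, cfg3$decay))
  expect_true(all(diff(ag) < 0))

  set.seed(2)
  h5 <- make_per_gc_params(hypothesis_config("H5", antigen_sd = 0), sch)
  expect_true(all(sapply(h5$params_list, `[[`, "antigen_per_fdc") == 3000))

  h4 <- make_per_gc_params(hypothesis_config("H4"), sch)
  modes <- sapply(h4$founders_list, `[[`, "mode")
  expect_identical(modes, c(rep("random", 4), rep("epitope_specific", 4)))
  h4b <- make_per_gc_params(hypothesis_config("H4",
                                              variant = "early_specific"),
                            sch)
  expect_identical(sapply(h4b$founders_list, `[[`, "mode"),
                   c(rep("epitope_specific", 4), rep("random", 4)))
  expect_length(h4$epitopes, 3L)

  h7 <- make_per_gc_params(hypothesis_config("H7"), sch)
  expect_equal(sapply(h7$params_list, `[[`, "influx_rate"),
               2 * rep_len(c(0.5, 0.75, 1, 1.5, 2), 8))

  h8 <- make_per_gc_params(hypothesis_config("H8",
                                             founder_distance = c(1, 3, 5)),
                           sch)
  expect_equal(sapply(h8$founders_list, `[[`, "distance_from_optimum"),
               rep_len(c(1, 3, 5), 8))

  expect_error(hypothesis_config("H9"), "H1, H2")
})

test_that("H2 defaults extend formation while H1 restricts it", {
  c1 <- hypothesis_config("H1")
  c2 <- hypothesis_config("H2")
  expect_identical(c1$n_intervals, 8L)
  expect_identical(c2$n_intervals, 15L)
  expect_lt(c1$horizon, c2$horizon)
  # most H1 formation happens within 12 days
  expect_gte(hill_cumulative(288, c1$hill) / c1$hill$nmax, 0.9)
  # H2 keeps forming GCs well past day 12
  expect_lt(hill_cumulative(288, c2$hill) / c2$hill$nmax, 0.7)
})

test_that("sweeping the reference value reproduces the reference exactly", {
  sw <- sweep_parameter("recycling_prob", c(0.8), repeats = 3, seed = 21)
  expect_identical(sw$normalized, 1)
  expect_identical(attr(sw, "lifetimes")[, 1],
                   attr(sw, "reference_lifetimes"))
  expect_error(sweep_parameter("not_a_knob", 1), "unknown sweep")
})
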