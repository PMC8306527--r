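truth_fixed <- function(noise_sd = 0, L = 300) {
  synthetic_truth(hill_params(120, 96, 3),
                  lifetime = list(type = "fixed", L = L),
                  noise_sd = noise_sd)
}

test_that("noiseless count series equals the closed-form expectation", {
  tr <- truth_fixed(0)
  set.seed(1)
  s <- generate_count_series(tr)
  expect_equal(s$value, expected_count(tr, s$time_days * 24))
  # reproducible bit for bit under a fixed seed
  tr_n <- truth_fixed(0.2)
  set.seed(9); a <- generate_count_series(tr_n)
  set.seed(9); b <- generate_count_series(tr_n)
  expect_identical(a, b)
})

test_that("count curve mass conserves formation mass times lifetime", {
  tr <- truth_fixed(0, L = 300)
  grid <- seq(0, 1500, by = 1)
  integral <- sum(expected_count(tr, grid)) * 1
  total_mass <- hill_cumulative(tr$formation_horizon, tr$hill)
  expect_equal(integral, total_mass * 300, tolerance = 0.01)
})

test_that("decay-driven truth contracts over a wider window than fixed-L", {
  dec <- synthetic_truth(hill_params(120, 96, 3),
                         lifetime = list(type = "decay",
                                         decay = rao_decay()),
                         noise_sd = 0)
  fix <- truth_fixed(0)
  span <- function(tr) {
    g <- seq(0, 1400, by = 2)
    y <- expected_count(tr, g)
    pk <- max(y)
    after <- g > g[which.max(y)]
    hi <- max(g[after & y >= 0.75 * pk])
    lo <- max(g[after & y >= 0.25 * pk])
    lo - hi   # time to fall from 75% to 25% of peak
  }
  expect_gt(span(dec), span(fix))
})

test_that("volume series is normalized at day 7 and scale invariant", {
  tr <- truth_fixed(0)
  set.seed(2)
  v <- generate_volume_series(tr)
  expect_equal(v$value[v$time_days == 7], 1)
  big <- synthetic_truth(hill_params(240, 96, 3),
                         lifetime = list(type = "fixed", L = 300),
                         noise_sd = 0)
  set.seed(2)
  v2 <- generate_volume_series(big)
  expect_equal(v$value, v2$value)   # doubling Nmax cancels in normalization
  # if every GC is gone by day 7, normalization must fail loudly
  empty <- synthetic_truth(hill_params(120, 12, 3),
                           lifetime = list(type = "fixed", L = 1),
                           noise_sd = 0, formation_horizon = 24)
  expect_error(generate_volume_series(empty), "day 7")
})

test_that("Hill parameters are recovered from clean rising phases", {
  tr <- synthetic_truth(hill_params(120, 96, 3),
                        lifetime = list(type = "fixed", L = 900),
                        noise_sd = 0, times_d = 1:14,
                        formation_horizon = 336)
  set.seed(3)
  fit <- recover_hill(generate_count_series(tr))
  expect_equal(fit$nmax, 120, tolerance = 0.01)
  expect_equal(fit$t_half, 96, tolerance = 0.01)
  expect_equal(fit$n, 3, tolerance = 0.01)
  short <- experimental_series(1:3, c(1, 5, 20), "gc_count")
  expect_error(recover_hill(short), "at least 4")
})
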