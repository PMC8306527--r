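test_that("Hill formation curve satisfies its identities", {
  hp <- hill_params(120, 96, 3)
  expect_identical(hill_cumulative(0, hp), 0)
  expect_equal(hill_cumulative(96, hp), 60)
  expect_equal(hill_cumulative(192, hp), 120 * 8 / 9)
  grid <- seq(0, 2000, length.out = 1000)
  expect_true(all(diff(hill_cumulative(grid, hp)) >= 0))
  expect_error(hill_cumulative(-1, hp), "non-negative")
  expect_error(hill_params(0, 96, 3))
})

test_that("schedules partition the window and conserve the Hill mass", {
  hp <- hill_params(120, 96, 2)
  set.seed(1)
  sch <- build_schedule(hp, 8, 288, 24)
  expect_equal(sum(sch$weight), hill_cumulative(288, hp))
  expect_true(all(sch$init_time >= sch$start & sch$init_time <= sch$end))
  expect_equal(sch$end[-8], sch$start[-1])
  # a section-of-spleen scale schedule: each representative stands for
  # 1 to 30 GCs
  expect_true(all(sch$weight >= 1 & sch$weight <= 30))
  # no jitter puts representatives exactly at interval midpoints
  sch0 <- build_schedule(hp, 8, 288, 0)
  expect_identical(sch0$init_time, sch0$midpoint)
  expect_error(build_schedule(hp, 0, 288), "n_intervals")
})

test_that("lifetime is the total supra-threshold duration", {
  times <- seq(0, 480, by = 6)
  live <- ifelse(times >= 48 & times < 348, 500, 0)
  expect_equal(gc_lifetime(fake_run(times, live)), 300)
  expect_equal(gc_lifetime(fake_run(times, rep(50, length(times)))), 0)
  # threshold 0 counts any live cell
  expect_equal(gc_lifetime(fake_run(times, live), threshold = 0), 300)
  # multiple supra-threshold episodes add up
  live2 <- ifelse((times >= 48 & times < 96) | (times >= 192 & times < 240),
                  500, 0)
  expect_equal(gc_lifetime(fake_run(times, live2)), 96)
})

test_that("active-GC counting weights representatives by interval mass", {
  times <- seq(0, 480, by = 6)
  r1 <- fake_run(times, ifelse(times < 240, 500, 0), init_time = 24)
  r2 <- fake_run(times, ifelse(times < 240, 500, 0), init_time = 120)
  sch <- data.frame(start = c(0, 96), end = c(96, 192),
                    midpoint = c(48, 144), init_time = c(24, 120),
                    weight = c(30, 5))
  res <- structure(list(runs = list(r1, r2), schedule = sch,
                        summary = NULL), class = "cohort_result")
  expect_equal(count_active_gcs(res, 0), 0)       # nothing formed yet
  expect_equal(count_active_gcs(res, 100), 30)    # only the first is up
  expect_equal(count_active_gcs(res, 150), 35)    # both active
  expect_equal(count_active_gcs(res, 300), 5)     # first one ended
  expect_error(count_active_gcs(res, -5), "non-negative")
  # volume is linear in the weights
  v <- total_volume(res, 150)
  expect_gt(v, 0)
  sch2 <- sch; sch2$weight <- sch$weight * 2
  res2 <- structure(list(runs = list(r1, r2), schedule = sch2,
                         summary = NULL), class = "cohort_result")
  expect_equal(total_volume(res2, 150), 2 * v)
})

test_that("cohorts are deterministic and order-independent", {
  hp <- hill_params(120, 96, 3)
  set.seed(2)
  sch <- build_schedule(hp, 3, 288, 24)
  pl <- rep(list(fast_params()), 3)
  seeds <- c(101L, 102L, 103L)
  res_a <- run_cohort(pl, sch, epitopes = default_epitopes(), seeds = seeds)
  res_b <- run_cohort(pl, sch, epitopes = default_epitopes(), seeds = seeds)
  expect_identical(res_a$summary, res_b$summary)
  # permuting representatives (with their seeds) leaves the curves unchanged
  perm <- c(3, 1, 2)
  sch_p <- sch[perm, ]
  res_p <- run_cohort(pl, sch_p, epitopes = default_epitopes(),
                      seeds = seeds[perm])
  t_grid <- seq(0, 400, by = 6)
  expect_equal(count_active_gcs(res_p, t_grid),
               count_active_gcs(res_a, t_grid))
  expect_equal(total_volume(res_p, t_grid), total_volume(res_a, t_grid))
  expect_error(run_cohort(pl[1:2], sch, seeds = seeds), "one gc_params")
})

test_that("repeat aggregation reports means and standard deviations", {
  d1 <- data.frame(time_h = c(0, 6), n_gc = c(1, 3), volume = c(10, 30))
  d2 <- data.frame(time_h = c(0, 6), n_gc = c(3, 5), volume = c(30, 10))
  agg <- aggregate_repeats(list(d1, d2))
  expect_equal(agg$n_gc_mean, c(2, 4))
  expect_equal(agg$n_gc_sd, c(sd(c(1, 3)), sd(c(3, 5))))
  expect_equal(agg$volume_mean, c(20, 20))
  one <- aggregate_repeats(list(d1))
  expect_equal(one$n_gc_sd, c(0, 0))
})
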