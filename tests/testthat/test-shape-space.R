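test_that("affinity kernel behaves as a Gaussian of shape-space distance", {
  e <- epitope(c(5, 5, 5, 5))
  expect_identical(affinity(c(5, 5, 5, 5), e), 1)
  # maximal separation along one axis: d = 8
  expect_equal(affinity(c(1, 5, 5, 5), c(9, 5, 5, 5)), exp(-64 / 2.8^2))
  expect_lt(affinity(c(1, 5, 5, 5), c(9, 5, 5, 5)), 0.01)
  # symmetric under swapping cell and optimum
  expect_equal(affinity(c(2, 3, 4, 5), c(7, 6, 5, 4)),
               affinity(c(7, 6, 5, 4), c(2, 3, 4, 5)))
  # strictly decreasing in distance along an axis
  a <- sapply(0:4, function(d) affinity(c(5 + d, 5, 5, 5), e))
  expect_true(all(diff(a) < 0))
  expect_true(all(a > 0 & a <= 1))
})

test_that("multi-epitope affinity equals the brute-force per-epitope max", {
  eps <- three_epitope_panel()
  set.seed(1)
  for (i in 1:50) {
    p <- shape_position(sample(0:9, 4, replace = TRUE))
    brute <- max(sapply(eps, function(e) affinity(p, e)))
    expect_equal(affinity_max(p, eps), brute)
  }
})

test_that("positions and epitope panels are validated", {
  expect_error(shape_position(c(1, 2, 3)), "4 coordinates")
  expect_error(shape_position(c(1, 2, 3, 12)), "within")
  expect_error(epitope_panel(epitope(c(1, 1, 1, 1), 0.6),
                             epitope(c(8, 8, 8, 8), 0.3)),
               "sum to 1")
  expect_error(epitope_panel(epitope(c(1, 1, 1, 1), 0.5),
                             epitope(c(3, 1, 1, 1), 0.5)),
               "lattice steps apart")
})

test_that("mutation moves one coordinate by one step or leaves it alone", {
  p <- shape_position(c(4, 5, 6, 3))
  set.seed(2)
  for (i in 1:50) expect_identical(mutate_position(p, 0), p)

  set.seed(3)
  n_moved <- 0L
  for (i in 1:10000) {
    q <- mutate_position(p, 1)
    d <- abs(unclass(q) - unclass(p))
    expect_identical(sum(d), 1L)   # exactly one coordinate, by exactly 1
    n_moved <- n_moved + 1L
  }
  expect_identical(n_moved, 10000L)
})

test_that("mutation frequency matches the per-division probability", {
  p <- shape_position(c(4, 5, 6, 3))
  set.seed(4)
  moved <- replicate(10000, !identical(mutate_position(p, 0.5), p))
  expect_equal(mean(moved), 0.5, tolerance = 0.04)
})

test_that("mutation respects lattice bounds", {
  corner <- shape_position(c(0, 0, 9, 9))
  set.seed(5)
  for (i in 1:500) {
    q <- mutate_position(corner, 1)
    expect_true(all(unclass(q) >= 0 & unclass(q) <= 9))
  }
})

test_that("epitope-specific founders land on the requested shell", {
  eps <- default_epitopes()
  spec0 <- founder_spec("epitope_specific", target_epitope = 1L,
                        distance_from_optimum = 0)
  set.seed(6)
  f0 <- sample_founders(spec0, eps, 10)
  expect_true(all(apply(f0, 1, function(r) all(r == c(5, 5, 5, 5)))))

  spec2 <- founder_spec("epitope_specific", target_epitope = 1L,
                        distance_from_optimum = 2)
  set.seed(7)
  f2 <- sample_founders(spec2, eps, 1000)
  d <- sqrt(rowSums((f2 - 5)^2))
  expect_true(all(round(d) == 2))
})

test_that("random founders keep their distance from every optimum", {
  eps <- three_epitope_panel()
  set.seed(8)
  f <- sample_founders(founder_spec("random"), eps, 1000)
  for (e in eps) {
    opt <- matrix(as.numeric(e$optimum), nrow(f), 4, byrow = TRUE)
    expect_true(all(sqrt(rowSums((f - opt)^2)) >= 5))
  }
})

test_that("impossible founder shells raise informative errors", {
  eps <- default_epitopes()
  spec <- founder_spec("epitope_specific", target_epitope = 1L,
                       distance_from_optimum = 20)
  expect_error(sample_founders(spec, eps, 1), "distance 20")
  expect_error(founder_spec("epitope_specific"), "target_epitope")
})
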