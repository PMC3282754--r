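test_that("spatial selectivity is the log10 in/out rate ratio", {
  m <- flat_map(matrix(c(10, 1, 1, 1), 2, 2))
  f <- define_place_field(m, "above_mean")   # mean 3.25 -> field = {10}
  expect_equal(f$pixels, 1L)
  expect_equal(spatial_selectivity(m, f), 1.0)

  m2 <- flat_map(matrix(c(4, 0.5, 0.5, 0.5), 2, 2))
  expect_equal(spatial_selectivity(m2, manual_field(1L)), log10(8))

  # in-field equals out-field -> selectivity 0
  m3 <- flat_map(matrix(5, 2, 2))
  expect_equal(spatial_selectivity(m3, manual_field(1L)), 0)

  # silent out-field -> infinite, flagged by the caller
  m4 <- flat_map(matrix(c(3, 0, 0, 0), 2, 2))
  expect_identical(spatial_selectivity(m4, manual_field(1L)), Inf)

  expect_error(spatial_selectivity(m, manual_field(integer(0))),
               class = "pf_error_empty")
})

test_that("spatial coherence tracks local smoothness", {
  expect_error(spatial_coherence(flat_map(matrix(1, 5, 5))),
               class = "pf_error_undefined_coherence")

  smooth <- gaussian_rate_map(c(5, 0), width = 4, arena_radius = 15)
  expect_gt(spatial_coherence(smooth)$r, 0.8)

  set.seed(31)
  noisy <- flat_map(matrix(runif(900), 30, 30))
  expect_lt(abs(spatial_coherence(noisy)$r), 0.1)

  # Fisher Z is atanh of the (clipped) correlation
  co <- spatial_coherence(smooth)
  expect_equal(co$z, atanh(co$r))
  # affine invariance of coherence
  shifted <- flat_map(3 * smooth$rate + 2, valid = smooth$valid)
  shifted$occupancy <- smooth$occupancy
  expect_equal(spatial_coherence(shifted)$r, co$r, tolerance = 1e-12)
})

test_that("spatial information matches hand-evaluated cases", {
  # uniform map carries no positional information
  u <- flat_map(matrix(3, 5, 5))
  expect_lt(abs(spatial_information(u)), 1e-12)

  # two equally occupied pixels at 2 and 0 Hz -> 1 bit/s
  two <- flat_map(matrix(c(2, 0, 0, 0), 2, 2),
                  occupancy = matrix(c(1, 1, 0, 0), 2, 2),
                  valid = matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
  expect_equal(spatial_information(two), 1.0)

  # nonnegative on arbitrary maps; scales linearly with rate
  set.seed(41)
  for (k in 1:20) {
    m <- flat_map(matrix(rexp(36), 6, 6), occupancy = matrix(runif(36, 0.5, 2), 6, 6))
    I <- spatial_information(m)
    expect_gt(I, -1e-12)
    m2 <- m; m2$rate <- 3 * m$rate
    expect_equal(spatial_information(m2), 3 * I, tolerance = 1e-10)
  }
})

test_that("information is invariant to pixel relabeling", {
  set.seed(43)
  r <- matrix(rexp(25), 5, 5)
  occ <- matrix(runif(25, 0.5, 2), 5, 5)
  perm <- sample(25)
  m1 <- flat_map(r, occupancy = occ)
  m2 <- flat_map(matrix(r[perm], 5, 5), occupancy = matrix(occ[perm], 5, 5))
  expect_equal(spatial_information(m1), spatial_information(m2), tolerance = 1e-12)
})

test_that("coherence falls with pixel noise; information falls with untuned firing", {
  base <- gaussian_rate_map(c(5, 0), width = 4, arena_radius = 15, peak = 5,
                            baseline = 0.5)
  # iid pixel noise destroys local smoothness
  set.seed(47)
  eps <- matrix(rnorm(900), 30, 30)
  coh <- vapply(c(0, 1, 3), function(sd) {
    noisy <- base
    noisy$rate <- pmax(base$rate + sd * eps, 0)
    noisy$rate[!base$valid] <- NA
    spatial_coherence(noisy)$r
  }, numeric(1))
  expect_true(all(diff(coh) < 0))
  # spatially uniform (untuned) firing dilutes positional information
  info <- vapply(c(0, 2, 5), function(b) {
    m <- base
    m$rate <- base$rate + b
    m$rate[!base$valid] <- NA
    spatial_information(m)
  }, numeric(1))
  expect_true(all(diff(info) < 0))
})
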