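test_that("trajectories have the right size, stay inside, and are reproducible", {
  tp <- trajectory_params(duration = 300, seed = 101)
  tr <- simulate_trajectory(tp)
  expect_length(tr, 300 * 60)
  expect_true(all(tr$x^2 + tr$y^2 < 15^2))
  tr2 <- simulate_trajectory(tp)
  expect_identical(tr, tr2)
})

test_that("realized mean speed tracks the requested mean speed", {
  tr <- simulate_trajectory(trajectory_params(mean_speed = 6.2, duration = 600,
                                              seed = 103))
  v <- sqrt(diff(tr$x)^2 + diff(tr$y)^2) * 60
  expect_lt(abs(mean(v) - 6.2) / 6.2, 0.05)
})

test_that("spike generation respects rate support and tuning", {
  tr <- simulate_trajectory(trajectory_params(duration = 120, seed = 107))
  silent <- cell_params(peak_event_rate = 0, baseline_event_rate = 0)
  expect_length(simulate_place_cell(tr, silent, seed = 1), 0)

  # track pinned at the wall, narrow field at the centre: (near-)silent
  th <- seq(0, 20 * pi, length.out = 6000)
  wall <- position_track(seq(0, 99.99, length.out = 6000),
                         14 * cos(th), 14 * sin(th))
  far <- cell_params(field_center = c(0, 0), field_width = 2,
                     baseline_event_rate = 0, peak_event_rate = 6)
  expect_lt(length(simulate_place_cell(wall, far, seed = 2)), 3)

  # overall rate grows monotonically with the peak event rate
  n <- vapply(c(1, 4, 10), function(pk) {
    length(simulate_place_cell(tr, cell_params(peak_event_rate = pk), seed = 5))
  }, numeric(1))
  expect_true(all(diff(n) > 0))
})

test_that("spikes fall within the session and burst amplitudes decay", {
  tr <- simulate_trajectory(trajectory_params(duration = 300, seed = 109))
  sp <- simulate_place_cell(tr, cell_params(p_single = 0.4), seed = 110)
  expect_true(all(sp$times >= 0 & sp$times <= 300))
  b <- detect_bursts(sp)
  expect_gt(length(b), 50)
  # within-burst amplitudes decay by integer powers of (1 - amp_decay)
  ratios <- unlist(lapply(b$index, function(ix) {
    a <- sp$amplitudes[ix]
    a[-1] / a[-length(a)]
  }))
  expect_true(all(ratios < 1))
  k <- log(ratios) / log(0.8)
  expect_true(all(abs(k - round(k)) < 1e-6))
})

test_that("spike generation is invariant to the track time origin", {
  tr <- simulate_trajectory(trajectory_params(duration = 120, seed = 113))
  shifted <- position_track(tr$times + 500, tr$x, tr$y)
  a <- simulate_place_cell(tr, cell_params(), seed = 114)
  b <- simulate_place_cell(shifted, cell_params(), seed = 114)
  expect_equal(b$times, a$times + 500, tolerance = 1e-9)
  expect_equal(b$amplitudes, a$amplitudes)
})

test_that("cue protocol transforms field centres by cue type", {
  desc2 <- session_descriptor(2, 15, 90, 1500)   # card rotated +90 CCW
  distal <- cell_params(field_center = c(10, 0), cue_type = "distal")
  expect_equal(apply_cue_protocol(distal, desc2)$field_center, c(10, 0))

  local <- cell_params(field_center = c(10, 0), cue_type = "local")
  expect_equal(apply_cue_protocol(local, desc2)$field_center, c(0, 10),
               tolerance = 1e-12)

  remap <- cell_params(field_center = c(7, 0), cue_type = "remap")
  r1 <- apply_cue_protocol(remap, desc2, seed = 115)
  r2 <- apply_cue_protocol(remap, desc2, seed = 115)
  expect_identical(r1$field_center, r2$field_center)
  # redraw is angularly separated from both the original and card position
  ang <- atan2(r1$field_center[2], r1$field_center[1]) * 180 / pi
  dd <- function(a, b) { d <- abs(a - b) %% 360; min(d, 360 - d) }
  expect_gte(dd(ang, 0), 60)
  expect_gte(dd(ang, 90), 60)
})

test_that("cohorts are sized, typed and bit-reproducible", {
  g <- group_params(cue_mix = c(distal = 2, local = 2, remap = 1))
  p <- cohort_protocol(duration = 30)
  co <- generate_cohort(5, g, p, master_seed = 117)
  expect_length(co, 5)
  expect_true(all(vapply(co, function(c) length(c$sessions), integer(1)) == 3))
  expect_equal(sort(table(vapply(co, `[[`, "", "cue_type"))),
               sort(table(c("distal", "distal", "local", "local", "remap"))))
  co2 <- generate_cohort(5, g, p, master_seed = 117)
  expect_identical(co, co2)
})

test_that("group ISI parameters propagate to detected intra-burst intervals", {
  tr <- simulate_trajectory(trajectory_params(duration = 600, seed = 119))
  isi1_mean <- function(mu, shape, seed) {
    cp <- cell_params(intra_isi_mean = mu, intra_isi_shape = shape,
                      p_single = 0.5)
    b <- detect_bursts(simulate_place_cell(tr, cp, seed = seed))
    mean(intra_burst_isi_series(b, 1))
  }
  slow <- isi1_mean(3.9, 3, 120)
  fast <- isi1_mean(2.5, 4, 121)
  expect_gt(slow, fast)          # mutant-like group has longer intra-burst ISIs
  expect_lt(abs(fast - 2.5), 0.4)
})
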