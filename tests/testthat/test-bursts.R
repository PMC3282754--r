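test_that("burst detection follows the 15-ms diminishing-amplitude rule", {
  # hand-traced example: ms times [0,5,12,40,100,101]
  st <- spike_train(c(0, 5, 12, 40, 100, 101) / 1000,
                    c(100, 80, 60, 90, 50, 45))
  b <- detect_bursts(st)
  expect_length(b, 2)
  expect_equal(b$index, list(1:3, 5:6))
  expect_equal(b$isis[[1]], c(5, 7))

  # single spike: no bursts
  expect_length(detect_bursts(spike_train(1, 50)), 0)

  # rising amplitude blocks a burst unless the criterion is relaxed
  pair <- spike_train(c(0, 0.008), c(50, 60))
  expect_length(detect_bursts(pair), 0)
  expect_length(detect_bursts(pair, enforce_amplitude = FALSE), 1)

  # amplitude tie terminates a burst
  tie <- spike_train(c(0, 0.005, 0.010), c(50, 50, 40))
  expect_equal(detect_bursts(tie)$index, list(2:3))
})

test_that("detector matches the greedy oracle and partitions spikes", {
  for (seed in 1:200) {
    st <- random_train(rate = runif(1, 0.5, 5) * 20, duration = 5, seed = seed)
    b <- detect_bursts(st)
    expect_identical(b$index, oracle_bursts(st$times, st$amplitudes))
    ix <- unlist(b$index)
    expect_equal(anyDuplicated(ix), 0)              # each spike in <= 1 burst
    expect_equal(b$n_spikes_in_bursts, length(ix))  # conservation
    expect_true(all(unlist(b$isis) <= 15 + 1e-9))
  }
})

test_that("adding spikes far from any burst leaves bursts unchanged", {
  st <- random_train(rate = 40, duration = 5, seed = 301)
  b <- detect_bursts(st)
  burst_times <- lapply(b$index, function(ix) st$times[ix])
  far <- max(st$times) + 1
  st2 <- spike_train(c(st$times, far), c(st$amplitudes, 70))
  b2 <- detect_bursts(st2)
  expect_equal(lapply(b2$index, function(ix) st2$times[ix]), burst_times)
})

test_that("burst metrics follow their definitions", {
  mk_burst <- function(t0) c(t0, t0 + 0.005)
  t <- sort(c(mk_burst(1), mk_burst(10), mk_burst(20), 3, 6, 15, 25))
  a <- rep(50, length(t)); a[match(c(1, 10, 20) + 0.005, t)] <- 40
  st <- spike_train(t, a)
  b <- detect_bursts(st)
  expect_length(b, 3)
  m <- burst_metrics(b, 30)
  expect_equal(m$burst_frequency, 0.1)
  expect_equal(m$intra_burst_spike_rate, 0.2)
  expect_equal(m$intra_burst_ratio, 60)
  expect_equal(m$mean_spikes_per_burst, 2)
  # inter-burst interval is end-to-next-start
  expect_equal(m$mean_inter_burst_interval, mean(c(10 - 1.005, 20 - 10.005)))

  none <- detect_bursts(spike_train(c(1, 2, 3), c(50, 50, 50)))
  m0 <- burst_metrics(none, 30)
  expect_equal(m0$burst_frequency, 0)
  expect_equal(m0$intra_burst_ratio, 0)
  expect_true(is.na(m0$mean_spikes_per_burst))
  expect_true(is.na(m0$mean_inter_burst_interval))
})

test_that("ISI histogram statistics match closed forms", {
  # uniform over 8 bins -> 3 bits
  u <- isi_statistics(seq(0.5, 7.5, by = 1), bin_width = 1, range = c(0, 8))
  expect_equal(u$entropy, 3)
  # counts (1,1,2) -> 1.5 bits
  s <- isi_statistics(c(0.5, 1.5, 2.5, 2.7), bin_width = 1, range = c(0, 3))
  expect_equal(s$entropy, 1.5)
  expect_equal(s$peak_time, 2.5)           # modal bin centre
  # identical intervals: cv 0, entropy 0
  e <- isi_statistics(rep(5, 10), bin_width = 0.5, range = c(0, 15))
  expect_equal(e$cv, 0)
  expect_equal(e$entropy, 0)
  expect_equal(e$sd, 0)
  # modal ties resolve to the smallest bin; peak search can be restricted
  tie <- isi_statistics(c(1.5, 1.6, 30.2, 30.3), bin_width = 1,
                        range = c(0, 500), peak_range = c(1, 50))
  expect_equal(tie$peak_time, 1.5)
  late <- isi_statistics(c(1.5, 1.6, 30.2, 30.3, 30.4), bin_width = 1,
                         range = c(0, 500), peak_range = c(10, 50))
  expect_equal(late$peak_time, 30.5)
  expect_error(isi_statistics(numeric(0), 1, c(0, 15)), class = "pf_error_empty")
})

test_that("ordinal intra-burst ISI series are extracted per burst", {
  st <- spike_train(c(0, 0.004, 0.1, 0.104, 0.109, 0.5) ,
                    c(90, 70, 95, 80, 65, 50))
  b <- detect_bursts(st)          # sizes 2 and 3
  expect_length(intra_burst_isi_series(b, 1), 2)
  expect_length(intra_burst_isi_series(b, 2), 1)
  expect_length(intra_burst_isi_series(b, 3), 0)
  expect_equal(intra_burst_isi_series(b, 2), 5)
})

test_that("burst reliability is the in-field fraction of burst onsets", {
  geom <- map_geometry(5, 1)
  # four burst onsets: three in the field pixel, one elsewhere
  track <- dwell_track(c(0.5, 3.5), c(0.5, 0.5), dwell = 10, rate = 10)
  mkb <- function(t0) c(t0, t0 + 0.005)
  t <- sort(c(mkb(1), mkb(4), mkb(7), mkb(15)))
  a <- rep(c(60, 40), 4)
  b <- detect_bursts(spike_train(t, a))
  expect_length(b, 4)
  fld_px <- 6L + (6L - 1L) * 10L   # pixel containing (0.5, 0.5) on a 10-grid
  expect_equal(burst_reliability(b, track, manual_field(fld_px), geom), 0.75)
  other <- 9L + (6L - 1L) * 10L
  expect_equal(burst_reliability(b, track, manual_field(c(fld_px, other)), geom), 1)
  expect_equal(burst_reliability(b, track, manual_field(1L), geom), 0)
})

test_that("burst place map counts burst onsets per pixel", {
  track <- dwell_track(c(0.5, 3.5), c(0.5, 0.5), dwell = 2, rate = 10)
  b <- detect_bursts(spike_train(c(1, 1.005), c(60, 40)))
  m <- burst_place_map(b, track, arena_radius = 5)
  px <- floor((0.5 + 5) / 1) + 1
  expect_equal(m$rate[px, px], 0.5)   # 1 burst / 2 s dwell
})

test_that("burst field overlaps the spike field on a synthetic place cell", {
  track <- simulate_trajectory(trajectory_params(duration = 900, seed = 71))
  cp <- cell_params(field_center = c(6, -3), p_single = 0.5)
  spikes <- simulate_place_cell(track, cp, seed = 72)
  b <- detect_bursts(spikes)
  sm <- compute_rate_map(spikes, track, 15)
  bm <- burst_place_map(b, track, 15)
  centroid <- function(m) {
    f <- define_place_field(m, "top_quartile")
    n <- m$geometry$n
    i <- ((f$pixels - 1) %% n) + 1
    j <- ((f$pixels - 1) %/% n) + 1
    c(mean(m$geometry$centers[i]), mean(m$geometry$centers[j]))
  }
  expect_lt(sqrt(sum((centroid(sm) - centroid(bm))^2)), cp$field_width)
})
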