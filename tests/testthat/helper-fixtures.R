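# Independent burst oracle: an explicit greedy left-to-right scan over the
# spike train, kept deliberately separate from the package's vectorised
# maximal-run implementation.
oracle_bursts <- function(times, amps, max_isi_ms = 15, enforce_amplitude = TRUE) {
  n <- length(times)
  out <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n &&
           (times[j + 1] - times[j]) * 1000 <= max_isi_ms &&
           (!enforce_amplitude || amps[j + 1] < amps[j])) {
      j <- j + 1L
    }
    if (j > i) out[[length(out) + 1L]] <- i:j
    i <- j + 1L
  }
  out
}

# Random homogeneous-Poisson spike train with random amplitudes.
random_train <- function(rate, duration, seed) {
  set.seed(seed)
  n <- stats::rpois(1, rate * duration)
  if (n < 1) n <- 1
  t <- sort(stats::runif(n, 0, duration))
  t <- t[c(TRUE, diff(t) > 1e-9)]
  spike_train(t, stats::runif(length(t), 10, 100))
}

# Free-grid rate map from a rate matrix with uniform unit occupancy.
flat_map <- function(rate, occupancy = NULL, valid = NULL) {
  rate <- as.matrix(rate)
  geom <- map_geometry(NULL, n = nrow(rate))
  if (is.null(occupancy)) occupancy <- matrix(1, nrow(rate), ncol(rate))
  rate_map(rate, occupancy, geom, valid = valid)
}

# Minimal hand-built place field over given linear pixel indices.
manual_field <- function(pixels, mode = "above_mean") {
  structure(list(pixels = pixels, mode = mode, size = length(pixels),
                 threshold = NA_real_),
            class = "place_field")
}

# Stationary dwell track: `dwell` seconds at each (x, y) location in turn,
# sampled at `rate` Hz.
dwell_track <- function(xs, ys, dwell, rate = 10) {
  per <- round(dwell * rate)
  t <- (seq_len(per * length(xs)) - 1) / rate
  position_track(t, rep(xs, each = per), rep(ys, each = per))
}
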