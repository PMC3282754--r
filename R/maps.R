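#' Square-pixel grid geometry over a circular arena
#'
#' An axis-aligned, arena-centred grid of `pixel_size`-cm square pixels.
#' Pixel (i, j) (0-based) covers the half-open square
#' `[x0 + i*s, x0 + (i+1)*s) x [y0 + j*s, y0 + (j+1)*s)` with
#' `x0 = y0 = -arena_radius`. Pixels lying wholly outside the circle are
#' permanently invalid. For a 30-cm arena at 1-cm pixels this yields on the
#' order of 700 candidate pixels.
#'
#' @param arena_radius Arena radius in cm; `NULL` gives a free rectangular
#'   grid (used for hand-constructed maps).
#' @param pixel_size Pixel edge in cm (default 1).
#' @param n Grid side length in pixels; derived from the radius when omitted.
#' @return An object of class `map_geometry`.
#' @export
map_geometry <- function(arena_radius, pixel_size = 1, n = NULL) {
  if (is.null(n)) {
    if (is.null(arena_radius)) pf_error("pf_error_invalid", "need arena_radius or n")
    n <- ceiling(2 * arena_radius / pixel_size)
  }
  x0 <- if (is.null(arena_radius)) 0 else -arena_radius
  lo <- x0 + (seq_len(n) - 1) * pixel_size
  hi <- lo + pixel_size
  centers <- lo + pixel_size / 2
  if (is.null(arena_radius)) {
    in_arena <- matrix(TRUE, n, n)
  } else {
    # distance from arena centre to the nearest point of each pixel square
    clamp0 <- function(lo, hi) pmin(pmax(0, lo), hi)
    nx <- clamp0(lo, hi)
    ny <- clamp0(lo, hi)
    in_arena <- outer(nx^2, ny^2, `+`) < arena_radius^2
  }
  structure(list(n = n, x0 = x0, y0 = x0, pixel_size = pixel_size,
                 arena_radius = arena_radius, centers = centers,
                 in_arena = in_arena),
            class = "map_geometry")
}

same_geometry <- function(a, b) {
  isTRUE(a$n == b$n) && isTRUE(all.equal(a$pixel_size, b$pixel_size)) &&
    isTRUE(all.equal(a$x0, b$x0)) &&
    identical(is.null(a$arena_radius), is.null(b$arena_radius)) &&
    (is.null(a$arena_radius) || isTRUE(all.equal(a$arena_radius, b$arena_radius)))
}

## Map coordinates to 1-based pixel indices (clamped into the grid).
coord_to_pixel <- function(geom, x, y) {
  i <- pmin(pmax(floor((x - geom$x0) / geom$pixel_size) + 1L, 1L), geom$n)
  j <- pmin(pmax(floor((y - geom$y0) / geom$pixel_size) + 1L, 1L), geom$n)
  cbind(i = i, j = j)
}

#' Construct a rate map from matrices
#'
#' Low-level constructor used by [compute_rate_map()] and by tests that
#' build maps analytically. `rate` must equal `counts / occupancy` wherever
#' the map is valid; entries outside the validity mask are stored as `NA`.
#'
#' @param rate Matrix of firing rates (Hz per pixel).
#' @param occupancy Matrix of dwell times (s per pixel).
#' @param geometry A [map_geometry()].
#' @param valid Logical validity mask; defaults to in-arena pixels with
#'   positive occupancy.
#' @param counts Optional matrix of event counts per pixel.
#' @return An object of class `rate_map`.
#' @export
rate_map <- function(rate, occupancy, geometry, valid = NULL, counts = NULL) {
  rate <- as.matrix(rate); occupancy <- as.matrix(occupancy)
  n <- geometry$n
  if (!all(dim(rate) == c(n, n)) || !all(dim(occupancy) == c(n, n))) {
    pf_error("pf_error_geometry", "rate/occupancy dimensions do not match geometry")
  }
  if (is.null(valid)) valid <- geometry$in_arena & occupancy > 0
  rate[!valid] <- NA_real_
  structure(list(rate = rate, occupancy = occupancy, valid = valid,
                 counts = counts, geometry = geometry),
            class = "rate_map")
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf("<rate_map> %dx%d grid (%.0f-cm pixels), %d valid pixels, mean rate %.3f Hz\n",
              x$geometry$n, x$geometry$n, x$geometry$pixel_size,
              sum(x$valid), overall_rate(x)))
  invisible(x)
}

#' Occupancy-normalised firing-rate map
#'
#' Bins the session into square pixels: each spike (or other point event,
#' e.g. a burst onset) is assigned to the pixel of the temporally nearest
#' track sample; occupancy accrues one inter-sample interval per track
#' sample; the rate in a pixel is its event count divided by its occupancy.
#' Pixels visited for less than `min_occupancy` seconds are marked invalid
#' and excluded from every downstream statistic.
#'
#' @param spikes A [spike_train()], or a numeric vector of event times in
#'   seconds (used for burst-onset maps).
#' @param track A [position_track()].
#' @param arena_radius Arena radius in cm.
#' @param pixel_size Pixel edge in cm (default 1).
#' @param min_occupancy Minimum dwell time (s) for a pixel to be valid
#'   (default 0.1).
#' @param geometry Optional precomputed [map_geometry()].
#' @return A [rate_map()].
#' @export
compute_rate_map <- function(spikes, track, arena_radius, pixel_size = 1,
                             min_occupancy = 0.1, geometry = NULL) {
  if (!inherits(track, "position_track")) pf_error("pf_error_invalid", "track must be a position_track")
  if (length(track) < 2) pf_error("pf_error_empty", "track must contain at least 2 samples")
  times <- if (inherits(spikes, "spike_train")) spikes$times else as.numeric(spikes)
  if (is.null(geometry)) geometry <- map_geometry(arena_radius, pixel_size)
  n <- geometry$n
  dt <- stats::median(diff(track$times))

  px <- coord_to_pixel(geometry, track$x, track$y)
  lin <- px[, 1L] + (px[, 2L] - 1L) * n
  occupancy <- matrix(tabulate(lin, nbins = n * n) * dt, n, n)

  if (length(times)) {
    s <- nearest_sample(times, track$times)
    counts <- matrix(tabulate(lin[s], nbins = n * n), n, n)
  } else {
    counts <- matrix(0L, n, n)
  }
  valid <- geometry$in_arena & occupancy >= max(min_occupancy, .Machine$double.eps)
  rate <- counts / occupancy
  rate[!valid] <- NA_real_
  rate_map(rate, occupancy, geometry, valid = valid, counts = counts)
}

#' Occupancy-weighted overall firing rate of a map
#'
#' Total event count divided by total dwell time over valid pixels; equals
#' the session mean firing rate when no pixels are discarded.
#'
#' @param map A [rate_map()].
#' @return Rate in Hz.
#' @export
overall_rate <- function(map) {
  v <- map$valid
  if (!any(v)) pf_error("pf_error_empty", "rate map has no valid pixels")
  sum(map$rate[v] * map$occupancy[v]) / sum(map$occupancy[v])
}

#' Define a place field on a rate map
#'
#' Two definitions are supported: `above_mean` takes every valid pixel
#' whose rate strictly exceeds the cell's overall (occupancy-weighted) mean
#' firing rate -- the field-size definition used for the headline place-field
#' statistics -- and `top_quartile` takes the 25% of valid pixels with the
#' highest rates (ceiling count; ties broken by pixel index order).
#'
#' @param map A [rate_map()].
#' @param mode `"above_mean"` or `"top_quartile"`.
#' @return An object of class `place_field` with elements `pixels` (linear
#'   indices into the map matrices), `mode`, `size` and `threshold`.
#' @export
define_place_field <- function(map, mode = c("above_mean", "top_quartile")) {
  mode <- match.arg(mode)
  v <- which(map$valid)
  if (!length(v)) pf_error("pf_error_empty", "rate map has no valid pixels")
  r <- map$rate[v]
  if (mode == "above_mean") {
    thr <- overall_rate(map)
    members <- v[r > thr]
  } else {
    m <- ceiling(0.25 * length(v))
    ord <- order(-r, v)
    members <- sort(v[ord[seq_len(m)]])
    thr <- min(r[ord[seq_len(m)]])
  }
  structure(list(pixels = members, mode = mode, size = length(members),
                 threshold = thr),
            class = "place_field")
}

#' @export
print.place_field <- function(x, ...) {
  cat(sprintf("<place_field> %s, %d pixels\n", x$mode, x$size))
  invisible(x)
}

#' Analytic Gaussian-bump rate map
#'
#' Builds a noiseless rate map with uniform occupancy from a 2-D Gaussian
#' tuning surface, `baseline + peak * exp(-||p - center||^2 / (2 width^2))`
#' evaluated at pixel centres. Used to construct smooth reference fields
#' for rotation-recovery and regression checks.
#'
#' @param center Field centre `c(x, y)` in cm.
#' @param width Gaussian sd in cm.
#' @param arena_radius Arena radius in cm.
#' @param peak,baseline Peak (above baseline) and baseline rates in Hz.
#' @param pixel_size Pixel edge in cm.
#' @param occupancy Dwell time per pixel in seconds (uniform).
#' @return A [rate_map()].
#' @export
gaussian_rate_map <- function(center, width, arena_radius, peak = 10,
                              baseline = 0, pixel_size = 1, occupancy = 1) {
  geom <- map_geometry(arena_radius, pixel_size)
  cx <- geom$centers
  d2 <- outer((cx - center[1])^2, (cx - center[2])^2, `+`)
  rate <- baseline + peak * exp(-d2 / (2 * width^2))
  occ <- matrix(occupancy, geom$n, geom$n)
  occ[!geom$in_arena] <- 0
  rate_map(rate, occ, geom, valid = geom$in_arena)
}

#' Export a rate map as a dense delimited matrix
#'
#' Writes the rate matrix as CSV with `NA` marking invalid pixels; rows are
#' x-indices, columns y-indices.
#'
#' @param map A [rate_map()].
#' @param path Output file path.
#' @export
write_rate_map <- function(map, path) {
  utils::write.table(map$rate, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
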