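#' Detect complex-spike bursts
#'
#' A burst is any event of two or more spikes in which each spike occurs
#' within `max_isi_ms` of its predecessor with progressively (strictly)
#' decreasing amplitudes. Detection is a left-to-right scan that extends
#' the current candidate while the next inter-spike interval and amplitude
#' satisfy the rule; because the rule constrains only consecutive spike
#' pairs, the scan partitions the train into maximal qualifying runs, and
#' each spike belongs to at most one burst. Amplitude ties terminate a
#' burst. The amplitude criterion can be switched off.
#'
#' @param spikes A [spike_train()].
#' @param max_isi_ms Maximum intra-burst inter-spike interval in ms
#'   (default 15).
#' @param enforce_amplitude Require strictly decreasing amplitudes
#'   (default `TRUE`).
#' @return An object of class `burst_set`: `index` (list of member spike
#'   index vectors), `isis` (list of member ISI vectors, ms), `start_time`,
#'   `end_time` (s), `n_spikes_in_bursts`, `n_spikes_total`.
#' @export
detect_bursts <- function(spikes, max_isi_ms = 15, enforce_amplitude = TRUE) {
  if (!inherits(spikes, "spike_train")) pf_error("pf_error_invalid", "spikes must be a spike_train")
  n <- length(spikes)
  empty <- structure(list(index = list(), isis = list(),
                          start_time = numeric(0), end_time = numeric(0),
                          n_spikes_in_bursts = 0L, n_spikes_total = n,
                          max_isi_ms = max_isi_ms,
                          enforce_amplitude = enforce_amplitude),
                     class = "burst_set")
  if (n < 2) return(empty)
  t <- spikes$times; a <- spikes$amplitudes
  ok <- diff(t) * 1000 <= max_isi_ms
  if (enforce_amplitude) ok <- ok & diff(a) < 0
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep)) return(empty)
  index <- lapply(keep, function(k) starts[k]:(ends[k] + 1L))
  isis <- lapply(index, function(ix) diff(t[ix]) * 1000)
  structure(list(
    index = index,
    isis = isis,
    start_time = vapply(index, function(ix) t[ix[1]], numeric(1)),
    end_time = vapply(index, function(ix) t[ix[length(ix)]], numeric(1)),
    n_spikes_in_bursts = sum(lengths(index)),
    n_spikes_total = n,
    max_isi_ms = max_isi_ms,
    enforce_amplitude = enforce_amplitude
  ), class = "burst_set")
}

#' @export
length.burst_set <- function(x) length(x$index)

#' @export
print.burst_set <- function(x, ...) {
  cat(sprintf("<burst_set> %d bursts, %d of %d spikes in bursts\n",
              length(x), x$n_spikes_in_bursts, x$n_spikes_total))
  invisible(x)
}

#' Session-level burst statistics
#'
#' Burst frequency (bursts/s), intra-burst spike rate (burst spikes over
#' total recording time), mean spikes per burst (burst length), the
#' percentage of all spikes that occur inside bursts, and the mean
#' inter-burst interval (gap from the end of each burst to the start of the
#' next). With fewer than two bursts the inter-burst interval is flagged
#' missing (`NA`); with no bursts, frequency and ratio are 0 and the
#' remaining statistics missing.
#'
#' @param bursts A [detect_bursts()] result.
#' @param duration Recording duration in seconds.
#' @return A named list of class `burst_metrics`.
#' @export
burst_metrics <- function(bursts, duration) {
  if (!is.finite(duration) || duration <= 0) pf_error("pf_error_invalid", "duration must be > 0")
  nb <- length(bursts)
  sizes <- lengths(bursts$index)
  in_bursts <- sum(sizes)
  ntot <- bursts$n_spikes_total
  structure(list(
    n_bursts = nb,
    burst_frequency = nb / duration,
    intra_burst_spike_rate = in_bursts / duration,
    mean_spikes_per_burst = if (nb) mean(sizes) else NA_real_,
    intra_burst_ratio = if (ntot > 0) 100 * in_bursts / ntot else 0,
    mean_inter_burst_interval = if (nb >= 2)
      mean(bursts$start_time[-1] - bursts$end_time[-nb]) else NA_real_
  ), class = "burst_metrics")
}

#' Histogram-based statistics of an interval sample
#'
#' Bins the intervals into fixed-width bins over `range` (half-open on the
#' left: an interval falls in bin b if `lo + (b-1)*w < x <= lo + b*w`), and
#' reports the centre of the modal bin (restricted to `peak_range`, ties to
#' the smallest), the Shannon entropy `-sum p_b log2 p_b` over non-empty
#' bins, and the coefficient of variation and standard deviation of the raw
#' intervals. Intervals outside `range` are excluded from the histogram but
#' retained for CV/SD.
#'
#' @param intervals Intervals in ms (at least 2).
#' @param bin_width Histogram bin width in ms.
#' @param range Histogram range `c(lo, hi)` in ms.
#' @param peak_range Range searched for the modal bin (default: `range`).
#' @return A named list of class `isi_stats`: `peak_time`, `cv`, `entropy`,
#'   `sd`, plus the `counts` and bin `centers`.
#' @export
isi_statistics <- function(intervals, bin_width, range = c(0, 15),
                           peak_range = range) {
  intervals <- as.numeric(intervals)
  if (length(intervals) < 2) pf_error("pf_error_empty", "need at least 2 intervals")
  nb <- ceiling((range[2] - range[1]) / bin_width)
  inr <- intervals[intervals > range[1] & intervals <= range[1] + nb * bin_width]
  bin <- ceiling((inr - range[1]) / bin_width)
  counts <- tabulate(bin, nbins = nb)
  centers <- range[1] + (seq_len(nb) - 0.5) * bin_width
  if (sum(counts) == 0) pf_error("pf_error_empty", "no intervals fall inside the histogram range")
  p <- counts / sum(counts)
  entropy <- -sum(p[p > 0] * log2(p[p > 0]))
  in_peak <- centers >= peak_range[1] & centers <= peak_range[2]
  cand <- which(in_peak)
  peak <- cand[which.max(counts[cand])]
  structure(list(
    peak_time = centers[peak],
    cv = stats::sd(intervals) / mean(intervals),
    entropy = entropy,
    sd = stats::sd(intervals),
    counts = counts,
    centers = centers
  ), class = "isi_stats")
}

#' Ordinal intra-burst inter-spike intervals
#'
#' The k-th ISI from every burst with at least k+1 spikes, in burst order:
#' ISI-1 is the interval between the first and second spikes of a burst,
#' ISI-2 between the second and third, and so on.
#'
#' @param bursts A [detect_bursts()] result.
#' @param k Ordinal (>= 1).
#' @return Numeric vector of intervals in ms.
#' @export
intra_burst_isi_series <- function(bursts, k) {
  if (k < 1) pf_error("pf_error_invalid", "k must be >= 1")
  out <- vapply(bursts$isis, function(v) if (length(v) >= k) v[k] else NA_real_,
                numeric(1))
  out[!is.na(out)]
}

#' Fraction of bursts occurring inside the place field
#'
#' Each burst is located at the animal's pixel at the burst's first spike
#' (temporally nearest track sample); the reliability is the fraction of
#' bursts whose location falls inside the field. A perfectly reliable cell
#' bursts only within its field.
#'
#' @param bursts A [detect_bursts()] result (at least 1 burst).
#' @param track A [position_track()].
#' @param field A [define_place_field()] result.
#' @param geometry The [map_geometry()] of the map the field was defined on.
#' @return Fraction in `[0, 1]`.
#' @export
burst_reliability <- function(bursts, track, field, geometry) {
  if (length(bursts) < 1) pf_error("pf_error_empty", "no bursts detected")
  s <- nearest_sample(bursts$start_time, track$times)
  px <- coord_to_pixel(geometry, track$x[s], track$y[s])
  lin <- px[, 1L] + (px[, 2L] - 1L) * geometry$n
  mean(lin %in% field$pixels)
}

#' Burst place map
#'
#' An occupancy-normalised map of burst onsets (bursts/s per pixel), built
#' exactly like the spike rate map but counting one event per burst at its
#' first spike. Its [spatial_coherence()] quantifies how smoothly bursting
#' intensity varies over space.
#'
#' @inheritParams compute_rate_map
#' @param bursts A [detect_bursts()] result.
#' @return A [rate_map()] in bursts/s.
#' @export
burst_place_map <- function(bursts, track, arena_radius, pixel_size = 1,
                            min_occupancy = 0.1, geometry = NULL) {
  compute_rate_map(bursts$start_time, track, arena_radius,
                   pixel_size = pixel_size, min_occupancy = min_occupancy,
                   geometry = geometry)
}

#' Per-burst table export
#'
#' One row per burst with its onset, size, first three intra-burst ISIs,
#' pixel location and field membership.
#'
#' @param bursts A [detect_bursts()] result.
#' @param track A [position_track()].
#' @param geometry A [map_geometry()].
#' @param field Optional [define_place_field()] result.
#' @return A data frame.
#' @export
burst_table <- function(bursts, track, geometry, field = NULL) {
  nb <- length(bursts)
  kth <- function(k) vapply(bursts$isis, function(v)
    if (length(v) >= k) v[k] else NA_real_, numeric(1))
  if (nb == 0) {
    return(data.frame(burst_id = integer(0), start_time_s = numeric(0),
                      n_spikes = integer(0), isi1_ms = numeric(0),
                      isi2_ms = numeric(0), isi3_ms = numeric(0),
                      pixel_i = integer(0), pixel_j = integer(0),
                      in_field = logical(0)))
  }
  s <- nearest_sample(bursts$start_time, track$times)
  px <- coord_to_pixel(geometry, track$x[s], track$y[s])
  lin <- px[, 1L] + (px[, 2L] - 1L) * geometry$n
  data.frame(
    burst_id = seq_len(nb),
    start_time_s = bursts$start_time,
    n_spikes = lengths(bursts$index),
    isi1_ms = kth(1), isi2_ms = kth(2), isi3_ms = kth(3),
    pixel_i = px[, 1L], pixel_j = px[, 2L],
    in_field = if (is.null(field)) NA else lin %in% field$pixels
  )
}

#' Restrict a spike train to burst member spikes
#'
#' Returns the sub-train containing only spikes that belong to a detected
#' burst, e.g. to compute spatial selectivity from burst spikes only.
#'
#' @param spikes A [spike_train()].
#' @param bursts A [detect_bursts()] result for `spikes`.
#' @return A [spike_train()].
#' @export
burst_spikes <- function(spikes, bursts) {
  ix <- sort(unlist(bursts$index))
  spike_train(spikes$times[ix], spikes$amplitudes[ix])
}
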