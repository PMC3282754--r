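#' @keywords internal
"_PACKAGE"

## Condition helper: all package errors carry class "pf_error" plus a
## specific subclass so callers can distinguish failure modes.
pf_error <- function(class, msg) {
  stop(structure(
    class = c(class, "pf_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

## Evaluate `code` under a temporary RNG state seeded with `seed`;
## the caller's .Random.seed is restored afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Spike train for one cell-session
#'
#' Ordered spike times with one peak amplitude per spike. Amplitudes are
#' required by the burst definition (a complex-spike burst has progressively
#' decreasing amplitudes); if none are supplied a constant amplitude of 1 is
#' used, which effectively disables the amplitude criterion.
#'
#' @param times Spike times in seconds, strictly increasing.
#' @param amplitudes Per-spike peak amplitudes (arbitrary units, > 0);
#'   defaults to 1 for every spike.
#' @return An object of class `spike_train` with elements `times` and
#'   `amplitudes`.
#' @export
spike_train <- function(times, amplitudes = NULL) {
  times <- as.numeric(times)
  if (anyNA(times)) pf_error("pf_error_invalid", "spike times contain NA")
  if (length(times) > 1 && any(diff(times) <= 0)) {
    pf_error("pf_error_nonmonotonic_time", "spike times must be strictly increasing")
  }
  if (is.null(amplitudes)) amplitudes <- rep(1, length(times))
  amplitudes <- as.numeric(amplitudes)
  if (length(amplitudes) != length(times)) {
    pf_error("pf_error_invalid", "times and amplitudes must have equal length")
  }
  if (any(!is.finite(amplitudes)) || any(amplitudes <= 0)) {
    pf_error("pf_error_invalid", "amplitudes must be finite and > 0")
  }
  structure(list(times = times, amplitudes = amplitudes), class = "spike_train")
}

#' @export
length.spike_train <- function(x) length(x$times)

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes over %.1f s\n", length(x),
              if (length(x)) diff(range(x$times)) else 0))
  invisible(x)
}

#' Position track of the animal
#'
#' Timestamped 2-D head position in an arena-centred frame (origin at the
#' cylinder centre), nominally sampled at 60 Hz by an overhead camera.
#'
#' @param times Sample timestamps in seconds, strictly increasing.
#' @param x,y Coordinates in cm.
#' @param arena_radius Optional arena radius in cm; if given, every sample
#'   must lie inside the arena.
#' @return An object of class `position_track`.
#' @export
position_track <- function(times, x, y, arena_radius = NULL) {
  times <- as.numeric(times); x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(times) || length(y) != length(times)) {
    pf_error("pf_error_invalid", "times, x and y must have equal length")
  }
  if (length(times) == 0) pf_error("pf_error_empty", "empty position track")
  if (length(times) > 1 && any(diff(times) <= 0)) {
    pf_error("pf_error_nonmonotonic_time", "track times must be strictly increasing")
  }
  if (!is.null(arena_radius)) {
    r2 <- x^2 + y^2
    if (any(r2 > (arena_radius + 1e-6)^2)) {
      pf_error("pf_error_out_of_arena", sprintf(
        "%d track samples fall outside the %.1f-cm arena radius",
        sum(r2 > (arena_radius + 1e-6)^2), arena_radius))
    }
  }
  structure(list(times = times, x = x, y = y), class = "position_track")
}

#' @export
length.position_track <- function(x) length(x$times)

#' @export
print.position_track <- function(x, ...) {
  cat(sprintf("<position_track> %d samples, %.1f s\n", length(x),
              diff(range(x$times))))
  invisible(x)
}

#' Session descriptor
#'
#' Metadata for one recording session: arena size, position of the local
#' cue card, and session duration. Card angle is the azimuth of the card
#' centre, counter-clockwise positive, in `[0, 360)`.
#'
#' @param session_id Integer session number (1..3 in the standard protocol).
#' @param arena_radius Arena radius in cm.
#' @param card_angle Cue-card centre angle in degrees, in `[0, 360)`.
#' @param duration Session duration in seconds.
#' @return An object of class `session_descriptor`.
#' @export
session_descriptor <- function(session_id, arena_radius, card_angle, duration) {
  session_id <- as.integer(session_id)
  if (!is.finite(arena_radius) || arena_radius <= 0) {
    pf_error("pf_error_invalid", "arena_radius must be > 0")
  }
  if (!is.finite(duration) || duration <= 0) {
    pf_error("pf_error_invalid", "duration must be > 0")
  }
  card_angle <- as.numeric(card_angle) %% 360
  structure(list(session_id = session_id, arena_radius = arena_radius,
                 card_angle = card_angle, duration = duration),
            class = "session_descriptor")
}

#' @export
print.session_descriptor <- function(x, ...) {
  cat(sprintf("<session %d> radius %.0f cm, card at %.0f deg, %.0f s\n",
              x$session_id, x$arena_radius, x$card_angle, x$duration))
  invisible(x)
}

## Index of the temporally nearest track sample for each query time.
nearest_sample <- function(t, times) {
  i <- findInterval(t, times)
  i0 <- pmax(i, 1L)
  i1 <- pmin(i + 1L, length(times))
  ifelse(abs(times[i1] - t) < abs(t - times[i0]), i1, i0)
}
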