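#' Pixel-by-pixel similarity of two rate maps
#'
#' Pearson correlation over pixels valid in both maps, the standard
#' cross-session stability index, with its Fisher Z transform.
#'
#' @param a,b [rate_map()] objects on the same grid.
#' @return List of class `similarity_result` with `r`, `z`, `n_pixels`.
#' @export
map_similarity <- function(a, b) {
  if (!same_geometry(a$geometry, b$geometry)) {
    pf_error("pf_error_geometry", "rate maps have different grid geometry")
  }
  joint <- a$valid & b$valid
  if (sum(joint) < 10) {
    pf_error("pf_error_degenerate", "fewer than 10 jointly valid pixels")
  }
  x <- a$rate[joint]; y <- b$rate[joint]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    pf_error("pf_error_degenerate", "zero rate variance on jointly valid pixels")
  }
  r <- stats::cor(x, y)
  structure(list(r = r, z = fisher_z(r), n_pixels = sum(joint)),
            class = "similarity_result")
}

## Linear source-pixel indices for rotating a map by `angle` degrees CCW
## about the arena centre (nearest-neighbour resampling); NA where the
## source falls outside the grid.
rotation_source_index <- function(geom, angle) {
  n <- geom$n
  cx <- geom$centers
  X <- matrix(cx, n, n)
  Y <- matrix(cx, n, n, byrow = TRUE)
  rad <- angle * pi / 180
  # target centre rotated by -angle gives the source location
  xs <- cos(rad) * X + sin(rad) * Y
  ys <- -sin(rad) * X + cos(rad) * Y
  si <- floor((xs - geom$x0) / geom$pixel_size) + 1
  sj <- floor((ys - geom$y0) / geom$pixel_size) + 1
  ok <- si >= 1 & si <= n & sj >= 1 & sj <= n
  idx <- si + (sj - 1) * n
  idx[!ok] <- NA_integer_
  idx
}

#' Rotation search for maximal map similarity
#'
#' Rotates map `b` about the arena centre through `{0, step, ...}` degrees
#' (nearest-neighbour resampling; pixels sourced from outside the arena are
#' invalid), computes the pixel-by-pixel correlation with `a` on jointly
#' valid pixels at each angle, and returns the angle of maximum correlation
#' (ties broken towards the smallest angle). `abs_rotation` folds the angle
#' to `[0, 180]`, the direction-agnostic amount of rotation.
#'
#' @param a Fixed [rate_map()].
#' @param b [rate_map()] to be rotated.
#' @param step Angular step in degrees (default 1).
#' @return List of class `rotation_result` with `best_angle`, `max_r`,
#'   `max_z`, `abs_rotation`, and the per-angle correlation profile `r_by_angle`.
#' @export
best_rotation <- function(a, b, step = 1) {
  if (!same_geometry(a$geometry, b$geometry)) {
    pf_error("pf_error_geometry", "rate maps have different grid geometry")
  }
  if (is.null(a$geometry$arena_radius)) {
    pf_error("pf_error_geometry", "rotation search needs an arena-centred grid")
  }
  angles <- seq(0, 360 - step, by = step)
  avalid <- a$valid
  arate <- a$rate
  brate <- b$rate             # NA at invalid pixels already
  rs <- rep(NA_real_, length(angles))
  for (k in seq_along(angles)) {
    idx <- rotation_source_index(a$geometry, angles[k])
    bv <- brate[idx]          # NA propagates for out-of-grid / invalid source
    joint <- avalid & !is.na(bv)
    if (sum(joint) < 10) next
    x <- arate[joint]; y <- bv[joint]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    rs[k] <- stats::cor(x, y)
  }
  if (all(is.na(rs))) pf_error("pf_error_degenerate", "no angle yields a defined correlation")
  best <- which.max(replace(rs, is.na(rs), -Inf))
  ang <- angles[best]
  structure(list(best_angle = ang, max_r = rs[best], max_z = fisher_z(rs[best]),
                 abs_rotation = min(ang, 360 - ang),
                 r_by_angle = stats::setNames(rs, angles)),
            class = "rotation_result")
}

#' @export
print.rotation_result <- function(x, ...) {
  cat(sprintf("<rotation_result> best %g deg (abs %g), r = %.3f\n",
              x$best_angle, x$abs_rotation, x$max_r))
  invisible(x)
}

## Circular distance folded to [0, 180].
fold_angle <- function(d) {
  d <- abs(d) %% 360
  pmin(d, 360 - d)
}

#' Classify a field's cue dependency from its best rotation
#'
#' A field that stayed within a 90-degree arc (+/-45 degrees) of its
#' original position is "distal" (it followed the unmoved distal light); a
#' field within +/-45 degrees of the rotated cue-card position is "local";
#' everything else "remap". The exact 45-degree boundary falls to remap
#' (half-open windows). The rotation angle is interpreted as the field's
#' displacement, i.e. the rotation of the earlier session's map that best
#' matches the later one.
#'
#' @param rotation A [best_rotation()] result, or a best angle in degrees.
#' @param card_rotation Card rotation between the two sessions in degrees,
#'   in `(-180, 180]`, CCW positive.
#' @return One of `"distal"`, `"local"`, `"remap"`.
#' @export
classify_cue_following <- function(rotation, card_rotation) {
  ang <- if (inherits(rotation, "rotation_result")) rotation$best_angle else as.numeric(rotation)
  d0 <- fold_angle(ang)
  dc <- fold_angle(ang - card_rotation)
  if (d0 < 45) "distal" else if (dc < 45) "local" else "remap"
}

#' Similarity baseline from random cell pairs
#'
#' Fisher-Z similarities of randomly picked pairs of different cells, the
#' chance-level reference against which within-cell stability is compared.
#' Pairs are sampled without replacement when enough distinct pairs exist.
#'
#' @param maps List of [rate_map()] objects (one cell each, same grid).
#' @param n_pairs Number of pairs (default: all distinct pairs).
#' @param seed Optional RNG seed.
#' @return Numeric vector of z values (degenerate pairs dropped).
#' @export
random_pair_baseline <- function(maps, n_pairs = NULL, seed = NULL) {
  m <- length(maps)
  if (m < 2) pf_error("pf_error_invalid", "need at least 2 cells")
  pairs <- utils::combn(m, 2)
  total <- ncol(pairs)
  if (is.null(n_pairs)) n_pairs <- total
  sel <- if (n_pairs >= total) seq_len(total) else
    with_seed(seed, sample.int(total, n_pairs))
  z <- vapply(sel, function(k) {
    tryCatch(map_similarity(maps[[pairs[1, k]]], maps[[pairs[2, k]]])$z,
             pf_error = function(e) NA_real_)
  }, numeric(1))
  z[!is.na(z)]
}
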