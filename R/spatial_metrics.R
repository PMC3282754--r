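## Fisher Z transform with the correlation clipped away from +/-1 so the
## transform stays finite.
fisher_z <- function(r, clip = 1 - 1e-7) atanh(pmin(pmax(r, -clip), clip))

#' Spatial selectivity of a place field
#'
#' `log10(in-field mean rate / out-field mean rate)`, with unweighted pixel
#' means. A silent out-field returns `Inf`; callers treat infinite
#' selectivity as a flagged value and exclude it from averages.
#'
#' @param map A [rate_map()].
#' @param field A [define_place_field()] result.
#' @return Selectivity in log10 units.
#' @export
spatial_selectivity <- function(map, field) {
  v <- which(map$valid)
  inside <- field$pixels
  outside <- setdiff(v, inside)
  if (!length(inside)) pf_error("pf_error_empty", "place field is empty")
  if (!length(outside)) pf_error("pf_error_empty", "place-field complement is empty")
  rin <- mean(map$rate[inside])
  rout <- mean(map$rate[outside])
  if (rout == 0) return(Inf)
  log10(rin / rout)
}

## Mean rate over the (up to 8) valid neighbours of every pixel, plus the
## neighbour count used.
neighbor_mean <- function(map) {
  n <- map$geometry$n
  r0 <- map$rate
  r0[!map$valid] <- 0
  v0 <- map$valid * 1
  s <- matrix(0, n, n); cnt <- matrix(0, n, n)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    si <- max(1, 1 + di):min(n, n + di)   # rows of the shifted source
    ti <- max(1, 1 - di):min(n, n - di)   # rows of the target
    sj <- max(1, 1 + dj):min(n, n + dj)
    tj <- max(1, 1 - dj):min(n, n - dj)
    s[ti, tj] <- s[ti, tj] + r0[si, sj]
    cnt[ti, tj] <- cnt[ti, tj] + v0[si, sj]
  }
  nb <- s / cnt
  nb[cnt == 0] <- NA_real_
  list(mean = nb, count = cnt)
}

#' Spatial coherence of a rate map
#'
#' Pearson correlation between the rate of each valid pixel and the mean
#' rate over its (valid) 8 neighbours, a measure of local smoothness of the
#' firing surface, plus its Fisher Z transform for parametric comparison.
#' Pixels without any valid neighbour are skipped.
#'
#' @param map A [rate_map()].
#' @return List with elements `r` and `z`.
#' @export
spatial_coherence <- function(map) {
  nb <- neighbor_mean(map)
  use <- map$valid & nb$count >= 1
  if (sum(use) < 3) pf_error("pf_error_empty", "fewer than 3 pixels with valid neighbors")
  x <- map$rate[use]
  y <- nb$mean[use]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    pf_error("pf_error_undefined_coherence",
             "coherence undefined: zero variance in rates or neighbor means")
  }
  r <- stats::cor(x, y)
  list(r = r, z = fisher_z(r))
}

#' Spatial information rate of a rate map
#'
#' The information-theoretic rate `I = sum_x p(x) lambda(x) log2(lambda(x)/lambda_bar)`
#' in bits/s, where `p(x)` is the occupancy probability of pixel `x`
#' (renormalised over valid pixels), `lambda(x)` its firing rate, and
#' `lambda_bar = sum_x p(x) lambda(x)` the occupancy-weighted mean rate.
#' Pixels with zero rate contribute zero.
#'
#' @param map A [rate_map()].
#' @return Information rate in bits/s.
#' @export
spatial_information <- function(map) {
  v <- map$valid
  if (!any(v)) pf_error("pf_error_empty", "rate map has no valid pixels")
  p <- map$occupancy[v] / sum(map$occupancy[v])
  lam <- map$rate[v]
  lbar <- sum(p * lam)
  if (lbar <= 0) pf_error("pf_error_empty", "overall mean rate is zero")
  pos <- lam > 0
  sum(p[pos] * lam[pos] * log2(lam[pos] / lbar))
}

#' All scalar spatial statistics for one rate map
#'
#' Bundles the per-session spatial battery: overall (occupancy-weighted)
#' rate, in/out-field rates, selectivity, coherence (r and Fisher Z),
#' information rate, and field size. Coherence is `NA` (flagged missing)
#' when undefined.
#'
#' @param map A [rate_map()].
#' @param field Optional [define_place_field()] result; defaults to the
#'   above-mean field of `map`.
#' @return A named list of class `spatial_metrics`.
#' @export
spatial_metrics <- function(map, field = NULL) {
  if (is.null(field)) field <- define_place_field(map, "above_mean")
  v <- which(map$valid)
  inside <- field$pixels
  outside <- setdiff(v, inside)
  coh <- tryCatch(spatial_coherence(map),
                  pf_error = function(e) list(r = NA_real_, z = NA_real_))
  sel <- if (length(inside) && length(outside)) spatial_selectivity(map, field) else NA_real_
  structure(list(
    overall_rate = overall_rate(map),
    in_field_rate = if (length(inside)) mean(map$rate[inside]) else NA_real_,
    out_field_rate = if (length(outside)) mean(map$rate[outside]) else NA_real_,
    selectivity = sel,
    coherence_r = coh$r,
    coherence_z = coh$z,
    information_rate = spatial_information(map),
    field_size = field$size
  ), class = "spatial_metrics")
}
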