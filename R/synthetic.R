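#' Parameters for a simulated foraging trajectory
#'
#' Defaults emulate random foraging in the standard recording arena: a
#' 30-cm-diameter cylinder tracked at 60 Hz, mean running speed 6.2 cm/s,
#' 25-min sessions.
#'
#' @param mean_speed Mean running speed, cm/s.
#' @param heading_persistence Correlation time of the heading, s; smaller
#'   values give more tortuous paths.
#' @param sample_rate Tracking rate, Hz.
#' @param arena_radius Arena radius, cm.
#' @param duration Session length, s.
#' @param seed RNG seed.
#' @return A list of class `trajectory_params`.
#' @export
trajectory_params <- function(mean_speed = 6.2, heading_persistence = 1,
                              sample_rate = 60, arena_radius = 15,
                              duration = 1500, seed = NULL) {
  if (mean_speed <= 0 || sample_rate <= 0 || duration <= 0 || arena_radius <= 0) {
    pf_error("pf_error_invalid", "trajectory parameters must be positive")
  }
  structure(list(mean_speed = mean_speed,
                 heading_persistence = heading_persistence,
                 sample_rate = sample_rate, arena_radius = arena_radius,
                 duration = duration, seed = seed),
            class = "trajectory_params")
}

#' Parameters for a simulated place cell
#'
#' The generator is doubly stochastic: firing *events* are an inhomogeneous
#' Poisson process whose rate is a Gaussian bump over the arena
#' (`baseline + peak * exp(-d^2 / 2 width^2)`); each event is a lone spike
#' with probability `p_single`, otherwise a burst whose spike count beyond
#' two is geometric with continuation probability `burst_continue` and
#' whose consecutive ISIs are gamma-distributed with mean `intra_isi_mean`
#' and shape `intra_isi_shape`, truncated by rejection to (0, 15) ms so
#' that generated bursts are detectable by the 15-ms criterion. Amplitudes
#' fall by the factor `1 - amp_decay` per successive spike in a burst.
#'
#' The burst-structure defaults (p_single 0.82, burst_continue 0.18) place
#' roughly a third of spikes in bursts at about 2.2 spikes per burst, and
#' the control-like ISI defaults (mean 2.5 ms, shape 4) match the temporal
#' scale of recorded complex spikes; see the methods vignette.
#'
#' @param field_center Place-field centre `c(x, y)`, cm.
#' @param field_width Gaussian sd of the field, cm.
#' @param peak_event_rate Event rate at the field centre above baseline, Hz.
#' @param baseline_event_rate Event rate far from the field, Hz.
#' @param p_single Probability that an event is a lone spike.
#' @param burst_continue Probability of adding one more spike to a burst.
#' @param intra_isi_mean Mean intra-burst ISI, ms (must be < 15).
#' @param intra_isi_shape Gamma shape of intra-burst ISIs (smaller = more
#'   dispersed).
#' @param amp0 Amplitude of a lone spike / first spike of a burst.
#' @param amp_decay Fractional amplitude drop per successive burst spike.
#' @param cue_type `"distal"`, `"local"` or `"remap"`.
#' @return A list of class `cell_params`.
#' @export
cell_params <- function(field_center = c(7, 0), field_width = 4,
                        peak_event_rate = 6, baseline_event_rate = 0.1,
                        p_single = 0.82, burst_continue = 0.18,
                        intra_isi_mean = 2.5, intra_isi_shape = 4,
                        amp0 = 100, amp_decay = 0.2,
                        cue_type = c("distal", "local", "remap")) {
  cue_type <- match.arg(cue_type)
  if (p_single < 0 || p_single > 1) pf_error("pf_error_invalid", "p_single must be in [0, 1]")
  if (burst_continue <= 0 || burst_continue >= 1) pf_error("pf_error_invalid", "burst_continue must be in (0, 1)")
  if (intra_isi_mean <= 0 || intra_isi_mean >= 15) pf_error("pf_error_invalid", "intra_isi_mean must be in (0, 15) ms")
  if (amp_decay <= 0 || amp_decay >= 1) pf_error("pf_error_invalid", "amp_decay must be in (0, 1)")
  structure(list(field_center = field_center, field_width = field_width,
                 peak_event_rate = peak_event_rate,
                 baseline_event_rate = baseline_event_rate,
                 p_single = p_single, burst_continue = burst_continue,
                 intra_isi_mean = intra_isi_mean,
                 intra_isi_shape = intra_isi_shape,
                 amp0 = amp0, amp_decay = amp_decay, cue_type = cue_type),
            class = "cell_params")
}

#' Simulate a random-foraging trajectory
#'
#' Heading follows a random walk whose increment variance is set by
#' `heading_persistence`; speed follows a mean-reverting AR(1) around
#' `mean_speed` (relaxation 2 s, stationary sd 25% of the mean, floored at
#' zero); the wall reflects the velocity specularly. Deterministic given
#' the seed.
#'
#' @param params A [trajectory_params()].
#' @return A [position_track()] with `duration * sample_rate` samples, all
#'   strictly inside the arena.
#' @export
simulate_trajectory <- function(params) {
  stopifnot(inherits(params, "trajectory_params"))
  with_seed(params$seed, {
    n <- round(params$duration * params$sample_rate)
    dt <- 1 / params$sample_rate
    R <- params$arena_radius - 0.5        # keep the head centre off the wall
    mu <- params$mean_speed

    # speed: AR(1) around mu, relaxation 2 s, stationary sd 0.25 mu
    phi <- exp(-dt / 2)
    innov_sd <- 0.25 * mu * sqrt(1 - phi^2)
    e <- as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), phi,
                                  method = "recursive",
                                  init = stats::rnorm(1, 0, 0.25 * mu)))
    v <- pmax(mu + e, 0)

    inc <- stats::rnorm(n, 0, sqrt(2 * dt / params$heading_persistence))
    th0 <- stats::runif(1, 0, 2 * pi)
    r0 <- sqrt(stats::runif(1)) * R * 0.8
    a0 <- stats::runif(1, 0, 2 * pi)

    x <- numeric(n); y <- numeric(n)
    x[1] <- r0 * cos(a0); y[1] <- r0 * sin(a0)
    th <- th0
    k <- 1L
    block <- 4000L
    while (k < n) {
      hi <- min(n, k + block)
      seg <- (k + 1L):hi
      seg_th <- th + cumsum(inc[seg])
      px <- x[k] + cumsum(v[seg] * dt * cos(seg_th))
      py <- y[k] + cumsum(v[seg] * dt * sin(seg_th))
      out <- which(px * px + py * py > R * R)
      if (!length(out)) {
        x[seg] <- px; y[seg] <- py
        th <- seg_th[length(seg)]
        k <- hi
      } else {
        j <- out[1]
        if (j > 1) {
          x[seg[1:(j - 1)]] <- px[1:(j - 1)]
          y[seg[1:(j - 1)]] <- py[1:(j - 1)]
        }
        # reflect the incoming velocity off the wall normal at the last
        # inside position, then take the offending step with the new heading
        x0 <- if (j > 1) px[j - 1] else x[k]
        y0 <- if (j > 1) py[j - 1] else y[k]
        nrm <- sqrt(x0 * x0 + y0 * y0)
        if (nrm < 1e-9) { nx <- 1; ny <- 0 } else { nx <- x0 / nrm; ny <- y0 / nrm }
        vx <- cos(seg_th[j]); vy <- sin(seg_th[j])
        dotp <- vx * nx + vy * ny
        rx <- vx - 2 * dotp * nx; ry <- vy - 2 * dotp * ny
        th <- atan2(ry, rx)
        idx <- seg[j]
        xn <- x0 + v[idx] * dt * cos(th)
        yn <- y0 + v[idx] * dt * sin(th)
        if (xn * xn + yn * yn > R * R) {   # cornered: pull radially inward
          sc <- (R * 0.98) / sqrt(xn * xn + yn * yn)
          xn <- xn * sc; yn <- yn * sc
        }
        x[idx] <- xn; y[idx] <- yn
        k <- idx
      }
    }
    position_track((seq_len(n) - 1) * dt, x, y, arena_radius = params$arena_radius)
  })
}

#' Simulate a bursty place-tuned spike train
#'
#' Firing events are drawn by thinning a homogeneous Poisson process at the
#' peak of the Gaussian tuning function evaluated along the trajectory;
#' each event is then expanded into a lone spike or a burst as described in
#' [cell_params()]. Spikes are clipped to the track's time span and the
#' train is sorted (near-simultaneous spikes from overlapping events are
#' dropped to keep times strictly increasing).
#'
#' @param track A [position_track()].
#' @param params A [cell_params()].
#' @param seed RNG seed.
#' @return A [spike_train()].
#' @export
simulate_place_cell <- function(track, params, seed = NULL) {
  stopifnot(inherits(track, "position_track"), inherits(params, "cell_params"))
  if (length(track) < 2) pf_error("pf_error_empty", "empty track")
  with_seed(seed, {
    t0 <- track$times[1]
    Tdur <- track$times[length(track$times)] - t0
    d2 <- (track$x - params$field_center[1])^2 + (track$y - params$field_center[2])^2
    lam <- params$baseline_event_rate +
      params$peak_event_rate * exp(-d2 / (2 * params$field_width^2))
    lmax <- max(lam)
    if (lmax <= 0) return(spike_train(numeric(0)))
    n_ev <- stats::rpois(1, lmax * Tdur)
    if (n_ev == 0) return(spike_train(numeric(0)))
    ev <- t0 + sort(stats::runif(n_ev)) * Tdur
    keep <- stats::runif(n_ev) < lam[nearest_sample(ev, track$times)] / lmax
    ev <- ev[keep]
    if (!length(ev)) return(spike_train(numeric(0)))

    times <- vector("list", length(ev))
    amps <- vector("list", length(ev))
    for (i in seq_along(ev)) {
      if (stats::runif(1) < params$p_single) {
        times[[i]] <- ev[i]
        amps[[i]] <- params$amp0
      } else {
        nspk <- 2 + stats::rgeom(1, 1 - params$burst_continue)
        nspk <- min(nspk, 10L)
        isis <- numeric(nspk - 1)
        for (m in seq_len(nspk - 1)) {
          repeat {
            g <- stats::rgamma(1, shape = params$intra_isi_shape,
                               rate = params$intra_isi_shape / params$intra_isi_mean)
            if (g > 0 && g < 15) break
          }
          isis[m] <- g
        }
        times[[i]] <- ev[i] + cumsum(c(0, isis)) / 1000
        amps[[i]] <- params$amp0 * (1 - params$amp_decay)^(0:(nspk - 1))
      }
    }
    tt <- unlist(times); aa <- unlist(amps)
    inside <- tt >= t0 & tt <= t0 + Tdur
    tt <- tt[inside]; aa <- aa[inside]
    o <- order(tt)
    tt <- tt[o]; aa <- aa[o]
    if (length(tt) > 1) {
      dup <- c(FALSE, diff(tt) <= 0)
      tt <- tt[!dup]; aa <- aa[!dup]
    }
    spike_train(tt, aa)
  })
}

#' Apply the cue protocol of a session to a cell's parameters
#'
#' Transforms the field centre according to the cell's cue dependency and
#' the session's card position relative to the reference (session-1) card
#' angle: distal cells are anchored to the unmoved distal light and keep
#' their centre; local cells follow the card, rotating their centre by the
#' card rotation; remap cells are redrawn at a new location -- similar
#' eccentricity (x0.8-1.25), azimuth at least 60 degrees away from both
#' the original and the card-following position -- so that a generated
#' remap is unambiguous under the rotation-based classification.
#'
#' @param params A [cell_params()].
#' @param descriptor The session's [session_descriptor()].
#' @param base_card_angle Card angle of the reference session, degrees.
#' @param seed RNG seed (used for remap redraws).
#' @return A [cell_params()] with the transformed `field_center`.
#' @export
apply_cue_protocol <- function(params, descriptor, base_card_angle = 0,
                               seed = NULL) {
  stopifnot(inherits(params, "cell_params"),
            inherits(descriptor, "session_descriptor"))
  delta <- (descriptor$card_angle - base_card_angle) %% 360
  ctr <- params$field_center
  if (params$cue_type == "distal") return(params)
  if (params$cue_type == "local") {
    rad <- delta * pi / 180
    params$field_center <- c(cos(rad) * ctr[1] - sin(rad) * ctr[2],
                             sin(rad) * ctr[1] + cos(rad) * ctr[2])
    return(params)
  }
  # remap
  with_seed(seed, {
    r_old <- sqrt(sum(ctr^2))
    phi_old <- atan2(ctr[2], ctr[1]) * 180 / pi
    r_new <- min(max(r_old * stats::runif(1, 0.8, 1.25), 3),
                 descriptor$arena_radius - 4)
    repeat {
      dphi <- stats::runif(1, 0, 360)
      if (fold_angle(dphi) >= 60 && fold_angle(dphi - delta) >= 60) break
    }
    phi <- (phi_old + dphi) * pi / 180
    params$field_center <- r_new * c(cos(phi), sin(phi))
    params
  })
}

#' Group-level parameter distributions for a synthetic cohort
#'
#' Defines the distributions from which per-cell parameters are drawn.
#' `cue_mix` may be given as exact per-class counts (summing to the number
#' of cells) or as probabilities. Control-like defaults; a mutant-like
#' group raises `intra_isi_mean` to 3.9 ms with more between-cell spread
#' and a lower gamma shape.
#'
#' @param intra_isi_mean Group mean of the per-cell intra-burst ISI mean, ms.
#' @param intra_isi_sd Between-cell sd of the per-cell ISI mean, ms.
#' @param intra_isi_shape Gamma shape of intra-burst ISIs.
#' @param p_single,burst_continue Burst-structure parameters (see
#'   [cell_params()]).
#' @param peak_event_rate,baseline_event_rate Field event rates, Hz.
#' @param field_width Field sd, cm.
#' @param field_radius_range Range of field-centre eccentricities, cm.
#' @param amp0,amp_decay Amplitude parameters.
#' @param cue_mix Named vector (`distal`, `local`, `remap`) of counts or
#'   probabilities.
#' @return A list of class `group_params`.
#' @export
group_params <- function(intra_isi_mean = 2.5, intra_isi_sd = 0.6,
                         intra_isi_shape = 4, p_single = 0.82,
                         burst_continue = 0.18, peak_event_rate = 6,
                         baseline_event_rate = 0.1, field_width = 4,
                         field_radius_range = c(4, 10), amp0 = 100,
                         amp_decay = 0.2,
                         cue_mix = c(distal = 1, local = 0, remap = 0)) {
  structure(list(intra_isi_mean = intra_isi_mean, intra_isi_sd = intra_isi_sd,
                 intra_isi_shape = intra_isi_shape, p_single = p_single,
                 burst_continue = burst_continue,
                 peak_event_rate = peak_event_rate,
                 baseline_event_rate = baseline_event_rate,
                 field_width = field_width,
                 field_radius_range = field_radius_range,
                 amp0 = amp0, amp_decay = amp_decay, cue_mix = cue_mix),
            class = "group_params")
}

#' Three-session cue-rotation protocol
#'
#' The standard protocol: sessions 1 and 3 with the card at its reference
#' position, session 2 with the card rotated 90 degrees counter-clockwise.
#'
#' @param card_angles Card angle per session, degrees.
#' @param duration Session length, s.
#' @param arena_radius Arena radius, cm.
#' @param sample_rate Tracking rate, Hz.
#' @param mean_speed Mean running speed, cm/s.
#' @param heading_persistence Heading correlation time, s.
#' @return A list of class `cohort_protocol`.
#' @export
cohort_protocol <- function(card_angles = c(0, 90, 0), duration = 1500,
                            arena_radius = 15, sample_rate = 60,
                            mean_speed = 6.2, heading_persistence = 1) {
  structure(list(card_angles = card_angles, duration = duration,
                 arena_radius = arena_radius, sample_rate = sample_rate,
                 mean_speed = mean_speed,
                 heading_persistence = heading_persistence),
            class = "cohort_protocol")
}

#' Generate a synthetic cohort of place cells under a cue protocol
#'
#' Draws per-cell parameters from the group distributions, assigns cue
#' types, and simulates an independent trajectory and spike train for every
#' session of every cell. Fully reproducible from `master_seed`.
#'
#' @param n_cells Number of cells.
#' @param group A [group_params()].
#' @param protocol A [cohort_protocol()].
#' @param master_seed Integer seed for the whole cohort.
#' @param group_label Label attached to every cell (e.g. `"control"`).
#' @return A list of class `cohort`: one element per cell with `cell_id`,
#'   `group`, `cue_type`, `params` (session-1 parameters) and `sessions`, a
#'   list of `(spikes, track, descriptor)` per session.
#' @export
generate_cohort <- function(n_cells, group = group_params(),
                            protocol = cohort_protocol(), master_seed = 1,
                            group_label = "group") {
  stopifnot(n_cells >= 1)
  ns <- length(protocol$card_angles)
  with_seed(master_seed, {
    mix <- group$cue_mix[c("distal", "local", "remap")]
    mix[is.na(mix)] <- 0
    if (isTRUE(all.equal(sum(mix), n_cells)) && all(mix == round(mix))) {
      cue_types <- sample(rep(c("distal", "local", "remap"), times = mix))
    } else {
      cue_types <- sample(c("distal", "local", "remap"), n_cells,
                          replace = TRUE, prob = mix / sum(mix))
    }
    seeds <- sample.int(.Machine$integer.max - 1, n_cells * 3 * ns)
    dim(seeds) <- c(n_cells, 3 * ns)

    cells <- vector("list", n_cells)
    for (ci in seq_len(n_cells)) {
      isi_mean <- min(max(stats::rnorm(1, group$intra_isi_mean, group$intra_isi_sd),
                          0.8), 12)
      rr <- group$field_radius_range
      r <- sqrt(stats::runif(1, rr[1]^2, rr[2]^2))
      a <- stats::runif(1, 0, 2 * pi)
      base <- cell_params(field_center = r * c(cos(a), sin(a)),
                          field_width = group$field_width,
                          peak_event_rate = group$peak_event_rate,
                          baseline_event_rate = group$baseline_event_rate,
                          p_single = group$p_single,
                          burst_continue = group$burst_continue,
                          intra_isi_mean = isi_mean,
                          intra_isi_shape = group$intra_isi_shape,
                          amp0 = group$amp0, amp_decay = group$amp_decay,
                          cue_type = cue_types[ci])
      sessions <- vector("list", ns)
      for (s in seq_len(ns)) {
        desc <- session_descriptor(s, protocol$arena_radius,
                                   protocol$card_angles[s], protocol$duration)
        pars <- if (s == 1) base else
          apply_cue_protocol(base, desc,
                             base_card_angle = protocol$card_angles[1],
                             seed = seeds[ci, 3 * s])
        tp <- trajectory_params(mean_speed = protocol$mean_speed,
                                heading_persistence = protocol$heading_persistence,
                                sample_rate = protocol$sample_rate,
                                arena_radius = protocol$arena_radius,
                                duration = protocol$duration,
                                seed = seeds[ci, 3 * s - 2])
        track <- simulate_trajectory(tp)
        spikes <- simulate_place_cell(track, pars, seed = seeds[ci, 3 * s - 1])
        sessions[[s]] <- list(spikes = spikes, track = track, descriptor = desc)
      }
      cells[[ci]] <- list(cell_id = sprintf("cell_%02d", ci),
                          group = group_label, cue_type = cue_types[ci],
                          params = base, sessions = sessions)
    }
    structure(cells, class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d cells x %d sessions\n", length(x),
              length(x[[1]]$sessions)))
  invisible(x)
}
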