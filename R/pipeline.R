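#' Analysis configuration
#'
#' All tunable analysis defaults in one place: map binning, burst
#' detection, ISI histogram layouts (0.5-ms bins over (0, 15] ms for
#' intra-burst intervals; 1-ms bins over (0, 500] ms with the peak searched
#' on [1, 50] ms for whole-session ISIs), the span grid for the spatial
#' regression, and which session gates cell inclusion.
#'
#' @param pixel_size Map pixel edge, cm.
#' @param min_occupancy Minimum pixel dwell time, s.
#' @param max_isi_ms Burst ISI criterion, ms.
#' @param enforce_amplitude Require decreasing amplitudes in bursts.
#' @param span_grid Candidate smoothing spans.
#' @param cv_folds Cross-validation folds for span selection.
#' @param intra_bin_ms,intra_range_ms Intra-burst ISI histogram layout.
#' @param session_bin_ms,session_range_ms,session_peak_ms Whole-session ISI
#'   histogram layout and peak-search window.
#' @param inclusion_session Session whose rate/selectivity gate inclusion.
#' @param seed Seed for the (seeded) fold assignment.
#' @return A list of class `pf_config`.
#' @export
pf_config <- function(pixel_size = 1, min_occupancy = 0.1, max_isi_ms = 15,
                      enforce_amplitude = TRUE,
                      span_grid = c(0.05, 0.1, 0.2, 0.3, 0.5, 0.75, 1),
                      cv_folds = 10, intra_bin_ms = 0.5,
                      intra_range_ms = c(0, 15), session_bin_ms = 1,
                      session_range_ms = c(0, 500),
                      session_peak_ms = c(1, 50), inclusion_session = 1,
                      seed = 1) {
  structure(list(pixel_size = pixel_size, min_occupancy = min_occupancy,
                 max_isi_ms = max_isi_ms,
                 enforce_amplitude = enforce_amplitude,
                 span_grid = span_grid, cv_folds = cv_folds,
                 intra_bin_ms = intra_bin_ms, intra_range_ms = intra_range_ms,
                 session_bin_ms = session_bin_ms,
                 session_range_ms = session_range_ms,
                 session_peak_ms = session_peak_ms,
                 inclusion_session = inclusion_session, seed = seed),
            class = "pf_config")
}

#' Cell-inclusion filter
#'
#' A cell qualifies as a place cell when its mean firing rate exceeds
#' 0.2 Hz and its spatial selectivity exceeds 0.5 (both strictly, at the
#' same time).
#'
#' @param mean_rate Mean firing rate, Hz.
#' @param selectivity Spatial selectivity, log10 units.
#' @return Logical.
#' @export
include_cell <- function(mean_rate, selectivity) {
  isTRUE(mean_rate > 0.2) && isTRUE(selectivity > 0.5)
}

## NA-safe wrapper: run expr, flag any package error as missing.
or_na <- function(expr) tryCatch(expr, pf_error = function(e) NA_real_)

## Metrics for a single session: one-row data frame.
session_metrics_row <- function(spikes, track, descriptor, config,
                                cv_seed = NULL) {
  geom <- map_geometry(descriptor$arena_radius, config$pixel_size)
  map <- compute_rate_map(spikes, track, descriptor$arena_radius,
                          pixel_size = config$pixel_size,
                          min_occupancy = config$min_occupancy,
                          geometry = geom)
  field <- define_place_field(map, "above_mean")
  field_tq <- define_place_field(map, "top_quartile")
  sm <- spatial_metrics(map, field)

  bursts <- detect_bursts(spikes, config$max_isi_ms, config$enforce_amplitude)
  bm <- burst_metrics(bursts, descriptor$duration)

  isi_all <- if (length(spikes) >= 3) diff(spikes$times) * 1000 else numeric(0)
  sess_isi <- if (length(isi_all) >= 2)
    or_na(isi_statistics(isi_all, config$session_bin_ms,
                         config$session_range_ms, config$session_peak_ms))
    else NA
  k_stats <- lapply(1:3, function(k) {
    iv <- intra_burst_isi_series(bursts, k)
    if (length(iv) >= 2)
      list(mean = mean(iv),
           stats = or_na(isi_statistics(iv, config$intra_bin_ms,
                                        config$intra_range_ms)))
    else list(mean = NA_real_, stats = NA)
  })
  stat_field <- function(s, f) if (is.list(s)) s[[f]] else NA_real_

  rel_am <- if (length(bursts)) burst_reliability(bursts, track, field, geom) else NA_real_
  rel_tq <- if (length(bursts)) burst_reliability(bursts, track, field_tq, geom) else NA_real_
  bmap_coh <- if (length(bursts) >= 2) {
    bmap <- burst_place_map(bursts, track, descriptor$arena_radius,
                            config$pixel_size, config$min_occupancy, geom)
    or_na(spatial_coherence(bmap)$r)
  } else NA_real_

  reg <- tryCatch({
    sel <- select_span_cv(map, config$span_grid, k = config$cv_folds,
                          seed = cv_seed)
    fit_spatial_regression(map, sel$span)
  }, pf_error = function(e) NULL)

  data.frame(
    session_id = descriptor$session_id,
    n_spikes = length(spikes),
    overall_rate = sm$overall_rate,
    in_field_rate = sm$in_field_rate,
    out_field_rate = sm$out_field_rate,
    selectivity = ifelse(is.finite(sm$selectivity), sm$selectivity, NA_real_),
    field_size = sm$field_size,
    coherence_r = sm$coherence_r,
    coherence_z = sm$coherence_z,
    information_rate = sm$information_rate,
    isi_peak_ms = stat_field(sess_isi, "peak_time"),
    isi_cv = stat_field(sess_isi, "cv"),
    isi_entropy = stat_field(sess_isi, "entropy"),
    isi_sd_ms = stat_field(sess_isi, "sd"),
    n_bursts = bm$n_bursts,
    burst_frequency = bm$burst_frequency,
    intra_burst_spike_rate = bm$intra_burst_spike_rate,
    mean_spikes_per_burst = bm$mean_spikes_per_burst,
    intra_burst_ratio = bm$intra_burst_ratio,
    mean_inter_burst_interval = bm$mean_inter_burst_interval,
    isi1_mean_ms = k_stats[[1]]$mean,
    isi1_entropy = stat_field(k_stats[[1]]$stats, "entropy"),
    isi1_cv = stat_field(k_stats[[1]]$stats, "cv"),
    isi1_sd_ms = stat_field(k_stats[[1]]$stats, "sd"),
    isi2_mean_ms = k_stats[[2]]$mean,
    isi2_entropy = stat_field(k_stats[[2]]$stats, "entropy"),
    isi3_mean_ms = k_stats[[3]]$mean,
    isi3_entropy = stat_field(k_stats[[3]]$stats, "entropy"),
    reliability_above_mean = rel_am,
    reliability_top_quartile = rel_tq,
    burst_map_coherence_r = bmap_coh,
    span = if (is.null(reg)) NA_real_ else reg$span,
    pve = if (is.null(reg)) NA_real_ else reg$pve
  )
}

#' Full per-cell analysis across a session protocol
#'
#' Computes every per-session metric (spatial battery, burst battery, ISI
#' statistics, burst reliability, spatial-regression fit), all pairwise
#' stability results (pixel similarity, rotation search, cue
#' classification), pooled firing properties on the concatenation of all
#' sessions, and the inclusion decision.
#'
#' For each session pair the rotation search rotates the earlier session's
#' map to best match the later one, so the reported angle is the field's
#' displacement and is compared directly against the card rotation.
#'
#' @param sessions List of sessions (each with `spikes`, `track`,
#'   `descriptor`), e.g. one element of a [generate_cohort()] or
#'   [read_cohort()] result.
#' @param cell_id,group Labels copied into the output tables.
#' @param config A [pf_config()].
#' @param fit_regression Set `FALSE` to skip the (comparatively expensive)
#'   span selection and spatial regression.
#' @return A list of class `cell_analysis`: `sessions` (data frame, one row
#'   per session plus one `session_id = 0` row for the pooled
#'   concatenation), `pairs` (data frame of pairwise stability results) and
#'   `included` (logical).
#' @export
analyze_cell <- function(sessions, cell_id = "cell", group = NA_character_,
                         config = pf_config(), fit_regression = TRUE) {
  ns <- length(sessions)
  if (ns < 1) pf_error("pf_error_empty", "no sessions")
  cfg <- config
  if (!fit_regression) cfg$span_grid <- numeric(0)

  rows <- vector("list", ns)
  maps <- vector("list", ns)
  for (s in seq_len(ns)) {
    ses <- sessions[[s]]
    row <- tryCatch(
      session_metrics_row(ses$spikes, ses$track, ses$descriptor,
                          if (fit_regression) config else cfg,
                          cv_seed = config$seed + s),
      pf_error = function(e) pf_error(class(e)[1], sprintf(
        "%s session %d: %s", cell_id, s, conditionMessage(e))))
    if (!fit_regression) { row$span <- NA_real_; row$pve <- NA_real_ }
    rows[[s]] <- row
    geom <- map_geometry(ses$descriptor$arena_radius, config$pixel_size)
    maps[[s]] <- compute_rate_map(ses$spikes, ses$track,
                                  ses$descriptor$arena_radius,
                                  config$pixel_size, config$min_occupancy,
                                  geometry = geom)
  }

  ## pooled firing properties on the concatenation of all sessions
  offs <- cumsum(c(0, vapply(sessions, function(s) s$descriptor$duration,
                             numeric(1))))[seq_len(ns)]
  all_t <- unlist(lapply(seq_len(ns), function(s)
    sessions[[s]]$spikes$times + offs[s]))
  all_a <- unlist(lapply(seq_len(ns), function(s)
    sessions[[s]]$spikes$amplitudes))
  o <- order(all_t)
  keep <- c(TRUE, diff(all_t[o]) > 0)
  pooled <- spike_train(all_t[o][keep], all_a[o][keep])
  total_dur <- sum(vapply(sessions, function(s) s$descriptor$duration, numeric(1)))
  pb <- detect_bursts(pooled, config$max_isi_ms, config$enforce_amplitude)
  pbm <- burst_metrics(pb, total_dur)
  p_isi <- if (length(pooled) >= 3)
    or_na(isi_statistics(diff(pooled$times) * 1000, config$session_bin_ms,
                         config$session_range_ms, config$session_peak_ms))
    else NA
  p_isi1 <- intra_burst_isi_series(pb, 1)
  pooled_row <- rows[[1]][0, ]
  pooled_row[1, ] <- NA
  pooled_row$session_id <- 0L
  pooled_row$n_spikes <- length(pooled)
  pooled_row$overall_rate <- length(pooled) / total_dur
  pooled_row$isi_peak_ms <- if (is.list(p_isi)) p_isi$peak_time else NA_real_
  pooled_row$isi_cv <- if (is.list(p_isi)) p_isi$cv else NA_real_
  pooled_row$isi_entropy <- if (is.list(p_isi)) p_isi$entropy else NA_real_
  pooled_row$isi_sd_ms <- if (is.list(p_isi)) p_isi$sd else NA_real_
  pooled_row$n_bursts <- pbm$n_bursts
  pooled_row$burst_frequency <- pbm$burst_frequency
  pooled_row$intra_burst_spike_rate <- pbm$intra_burst_spike_rate
  pooled_row$mean_spikes_per_burst <- pbm$mean_spikes_per_burst
  pooled_row$intra_burst_ratio <- pbm$intra_burst_ratio
  pooled_row$mean_inter_burst_interval <- pbm$mean_inter_burst_interval
  pooled_row$isi1_mean_ms <- if (length(p_isi1) >= 2) mean(p_isi1) else NA_real_

  sess_tab <- rbind(do.call(rbind, rows), pooled_row)
  sess_tab <- cbind(cell_id = cell_id, group = group, sess_tab)

  pairs <- NULL
  if (ns >= 2) {
    combos <- utils::combn(ns, 2)
    plist <- lapply(seq_len(ncol(combos)), function(k) {
      i <- combos[1, k]; j <- combos[2, k]
      sim <- tryCatch(map_similarity(maps[[i]], maps[[j]]),
                      pf_error = function(e) list(r = NA_real_, z = NA_real_,
                                                  n_pixels = NA_integer_))
      rot <- tryCatch(best_rotation(maps[[j]], maps[[i]]),
                      pf_error = function(e) NULL)
      card <- sessions[[j]]$descriptor$card_angle -
        sessions[[i]]$descriptor$card_angle
      card <- ((card + 180) %% 360) - 180
      data.frame(cell_id = cell_id, group = group,
                 pair = sprintf("%dv%d", i, j),
                 r = sim$r, z = sim$z, n_pixels = sim$n_pixels,
                 best_angle = if (is.null(rot)) NA_real_ else rot$best_angle,
                 max_r = if (is.null(rot)) NA_real_ else rot$max_r,
                 max_z = if (is.null(rot)) NA_real_ else rot$max_z,
                 abs_rotation = if (is.null(rot)) NA_real_ else rot$abs_rotation,
                 card_rotation = card,
                 cue_class = if (is.null(rot)) NA_character_ else
                   classify_cue_following(rot, card))
    })
    pairs <- do.call(rbind, plist)
  }

  inc_row <- min(config$inclusion_session, ns)
  included <- include_cell(sess_tab$overall_rate[inc_row],
                           rows[[inc_row]]$selectivity)
  structure(list(sessions = sess_tab, pairs = pairs, included = included),
            class = "cell_analysis")
}

#' Welch group comparison over a set of metrics
#'
#' Two-tailed unequal-variance (Welch) t-tests per metric, with
#' Welch-Satterthwaite degrees of freedom, group means with SEMs, and a
#' Benjamini-Hochberg adjusted p-value column added for transparency (the
#' per-metric p-values themselves are reported unadjusted). Missing values
#' are excluded pairwise per metric; a metric with fewer than two
#' observations in either group is returned as `NA` with a warning.
#'
#' @param metrics1,metrics2 Data frames of per-cell metrics for the two
#'   groups.
#' @param metrics Character vector of metric column names; defaults to the
#'   shared numeric columns.
#' @param labels Group labels for the output.
#' @return A data frame with one row per metric: means, SEMs, `t`, `df`,
#'   `p`, `p_bh`.
#' @export
compare_groups <- function(metrics1, metrics2, metrics = NULL,
                           labels = c("group1", "group2")) {
  if (is.null(metrics)) {
    shared <- intersect(names(metrics1), names(metrics2))
    metrics <- shared[vapply(shared, function(m)
      is.numeric(metrics1[[m]]) && is.numeric(metrics2[[m]]), logical(1))]
    metrics <- setdiff(metrics, c("session_id", "n_spikes"))
  }
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  rows <- lapply(metrics, function(m) {
    x <- metrics1[[m]]; x <- x[is.finite(x)]
    y <- metrics2[[m]]; y <- y[is.finite(y)]
    if (length(x) < 2 || length(y) < 2) {
      warning(sprintf("metric '%s': fewer than 2 observations in a group", m),
              call. = FALSE)
      return(data.frame(metric = m, mean1 = NA_real_, sem1 = NA_real_,
                        n1 = length(x), mean2 = NA_real_, sem2 = NA_real_,
                        n2 = length(y), t = NA_real_, df = NA_real_,
                        p = NA_real_))
    }
    tt <- stats::t.test(x, y, var.equal = FALSE)
    data.frame(metric = m, mean1 = mean(x), sem1 = sem(x), n1 = length(x),
               mean2 = mean(y), sem2 = sem(y), n2 = length(y),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  names(out)[c(2, 3, 4, 5, 6, 7)] <-
    c(paste0("mean_", labels[1]), paste0("sem_", labels[1]), paste0("n_", labels[1]),
      paste0("mean_", labels[2]), paste0("sem_", labels[2]), paste0("n_", labels[2]))
  out
}

#' Analyse a whole cohort
#'
#' Runs [analyze_cell()] over every cell and binds the per-session and
#' pairwise tables; cells failing the inclusion filter are kept in the
#' output but flagged, so group tables can subset on `included`.
#'
#' @param cohort A [generate_cohort()] or [read_cohort()] result.
#' @param group Group label.
#' @param config A [pf_config()].
#' @param fit_regression Passed to [analyze_cell()].
#' @return A list with data frames `sessions` and `pairs`, both carrying an
#'   `included` column.
#' @export
analyze_cohort <- function(cohort, group = NA_character_, config = pf_config(),
                           fit_regression = TRUE) {
  res <- lapply(cohort, function(cell) {
    analyze_cell(cell$sessions, cell_id = cell$cell_id,
                 group = if (!is.null(cell$group)) cell$group else group,
                 config = config, fit_regression = fit_regression)
  })
  sess <- do.call(rbind, lapply(res, function(r)
    cbind(r$sessions, included = r$included)))
  pairs <- do.call(rbind, lapply(res, function(r)
    if (is.null(r$pairs)) NULL else cbind(r$pairs, included = r$included)))
  list(sessions = sess, pairs = pairs)
}
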