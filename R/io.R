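## Read a delimited table, turning the usual failure modes into distinct
## package error classes.
read_table_checked <- function(path, required) {
  if (!file.exists(path)) pf_error("pf_error_missing_file", paste("file not found:", path))
  d <- tryCatch(utils::read.csv(path),
                error = function(e) pf_error("pf_error_empty_file",
                                             paste("cannot read", path, ":", conditionMessage(e))))
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    pf_error("pf_error_missing_column",
             sprintf("%s: missing column(s) %s", path, paste(missing, collapse = ", ")))
  }
  if (nrow(d) == 0) pf_error("pf_error_empty_file", paste(path, "has no data rows"))
  d
}

#' Read a spike table
#'
#' CSV with columns `time_s` (seconds, strictly increasing) and `amplitude`
#' (arbitrary units, > 0).
#'
#' @param path File path.
#' @return A [spike_train()].
#' @export
read_spikes <- function(path) {
  d <- read_table_checked(path, c("time_s", "amplitude"))
  spike_train(d$time_s, d$amplitude)
}

#' Read a position-tracking table
#'
#' CSV with columns `time_s`, `x_cm`, `y_cm` in an arena-centred frame.
#'
#' @param path File path.
#' @param arena_radius Optional radius (cm) for containment validation.
#' @return A [position_track()].
#' @export
read_track <- function(path, arena_radius = NULL) {
  d <- read_table_checked(path, c("time_s", "x_cm", "y_cm"))
  position_track(d$time_s, d$x_cm, d$y_cm, arena_radius = arena_radius)
}

#' Read a session descriptor
#'
#' YAML key/value file with `session_id`, `arena_radius_cm`,
#' `card_angle_deg`, `duration_s`.
#'
#' @param path File path.
#' @return A [session_descriptor()].
#' @export
read_session_descriptor <- function(path) {
  if (!file.exists(path)) pf_error("pf_error_missing_file", paste("file not found:", path))
  y <- yaml::read_yaml(path)
  need <- c("session_id", "arena_radius_cm", "card_angle_deg", "duration_s")
  missing <- setdiff(need, names(y))
  if (length(missing)) {
    pf_error("pf_error_missing_column",
             sprintf("%s: missing key(s) %s", path, paste(missing, collapse = ", ")))
  }
  session_descriptor(y$session_id, y$arena_radius_cm, y$card_angle_deg, y$duration_s)
}

#' Read and validate one recorded session
#'
#' Loads the spike table, track and descriptor, validates the track against
#' the arena radius, and drops (with a message) any spikes outside
#' `[0, duration]`.
#'
#' @param spike_path,track_path,descriptor_path File paths.
#' @return A list with `spikes`, `track`, `descriptor` and
#'   `n_spikes_dropped`.
#' @export
read_session <- function(spike_path, track_path, descriptor_path) {
  descriptor <- read_session_descriptor(descriptor_path)
  spikes <- read_spikes(spike_path)
  track <- read_track(track_path, arena_radius = descriptor$arena_radius)
  inside <- spikes$times >= 0 & spikes$times <= descriptor$duration
  dropped <- sum(!inside)
  if (dropped > 0) {
    message(sprintf("read_session: dropped %d spike(s) outside [0, %g] s",
                    dropped, descriptor$duration))
    spikes <- spike_train(spikes$times[inside], spikes$amplitudes[inside])
  }
  list(spikes = spikes, track = track, descriptor = descriptor,
       n_spikes_dropped = dropped)
}

#' Write one session in the canonical file layout
#'
#' Writes `spikes.csv`, `track.csv` and `session.yaml` into `dir`.
#'
#' @param session A list with `spikes`, `track`, `descriptor` (as produced
#'   by [generate_cohort()] or [read_session()]).
#' @param dir Output directory (created if needed).
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(time_s = session$spikes$times,
                              amplitude = session$spikes$amplitudes),
                   file.path(dir, "spikes.csv"), row.names = FALSE)
  utils::write.csv(data.frame(time_s = session$track$times,
                              x_cm = session$track$x, y_cm = session$track$y),
                   file.path(dir, "track.csv"), row.names = FALSE)
  d <- session$descriptor
  yaml::write_yaml(list(session_id = d$session_id,
                        arena_radius_cm = d$arena_radius,
                        card_angle_deg = d$card_angle,
                        duration_s = d$duration),
                   file.path(dir, "session.yaml"))
  invisible(dir)
}

#' Write / read a whole synthetic cohort on disk
#'
#' Layout: `dir/<cell_id>/session_<s>/{spikes.csv,track.csv,session.yaml}`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Root directory.
#' @export
write_cohort <- function(cohort, dir) {
  for (cell in cohort) {
    for (s in seq_along(cell$sessions)) {
      write_session(cell$sessions[[s]],
                    file.path(dir, cell$cell_id, sprintf("session_%d", s)))
    }
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @return `read_cohort`: a list of cells, each with `cell_id` and
#'   `sessions` (lists of `spikes`, `track`, `descriptor`).
#' @export
read_cohort <- function(dir) {
  cells <- sort(list.dirs(dir, recursive = FALSE))
  lapply(cells, function(cd) {
    sess_dirs <- sort(list.dirs(cd, recursive = FALSE))
    sessions <- lapply(sess_dirs, function(sd) {
      read_session(file.path(sd, "spikes.csv"), file.path(sd, "track.csv"),
                   file.path(sd, "session.yaml"))
    })
    list(cell_id = basename(cd), sessions = sessions)
  })
}

#' Write / read the per-cell-session metrics report
#'
#' A delimited table with one row per cell-session and all scalar metric
#' fields; round-trips losslessly (times stable well past 1e-6 s).
#'
#' @param metrics A data frame of metrics (see [analyze_cell()]).
#' @param path Output file path.
#' @export
write_metrics_report <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics_report
#' @export
read_metrics_report <- function(path) {
  if (!file.exists(path)) pf_error("pf_error_missing_file", paste("file not found:", path))
  utils::read.csv(path)
}
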