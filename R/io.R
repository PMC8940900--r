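# Plain-text I/O: trajectory and metrics CSVs, machine-readable report JSON.

#' Write / read a trajectory CSV
#'
#' Columns `time_s`, `x_cm`, `y_cm`. Reading requires the arena the track was
#' recorded in (geometry is not serialized with the samples).
#'
#' @param traj a `trajectory`.
#' @param path CSV path.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  utils::write.csv(data.frame(time_s = traj$time_s, x_cm = traj$x_cm,
                              y_cm = traj$y_cm),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @param arena the `arena_spec` the track belongs to.
#' @param video_hz frame rate; inferred from the time column when omitted.
#' @export
read_trajectory_csv <- function(path, arena, video_hz = NULL) {
  d <- utils::read.csv(path)
  stopifnot(all(c("time_s", "x_cm", "y_cm") %in% names(d)))
  dt <- diff(d$time_s)
  if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-6 * mean(dt)) {
    stop("trajectory times must be strictly increasing and uniform")
  }
  if (is.null(video_hz)) video_hz <- 1 / mean(dt)
  new_trajectory(d$time_s, d$x_cm, d$y_cm, arena, video_hz)
}

#' Write / read a two-channel photometry CSV
#'
#' Columns `time_s`, `f490`, `f405`; synchronization events are written to a
#' companion `<path>.events.csv` (`time_s`, `label`) when present.
#'
#' @param rec a `photometry_recording`.
#' @param path CSV path.
#' @export
write_photometry_csv <- function(rec, path) {
  stopifnot(inherits(rec, "photometry_recording"))
  utils::write.csv(data.frame(time_s = rec$time_s, f490 = rec$f490,
                              f405 = rec$f405),
                   path, row.names = FALSE)
  if (!is.null(rec$sync_events)) {
    utils::write.csv(rec$sync_events, paste0(path, ".events.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_photometry_csv
#' @export
read_photometry_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("time_s", "f490", "f405") %in% names(d)))
  ev_path <- paste0(path, ".events.csv")
  sync <- if (file.exists(ev_path)) utils::read.csv(ev_path) else NULL
  rate <- 1 / mean(diff(d$time_s))
  new_photometry_recording(d$time_s, d$f490, d$f405, rate, sync_events = sync)
}

#' Write a pipeline report as machine-readable JSON
#'
#' Serializes the per-mouse metrics table, correlation panel, group
#' comparisons, seed and package version (ground truth is kept out of the
#' analysis report).
#'
#' @param report a `pipeline_report`.
#' @param path output path.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "pipeline_report"))
  gc_ser <- lapply(report$group_comparisons, function(g) {
    list(omnibus = g$omnibus, statistic = g$statistic, df = g$df, p = g$p,
         correction = g$correction, pairwise = g$pairwise)
  })
  jsonlite::write_json(
    list(metrics = report$metrics, correlations = report$correlations,
         group_comparisons = gc_ser, seed = report$seed,
         version = report$version),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
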