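# Photometry processing: isosbestic control fit, dF/F, session z-score,
# compartment AUC, MAD-threshold event detection, peri-event dynamics.

#' Least-squares fit of the isosbestic control channel to the signal channel
#'
#' Ordinary least squares of the 490-nm signal on the 405-nm control over the
#' full session; the fitted control absorbs bleaching and motion artifacts
#' shared by the two channels.
#'
#' @param rec a `photometry_recording` (>= 2 samples).
#' @return list with `slope`, `intercept` and `fitted405` (the scaled control
#'   used as the dF/F reference). A constant control channel makes the fit
#'   singular; the function falls back to an intercept-only fit with a
#'   warning.
#' @export
fit_control <- function(rec) {
  stopifnot(inherits(rec, "photometry_recording"), length(rec$f490) >= 2)
  x <- rec$f405; y <- rec$f490
  if (stats::sd(x) == 0) {
    warning("constant 405 nm control: singular fit, falling back to intercept only")
    return(list(slope = 0, intercept = mean(y), fitted405 = rep(mean(y), length(y))))
  }
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  list(slope = slope, intercept = intercept, fitted405 = slope * x + intercept)
}

#' Fractional fluorescence change and session z-score
#'
#' `dF/F = (f490 - fitted405) / fitted405` at each sample, then z-scored over
#' the entire session so recordings are comparable across mice.
#'
#' @param rec a `photometry_recording`.
#' @param fitted405 fitted control from [fit_control()]; computed if omitted.
#' @return object of class `dff_series`: `time_s`, `dff`, `z`, `rate_hz`,
#'   `fit` (slope, intercept), `sync_events`.
#' @export
dff <- function(rec, fitted405 = NULL) {
  stopifnot(inherits(rec, "photometry_recording"))
  fit <- NULL
  if (is.null(fitted405)) {
    fit <- fit_control(rec)
    fitted405 <- fit$fitted405
  }
  bad <- which(fitted405 <= 0)
  if (length(bad)) {
    stop(sprintf("fitted control is non-positive at sample %d", bad[1]))
  }
  d <- (rec$f490 - fitted405) / fitted405
  structure(list(time_s = rec$time_s, dff = d,
                 z = as.numeric(scale(d)), rate_hz = rec$rate_hz,
                 fit = fit[c("slope", "intercept")],
                 sync_events = rec$sync_events),
            class = "dff_series")
}

#' @export
print.dff_series <- function(x, ...) {
  cat(sprintf("<dff_series> %d samples @ %g Hz, dff range [%.3g, %.3g]\n",
              length(x$dff), x$rate_hz, min(x$dff), max(x$dff)))
  invisible(x)
}

#' Trapezoidal area under the curve per behavioral compartment
#'
#' Integrates the session z-scored dF/F over the time spent in each
#' compartment: the in-zone samples are split into contiguous visits, each
#' visit is integrated with the trapezoidal rule, and visit areas are summed
#' per zone. The per-second mean (`auc / seconds in zone`) is also reported
#' for comparisons across unequal zone times.
#'
#' @param series a `dff_series`.
#' @param masks named list of logical vectors on the photometry time base,
#'   one per zone (see [zone_masks()]).
#' @return data frame with `zone`, `auc` (z * s), `time_s` (integrated zone
#'   time), `auc_per_s`, and `zero_duration` flag for empty masks.
#' @export
compartment_auc <- function(series, masks) {
  stopifnot(inherits(series, "dff_series"), is.list(masks), length(names(masks)) == length(masks))
  out <- lapply(names(masks), function(zn) {
    m <- masks[[zn]]
    stopifnot(length(m) == length(series$z))
    if (!any(m)) {
      return(data.frame(zone = zn, auc = 0, time_s = 0, auc_per_s = NA_real_,
                        zero_duration = TRUE))
    }
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    auc <- 0; tt <- 0
    for (k in which(r$values)) {
      i <- starts[k]:ends[k]
      if (length(i) > 1) {
        auc <- auc + pracma::trapz(series$time_s[i], series$z[i])
        tt <- tt + series$time_s[i[length(i)]] - series$time_s[i[1]]
      }
    }
    data.frame(zone = zn, auc = auc, time_s = tt,
               auc_per_s = if (tt > 0) auc / tt else NA_real_,
               zero_duration = tt == 0)
  })
  do.call(rbind, out)
}

#' Per-zone occupancy masks on the photometry time base
#'
#' Resamples a trajectory's zone assignment onto photometry sample times by
#' nearest-sample snapping (ties toward the earlier sample).
#'
#' @param traj a `trajectory`.
#' @param time_s photometry sample times.
#' @return named list of logical vectors, one per arena zone.
#' @export
zone_masks <- function(traj, time_s) {
  stopifnot(inherits(traj, "trajectory"))
  idx <- pmin(length(traj$time_s), pmax(1L, floor(time_s * traj$video_hz + 0.5) + 1L))
  zi <- assign_zone(traj$x_cm[idx], traj$y_cm[idx], traj$arena)
  zn <- names(traj$arena$zones)
  stats::setNames(lapply(seq_along(zn), function(k) !is.na(zi) & zi == k), zn)
}

#' Threshold for calcium-event detection
#'
#' The event threshold is the session median of dF/F plus `multiplier` times
#' the raw (unscaled) median absolute deviation. With the default multiplier
#' 2.91 this is the approximate two-sided 95% band for Gaussian data, because
#' 2.91 x 0.6745 is about 1.96 standard deviations.
#'
#' @param x numeric samples (typically dF/F).
#' @param multiplier MAD multiplier (default 2.91).
#' @return list with `center` (median), `mad` (raw MAD), `multiplier`,
#'   `threshold`.
#' @export
event_threshold <- function(x, multiplier = 2.91) {
  med <- stats::median(x)
  m <- stats::mad(x, constant = 1)
  list(center = med, mad = m, multiplier = multiplier,
       threshold = med + multiplier * m)
}

#' Detect calcium transient events by MAD threshold
#'
#' Events are supra-threshold excursions of dF/F above the session median
#' plus `multiplier` x raw MAD, timestamped at the excursion maximum; events
#' closer than `min_iei_s` to the previously accepted event are dropped
#' (chronological greedy rule).
#'
#' @param series a `dff_series` with at least one second of samples.
#' @param multiplier MAD multiplier (default 2.91).
#' @param min_iei_s minimum inter-event interval (default 0.5 s).
#' @return object of class `event_series`: `times_s`, `threshold`, `mad`,
#'   `events_per_min`, `n`, `degenerate` flag (constant signal).
#' @export
detect_events <- function(series, multiplier = 2.91, min_iei_s = 0.5) {
  stopifnot(inherits(series, "dff_series"))
  if (length(series$dff) < series$rate_hz) stop("need at least 1 s of samples")
  thr <- event_threshold(series$dff, multiplier)
  dur_min <- (length(series$dff) / series$rate_hz) / 60
  if (thr$mad == 0) {
    return(structure(list(times_s = numeric(0), threshold = thr$threshold,
                          mad = 0, events_per_min = 0, n = 0L,
                          degenerate = TRUE), class = "event_series"))
  }
  above <- series$dff > thr$threshold
  times <- numeric(0)
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    peaks <- vapply(which(r$values), function(k) {
      i <- starts[k]:ends[k]
      i[which.max(series$dff[i])]
    }, integer(1))
    cand <- series$time_s[peaks]
    keep <- numeric(0)
    last <- -Inf
    for (tt in cand) {
      if (tt - last >= min_iei_s) {
        keep <- c(keep, tt)
        last <- tt
      }
    }
    times <- keep
  }
  structure(list(times_s = times, threshold = thr$threshold, mad = thr$mad,
                 events_per_min = length(times) / dur_min, n = length(times),
                 degenerate = FALSE), class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series> %d events (%.2f /min), threshold %.4g\n",
              x$n, x$events_per_min, x$threshold))
  invisible(x)
}

#' Peri-event epochs time-locked to behavior onsets
#'
#' For each onset, the raw dF/F in the `[-5, +5]` s window is extracted,
#' z-scored within the window, and offset so the `[-5, -4]` s baseline mean is
#' exactly zero; at most `max_epochs_per_mouse` epochs are kept per mouse and
#' onset label (the first ones chronologically), and onsets too close to the
#' record edges are skipped with a message.
#'
#' @param series a `dff_series`.
#' @param onsets data frame with `time_s` and optionally `label` and `mouse`
#'   columns (single label/mouse assumed when absent), or a numeric vector of
#'   onset times.
#' @param window peri-event window (s), default `c(-5, 5)`.
#' @param baseline baseline-offset window (s), default `c(-5, -4)`.
#' @param max_epochs_per_mouse epoch cap per mouse per label (default 5).
#' @return object of class `peri_event_matrix`: `time_rel`, `epochs` (epoch x
#'   time matrix), `label`, `mouse`, `mean_trace`, `n_skipped`.
#' @export
peri_event <- function(series, onsets, window = c(-5, 5), baseline = c(-5, -4),
                       max_epochs_per_mouse = 5) {
  stopifnot(inherits(series, "dff_series"))
  if (is.numeric(onsets)) onsets <- data.frame(time_s = onsets)
  if (!"label" %in% names(onsets)) onsets$label <- "event"
  if (!"mouse" %in% names(onsets)) onsets$mouse <- "m1"
  onsets <- onsets[order(onsets$time_s), , drop = FALSE]

  rate <- series$rate_hz
  off <- seq(round(window[1] * rate), round(window[2] * rate))
  time_rel <- off / rate
  bl <- time_rel >= baseline[1] & time_rel <= baseline[2]

  kept <- list(); lab <- character(0); mus <- character(0)
  counts <- list()
  n_skip <- 0L
  for (i in seq_len(nrow(onsets))) {
    idx0 <- floor(onsets$time_s[i] * rate + 0.5) + 1L # nearest sample, ties earlier
    idx <- idx0 + off
    if (idx[1] < 1L || idx[length(idx)] > length(series$dff)) {
      message(sprintf("peri_event: onset at %.2f s too close to record edge, skipped",
                      onsets$time_s[i]))
      n_skip <- n_skip + 1L
      next
    }
    key <- paste(onsets$mouse[i], onsets$label[i], sep = "\r")
    k <- counts[[key]]
    if (is.null(k)) k <- 0L
    if (k >= max_epochs_per_mouse) next
    counts[[key]] <- k + 1L
    w <- series$dff[idx]
    zw <- as.numeric(scale(w))
    if (any(!is.finite(zw))) zw <- rep(0, length(w)) # flat window
    zw <- zw - mean(zw[bl])
    kept[[length(kept) + 1L]] <- zw
    lab <- c(lab, onsets$label[i])
    mus <- c(mus, onsets$mouse[i])
  }
  if (!length(kept)) stop("no usable epochs")
  ep <- do.call(rbind, kept)
  structure(list(time_rel = time_rel, epochs = ep, label = lab, mouse = mus,
                 mean_trace = colMeans(ep), n_skipped = n_skip),
            class = "peri_event_matrix")
}

#' @export
print.peri_event_matrix <- function(x, ...) {
  cat(sprintf("<peri_event_matrix> %d epochs x %d samples, t in [%g, %g] s\n",
              nrow(x$epochs), ncol(x$epochs), min(x$time_rel), max(x$time_rel)))
  invisible(x)
}

#' Sliding-window slope of an averaged trace
#'
#' At each sample, the least-squares slope of the trace within a centered
#' window (default 0.5 s); windows are truncated at the record edges.
#'
#' @param x a `peri_event_matrix` (its mean trace is used), or a numeric
#'   trace with `time_s` supplied.
#' @param window_s window length (default 0.5 s).
#' @param time_s sample times, required when `x` is a bare numeric trace.
#' @return numeric slope series (units of z per second), same length as the
#'   trace.
#' @export
sliding_slope <- function(x, window_s = 0.5, time_s = NULL) {
  if (inherits(x, "peri_event_matrix")) {
    time_s <- x$time_rel
    y <- x$mean_trace
  } else {
    y <- x
    if (is.null(time_s)) stop("time_s required for a bare trace")
  }
  n <- length(y)
  if (n < 2 || (time_s[n] - time_s[1]) < window_s) {
    stop("trace shorter than the sliding window")
  }
  half <- window_s / 2
  out <- numeric(n)
  lo <- 1L
  hi <- 1L
  for (i in seq_len(n)) {
    while (time_s[lo] < time_s[i] - half - 1e-12) lo <- lo + 1L
    while (hi < n && time_s[hi + 1L] <= time_s[i] + half + 1e-12) hi <- hi + 1L
    tt <- time_s[lo:hi]; yy <- y[lo:hi]
    tc <- tt - mean(tt)
    out[i] <- sum(tc * (yy - mean(yy))) / sum(tc^2)
  }
  out
}

#' Mean z-score in the one-second bin around the behavior onset
#'
#' Arithmetic mean of the averaged peri-event trace over `[-0.5, +0.5]` s,
#' the summary statistic compared between conditions.
#'
#' @param x a `peri_event_matrix`, or a numeric trace with `time_s`.
#' @param bin bin limits (s), default `c(-0.5, 0.5)`.
#' @param time_s sample times when `x` is a bare trace.
#' @return scalar mean z.
#' @export
summary_bin <- function(x, bin = c(-0.5, 0.5), time_s = NULL) {
  if (inherits(x, "peri_event_matrix")) {
    time_s <- x$time_rel
    y <- x$mean_trace
  } else {
    y <- x
    if (is.null(time_s)) stop("time_s required for a bare trace")
  }
  sel <- time_s >= bin[1] - 1e-12 & time_s <= bin[2] + 1e-12
  if (!any(sel)) stop("trace does not cover the summary bin")
  mean(y[sel])
}
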