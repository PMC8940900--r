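# Synthetic two-channel fiber photometry: behavior-locked calcium transients
# on a bleaching baseline with shared motion artifacts, plus an isosbestic
# control channel, sampled at the decimated acquisition rate (381 Hz).

#' Calcium-transient kernel
#'
#' Rise-and-decay kernel `k(t) = A (1 - exp(-t/tau_r)) exp(-t/tau_d)` used for
#' injected transients; time constants default to typical values for the slow
#' and fast GCaMP6 variants.
#'
#' @param t time since event onset (s, >= 0).
#' @param amplitude peak scale `A` (arbitrary fluorescence units).
#' @param sensor `"GCaMP6s"` (tau_r 0.18 s, tau_d 1.4 s) or `"GCaMP6f"`
#'   (0.05 s, 0.40 s).
#' @param tau_r,tau_d optional explicit time constants (s), overriding sensor.
#' @return kernel values at `t`.
#' @export
transient_kernel <- function(t, amplitude = 1, sensor = c("GCaMP6s", "GCaMP6f"),
                             tau_r = NULL, tau_d = NULL) {
  sensor <- match.arg(sensor)
  tc <- switch(sensor, GCaMP6s = c(0.18, 1.4), GCaMP6f = c(0.05, 0.40))
  if (is.null(tau_r)) tau_r <- tc[1]
  if (is.null(tau_d)) tau_d <- tc[2]
  ifelse(t < 0, 0, amplitude * (1 - exp(-t / tau_r)) * exp(-t / tau_d))
}

# analytic peak time and value of the transient kernel
kernel_peak <- function(amplitude = 1, tau_r, tau_d) {
  tstar <- tau_r * log(1 + tau_d / tau_r)
  list(t = tstar, value = amplitude * (1 - exp(-tstar / tau_r)) * exp(-tstar / tau_d))
}

new_photometry_recording <- function(time_s, f490, f405, rate_hz,
                                     sync_events = NULL, true_events = NULL) {
  stopifnot(length(f490) == length(f405), rate_hz > 0,
            all(diff(time_s) > 0))
  structure(list(time_s = time_s, f490 = f490, f405 = f405, rate_hz = rate_hz,
                 sync_events = sync_events, true_events = true_events),
            class = "photometry_recording")
}

#' @export
print.photometry_recording <- function(x, ...) {
  cat(sprintf("<photometry_recording> %d samples @ %g Hz (%.1f s), %d sync events\n",
              length(x$f490), x$rate_hz, length(x$f490) / x$rate_hz,
              if (is.null(x$sync_events)) 0L else nrow(x$sync_events)))
  invisible(x)
}

#' Generate a synthetic two-channel photometry recording
#'
#' The calcium-dependent channel is
#' `f490 = (B490 + sum of transients) * bleach(t) + motion + noise` and the
#' isosbestic control is `f405 = B405 * bleach(t) + gain * motion + noise`;
#' both channels share the bleaching profile (double-exponential decay) and
#' the motion artifact (an AR(1) process), so the least-squares control fit
#' can absorb them. Transients arrive as an inhomogeneous Poisson process
#' whose rate increases while the mouse occupies a designated zone of the
#' trajectory's arena (behavior locking); true event onset times are retained
#' as ground truth.
#'
#' @param traj a `trajectory` covering the recording window.
#' @param rate_hz photometry sampling rate (default 381 Hz).
#' @param sensor `"GCaMP6s"` or `"GCaMP6f"`.
#' @param base_per_min baseline transient rate (events/min).
#' @param zone_gain_per_min added rate while in `rate_zone` (events/min).
#' @param rate_zone zone whose occupancy raises the transient rate; `NULL`
#'   (or a zone absent from the arena) leaves the rate homogeneous.
#' @param amp_mean,amp_cv transient amplitude mean (a.u.) and coefficient of
#'   variation (lognormal).
#' @param b490,b405 channel baselines (a.u.).
#' @param motion_sd,motion_tau_s motion-artifact sd (a.u.) and AR time
#'   constant (s); `motion_sd = 0` disables motion.
#' @param motion_gain_405 motion gain into the control channel.
#' @param bleach_tau_s,bleach_frac double-exponential bleach time constants
#'   (s) and the weight of the fast component; `bleach_frac = c(0, 0)` gives
#'   a flat profile.
#' @param noise_sd per-channel white measurement noise (a.u.).
#' @param seed RNG seed.
#' @return a `photometry_recording`; `true_events` holds ground-truth onset
#'   times and `sync_events` the entries into `rate_zone`.
#' @export
gen_photometry <- function(traj, rate_hz = 381, sensor = c("GCaMP6s", "GCaMP6f"),
                           base_per_min = 6, zone_gain_per_min = 12,
                           rate_zone = "open",
                           amp_mean = 8, amp_cv = 0.25,
                           b490 = 100, b405 = 80,
                           motion_sd = 2, motion_tau_s = 0.3,
                           motion_gain_405 = 0.8,
                           bleach_tau_s = c(60, 1000), bleach_frac = c(0.15, 0.85),
                           noise_sd = 0.5, seed = 1) {
  sensor <- match.arg(sensor)
  stopifnot(inherits(traj, "trajectory"))
  if (!isTRUE(rate_hz > 0)) stop("sampling rate must be positive")
  dur <- length(traj$time_s) / traj$video_hz
  n <- round(dur * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  dt <- 1 / rate_hz

  # behavior-locked rate: nearest trajectory sample (ties toward earlier)
  in_zone <- rep(FALSE, n)
  if (!is.null(rate_zone) && rate_zone %in% names(traj$arena$zones)) {
    idx <- pmin(length(traj$time_s), pmax(1L, floor(t * traj$video_hz + 0.5) + 1L))
    zi <- assign_zone(traj$x_cm[idx], traj$y_cm[idx], traj$arena)
    in_zone <- !is.na(zi) & names(traj$arena$zones)[zi] == rate_zone
  }
  lambda <- (base_per_min + zone_gain_per_min * in_zone) / 60 # events/s

  with_local_seed(seed, {
    ev <- which(stats::runif(n) < lambda * dt)
    ev_t <- t[ev]
    tc <- switch(sensor, GCaMP6s = c(0.18, 1.4), GCaMP6f = c(0.05, 0.40))
    kl <- ceiling((tc[1] * 6 + tc[2] * 6) * rate_hz)
    kt <- (seq_len(kl) - 1) / rate_hz
    s <- numeric(n + kl)
    if (length(ev)) {
      sdlog <- sqrt(log(1 + amp_cv^2))
      amps <- stats::rlnorm(length(ev), log(amp_mean) - sdlog^2 / 2, sdlog)
      for (i in seq_along(ev)) {
        k <- transient_kernel(kt, amps[i], tau_r = tc[1], tau_d = tc[2])
        j <- ev[i]:(ev[i] + kl - 1)
        s[j] <- s[j] + k
      }
    }
    s <- s[seq_len(n)]

    bleach <- 1 - bleach_frac[1] * (1 - exp(-t / bleach_tau_s[1])) -
      bleach_frac[2] * (1 - exp(-t / bleach_tau_s[2]))
    motion <- numeric(n)
    if (motion_sd > 0) {
      phi <- exp(-dt / motion_tau_s)
      innov <- stats::rnorm(n, 0, motion_sd * sqrt(1 - phi^2))
      motion <- as.numeric(stats::filter(innov, phi, method = "recursive"))
    }
    f490 <- (b490 + s) * bleach + motion + stats::rnorm(n, 0, noise_sd)
    f405 <- b405 * bleach + motion_gain_405 * motion + stats::rnorm(n, 0, noise_sd)

    sync <- NULL
    if (!is.null(rate_zone) && rate_zone %in% names(traj$arena$zones)) {
      et <- zone_entry_times(traj, rate_zone)
      if (length(et)) sync <- data.frame(time_s = et, label = rate_zone)
    }
    new_photometry_recording(t, f490, f405, rate_hz,
                             sync_events = sync, true_events = ev_t)
  })
}
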