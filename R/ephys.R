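# Patch-clamp feature extraction: spike detection, firing rate, putative-DA
# classification, excitability curve, rheobase, Ih amplitude, sag metrics,
# and per-mouse aggregation.

#' Detect spikes in a cell-attached trace
#'
#' The trace is high-pass filtered (2nd-order Butterworth, default 100 Hz
#' cutoff, zero-phase), thresholded at `threshold_sd` robust standard
#' deviations (1.4826 x MAD) on the negative-going side, and each
#' sub-threshold excursion is timestamped at its extremum; a refractory
#' period suppresses double counts.
#'
#' @param trace numeric trace (>= 1 s), or a `cell_attached` object.
#' @param rate_hz sampling rate (taken from the object when omitted).
#' @param threshold_sd detection threshold in robust SDs (default 4).
#' @param hp_cutoff_hz high-pass cutoff (default 100 Hz).
#' @param refractory_ms minimum inter-spike interval (default 2 ms).
#' @param min_width_ms minimum excursion width; single-sample threshold
#'   crossings are noise at physiological spike widths (default 0.2 ms).
#' @return numeric spike times (s).
#' @export
detect_spikes <- function(trace, rate_hz = NULL, threshold_sd = 4,
                          hp_cutoff_hz = 100, refractory_ms = 2,
                          min_width_ms = 0.2) {
  if (inherits(trace, "cell_attached")) {
    if (is.null(rate_hz)) rate_hz <- trace$rate_hz
    trace <- trace$trace
  }
  stopifnot(!is.null(rate_hz), length(trace) >= rate_hz)
  bf <- signal::butter(2, hp_cutoff_hz / (rate_hz / 2), type = "high")
  f <- as.numeric(signal::filtfilt(bf, trace))
  rsd <- stats::mad(f) # default constant 1.4826: robust SD
  if (rsd == 0) return(numeric(0))
  thr <- -threshold_sd * rsd
  below <- f < thr
  if (!any(below)) return(numeric(0))
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  wide <- r$lengths >= max(1L, round(min_width_ms / 1000 * rate_hz))
  if (!any(r$values & wide)) return(numeric(0))
  peaks <- vapply(which(r$values & wide), function(k) {
    i <- starts[k]:ends[k]
    i[which.min(f[i])]
  }, integer(1))
  cand <- (peaks - 1) / rate_hz
  keep <- numeric(0)
  last <- -Inf
  for (tt in cand) {
    if (tt - last >= refractory_ms / 1000) {
      keep <- c(keep, tt)
      last <- tt
    }
  }
  keep
}

#' Firing rate from spike times
#' @param spike_times_s spike times (s).
#' @param duration_s record duration (s), > 0.
#' @return rate in Hz (`count / duration`).
#' @export
firing_rate <- function(spike_times_s, duration_s) {
  stopifnot(duration_s > 0)
  length(spike_times_s) / duration_s
}

#' Onset-to-trough latency of the average spike waveform
#'
#' Averages trace windows aligned on the detected spike troughs, then
#' measures the latency from the waveform beginning (the last pre-trough
#' sample at or below `onset_frac` of the positive-lobe peak) to the negative
#' trough.
#'
#' @param trace numeric trace or `cell_attached`.
#' @param spike_times_s spike (trough) times from [detect_spikes()].
#' @param rate_hz sampling rate.
#' @param pre_ms,post_ms window around the trough (default 3 ms each side).
#' @param onset_frac onset criterion as a fraction of the positive-lobe peak.
#' @return latency in ms (NA when no spikes).
#' @export
spike_trough_latency <- function(trace, spike_times_s, rate_hz = NULL,
                                 pre_ms = 3, post_ms = 3, onset_frac = 0.1) {
  if (inherits(trace, "cell_attached")) {
    if (is.null(rate_hz)) rate_hz <- trace$rate_hz
    trace <- trace$trace
  }
  if (!length(spike_times_s)) return(NA_real_)
  npre <- round(pre_ms / 1000 * rate_hz)
  npost <- round(post_ms / 1000 * rate_hz)
  idx <- round(spike_times_s * rate_hz) + 1L
  idx <- idx[idx - npre >= 1 & idx + npost <= length(trace)]
  if (!length(idx)) return(NA_real_)
  w <- colMeans(t(vapply(idx, function(i) trace[(i - npre):(i + npost)],
                         numeric(npre + npost + 1))))
  ctr <- npre + 1L
  pos_peak_i <- which.max(w[1:ctr])
  pos_peak <- w[pos_peak_i]
  if (pos_peak <= 0) return(NA_real_)
  pre_onset <- which(w[1:pos_peak_i] <= onset_frac * pos_peak)
  onset_i <- if (length(pre_onset)) max(pre_onset) else 1L
  (ctr - onset_i) / rate_hz * 1000
}

#' Putative dopamine-neuron classification
#'
#' A unit is accepted iff its firing rate is between 1 and 10 Hz (inclusive)
#' and its onset-to-trough spike duration strictly exceeds 1.1 ms.
#'
#' @param firing_hz firing rate (Hz), finite.
#' @param trough_latency_ms spike onset-to-trough duration (ms), finite.
#' @return logical flag.
#' @export
classify_putative_da <- function(firing_hz, trough_latency_ms) {
  stopifnot(all(is.finite(firing_hz)), all(is.finite(trough_latency_ms)))
  firing_hz >= 1 & firing_hz <= 10 & trough_latency_ms > 1.1
}

# count spikes in a current-clamp trace: rising crossings of `mark` mV within
# [from_s, to_s); simulated spikes are drawn as +30 mV samples
count_spikes_cc <- function(trace, rate_hz, from_s, to_s, mark = -20) {
  i0 <- max(1L, floor(from_s * rate_hz) + 1L)
  i1 <- min(length(trace), ceiling(to_s * rate_hz))
  v <- trace[i0:i1]
  sum(v[-1] >= mark & v[-length(v)] < mark) + as.integer(v[1] >= mark)
}

#' Spikes per command step of the excitability protocol
#'
#' Counts action potentials within each 1-s current step of an excitability
#' `sweep_set` (commands must cover -100..280 pA in 20 pA increments).
#'
#' @param sweeps a `sweep_set` with `protocol == "excitability"`.
#' @return data frame with `command_pA` and `n_spikes`.
#' @export
excitability_curve <- function(sweeps) {
  stopifnot(inherits(sweeps, "sweep_set"))
  if (sweeps$protocol != "excitability") stop("protocol must be 'excitability'")
  expected <- seq(-100, 280, by = 20)
  absent <- setdiff(expected, sweeps$commands)
  if (length(absent)) {
    stop(sprintf("missing command step(s): %s pA", paste(absent, collapse = ", ")))
  }
  n <- vapply(seq_along(sweeps$commands), function(i) {
    count_spikes_cc(sweeps$sweeps[[i]], sweeps$rate_hz,
                    sweeps$step_on_s, sweeps$step_off_s)
  }, integer(1))
  data.frame(command_pA = sweeps$commands, n_spikes = n)
}

#' Rheobase from an excitability curve
#'
#' The minimal command current eliciting at least one action potential;
#' `NA` when no step spikes.
#'
#' @param curve data frame from [excitability_curve()].
#' @return rheobase in pA, or `NA_real_` (undefined).
#' @export
rheobase <- function(curve) {
  stopifnot(all(c("command_pA", "n_spikes") %in% names(curve)))
  hit <- curve$command_pA[curve$n_spikes >= 1]
  if (!length(hit)) NA_real_ else min(hit)
}

#' Ih current amplitude per voltage-step command
#'
#' For each sweep of the voltage-clamp protocol, Ih is the mean current over
#' the final fraction of the step (steady state) minus the mean over a short
#' post-transient window (instantaneous current); inward currents are
#' negative.
#'
#' @param sweeps a `sweep_set` with `protocol == "ih_vclamp"`.
#' @param inst_window_s instantaneous window after step onset (default
#'   20-60 ms).
#' @param ss_frac final fraction of the step used as steady state (default
#'   0.1).
#' @return data frame with `command_mV` and `ih_pA`.
#' @export
ih_amplitude <- function(sweeps, inst_window_s = c(0.020, 0.060), ss_frac = 0.1) {
  stopifnot(inherits(sweeps, "sweep_set"))
  if (sweeps$protocol != "ih_vclamp") stop("protocol must be 'ih_vclamp'")
  dur <- sweeps$step_off_s - sweeps$step_on_s
  win_mean <- function(tr, a, b) {
    i <- (floor(a * sweeps$rate_hz) + 1L):min(length(tr), ceiling(b * sweeps$rate_hz))
    if (i[1] < 1 || i[length(i)] > length(tr)) stop("measurement window outside trace")
    mean(tr[i])
  }
  ih <- vapply(seq_along(sweeps$commands), function(k) {
    tr <- sweeps$sweeps[[k]]
    inst <- win_mean(tr, sweeps$step_on_s + inst_window_s[1],
                     sweeps$step_on_s + inst_window_s[2])
    ss <- win_mean(tr, sweeps$step_off_s - ss_frac * dur, sweeps$step_off_s)
    ss - inst
  }, numeric(1))
  data.frame(command_mV = sweeps$commands, ih_pA = ih)
}

#' Sag amplitude and ratio from a hyperpolarizing current step
#'
#' `V_peak` is the voltage minimum during the step, `V_ss` the mean over the
#' final fraction of the step, and `V_baseline` the pre-step mean. Sag
#' amplitude is `V_ss - V_peak` (repolarization from the peak, >= 0 for an
#' Ih-bearing cell); the sag ratio normalizes it by the full deflection,
#' `(V_ss - V_peak) / (V_baseline - V_peak)`. A peak outside the -90..-70 mV
#' target band yields a warning but the metrics are still returned.
#'
#' @param sweeps a `sweep_set` with a current-clamp hyperpolarizing step
#'   (protocol `"sag_cclamp"`), or any current-clamp sweep set.
#' @param sweep sweep index (default 1).
#' @param ss_frac final fraction of the step used as steady state.
#' @return list with `sag_amp_mV`, `sag_ratio`, `V_peak_mV`, `V_ss_mV`,
#'   `V_baseline_mV`.
#' @export
sag_metrics <- function(sweeps, sweep = 1, ss_frac = 0.1) {
  stopifnot(inherits(sweeps, "sweep_set"))
  tr <- sweeps$sweeps[[sweep]]
  r <- sweeps$rate_hz
  i_on <- floor(sweeps$step_on_s * r) + 1L
  i_off <- min(length(tr), ceiling(sweeps$step_off_s * r))
  dur <- sweeps$step_off_s - sweeps$step_on_s
  v_base <- mean(tr[max(1L, i_on - round(0.1 * r)):(i_on - 1L)])
  step <- tr[i_on:i_off]
  v_peak <- min(step)
  i_ss <- (floor((sweeps$step_off_s - ss_frac * dur) * r) + 1L):i_off
  v_ss <- mean(tr[i_ss])
  if (v_peak < -90 || v_peak > -70) {
    warning(sprintf("voltage peak %.1f mV outside the -90..-70 mV target band", v_peak))
  }
  list(sag_amp_mV = v_ss - v_peak,
       sag_ratio = (v_ss - v_peak) / (v_base - v_peak),
       V_peak_mV = v_peak, V_ss_mV = v_ss, V_baseline_mV = v_base)
}

#' Aggregate neuron-level features to mouse level
#'
#' Unweighted arithmetic mean of each numeric feature per mouse; by default
#' neurons failing the putative-dopamine criteria are excluded first
#' (mirroring the recording inclusion rule), and mice left with no neurons
#' are dropped with a message.
#'
#' @param features data frame with a `mouse` column, numeric feature columns,
#'   and optionally `is_putative_da`.
#' @param putative_da_only drop non-putative-DA neurons first (default TRUE).
#' @return data frame, one row per mouse with per-feature means and
#'   `n_neurons`.
#' @export
per_mouse_mean <- function(features, putative_da_only = TRUE) {
  stopifnot(is.data.frame(features), "mouse" %in% names(features))
  if (putative_da_only && "is_putative_da" %in% names(features)) {
    features <- features[features$is_putative_da %in% TRUE, , drop = FALSE]
  }
  all_mice <- unique(features$mouse)
  num <- names(features)[vapply(features, is.numeric, logical(1))]
  out <- lapply(all_mice, function(m) {
    g <- features[features$mouse == m, , drop = FALSE]
    if (!nrow(g)) return(NULL)
    row <- as.data.frame(lapply(g[num], mean))
    cbind(data.frame(mouse = m, n_neurons = nrow(g)), row)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    message("per_mouse_mean: no mice with included neurons")
    return(data.frame(mouse = character(0), n_neurons = integer(0)))
  }
  do.call(rbind, out)
}
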