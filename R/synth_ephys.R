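# Synthetic electrophysiology: a single-compartment spike-and-reset membrane
# with one Ih (HCN) gating variable, step protocols matching the recording
# conventions (1-s current steps -100..280 pA in 20 pA increments; 3-s
# voltage steps -120..-60 mV in 10 mV increments from a -60 mV hold), and
# cell-attached spike traces from a gamma renewal process.

#' Membrane model parameters
#'
#' Single-compartment leaky integrate-and-fire membrane with an Ih
#' conductance: `C dV/dt = -g_L (V - E_L) - g_h x (V - E_h) + I`, gating
#' `dx/dt = (x_inf(V) - x) / tau_h` with
#' `x_inf(V) = 1 / (1 + exp((V - V_half)/k))`, and spike-and-reset at `V_th`.
#' Units: pF, nS, mV, ms (so nS x mV = pA).
#'
#' @param C_pF capacitance.
#' @param g_L_nS leak conductance.
#' @param E_L_mV leak reversal.
#' @param V_th_mV spike threshold.
#' @param V_reset_mV reset voltage.
#' @param E_h_mV Ih reversal.
#' @param g_h_nS maximal Ih conductance.
#' @param V_half_mV,k_mV Ih activation midpoint and slope.
#' @param tau_h_ms Ih activation time constant.
#' @return named list of parameters.
#' @export
membrane_params <- function(C_pF = 100, g_L_nS = 5, E_L_mV = -60,
                            V_th_mV = -40, V_reset_mV = -60,
                            E_h_mV = -30, g_h_nS = 2,
                            V_half_mV = -85, k_mV = 6, tau_h_ms = 300) {
  p <- list(C_pF = C_pF, g_L_nS = g_L_nS, E_L_mV = E_L_mV, V_th_mV = V_th_mV,
            V_reset_mV = V_reset_mV, E_h_mV = E_h_mV, g_h_nS = g_h_nS,
            V_half_mV = V_half_mV, k_mV = k_mV, tau_h_ms = tau_h_ms)
  stop_if_not_finite(p, "membrane_params")
  stopifnot(p$g_L_nS > 0, p$C_pF > 0, p$tau_h_ms > 0)
  p
}

#' Ih steady-state activation
#' @param V_mV membrane voltage.
#' @param params [membrane_params()].
#' @return activation in \[0, 1\].
#' @export
x_inf <- function(V_mV, params) 1 / (1 + exp((V_mV - params$V_half_mV) / params$k_mV))

#' Subthreshold steady-state voltage under constant current
#'
#' Root of the current balance
#' `g_L (V - E_L) + g_h x_inf(V) (V - E_h) = I`; the analytic fixed point the
#' integrator must conserve.
#'
#' @param params [membrane_params()].
#' @param I_pA injected current.
#' @return steady-state voltage (mV).
#' @export
membrane_fixed_point <- function(params, I_pA = 0) {
  f <- function(V) params$g_L_nS * (V - params$E_L_mV) +
    params$g_h_nS * x_inf(V, params) * (V - params$E_h_mV) - I_pA
  stats::uniroot(f, c(-200, params$V_th_mV + 200), tol = 1e-10)$root
}

new_sweep_set <- function(protocol, commands, sweeps, rate_hz,
                          step_on_s, step_off_s, params = NULL) {
  structure(list(protocol = protocol, commands = commands, sweeps = sweeps,
                 rate_hz = rate_hz, step_on_s = step_on_s,
                 step_off_s = step_off_s, params = params),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> %s: %d sweeps @ %g kHz, step %g-%g s, commands %g..%g\n",
              x$protocol, length(x$sweeps), x$rate_hz / 1000, x$step_on_s,
              x$step_off_s, min(x$commands), max(x$commands)))
  invisible(x)
}

# forward-Euler current-clamp integration with spike-and-reset; spikes are
# drawn as a +30 mV sample so they can be counted from the waveform
integrate_cclamp <- function(params, I_pA, dt_ms) {
  n <- length(I_pA)
  V <- numeric(n)
  v <- membrane_fixed_point(params, I_pA[1])
  x <- x_inf(v, params)
  V[1] <- v
  gL <- params$g_L_nS; EL <- params$E_L_mV; gh <- params$g_h_nS
  Eh <- params$E_h_mV; Vh <- params$V_half_mV; kk <- params$k_mV
  th <- params$tau_h_ms; C <- params$C_pF
  Vth <- params$V_th_mV; Vr <- params$V_reset_mV
  for (i in 2:n) {
    x <- x + dt_ms * (1 / (1 + exp((v - Vh) / kk)) - x) / th
    v <- v + dt_ms * (-gL * (v - EL) - gh * x * (v - Eh) + I_pA[i]) / C
    if (v > Vth) {
      V[i] <- 30
      v <- Vr
    } else {
      V[i] <- v
    }
  }
  V
}

#' Generate step-protocol sweeps from the membrane model
#'
#' `excitability`: 1-s current steps from -100 to 280 pA in 20 pA increments
#' (current clamp, holding 0 pA). `ih_vclamp`: 3-s voltage steps from -120 to
#' -60 mV in 10 mV increments from a -60 mV holding potential; the returned
#' current is `I(t) = g_L (V - E_L) + g_h x(t) (V - E_h)`. `sag_cclamp`: a
#' 1-s hyperpolarizing current step sized from the instantaneous I-V relation
#' so the voltage peak lands near the requested target (about -80 mV).
#' Integration uses forward Euler at `dt_ms` (must be <= 0.1 ms).
#'
#' @param params [membrane_params()].
#' @param protocol one of `"excitability"`, `"ih_vclamp"`, `"sag_cclamp"`.
#' @param seed RNG seed (used only when `noise_sd > 0`).
#' @param dt_ms integration/sampling step (default 0.05 ms).
#' @param noise_sd additive Gaussian observation noise (mV or pA).
#' @param pre_s,post_s baseline before and tail after the step (s).
#' @param sag_peak_mV voltage-peak target for `sag_cclamp` (default -80).
#' @return a `sweep_set`; `sweeps` is a list of traces (mV for current clamp,
#'   pA for voltage clamp), one per command value.
#' @export
gen_step_protocols <- function(params, protocol = c("excitability", "ih_vclamp",
                                                    "sag_cclamp"),
                               seed = 1, dt_ms = 0.05, noise_sd = 0,
                               pre_s = 0.2, post_s = 0.2, sag_peak_mV = -80) {
  protocol <- match.arg(protocol)
  stop_if_not_finite(params, "params")
  stopifnot(dt_ms > 0, dt_ms <= 0.1)
  rate_hz <- 1000 / dt_ms

  step_s <- if (protocol == "ih_vclamp") 3 else 1
  n_pre <- round(pre_s * 1000 / dt_ms)
  n_step <- round(step_s * 1000 / dt_ms)
  n_post <- round(post_s * 1000 / dt_ms)
  n <- n_pre + n_step + n_post
  in_step <- c(rep(FALSE, n_pre), rep(TRUE, n_step), rep(FALSE, n_post))

  commands <- switch(protocol,
    excitability = seq(-100, 280, by = 20),
    ih_vclamp = seq(-120, -60, by = 10),
    sag_cclamp = {
      x0 <- x_inf(-60, params)
      I <- params$g_L_nS * (sag_peak_mV - params$E_L_mV) +
        params$g_h_nS * x0 * (sag_peak_mV - params$E_h_mV)
      round(I, 1)
    })

  with_local_seed(seed, {
    sweeps <- lapply(commands, function(cmd) {
      if (protocol == "ih_vclamp") {
        V <- ifelse(in_step, cmd, -60)
        # Euler recursion for x under piecewise-constant V (exact solution of
        # the discrete update, so identical to the stepwise loop)
        a <- dt_ms / params$tau_h_ms
        x <- numeric(n)
        x[1] <- x_inf(-60, params)
        seg <- rle(in_step)
        ends <- cumsum(seg$lengths)
        starts <- ends - seg$lengths + 1L
        for (k in seq_along(seg$lengths)) {
          v <- if (seg$values[k]) cmd else -60
          xi <- x_inf(v, params)
          i0 <- if (k == 1) 2L else starts[k]
          x0 <- if (k == 1) x[1] else x[starts[k] - 1L]
          m <- seq(i0, ends[k]) - (i0 - 1L)
          x[i0:ends[k]] <- xi + (x0 - xi) * (1 - a)^m
        }
        tr <- params$g_L_nS * (V - params$E_L_mV) +
          params$g_h_nS * x * (V - params$E_h_mV)
      } else {
        I <- ifelse(in_step, cmd, 0)
        tr <- integrate_cclamp(params, I, dt_ms)
      }
      if (noise_sd > 0) tr <- tr + stats::rnorm(n, 0, noise_sd)
      tr
    })
    new_sweep_set(protocol, commands, sweeps, rate_hz,
                  step_on_s = n_pre * dt_ms / 1000,
                  step_off_s = (n_pre + n_step) * dt_ms / 1000,
                  params = params)
  })
}

#' Generate a cell-attached spike trace
#'
#' Spike times follow a gamma renewal process (shape `isi_shape`, mean
#' interval `1 / rate_hz_spikes`); each spike contributes a stereotyped
#' biphasic waveform (positive lobe then negative trough, with the trough
#' `trough_latency_ms` after waveform onset) on additive Gaussian noise.
#' Ground-truth spike times are reported at the waveform trough.
#'
#' @param rate_hz_spikes mean firing rate (Hz); 0 yields pure noise.
#' @param duration_s trace duration (> 0).
#' @param noise_sd noise standard deviation (trace units; trough depth is
#'   `amplitude`).
#' @param seed RNG seed.
#' @param sample_rate_hz sampling rate (default 10 kHz).
#' @param isi_shape gamma shape of the inter-spike intervals (default 4,
#'   pacemaker-like regularity).
#' @param trough_latency_ms onset-to-trough latency of the waveform (must
#'   exceed the 0.4-ms positive lobe).
#' @param amplitude trough depth (default 1).
#' @return list of class `cell_attached`: `trace`, `rate_hz`, `duration_s`,
#'   `true_spike_times_s` (trough times), `trough_latency_ms`.
#' @export
gen_cell_attached <- function(rate_hz_spikes, duration_s, noise_sd = 0.1,
                              seed = 1, sample_rate_hz = 10000,
                              isi_shape = 4, trough_latency_ms = 1.5,
                              amplitude = 1) {
  stopifnot(rate_hz_spikes >= 0, duration_s > 0, sample_rate_hz > 0)
  d1 <- 0.4 # positive-lobe duration, ms
  if (trough_latency_ms <= d1) stop("trough latency must exceed the 0.4 ms positive lobe")
  if (rate_hz_spikes * duration_s > 5e5) stop("spike count would overflow the trace")
  n <- round(duration_s * sample_rate_hz)
  with_local_seed(seed, {
    trace <- stats::rnorm(n, 0, noise_sd)
    spikes <- numeric(0)
    if (rate_hz_spikes > 0) {
      m <- ceiling(rate_hz_spikes * duration_s * 2 + 20)
      isi <- stats::rgamma(m, shape = isi_shape,
                           rate = isi_shape * rate_hz_spikes)
      onsets <- cumsum(isi)
      d2 <- 2 * (trough_latency_ms - d1)
      wlen_ms <- d1 + d2
      onsets <- onsets[onsets < duration_s - wlen_ms / 1000]
      if (length(onsets)) {
        wt <- seq(0, wlen_ms, by = 1000 / sample_rate_hz)
        w <- ifelse(wt <= d1,
                    0.4 * amplitude * sin(pi * wt / d1),
                    -amplitude * sin(pi * (wt - d1) / d2))
        for (o in onsets) {
          i0 <- floor(o * sample_rate_hz) + 1L
          j <- i0:(i0 + length(w) - 1L)
          trace[j] <- trace[j] + w
        }
        spikes <- onsets + trough_latency_ms / 1000
      }
    }
    structure(list(trace = trace, rate_hz = sample_rate_hz,
                   duration_s = duration_s, true_spike_times_s = spikes,
                   trough_latency_ms = trough_latency_ms),
              class = "cell_attached")
  })
}

#' @export
print.cell_attached <- function(x, ...) {
  cat(sprintf("<cell_attached> %.1f s @ %g kHz, %d true spikes\n",
              x$duration_s, x$rate_hz / 1000, length(x$true_spike_times_s)))
  invisible(x)
}
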