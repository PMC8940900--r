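# Membrane simulator and cell-attached generator: analytic fixed points,
# LIF rheobase, closed-form Ih, renewal spike statistics.

test_that("passive cell at rest stays at the leak reversal", {
  p <- membrane_params(g_h_nS = 0)
  ss <- gen_step_protocols(p, "excitability")
  v0 <- ss$sweeps[[which(ss$commands == 0)]] # zero-current sweep
  expect_true(all(abs(v0 - p$E_L_mV) < 1e-9))
})

test_that("LIF rheobase is the first step strictly above g_L (V_th - E_L)", {
  p <- membrane_params(g_h_nS = 0) # g_L = 5 nS, E_L = -60, V_th = -40
  ss <- gen_step_protocols(p, "excitability")
  cur <- excitability_curve(ss)
  expect_equal(rheobase(cur), 120) # smallest step above 100 pA
  expect_true(all(cur$n_spikes[cur$command_pA <= 100] == 0))
})

test_that("voltage-clamp Ih amplitude matches the gating closed form", {
  # exact expectation including the finite measurement windows: under a
  # voltage clamp x(t) relaxes exponentially, so window means are analytic
  p <- membrane_params()
  ss <- gen_step_protocols(p, "ih_vclamp")
  ih <- ih_amplitude(ss)
  tau <- p$tau_h_ms / 1000
  mean_x <- function(V, a, b) {
    xi0 <- x_inf(-60, p); xiv <- x_inf(V, p)
    xiv + (xi0 - xiv) * tau * (exp(-a / tau) - exp(-b / tau)) / (b - a)
  }
  for (k in seq_along(ss$commands)) {
    V <- ss$commands[k]
    expected <- p$g_h_nS * (V - p$E_h_mV) *
      (mean_x(V, 2.7, 3.0) - mean_x(V, 0.020, 0.060))
    if (abs(expected) > 1) {
      expect_lt(abs(ih$ih_pA[k] - expected) / abs(expected), 0.02)
    }
  }
  # large tau relative to the instantaneous window: steady-state minus
  # instantaneous reduces to g_h (V - E_h) (x_inf(V) - x_inf(-60))
  ihm <- ih_amplitude(ss, inst_window_s = c(0.002, 0.006))
  V <- -120
  approx <- p$g_h_nS * (V - p$E_h_mV) * (x_inf(V, p) - x_inf(-60, p))
  expect_lt(abs(ihm$ih_pA[1] - approx) / abs(approx), 0.05)
})

test_that("simulator conserves the analytic subthreshold fixed point", {
  p <- membrane_params()
  ss <- gen_step_protocols(p, "ih_vclamp") # irrelevant; need cclamp below
  cc <- gen_step_protocols(p, "excitability")
  for (I in c(-100, -60, -20)) {
    tr <- cc$sweeps[[which(cc$commands == I)]]
    # late in the 1-s step the trajectory should sit near the balance root
    v_late <- tr[round(1.15 * cc$rate_hz)]
    expect_lt(abs(v_late - membrane_fixed_point(p, I)), 0.5)
  }
})

test_that("cell-attached spike counts follow the gamma renewal band", {
  ca <- gen_cell_attached(4, 60, seed = 12)
  # oracle: simulate renewal counts directly from the interval model
  counts <- withr::with_seed(77, {
    replicate(2000, sum(cumsum(rgamma(500, shape = 4, rate = 16)) < 60))
  })
  band <- stats::quantile(counts, c(0.005, 0.995))
  expect_gte(length(ca$true_spike_times_s), band[[1]])
  expect_lte(length(ca$true_spike_times_s), band[[2]])
  expect_length(gen_cell_attached(0, 10, seed = 1)$true_spike_times_s, 0)
})

test_that("waveform trough latency propagates to putative-DA classification", {
  wide <- gen_cell_attached(4, 30, seed = 3, trough_latency_ms = 1.5)
  narrow <- gen_cell_attached(4, 30, seed = 3, trough_latency_ms = 0.8)
  lat_w <- spike_trough_latency(wide, detect_spikes(wide))
  lat_n <- spike_trough_latency(narrow, detect_spikes(narrow))
  fr <- firing_rate(detect_spikes(wide), 30)
  expect_true(classify_putative_da(fr, lat_w))
  expect_false(classify_putative_da(fr, lat_n))
})

test_that("degenerate membrane parameters are rejected", {
  expect_error(membrane_params(g_L_nS = 0))
  expect_error(membrane_params(tau_h_ms = Inf), "non-finite")
  expect_error(gen_cell_attached(4, 30, trough_latency_ms = 0.3), "latency")
  expect_error(gen_cell_attached(1e5, 100), "overflow")
})
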