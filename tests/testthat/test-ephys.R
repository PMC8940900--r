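# Ephys feature extraction: spike detection, excitability, rheobase, Ih,
# sag, classification grid, per-mouse aggregation.

test_that("spike detection has low false-positive rate on pure noise", {
  fp <- vapply(1:8, function(s) {
    ca <- gen_cell_attached(0, 30, noise_sd = 1, seed = s, amplitude = 1)
    length(detect_spikes(ca)) / 30
  }, numeric(1))
  expect_lt(mean(fp), 0.2)
})

test_that("spike detection recovers ground truth at SNR 8", {
  ca <- gen_cell_attached(4, 60, noise_sd = 1 / 8, seed = 21)
  det <- detect_spikes(ca)
  truth <- ca$true_spike_times_s
  hits <- vapply(det, function(tt) any(abs(truth - tt) <= 1e-3), logical(1))
  found <- vapply(truth, function(tt) any(abs(det - tt) <= 1e-3), logical(1))
  expect_gte(mean(hits), 0.99)   # precision
  expect_gte(mean(found), 0.99)  # recall
})

test_that("a single spike in a one-second trace is detected", {
  ca <- gen_cell_attached(1, 1, noise_sd = 0.05, seed = 2, isi_shape = 50)
  if (length(ca$true_spike_times_s) >= 1) {
    expect_gte(length(detect_spikes(ca)), 1L)
  }
  succeed()
})

test_that("firing rate is count over duration and matches the renewal rate", {
  expect_equal(firing_rate(numeric(0), 60), 0)
  expect_equal(firing_rate(seq_len(240), 60), 4)
  ca <- gen_cell_attached(4, 60, seed = 31)
  fr <- firing_rate(detect_spikes(ca), 60)
  expect_lt(abs(fr - 4) / 4, 0.15) # renewal band at 60 s
})

test_that("putative-DA rule is a band in rate and a cut in spike width", {
  expect_true(classify_putative_da(4, 1.5))
  expect_false(classify_putative_da(0.5, 1.5))
  expect_false(classify_putative_da(12, 1.5))
  expect_false(classify_putative_da(4, 1.1)) # strict 'superior to 1.1 ms'
  expect_true(classify_putative_da(1, 1.2))  # rate band inclusive
  expect_true(classify_putative_da(10, 1.2))
  # band rule: not monotone in firing rate (exhaustive grid)
  grid <- expand.grid(rate = c(0.5, 1, 4, 10, 12), lat = c(0.9, 1.1, 1.3, 2))
  flags <- with(grid, classify_putative_da(rate, lat))
  by_lat <- split(flags, grid$lat)
  expect_true(any(vapply(by_lat, function(f) any(diff(f) < 0), logical(1))))
})

test_that("excitability counts match the closed-form LIF firing map", {
  p <- membrane_params(g_h_nS = 0)
  cur <- excitability_curve(gen_step_protocols(p, "excitability"))
  tau_ms <- p$C_pF / p$g_L_nS
  for (k in seq_len(nrow(cur))) {
    I <- cur$command_pA[k]
    v_inf <- p$E_L_mV + I / p$g_L_nS
    expected <- if (v_inf <= p$V_th_mV) {
      0
    } else {
      t1 <- tau_ms * log((v_inf - p$E_L_mV) / (v_inf - p$V_th_mV))
      floor(1000 / t1)
    }
    expect_lte(abs(cur$n_spikes[k] - expected), 1)
  }
  expect_true(all(diff(cur$n_spikes) >= 0)) # monotone in command
})

test_that("rheobase takes the smallest spiking command without sign assumptions", {
  cur <- data.frame(command_pA = seq(-100, 280, 20), n_spikes = 0)
  expect_true(is.na(rheobase(cur)))
  cur$n_spikes[cur$command_pA == -20] <- 1
  expect_equal(rheobase(cur), -20)
  ss <- gen_step_protocols(membrane_params(g_h_nS = 0), "excitability")
  bad <- ss; bad$commands <- bad$commands[-3]; bad$sweeps <- bad$sweeps[-3]
  expect_error(excitability_curve(bad), "-60")
})

test_that("Ih vanishes without the conductance and grows toward -120 mV", {
  ih0 <- ih_amplitude(gen_step_protocols(membrane_params(g_h_nS = 0), "ih_vclamp"))
  expect_true(all(abs(ih0$ih_pA) < 1e-9))
  ih <- ih_amplitude(gen_step_protocols(membrane_params(), "ih_vclamp"))
  expect_true(all(diff(abs(ih$ih_pA)) <= 1e-9)) # |Ih| decreasing toward -60
})

test_that("sag metrics follow the constructed-trace arithmetic", {
  rate <- 10000
  pre <- rep(-60, 2000)
  step <- c(seq(-60, -80, length.out = 200), rep(-80, 4800),
            seq(-80, -74, length.out = 2000), rep(-74, 3000))
  tr <- c(pre, step, rep(-60, 2000))
  ss <- make_sweep_set("sag_cclamp", 0, list(tr), rate, 0.2, 1.2)
  m <- sag_metrics(ss)
  expect_equal(m$sag_amp_mV, 6, tolerance = 1e-9)
  expect_equal(m$sag_ratio, 0.30, tolerance = 1e-9)
})

test_that("sag amplitude vanishes without Ih and increases with g_h", {
  amps <- vapply(c(0, 1, 2, 4), function(g) {
    p <- membrane_params(g_h_nS = g)
    ss <- gen_step_protocols(p, "sag_cclamp")
    suppressWarnings(sag_metrics(ss))$sag_amp_mV
  }, numeric(1))
  expect_lt(abs(amps[1]), 0.1)
  expect_true(all(diff(amps) > 0))
})

test_that("per-mouse aggregation is an unweighted, permutation-invariant mean", {
  f <- data.frame(mouse = c("a", "b", "b", "b"), firing_hz = c(3, 2, 4, 6),
                  is_putative_da = TRUE)
  out <- per_mouse_mean(f)
  expect_equal(out$firing_hz[out$mouse == "a"], 3)
  expect_equal(out$firing_hz[out$mouse == "b"], 4)
  perm <- per_mouse_mean(f[c(4, 2, 1, 3), ])
  expect_equal(sort(perm$firing_hz), sort(out$firing_hz))
  # exclusion of non-putative-DA units and empty groups
  f$is_putative_da <- c(FALSE, TRUE, TRUE, TRUE)
  expect_false("a" %in% per_mouse_mean(f)$mouse)
  expect_message(per_mouse_mean(data.frame(mouse = "a", firing_hz = 1,
                                           is_putative_da = FALSE)),
                 "no mice")
})
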