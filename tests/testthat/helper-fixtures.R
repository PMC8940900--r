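# Builders for hand-constructed objects used across test files.

# dff_series with prescribed samples (bypasses the control fit)
make_dff_series <- function(dff, rate_hz = 381) {
  structure(list(
    time_s = (seq_along(dff) - 1) / rate_hz,
    dff = dff,
    z = if (stats::sd(dff) > 0) as.numeric(scale(dff)) else dff * 0,
    rate_hz = rate_hz, fit = NULL, sync_events = NULL
  ), class = "dff_series")
}

# photometry recording with prescribed channels
make_recording <- function(f490, f405, rate_hz = 381) {
  circuitphys:::new_photometry_recording(
    (seq_along(f490) - 1) / rate_hz, f490, f405, rate_hz)
}

# trajectory with prescribed positions
make_trajectory <- function(x, y, arena, video_hz = 30) {
  circuitphys:::new_trajectory((seq_along(x) - 1) / video_hz, x, y,
                               arena, video_hz)
}

# current-clamp sweep set with prescribed traces
make_sweep_set <- function(protocol, commands, sweeps, rate_hz,
                           step_on_s, step_off_s) {
  circuitphys:::new_sweep_set(protocol, commands, sweeps, rate_hz,
                              step_on_s, step_off_s)
}
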