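# Internal utilities: seed splitting, input checks, small numeric helpers.

#' Derive a reproducible sub-seed from a master seed
#'
#' All stochastic stages draw their randomness from sub-seeds derived from one
#' master seed, so any stage can be regenerated in isolation. The scheme is a
#' fixed integer hash of `(seed, stage, index)`; all arithmetic stays below
#' 2^53 so it is exact in doubles, and the result is always in `[1, 2^31 - 2]`.
#'
#' @param seed master seed (integer-valued scalar).
#' @param stage character stage tag, e.g. `"trajectory"`.
#' @param index integer index within the stage (e.g. mouse number), default 0.
#' @return an integer usable with [set.seed()].
#' @export
split_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  code <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  m <- 2147483647 # 2^31 - 1, prime
  h <- ((abs(seed) %% m) * 69069 + index * 1000003 + code * 131 + 17) %% m
  as.integer(h %% (m - 1L) + 1)
}

# run expr under a local RNG state seeded with `seed`
with_local_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

stop_if_not_finite <- function(x, name) {
  if (!all(is.finite(unlist(x)))) {
    stop(sprintf("configuration error: non-finite value in '%s'", name), call. = FALSE)
  }
  invisible(TRUE)
}

clip01 <- function(x) pmin(1, pmax(0, x))

# reflect values into [lo, hi] (Brownian reflection fold)
reflect_fold <- function(z, lo, hi) {
  w <- hi - lo
  if (w <= 0) return(rep(lo, length(z)))
  m <- (z - lo) %% (2 * w)
  lo + ifelse(m > w, 2 * w - m, m)
}

#' Pulse-train timing arithmetic for patterned stimulation
#'
#' Converts a pulse/gap/train description (e.g. trains of 40-ms light pulses
#' separated by 10-ms gaps, one train every 5 s) into the within-train pulse
#' frequency and the train repetition rate.
#'
#' @param pulse_width_s pulse ON duration, seconds.
#' @param gap_s OFF gap between pulses within a train, seconds.
#' @param train_period_s time between train onsets, seconds.
#' @return list with `within_train_hz` and `train_rate_hz`.
#' @examples
#' stim_train_spec(0.040, 0.010, 5) # 20 Hz within-train, 0.2 Hz trains
#' @export
stim_train_spec <- function(pulse_width_s, gap_s, train_period_s) {
  stopifnot(pulse_width_s > 0, gap_s >= 0, train_period_s > 0)
  list(
    within_train_hz = 1 / (pulse_width_s + gap_s),
    train_rate_hz = 1 / train_period_s
  )
}
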