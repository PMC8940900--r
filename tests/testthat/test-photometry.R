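# Photometry processing: control fit, dF/F, AUC, event detection,
# peri-event contract, slope and summary statistics.

test_that("control fit recovers exact and noisy affine relations", {
  rate <- 381
  x <- 80 + sin(seq(0, 20, length.out = 2000))
  rec <- make_recording(x, x, rate)
  f <- fit_control(rec)
  expect_equal(f$slope, 1, tolerance = 1e-9)
  expect_equal(f$intercept, 0, tolerance = 1e-7)

  rec2 <- make_recording(2 * x + 3, x, rate)
  f2 <- fit_control(rec2)
  expect_equal(f2$slope, 2, tolerance = 1e-9)
  expect_equal(f2$intercept, 3, tolerance = 1e-7)

  withr::with_seed(5, {
    xn <- rnorm(5000, 80, 3)
    yn <- 1.4 * xn - 7 + rnorm(5000, 0, 0.5)
    rec3 <- make_recording(yn, xn, rate)
    f3 <- fit_control(rec3)
    cf <- stats::coef(stats::lm(yn ~ xn)) # independent OLS oracle
    expect_equal(f3$slope, unname(cf[2]), tolerance = 1e-9)
    expect_equal(f3$intercept, unname(cf[1]), tolerance = 1e-9)
    se <- summary(stats::lm(yn ~ xn))$coefficients[2, 2]
    expect_lt(abs(f3$slope - 1.4), 4 * se)
  })
})

test_that("dF/F arithmetic and the session z-score contract hold", {
  rate <- 381
  x <- 80 + sin(seq(0, 20, length.out = 2000))
  rec <- make_recording(x, x, rate)
  s <- dff(rec)
  expect_true(all(abs(s$dff) < 1e-9))

  fitted <- rep(100, 500)
  y <- fitted
  y[250] <- 110
  rec2 <- make_recording(y, fitted, rate)
  s2 <- dff(rec2, fitted405 = fitted)
  expect_equal(s2$dff[250], 0.10)
  expect_equal(mean(s2$z), 0, tolerance = 1e-9)
  expect_equal(sd(s2$z), 1, tolerance = 1e-9)
  # z-scoring idempotence
  expect_equal(as.numeric(scale(s2$z)), s2$z, tolerance = 1e-9)

  expect_error(dff(rec2, fitted405 = c(fitted[-1], -1)), "sample 500")
})

test_that("dF/F is invariant to a common gain on both channels", {
  withr::with_seed(8, {
    x <- 80 + cumsum(rnorm(3000, 0, 0.05))
    y <- 1.2 * x + 5 + rnorm(3000, 0, 0.2)
  })
  s1 <- dff(make_recording(y, x))
  s2 <- dff(make_recording(10 * y, 10 * x))
  expect_equal(s1$dff, s2$dff, tolerance = 1e-9)
})

test_that("compartment AUC reproduces rectangle, triangle and brute force", {
  rate <- 100
  n <- 3001
  s <- make_dff_series(rnorm(n), rate)
  s$z <- rep(1, n)
  mask <- rep(FALSE, n); mask[501:1501] <- TRUE # 10 s segment
  out <- compartment_auc(s, list(zone = mask))
  expect_equal(out$auc, 10, tolerance = 1e-9)
  expect_equal(out$auc_per_s, 1, tolerance = 1e-9)

  s$z <- seq(0, 3, length.out = n)
  mask2 <- rep(FALSE, n); mask2[1:1001] <- TRUE # ramp 0 -> 1 over 10 s
  out2 <- compartment_auc(s, list(zone = mask2))
  expect_equal(out2$auc, 5, tolerance = 1e-9)

  withr::with_seed(3, {
    z <- rnorm(n)
    m <- runif(n) < 0.4
  })
  s$z <- z
  got <- compartment_auc(s, list(zone = m))
  # brute-force oracle: explicit loop over contiguous segments
  auc <- 0
  i <- 1
  while (i <= n) {
    if (m[i]) {
      j <- i
      while (j < n && m[j + 1]) j <- j + 1
      if (j > i) {
        for (k in i:(j - 1)) {
          auc <- auc + (z[k] + z[k + 1]) / 2 * (s$time_s[k + 1] - s$time_s[k])
        }
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  expect_equal(got$auc, auc, tolerance = 1e-9)

  # additivity: zone AUC equals the sum over its visits
  r <- rle(m); ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  visit_sum <- sum(vapply(which(r$values), function(k) {
    mm <- rep(FALSE, n); mm[starts[k]:ends[k]] <- TRUE
    compartment_auc(s, list(v = mm))$auc
  }, numeric(1)))
  expect_equal(got$auc, visit_sum, tolerance = 1e-9)

  empty <- compartment_auc(s, list(zone = rep(FALSE, n)))
  expect_true(empty$zero_duration)
  expect_equal(empty$auc, 0)
})

test_that("MAD threshold has Gaussian 95% coverage and degenerates safely", {
  expect_equal(detect_events(make_dff_series(rep(1, 1000)))$n, 0L)
  expect_true(detect_events(make_dff_series(rep(1, 1000)))$degenerate)

  withr::with_seed(11, x <- rnorm(1e6))
  thr <- event_threshold(x)
  frac_above <- mean(x > thr$threshold)
  expect_lt(abs(frac_above - 0.025), 0.003)
})

test_that("recovery of injected transients is non-decreasing in amplitude", {
  # the raw event count is dominated by noise crossings at the ~1.96-sigma
  # threshold; the meaningful monotonicity is in recovered true transients
  tr <- gen_trajectory(arena_oft(), c(center = 0.2), 120, seed = 2)
  peak_lag <- circuitphys:::kernel_peak(1, 0.18, 1.4)$t
  matched <- vapply(c(1, 4, 12), function(a) {
    rec <- gen_photometry(tr, amp_mean = a, rate_zone = NULL, seed = 6)
    ev <- detect_events(dff(rec))
    sum(vapply(rec$true_events, function(t0) {
      any(abs(ev$times_s - (t0 + peak_lag)) < 1)
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(matched) >= 0))
  expect_gt(matched[3], 0)
})

test_that("peri-event epochs honor the baseline offset and epoch cap", {
  rate <- 381
  withr::with_seed(4, x <- rnorm(40 * rate))
  s <- make_dff_series(x, rate)
  onsets <- data.frame(time_s = seq(6, 34, by = 4), mouse = "m1",
                       label = "entry") # 8 candidate onsets
  pe <- peri_event(s, onsets)
  expect_equal(nrow(pe$epochs), 5L) # cap at five per mouse per label
  bl <- pe$time_rel >= -5 & pe$time_rel <= -4
  expect_true(all(abs(rowMeans(pe$epochs[, bl])) < 1e-9))
  expect_lt(abs(summary_bin(pe)), 0.5) # white noise: null summary

  # onsets too close to the record edge are skipped
  expect_message(
    pe2 <- peri_event(s, data.frame(time_s = c(2, 20), mouse = "m", label = "x")),
    "skipped")
  expect_equal(nrow(pe2$epochs), 1L)
})

test_that("a deterministic step matches the hand-computed window transform", {
  rate <- 381
  n <- 20 * rate
  h <- 0.3
  x <- rep(0, n)
  t0 <- 10
  i0 <- floor(t0 * rate + 0.5) + 1
  x[i0:n] <- h
  s <- make_dff_series(x, rate)
  pe <- peri_event(s, t0)
  # oracle: z-transform of the extracted window, then baseline offset
  off <- seq(round(-5 * rate), round(5 * rate))
  w <- x[i0 + off]
  zw <- (w - mean(w)) / sd(w)
  zw <- zw - mean(zw[off / rate >= -5 & off / rate <= -4])
  expect_equal(as.numeric(pe$epochs[1, ]), zw, tolerance = 1e-12)
  post <- pe$time_rel > 0.01
  expect_equal(unique(round(pe$epochs[1, post], 9)),
               round(zw[length(zw)], 9))
})

test_that("sliding slope recovers linear, constant and quadratic derivatives", {
  rate <- 381
  t <- seq(-5, 5, by = 1 / rate)
  expect_true(all(abs(sliding_slope(3 * t - 1, time_s = t) - 3) < 1e-9))
  expect_true(all(abs(sliding_slope(rep(2, length(t)), time_s = t)) < 1e-12))
  sl <- sliding_slope(t^2, time_s = t)
  interior <- seq_along(t) > rate & seq_along(t) < length(t) - rate
  expect_lt(max(abs(sl[interior] - 2 * t[interior])), 1e-6)
  expect_error(sliding_slope(c(1, 2), time_s = c(0, 0.1)), "shorter")
})

test_that("summary bin averages the centered second and respects symmetry", {
  rate <- 381
  t <- seq(-5, 5, by = 1 / rate)
  expect_equal(summary_bin(rep(1.7, length(t)), time_s = t), 1.7)
  expect_equal(summary_bin(t, time_s = t), 0, tolerance = 1e-9)
  expect_equal(summary_bin(sin(t), time_s = t), 0, tolerance = 1e-9)
})

test_that("the control channel yields null peri-event summaries", {
  tr <- gen_trajectory(arena_epm(), c(open = 0.3, closed = 0.5, center = 0.2),
                       120, seed = 14)
  rec <- gen_photometry(tr, seed = 15)
  # run the pipeline on the isosbestic channel: the 405 nm signal becomes
  # the analyzed channel, referenced to its own fitted slow trend
  ctl <- rec
  ctl$f490 <- rec$f405
  trend <- stats::fitted(stats::lm(rec$f405 ~ rec$time_s))
  s <- dff(ctl, fitted405 = trend)
  onsets <- rec$sync_events$time_s
  onsets <- onsets[onsets > 5.5 & onsets < 114]
  if (length(onsets) >= 2) {
    pe <- peri_event(s, onsets)
    expect_lt(abs(summary_bin(pe)), 0.8)
  }
  succeed()
})
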