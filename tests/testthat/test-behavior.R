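# Behavioral scoring: occupancy, entries, distance, preference indices,
# phenotype classification.

test_that("occupancy of a single-zone stay credits full time and one entry", {
  arena <- arena_oft()
  n <- 300 * 30
  traj <- make_trajectory(rep(22, n), rep(22, n), arena) # center of the box
  occ <- zone_occupancy(traj)
  z <- occ$zones
  expect_equal(z$time_s[z$zone == "center"], 300)
  expect_equal(z$entries[z$zone == "center"], 1)
  expect_equal(z$time_s[z$zone == "periphery"], 0)
  expect_equal(z$entries[z$zone == "periphery"], 0)
})

test_that("distance of a square path traversed once is its perimeter", {
  arena <- arena_oft()
  side <- seq(0, 10, by = 0.5)
  x <- 10 + c(side, rep(10, length(side)), rev(side), rep(0, length(side)))
  y <- 10 + c(rep(0, length(side)), side, rep(10, length(side)), rev(side))
  # drop duplicated corner points so each edge is walked exactly once
  keep <- c(TRUE, sqrt(diff(x)^2 + diff(y)^2) > 0)
  traj <- make_trajectory(x[keep], y[keep], arena)
  expect_equal(zone_occupancy(traj)$distance_cm, 40, tolerance = 1e-12)
})

test_that("entry counting matches a brute-force per-sample scan with hysteresis", {
  arena <- arena_oft()
  hz <- 30
  # 4 boundary crossings into the center zone, dwells well above min_dwell
  seg <- function(xc, k) rep(xc, k)
  x <- c(seg(5, 60), seg(22, 45), seg(5, 30), seg(22, 90), seg(5, 15))
  y <- rep(22, length(x))
  traj <- make_trajectory(x, y, arena, hz)
  occ <- zone_occupancy(traj, min_dwell_s = 0.2)

  # independent oracle: per-sample membership scan + run-length entry count
  inside <- x >= 17 & x <= 27 & y >= 17 & y <= 27
  r <- rle(inside)
  oracle_entries <- sum(r$values & r$lengths / hz >= 0.2)
  oracle_time <- sum(inside) / hz
  z <- occ$zones
  expect_equal(z$entries[z$zone == "center"], oracle_entries)
  expect_equal(oracle_entries, 2L)
  expect_equal(z$time_s[z$zone == "center"], oracle_time)
})

test_that("occupancy is exactly additive over an arena partition", {
  tr <- gen_trajectory(arena_epm(), c(open = 0.3, closed = 0.5, center = 0.2),
                       120, seed = 5)
  occ <- zone_occupancy(tr)
  expect_equal(sum(occ$zones$time_s), occ$duration_s, tolerance = 1e-12)
})

test_that("SI ratio follows the published formula and is scale invariant", {
  expect_equal(si_ratio(60, 60), 100)
  expect_equal(si_ratio(30, 60), 50)
  expect_equal(si_ratio(0, 60), 0)
  for (c in c(0.1, 2, 17)) {
    expect_equal(si_ratio(30 * c, 60 * c), si_ratio(30, 60))
  }
  expect_error(si_ratio(10, 0), "undefined")
})

test_that("classification is a step function of SI ratio with boundary at 100", {
  expect_equal(classify_mouse(130, TRUE), "A")
  expect_equal(classify_mouse(60, TRUE), "AD")
  expect_equal(classify_mouse(100, TRUE), "A") # boundary inclusive
  expect_equal(classify_mouse(99.999, TRUE), "AD")
  expect_equal(classify_mouse(60, FALSE), "CTL")
  expect_equal(classify_mouse(130, FALSE), "CTL")
})

test_that("consumption and sniffing preferences follow their formulas", {
  expect_equal(sucrose_preference(5, 5), 50)
  expect_equal(sucrose_preference(9, 1), 90)
  expect_equal(sucrose_preference(0, 4), 0)
  expect_error(sucrose_preference(0, 0), "zero")
  expect_equal(fust_preference(40, 40), 1)
  expect_equal(fust_preference(80, 40), 2)
  expect_equal(fust_preference(0, 40), 0)
  expect_error(fust_preference(10, 0), "undefined")
})
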