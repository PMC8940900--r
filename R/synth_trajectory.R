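# Synthetic video-tracking trajectories: a zone-biased random walk that hits
# prescribed zone-occupancy targets via a deficit-based dwell scheduler.

new_trajectory <- function(time_s, x_cm, y_cm, arena, video_hz) {
  structure(list(time_s = time_s, x_cm = x_cm, y_cm = y_cm,
                 arena = arena, video_hz = video_hz),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s arena, %d samples @ %g Hz (%.1f s)\n",
              x$arena$name, length(x$time_s), x$video_hz,
              length(x$time_s) / x$video_hz))
  invisible(x)
}

#' Generate an arena-confined trajectory with target zone occupancies
#'
#' Simulates a mouse as a reflected random walk confined to one arena zone at
#' a time. Dwell segments are scheduled greedily against the running deficit
#' between target and realized occupancy, so realized zone fractions converge
#' to the targets as duration grows; transitions between zones travel through
#' the arena center at a fixed transit speed, keeping the path continuous and
#' (for plus-shaped arenas) on the maze. Entry/exit realism is not modeled.
#'
#' @param arena an `arena_spec`.
#' @param occupancy_targets named numeric vector of target zone fractions,
#'   summing to at most 1. Zones absent from the targets share the remainder
#'   equally; if every zone is targeted, the remainder is redistributed
#'   proportionally.
#' @param duration_s trial duration (s), > 0.
#' @param video_hz tracking frame rate (default 30 Hz).
#' @param seed RNG seed.
#' @param step_sd_cm within-dwell per-frame step standard deviation.
#' @param step_max_cm hard cap on per-frame displacement.
#' @param transit_speed_cm_s speed of between-zone transits.
#' @param dwell_range_s min/max dwell-segment duration (s).
#' @return a `trajectory` with exactly `round(duration_s * video_hz)` samples.
#' @export
gen_trajectory <- function(arena, occupancy_targets, duration_s,
                           video_hz = 30, seed = 1,
                           step_sd_cm = 0.25, step_max_cm = 2,
                           transit_speed_cm_s = 25,
                           dwell_range_s = c(2, 10)) {
  stopifnot(inherits(arena, "arena_spec"), duration_s > 0, video_hz > 0)
  zn <- names(arena$zones)
  if (length(occupancy_targets)) {
    if (is.null(names(occupancy_targets)) || any(!nzchar(names(occupancy_targets))))
      stop("occupancy_targets must be named")
    bad <- setdiff(names(occupancy_targets), zn)
    if (length(bad)) stop(sprintf("unknown zone(s): %s", paste(bad, collapse = ", ")))
    if (any(occupancy_targets < 0) || sum(occupancy_targets) > 1 + 1e-9)
      stop("occupancy fractions must be non-negative and sum to <= 1")
  }
  targets <- stats::setNames(rep(0, length(zn)), zn)
  targets[names(occupancy_targets)] <- occupancy_targets
  rem <- 1 - sum(targets)
  untargeted <- setdiff(zn, names(occupancy_targets))
  if (rem > 1e-9) {
    if (length(untargeted)) {
      targets[untargeted] <- rem / length(untargeted)
    } else {
      targets <- targets / sum(targets)
    }
  }

  n <- round(duration_s * video_hz)
  dt <- 1 / video_hz
  ctr <- c(mean(arena$extents[1:2]), mean(arena$extents[3:4]))

  with_local_seed(seed, {
    realized <- stats::setNames(numeric(length(zn)), zn)
    xs <- numeric(n); ys <- numeric(n)
    filled <- 0L
    pos <- NULL

    rand_point <- function(r, margin = 0.15) {
      mx <- min(margin * (r$x1 - r$x0), 1); my <- min(margin * (r$y1 - r$y0), 1)
      c(stats::runif(1, r$x0 + mx, r$x1 - mx), stats::runif(1, r$y0 + my, r$y1 - my))
    }
    credit <- function(x, y) {
      z <- assign_zone(x, y, arena)
      tab <- tabulate(z, nbins = length(zn))
      realized <<- realized + tab
    }
    append_seg <- function(x, y) {
      k <- min(length(x), n - filled)
      if (k <= 0) return(invisible(FALSE))
      xs[filled + seq_len(k)] <<- x[seq_len(k)]
      ys[filled + seq_len(k)] <<- y[seq_len(k)]
      credit(x[seq_len(k)], y[seq_len(k)])
      filled <<- filled + k
      invisible(filled < n)
    }

    while (filled < n) {
      deficit <- targets * n - realized
      zi <- which.max(deficit + stats::runif(length(zn), 0, 0.5))
      zone <- arena$zones[[zi]]
      if (!is.null(pos) && point_in_zone(pos[1], pos[2], zone)) {
        # already inside the scheduled zone: dwell in the containing rectangle
        ri <- which(vapply(seq_len(nrow(zone)), function(i)
          point_in_zone(pos[1], pos[2], zone[i, ]), logical(1)))[1]
        r <- zone[ri, ]
        dest <- pos
      } else {
        areas <- (zone$x1 - zone$x0 + 1e-9) * (zone$y1 - zone$y0 + 1e-9)
        ri <- sample.int(nrow(zone), 1, prob = areas)
        r <- zone[ri, ]
        dest <- rand_point(r)
      }

      if (is.null(pos)) {
        pos <- dest
        append_seg(pos[1], pos[2])
      } else if (!point_in_zone(pos[1], pos[2], r)) {
        # transit: current -> arena center -> destination, constant speed
        d <- sqrt(sum((pos - ctr)^2)) + sqrt(sum((ctr - dest)^2))
        m <- max(1L, ceiling(d / (transit_speed_cm_s * dt)))
        f <- seq_len(m) / m
        brk <- sqrt(sum((pos - ctr)^2)) / max(d, 1e-12)
        tx <- ifelse(f <= brk,
                     pos[1] + (ctr[1] - pos[1]) * f / max(brk, 1e-12),
                     ctr[1] + (dest[1] - ctr[1]) * (f - brk) / max(1 - brk, 1e-12))
        ty <- ifelse(f <= brk,
                     pos[2] + (ctr[2] - pos[2]) * f / max(brk, 1e-12),
                     ctr[2] + (dest[2] - ctr[2]) * (f - brk) / max(1 - brk, 1e-12))
        if (!append_seg(tx, ty)) break
        pos <- dest
      } else {
        dest <- pos # already inside target rect: dwell in place
      }

      dwell_s <- stats::runif(1, dwell_range_s[1], dwell_range_s[2])
      need <- deficit[zi] / video_hz
      if (is.finite(need) && need > dwell_range_s[2]) dwell_s <- dwell_range_s[2]
      k <- max(2L, round(dwell_s * video_hz))
      dx <- pmax(-step_max_cm, pmin(step_max_cm, stats::rnorm(k, 0, step_sd_cm)))
      dy <- pmax(-step_max_cm, pmin(step_max_cm, stats::rnorm(k, 0, step_sd_cm)))
      wx <- reflect_fold(dest[1] + cumsum(dx), r$x0, r$x1)
      wy <- reflect_fold(dest[2] + cumsum(dy), r$y0, r$y1)
      keep_going <- append_seg(wx, wy)
      pos <- c(xs[filled], ys[filled])
      if (!keep_going) break
    }

    new_trajectory((seq_len(n) - 1) / video_hz, xs, ys, arena, video_hz)
  })
}
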