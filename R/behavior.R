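# Behavioral scoring: zone occupancy, social-interaction ratio, phenotype
# classification, consumption/preference indices.

#' Zone occupancy, entries, distance and velocity from a trajectory
#'
#' Zone membership uses the track's center point with closed rectangle
#' boundaries; when zones share a boundary, a sample is assigned to the first
#' matching zone in the arena's zone order, so a partition of the arena
#' yields exactly additive zone times. Time in zone is the number of member
#' samples times the sampling interval. An entry is a transition from outside
#' to inside that persists at least `min_dwell_s` (hysteresis against boundary
#' jitter); initial placement inside a zone counts as one entry.
#'
#' @param traj a `trajectory`.
#' @param min_dwell_s minimum dwell for an entry to count (default 0.2 s).
#' @return object of class `zone_occupancy`: data frame `zones` (zone,
#'   time_s, entries), plus `distance_cm`, `mean_velocity_cm_s`,
#'   `duration_s`, `zone_index` (per-sample zone assignment).
#' @export
zone_occupancy <- function(traj, min_dwell_s = 0.2) {
  stopifnot(inherits(traj, "trajectory"))
  n <- length(traj$time_s)
  if (n == 0L) stop("empty trajectory")
  dt <- 1 / traj$video_hz
  zn <- names(traj$arena$zones)
  zi <- assign_zone(traj$x_cm, traj$y_cm, traj$arena)

  time_s <- tabulate(zi, nbins = length(zn)) * dt
  entries <- integer(length(zn))
  r <- rle(ifelse(is.na(zi), 0L, zi))
  long_enough <- r$lengths * dt >= min_dwell_s - 1e-9
  for (k in seq_along(zn)) {
    entries[k] <- sum(r$values == k & long_enough)
  }
  dx <- diff(traj$x_cm); dy <- diff(traj$y_cm)
  dist <- sum(sqrt(dx^2 + dy^2))
  dur <- n * dt
  structure(list(
    zones = data.frame(zone = zn, time_s = time_s, entries = entries),
    distance_cm = dist,
    mean_velocity_cm_s = dist / dur,
    duration_s = dur,
    zone_index = zi
  ), class = "zone_occupancy")
}

#' @export
print.zone_occupancy <- function(x, ...) {
  cat(sprintf("<zone_occupancy> %.1f s, %.1f cm travelled\n", x$duration_s,
              x$distance_cm))
  print(x$zones, row.names = FALSE)
  invisible(x)
}

#' Entry times into a zone
#'
#' Onset times of entries (as defined in [zone_occupancy()]) into one zone;
#' used to time-lock photometry epochs to behavior.
#'
#' @inheritParams zone_occupancy
#' @param zone zone name.
#' @return numeric vector of entry times (s).
#' @export
zone_entry_times <- function(traj, zone, min_dwell_s = 0.2) {
  stopifnot(inherits(traj, "trajectory"))
  zn <- names(traj$arena$zones)
  k <- match(zone, zn)
  if (is.na(k)) stop(sprintf("unknown zone '%s'", zone))
  dt <- 1 / traj$video_hz
  zi <- assign_zone(traj$x_cm, traj$y_cm, traj$arena)
  r <- rle(ifelse(is.na(zi), 0L, zi))
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  keep <- r$values == k & r$lengths * dt >= min_dwell_s - 1e-9
  traj$time_s[starts[keep]]
}

#' Social-interaction ratio
#'
#' `SI ratio = 100 * time in interaction zone with target present /
#' time in the same zone with no target`. The no-target time must be
#' positive; a zero no-target time is an undefined ratio and raises an error
#' so the mouse can be flagged rather than given a fabricated value.
#'
#' @param time_target_s seconds in the interaction zone, target present.
#' @param time_notarget_s seconds in the interaction zone, target absent.
#' @return the ratio, in percent.
#' @examples
#' si_ratio(60, 60) # 100, the susceptible/resilient boundary
#' @export
si_ratio <- function(time_target_s, time_notarget_s) {
  stopifnot(time_target_s >= 0)
  if (!isTRUE(time_notarget_s > 0)) {
    stop("undefined SI ratio: no-target zone time is zero")
  }
  100 * time_target_s / time_notarget_s
}

#' Classify a mouse as CTL / A (resilient) / AD (susceptible)
#'
#' Stress-naive mice are controls (`CTL`). Defeated mice with SI ratio >= 100
#' are resilient to depressive-like behavior but anxious (`A`); defeated mice
#' with SI ratio < 100 are susceptible, anxious and depressed (`AD`). The
#' boundary is inclusive on the resilient side.
#'
#' @param si_ratio SI ratio in percent (finite, >= 0).
#' @param stressed logical, underwent chronic social defeat.
#' @return one of `"CTL"`, `"A"`, `"AD"`.
#' @export
classify_mouse <- function(si_ratio, stressed) {
  stopifnot(is.finite(si_ratio), si_ratio >= 0, is.logical(stressed))
  ifelse(!stressed, "CTL", ifelse(si_ratio >= 100, "A", "AD"))
}

#' Sucrose preference
#'
#' `SP = 100 * sucrose consumed / (sucrose + water consumed)`.
#'
#' @param sucrose_consumed_g,water_consumed_g grams consumed (total > 0).
#' @return preference in percent, in \[0, 100\].
#' @export
sucrose_preference <- function(sucrose_consumed_g, water_consumed_g) {
  stopifnot(sucrose_consumed_g >= 0, water_consumed_g >= 0)
  tot <- sucrose_consumed_g + water_consumed_g
  if (!isTRUE(tot > 0)) stop("total consumption is zero")
  100 * sucrose_consumed_g / tot
}

#' Female-urine preference (FUST)
#'
#' `preference = time in urine zone / time in water zone` (unitless).
#'
#' @param time_urine_zone_s,time_water_zone_s zone times (water > 0).
#' @return unitless ratio >= 0.
#' @export
fust_preference <- function(time_urine_zone_s, time_water_zone_s) {
  stopifnot(time_urine_zone_s >= 0)
  if (!isTRUE(time_water_zone_s > 0)) {
    stop("undefined urine preference: water-zone time is zero")
  }
  time_urine_zone_s / time_water_zone_s
}
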