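# Arena geometry: named zones as unions of axis-aligned rectangles (cm).

new_arena <- function(name, extents, zones) {
  for (zn in names(zones)) {
    z <- zones[[zn]]
    stopifnot(is.data.frame(z), all(c("x0", "x1", "y0", "y1") %in% names(z)))
    if (any(z$x0 < extents[1] - 1e-9 | z$x1 > extents[2] + 1e-9 |
            z$y0 < extents[3] - 1e-9 | z$y1 > extents[4] + 1e-9)) {
      stop(sprintf("zone '%s' extends outside arena extents", zn))
    }
  }
  if (anyDuplicated(names(zones))) stop("zone names must be unique")
  structure(list(name = name, extents = extents, zones = zones),
            class = "arena_spec")
}

#' @export
print.arena_spec <- function(x, ...) {
  cat(sprintf("<arena_spec> %s  [%.0f x %.0f cm], zones: %s\n", x$name,
              diff(x$extents[1:2]), diff(x$extents[3:4]),
              paste(names(x$zones), collapse = ", ")))
  invisible(x)
}

rect <- function(x0, x1, y0, y1) data.frame(x0 = x0, x1 = x1, y0 = y0, y1 = y1)

#' Elevated plus maze arena
#'
#' Plus-shaped maze built from 70-cm arms of width 5 cm crossing at a central
#' square, with `open` (two arms), `closed` (two arms) and `center` zones.
#' The open arms run vertically, the closed arms horizontally; coordinates are
#' centered on the maze center.
#'
#' @param arm_length_cm full end-to-end maze length (default 70).
#' @param arm_width_cm arm width (default 5).
#' @return an `arena_spec`.
#' @export
arena_epm <- function(arm_length_cm = 70, arm_width_cm = 5) {
  h <- arm_length_cm / 2
  w <- arm_width_cm / 2
  new_arena(
    "EPM", c(-h, h, -h, h),
    list(
      center = rect(-w, w, -w, w),
      open = rect(c(-w, -w), c(w, w), c(w, -h), c(h, -w)),
      closed = rect(c(w, -h), c(h, -w), c(-w, -w), c(w, w))
    )
  )
}

#' Open field arena
#'
#' A 44 x 44 cm box with a central 10 x 10 cm `center` zone; the remainder is
#' the `periphery` zone (a frame of four rectangles partitioning the box).
#'
#' @param side_cm box side (default 44).
#' @param center_cm center-zone side (default 10).
#' @return an `arena_spec`.
#' @export
arena_oft <- function(side_cm = 44, center_cm = 10) {
  lo <- (side_cm - center_cm) / 2
  hi <- lo + center_cm
  new_arena(
    "OFT", c(0, side_cm, 0, side_cm),
    list(
      center = rect(lo, hi, lo, hi),
      periphery = rect(c(0, hi, lo, lo), c(lo, side_cm, hi, hi),
                       c(0, 0, 0, hi), c(side_cm, side_cm, lo, side_cm))
    )
  )
}

#' Social-interaction arena
#'
#' An open field with a wire-mesh cage against one wall and an `interaction`
#' zone abutting it. The interaction-zone dimensions are not standardized, so
#' they are configuration knobs; the remainder of the box is the `other` zone.
#'
#' @param side_cm box side (default 44).
#' @param zone_w_cm interaction-zone width along the cage wall (default 14).
#' @param zone_d_cm interaction-zone depth into the arena (default 9).
#' @return an `arena_spec`.
#' @export
arena_si <- function(side_cm = 44, zone_w_cm = 14, zone_d_cm = 9) {
  x0 <- (side_cm - zone_w_cm) / 2
  x1 <- x0 + zone_w_cm
  y0 <- side_cm - zone_d_cm
  new_arena(
    "SI", c(0, side_cm, 0, side_cm),
    list(
      interaction = rect(x0, x1, y0, side_cm),
      other = rect(c(0, 0, x1), c(side_cm, x0, side_cm),
                   c(0, y0, y0), c(y0, side_cm, side_cm))
    )
  )
}

#' Three-chamber arena for the female urine sniffing test
#'
#' Three side-by-side chambers (44 x 17 cm each); 3 x 5 cm sniffing zones sit
#' at the center of the two side chambers (`urine_zone`, `water_zone`).
#'
#' @param chamber_l_cm chamber length (default 44, the y extent).
#' @param chamber_w_cm chamber width (default 17, the x extent).
#' @return an `arena_spec`.
#' @export
arena_three_chamber <- function(chamber_l_cm = 44, chamber_w_cm = 17) {
  W <- 3 * chamber_w_cm
  zc <- function(cx, cy) rect(cx - 1.5, cx + 1.5, cy - 2.5, cy + 2.5)
  cy <- chamber_l_cm / 2
  new_arena(
    "ThreeChamber", c(0, W, 0, chamber_l_cm),
    list(
      urine_zone = zc(chamber_w_cm / 2, cy),
      water_zone = zc(W - chamber_w_cm / 2, cy),
      left = rect(0, chamber_w_cm, 0, chamber_l_cm),
      middle = rect(chamber_w_cm, 2 * chamber_w_cm, 0, chamber_l_cm),
      right = rect(2 * chamber_w_cm, W, 0, chamber_l_cm)
    )
  )
}

# TRUE where (x, y) falls in any rectangle of the zone (closed boundaries)
point_in_zone <- function(x, y, zone_rects) {
  inside <- rep(FALSE, length(x))
  for (i in seq_len(nrow(zone_rects))) {
    r <- zone_rects[i, ]
    inside <- inside | (x >= r$x0 & x <= r$x1 & y >= r$y0 & y <= r$y1)
  }
  inside
}

# assign each sample to the first matching zone (ties resolved by zone order);
# returns a factor-like integer index into names(arena$zones), NA if unzoned
assign_zone <- function(x, y, arena) {
  out <- rep(NA_integer_, length(x))
  for (k in seq_along(arena$zones)) {
    hit <- is.na(out) & point_in_zone(x, y, arena$zones[[k]])
    out[hit] <- k
  }
  out
}
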