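# Angle convention: 12:00 on the ISUOG clock face is 0 degrees (occiput
# anterior, maternal midline); angles increase toward the maternal left,
# so 3:00 = 90 deg (LOT side) and 9:00 = 270 deg (ROT side).

.sector_levels  <- c("OA", "OP", "OT_LEFT", "OT_RIGHT")
.stratum_levels <- c("CLASSIC", "NEAR", "TRANSITIONAL", "OTHER")
.side_levels    <- c("LEFT", "RIGHT", "MIDLINE")

#' Convert a clock-face occiput position to a rotation angle
#'
#' The ISUOG convention describes fetal occiput position on a 12-hour clock
#' face (12:00 = occiput anterior, maternal midline). The dial maps linearly
#' to a rotation angle at 30 degrees per hour, so 3:30 is 105 degrees and
#' 8:30 is 255 degrees.
#'
#' @param hour Integer vector in 1..12.
#' @param minute Integer vector in 0..59 (clinical usage is 0/30).
#' @return Numeric vector of angles in degrees, in `[0, 360)`.
#' @examples
#' clock_to_degrees(3, 30)   # 105
#' clock_to_degrees(12, 0)   # 0
#' @export
clock_to_degrees <- function(hour, minute = 0) {
  if (length(minute) == 1L) minute <- rep(minute, length(hour))
  stopifnot(length(hour) == length(minute))
  bad <- !is.finite(hour) | hour != as.integer(hour) | hour < 1 | hour > 12
  if (any(bad)) stop("hour must be an integer in 1..12")
  bad <- !is.finite(minute) | minute != as.integer(minute) | minute < 0 | minute > 59
  if (any(bad)) stop("minute must be an integer in 0..59")
  (((hour %% 12) + minute / 60) * 30) %% 360
}

#' Convert a rotation angle back to the nearest clock-face position
#'
#' Inverse of [clock_to_degrees()] at minute resolution (one minute on the
#' dial is 0.5 degrees).
#'
#' @param theta Numeric vector of angles in degrees, `[0, 360)`.
#' @param as_string If `TRUE`, return `"H:MM"` strings instead of a data frame.
#' @return A data frame with columns `hour`, `minute`, or a character vector.
#' @export
degrees_to_clock <- function(theta, as_string = FALSE) {
  theta <- normalize_angle(theta)
  total_min <- round(theta * 2)      # minutes on the dial; 0.5 deg per minute
  total_min <- total_min %% 720
  hour <- total_min %/% 60
  minute <- total_min %% 60
  hour[hour == 0] <- 12L
  if (as_string) sprintf("%d:%02d", hour, minute)
  else data.frame(hour = as.integer(hour), minute = as.integer(minute))
}

#' Normalize an angle into `[0, 360)`
#'
#' @param theta Numeric vector of angles in degrees.
#' @return Numeric vector in `[0, 360)`.
#' @export
normalize_angle <- function(theta) {
  if (!all(is.finite(theta))) stop("theta must be finite")
  theta %% 360
}

#' ISUOG sector of a fetal occiput rotation angle
#'
#' Classifies an occiput rotation angle into the four ISUOG clock-face
#' sectors: occiput anterior (9:30-2:30), occiput posterior (3:30-8:30),
#' and the two transverse bands, LOT at 75-105 degrees and ROT at
#' 255-285 degrees. Transverse bands are closed on both ends.
#'
#' @param theta Numeric vector of angles in degrees.
#' @return Factor with levels `OA`, `OP`, `OT_LEFT`, `OT_RIGHT`.
#' @export
isuog_sector <- function(theta) {
  theta <- normalize_angle(theta)
  out <- rep("OA", length(theta))
  out[theta >= 75 & theta <= 105] <- "OT_LEFT"
  out[theta >= 255 & theta <= 285] <- "OT_RIGHT"
  out[theta > 105 & theta < 255] <- "OP"
  factor(out, levels = .sector_levels)
}

#' Canonical midline angle and side
#'
#' Folds a rotation angle onto the canonical `[0, 180]` midline-angle scale:
#' left-sided (LOT-side) angles are kept, right-sided (ROT-side) angles are
#' mirrored (`360 - theta`), so e.g. 284 degrees is the right-sided
#' equivalent of MLA 76. 0 and 180 degrees are midline.
#'
#' @param theta Numeric vector of angles in degrees.
#' @return Data frame with columns `value` (degrees, `[0, 180]`) and `side`
#'   (factor `LEFT`/`RIGHT`/`MIDLINE`).
#' @export
canonical_mla <- function(theta) {
  theta <- normalize_angle(theta)
  value <- pmin(theta, 360 - theta)
  side <- ifelse(theta == 0 | theta == 180, "MIDLINE",
                 ifelse(theta < 180, "LEFT", "RIGHT"))
  data.frame(value = value, side = factor(side, levels = .side_levels))
}

#' Midline-angle stratum of a transverse or near-transverse position
#'
#' Strata on the canonical midline angle `c`: classic transverse for
#' `75 <= c <= 105`, near-transverse for `70 <= c < 75`, transitional for
#' `60 <= c < 70`, and `OTHER` elsewhere (including posterior-side canonical
#' values above 105). Right-sided angles are folded via [canonical_mla()]
#' first, so 286 degrees (canonical 74) is near-transverse.
#'
#' @param theta Numeric vector of angles in degrees.
#' @return Factor with levels `CLASSIC`, `NEAR`, `TRANSITIONAL`, `OTHER`.
#' @export
mla_stratum <- function(theta) {
  cv <- canonical_mla(theta)$value
  out <- rep("OTHER", length(cv))
  out[cv >= 75 & cv <= 105] <- "CLASSIC"
  out[cv >= 70 & cv < 75] <- "NEAR"
  out[cv >= 60 & cv < 70] <- "TRANSITIONAL"
  factor(out, levels = .stratum_levels)
}
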