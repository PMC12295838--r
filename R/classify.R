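#' Color-code a single geometric parameter value
#'
#' Maps a measurement to GREEN (favorable for vaginal delivery), YELLOW
#' (intermediate risk) or RED (high risk for cesarean delivery) according to
#' the parameter's threshold bands. Values exactly on a breakpoint take the
#' riskier color.
#'
#' @param x Numeric vector of measurements.
#' @param bands One per-parameter entry of an [threshold_config()] object.
#' @param parameter Parameter name used in error messages.
#' @return Factor with levels `GREEN`, `YELLOW`, `RED`.
#' @examples
#' th <- default_thresholds()
#' classify_parameter(c(10, 15, 25), th$hsd, "hsd")  # GREEN YELLOW RED
#' @export
classify_parameter <- function(x, bands, parameter = "parameter") {
  if (!all(is.finite(x))) stop(parameter, ": values must be finite")
  d <- bands$domain
  if (any(x < d[1] | x > d[2]))
    stop(parameter, ": value outside configured domain [", d[1], ", ", d[2], "]")
  b <- bands$breakpoints
  colors <- if (length(b) == 2) c("GREEN", "YELLOW", "RED") else c("GREEN", "RED")
  if (bands$higher_is_risk) {
    idx <- vapply(x, function(v) sum(b <= v), 0L) + 1L   # breakpoint -> riskier
  } else {
    colors <- rev(colors)
    idx <- vapply(x, function(v) sum(b < v), 0L) + 1L    # breakpoint -> riskier (lower band)
  }
  factor(colors[idx], levels = .color_levels)
}

#' Assign the AIDA class from a four-parameter color pattern
#'
#' The AIDA class is the count of parameters not coded GREEN: class 0 has all
#' four parameters in the green zone, class 4 has all four in the red or
#' yellow zones, and YELLOW and RED each contribute one. The class therefore
#' depends only on the multiset of colors, not on which parameter carries
#' them.
#'
#' @param mla,aop,spd,ad Character or factor vectors of color codes
#'   (`GREEN`/`YELLOW`/`RED`), one element per case. Alternatively pass a
#'   data frame with columns `aida_mla`, `aida_aop`, `aida_spd`, `aida_ad`
#'   as `mla` and leave the rest missing.
#' @return Integer vector of AIDA classes in 0..4.
#' @examples
#' assign_aida_class("RED", "GREEN", "GREEN", "YELLOW")  # 2
#' @export
assign_aida_class <- function(mla, aop, spd, ad) {
  if (is.data.frame(mla)) {
    df <- mla
    need <- c("aida_mla", "aida_aop", "aida_spd", "aida_ad")
    if (!all(need %in% names(df)))
      stop("data frame input needs columns: ", paste(need, collapse = ", "))
    mla <- df$aida_mla; aop <- df$aida_aop; spd <- df$aida_spd; ad <- df$aida_ad
  }
  m <- cbind(as.character(mla), as.character(aop),
             as.character(spd), as.character(ad))
  if (!all(m %in% .color_levels))
    stop("color codes must be one of: ", paste(.color_levels, collapse = ", "))
  as.integer(rowSums(m != "GREEN"))
}

#' Color pattern and AIDA class from raw geometric measurements
#'
#' Composes [classify_parameter()] over the four parameters and
#' [assign_aida_class()]. The midline angle is folded onto the canonical
#' `[0, 180]` scale before thresholding, so right-sided (ROT) angles are
#' handled transparently.
#'
#' @param profile Data frame (or list) with numeric elements `aop`, `hsd`,
#'   `mla`, `ad`; `mla` in degrees on the `[0, 360)` rotation scale.
#' @param thresholds An [threshold_config()] object;
#'   defaults to [default_thresholds()].
#' @return Data frame with columns `aida_mla`, `aida_aop`, `aida_spd`,
#'   `aida_ad` (factors) and `aida_class` (integer).
#' @export
profile_to_class <- function(profile, thresholds = default_thresholds()) {
  profile <- as.data.frame(profile)
  need <- c("aop", "hsd", "mla", "ad")
  if (!all(need %in% names(profile)))
    stop("profile needs numeric columns: ", paste(need, collapse = ", "))
  mla_canon <- canonical_mla(profile$mla)$value
  out <- data.frame(
    aida_mla = classify_parameter(mla_canon, thresholds$mla, "mla"),
    aida_aop = classify_parameter(profile$aop, thresholds$aop, "aop"),
    aida_spd = classify_parameter(profile$hsd, thresholds$hsd, "hsd"),
    aida_ad  = classify_parameter(profile$ad, thresholds$ad, "ad")
  )
  out$aida_class <- assign_aida_class(out)
  out
}
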