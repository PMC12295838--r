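# Synthetic-cohort generator. Emulates the statistical structure the
# analysis assumes: three transverse strata with configurable weights,
# per-stratum color patterns, AIDA class = count of non-green colors, and a
# class-conditional cesarean probability gradient. Raw measurements are
# drawn from a latent multivariate normal and mapped into the band of the
# assigned color, so colors and raw values can never contradict each other
# under the active thresholds.

.pattern_key <- function(df)
  paste(df$aida_mla, df$aida_aop, df$aida_spd, df$aida_ad, sep = "|")

.stratum_band <- function(stratum)
  switch(stratum,
         CLASSIC = c(75, 105), NEAR = c(70, 75), TRANSITIONAL = c(60, 70),
         stop("no sampling band for stratum ", stratum))

# numeric interval of a color band, clipped to the domain
.color_band <- function(bands, color) {
  b <- bands$breakpoints; d <- bands$domain
  edges <- c(d[1], b, d[2])
  colors <- if (length(b) == 2) c("GREEN", "YELLOW", "RED") else c("GREEN", "RED")
  if (!bands$higher_is_risk) colors <- rev(colors)
  i <- match(color, colors)
  if (is.na(i)) stop("color ", color, " has no band under this configuration")
  c(edges[i], edges[i + 1])
}

#' Configuration of the synthetic-cohort generator
#'
#' Defaults are calibrated to the packaged reference cohort: stratum weights
#' 29/9/28 over classic / near-transverse / transitional (weight 0 for
#' other positions), per-stratum color-pattern frequencies fitted from the
#' fixture, and class-conditional cesarean probabilities equal to the
#' fixture's empirical class rates with the single-case class-0/1 cells
#' smoothed to a monotone gradient (class 4 remains certainty). These
#' smoothed cells are calibration choices, not published data.
#'
#' @param n Cohort size; default 66.
#' @param stratum_weights Named proportions over
#'   `CLASSIC`/`NEAR`/`TRANSITIONAL`/`OTHER`; must sum to 1 with weight 0 on
#'   `OTHER` (no sampling band is defined outside the transverse spectrum).
#' @param color_model Named list: per stratum, a named numeric vector of
#'   pattern frequencies, names `"mla|aop|spd|ad"` color strings.
#' @param cd_prob Numeric vector of cesarean probabilities indexed by AIDA
#'   class 0..4.
#' @param latent_correlation Optional 4x4 symmetric positive-definite
#'   correlation matrix (order mla, aop, hsd, ad) for the latent normal
#'   behind the raw measurements; default identity.
#' @param thresholds Active [threshold_config()]; default
#'   [default_thresholds()].
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n = 66,
                             stratum_weights = NULL,
                             color_model = NULL,
                             cd_prob = c(0.1, 0.5, 0.8, 29 / 32, 1.0),
                             latent_correlation = NULL,
                             thresholds = default_thresholds()) {
  if (is.null(stratum_weights))
    stratum_weights <- c(CLASSIC = 29, NEAR = 9, TRANSITIONAL = 28, OTHER = 0) / 66
  if (is.null(color_model))
    color_model <- fit_synthetic_config(aida_fixture())$color_model
  stopifnot(n >= 1)
  if (abs(sum(stratum_weights) - 1) > 1e-8) stop("stratum weights must sum to 1")
  if (any(stratum_weights < 0)) stop("stratum weights must be non-negative")
  if ("OTHER" %in% names(stratum_weights) && stratum_weights[["OTHER"]] > 0)
    stop("infeasible config: no sampling band for the OTHER stratum")
  if (length(cd_prob) != 5 || any(cd_prob < 0 | cd_prob > 1))
    stop("cd_prob must be 5 probabilities (classes 0..4)")
  if (!is.null(latent_correlation)) {
    lc <- latent_correlation
    if (!isTRUE(all.equal(lc, t(lc))) || any(eigen(lc, TRUE)$values <= 0) ||
        nrow(lc) != 4)
      stop("latent_correlation must be 4x4 symmetric positive-definite")
  }
  for (s in names(color_model)) {
    w <- color_model[[s]]
    if (!length(w) || any(w < 0) || sum(w) <= 0)
      stop("color model for stratum ", s, " must be non-degenerate")
  }
  structure(list(n = n, stratum_weights = stratum_weights,
                 color_model = color_model, cd_prob = cd_prob,
                 latent_correlation = latent_correlation,
                 thresholds = thresholds),
            class = "synthetic_config")
}

#' Fit a synthetic-cohort configuration from an observed cohort
#'
#' Empirical stratum weights, per-stratum color-pattern frequencies and
#' class-conditional cesarean rates become the generator configuration.
#' Classes unobserved in the cohort get rates interpolated linearly between
#' the nearest observed neighbors (ends carried), keeping the default
#' gradient monotone when the observed rates are.
#'
#' @param cohort An `aida_cohort` with colors and outcomes.
#' @param thresholds Active threshold configuration for the generator.
#' @return A `synthetic_config`.
#' @examples
#' cfg <- fit_synthetic_config(aida_fixture())
#' cfg$cd_prob[5]  # class 4: 1 (all cesarean)
#' @export
fit_synthetic_config <- function(cohort, thresholds = default_thresholds()) {
  if (!nrow(cohort)) stop("empty cohort")
  stratum <- mla_stratum(cohort$mla_deg)
  w <- table(stratum) / nrow(cohort)
  color_model <- lapply(levels(stratum)[table(stratum) > 0], function(s) {
    pat <- .pattern_key(as.data.frame(cohort)[stratum == s, , drop = FALSE])
    tab <- table(pat)
    stats::setNames(as.numeric(tab) / sum(tab), names(tab))
  })
  names(color_model) <- levels(stratum)[table(stratum) > 0]
  cls <- .cohort_class(cohort)
  ces <- binary_outcome(cohort) == "CESAREAN"
  rate <- vapply(0:4, function(k)
    if (any(cls == k)) mean(ces[cls == k]) else NA_real_, 0)
  if (all(is.na(rate))) stop("no classes observed")
  rate <- stats::approx(which(!is.na(rate)), rate[!is.na(rate)],
                        xout = 1:5, rule = 2)$y
  synthetic_config(n = nrow(cohort),
                   stratum_weights = stats::setNames(as.numeric(w), names(w)),
                   color_model = color_model, cd_prob = rate,
                   thresholds = thresholds)
}

#' Generate a synthetic labor cohort
#'
#' Samples `n` cases: stratum from the configured weights; canonical midline
#' angle from the latent normal mapped into the intersection of the stratum
#' band and the assigned MLA color band (left/right side with equal
#' probability, right-sided cases emitted as ROT angles `360 - MLA`); color
#' pattern from the per-stratum pattern model; raw measurements from the
#' latent multivariate normal mapped into each assigned color's band, so
#' [profile_to_class()] reproduces the assigned pattern by construction; and
#' the delivery outcome Bernoulli in the class-conditional cesarean
#' probability. Fully reproducible given config and seed.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return An `aida_cohort` (provenance `SYNTHETIC`) with raw measurement
#'   columns `aop`, `hsd`, `ad` and a `gen_stratum` column recording the
#'   generating stratum.
#' @export
generate_cohort <- function(config, seed = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n
  th <- config$thresholds
  set.seed(seed)
  w <- config$stratum_weights[names(config$stratum_weights) != "OTHER"]
  w <- w[w > 0]
  if (!all(names(w) %in% names(config$color_model)))
    stop("infeasible config: stratum with positive weight but no color model")
  stratum <- sample(names(w), n, replace = TRUE, prob = w)
  pattern <- vapply(stratum, function(s) {
    cm <- config$color_model[[s]]
    sample(names(cm), 1, prob = cm)
  }, "")
  colors <- do.call(rbind, strsplit(pattern, "|", fixed = TRUE))
  colnames(colors) <- c("aida_mla", "aida_aop", "aida_spd", "aida_ad")
  sigma <- if (is.null(config$latent_correlation)) diag(4)
           else config$latent_correlation
  z <- MASS::mvrnorm(n, mu = rep(0, 4), Sigma = sigma)
  if (n == 1) z <- matrix(z, nrow = 1)
  u <- stats::pnorm(z)   # columns: mla, aop, hsd, ad
  sample_band <- function(ui, lo, hi) lo + ui * (hi - lo)
  mla_canon <- aop <- hsd <- ad <- numeric(n)
  for (i in seq_len(n)) {
    sb <- .stratum_band(stratum[i])
    cb <- .color_band(th$mla, colors[i, "aida_mla"])
    lo <- max(sb[1], cb[1]); hi <- min(sb[2], cb[2])
    if (lo >= hi)
      stop("infeasible config: MLA color ", colors[i, "aida_mla"],
           " has no support inside the ", stratum[i], " stratum band")
    mla_canon[i] <- sample_band(u[i, 1], lo, hi)
    b <- .color_band(th$aop, colors[i, "aida_aop"])
    aop[i] <- sample_band(u[i, 2], b[1], b[2])
    b <- .color_band(th$hsd, colors[i, "aida_spd"])
    hsd[i] <- sample_band(u[i, 3], b[1], b[2])
    b <- .color_band(th$ad, colors[i, "aida_ad"])
    ad[i] <- sample_band(u[i, 4], b[1], b[2])
  }
  right <- stats::runif(n) < 0.5
  mla_deg <- ifelse(right, 360 - mla_canon, mla_canon)
  cls <- assign_aida_class(colors[, 1], colors[, 2], colors[, 3], colors[, 4])
  outcome <- ifelse(stats::runif(n) < config$cd_prob[cls + 1], "ICD", "NOICD")
  df <- data.frame(patient_id = sprintf("S%04d", seq_len(n)),
                   mla_deg = mla_deg, outcome = outcome,
                   aida_mla = colors[, 1], aida_aop = colors[, 2],
                   aida_spd = colors[, 3], aida_ad = colors[, 4],
                   aida_class = cls, aop = aop, hsd = hsd, ad = ad,
                   gen_stratum = stratum)
  as_cohort(df, provenance = "SYNTHETIC")
}
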