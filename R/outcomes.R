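# Descriptive results engine: stratified cesarean rates, class-level risk,
# class x stratum x outcome cross-tabulation, parameter color distributions.

.cohort_class <- function(cohort) {
  if ("aida_class" %in% names(cohort)) as.integer(cohort$aida_class)
  else assign_aida_class(as.data.frame(cohort))
}

#' Cesarean delivery rate by midline-angle stratum
#'
#' Groups the cohort by [mla_stratum()] and reports, per stratum, the number
#' of cases, cesarean count, exact rate, and the percentage rounded to one
#' decimal (the field's printing convention). An empty stratum has an
#' undefined (`NA`) rate, never 0. Strata are ordered by the observed risk
#' gradient: near-transverse, classic, transitional, then other.
#'
#' @param cohort An `aida_cohort`.
#' @param conf If non-`NULL`, a confidence level for Wilson score intervals
#'   on each rate.
#' @return Data frame with columns `stratum`, `n`, `cesarean`, `rate`,
#'   `pct` (and `lower`, `upper` when `conf` is given).
#' @examples
#' stratified_cd_rates(aida_fixture())
#' @export
stratified_cd_rates <- function(cohort, conf = NULL) {
  stratum <- mla_stratum(cohort$mla_deg)
  ces <- binary_outcome(cohort) == "CESAREAN"
  order <- c("NEAR", "CLASSIC", "TRANSITIONAL", "OTHER")
  out <- do.call(rbind, lapply(order, function(s) {
    idx <- stratum == s
    n <- sum(idx); k <- sum(ces[idx])
    data.frame(stratum = s, n = n, cesarean = k,
               rate = if (n > 0) k / n else NA_real_)
  }))
  out$pct <- round(out$rate * 100, 1)
  if (!is.null(conf)) {
    ci <- t(vapply(seq_len(nrow(out)), function(i) {
      if (out$n[i] == 0) c(NA_real_, NA_real_)
      else {
        w <- wilson_interval(out$cesarean[i], out$n[i], conf)
        c(w$lower, w$upper)
      }
    }, numeric(2)))
    out$lower <- ci[, 1]; out$upper <- ci[, 2]
  }
  out
}

#' Cesarean delivery rate by AIDA class
#'
#' @param cohort An `aida_cohort`. The class column is used when present,
#'   otherwise classes are computed from the colors by the counting rule.
#' @param conf Optional confidence level for Wilson intervals.
#' @return Data frame with one row per class 0..4: `aida_class`, `n`,
#'   `cesarean`, `rate`, `pct`.
#' @examples
#' class_cd_rates(aida_fixture())  # class 3: 29/32, class 4: 21/21
#' @export
class_cd_rates <- function(cohort, conf = NULL) {
  cls <- .cohort_class(cohort)
  ces <- binary_outcome(cohort) == "CESAREAN"
  out <- do.call(rbind, lapply(0:4, function(k) {
    idx <- cls == k
    n <- sum(idx)
    data.frame(aida_class = k, n = n, cesarean = sum(ces[idx]),
               rate = if (n > 0) sum(ces[idx]) / n else NA_real_)
  }))
  out$pct <- round(out$rate * 100, 1)
  if (!is.null(conf)) {
    ci <- t(vapply(seq_len(nrow(out)), function(i) {
      if (out$n[i] == 0) c(NA_real_, NA_real_)
      else {
        w <- wilson_interval(out$cesarean[i], out$n[i], conf)
        c(w$lower, w$upper)
      }
    }, numeric(2)))
    out$lower <- ci[, 1]; out$upper <- ci[, 2]
  }
  out
}

#' Class x stratum x outcome cross-tabulation
#'
#' Three-way contingency table of AIDA class (0..4), midline-angle stratum
#' and binary delivery outcome. Margins always sum to the cohort size.
#'
#' @param cohort An `aida_cohort`.
#' @return A `table` with dimensions `aida_class` (0..4), `stratum`,
#'   `outcome` (`CESAREAN`/`VAGINAL`).
#' @examples
#' margin.table(class_stratum_table(aida_fixture()), 1)  # 1 2 10 32 21
#' @export
class_stratum_table <- function(cohort) {
  cls <- factor(.cohort_class(cohort), levels = 0:4)
  table(aida_class = cls,
        stratum = mla_stratum(cohort$mla_deg),
        outcome = binary_outcome(cohort))
}

#' Color distribution of each parameter by stratum
#'
#' For each of the four parameters and each populated stratum: the fraction
#' of GREEN, YELLOW and RED codes, the RED fraction, and the combined
#' RED-or-YELLOW fraction (the summary convention used for the asynclitism
#' parameter). Percentages are rounded to one decimal.
#'
#' @param cohort An `aida_cohort`.
#' @return Data frame with columns `parameter` (`mla`/`aop`/`spd`/`ad`),
#'   `stratum`, `n`, `green`, `yellow`, `red` (counts), `red_pct`,
#'   `red_or_yellow_pct`.
#' @export
color_distribution <- function(cohort) {
  stratum <- mla_stratum(cohort$mla_deg)
  cols <- c(mla = "aida_mla", aop = "aida_aop", spd = "aida_spd", ad = "aida_ad")
  strata <- levels(stratum)[table(stratum) > 0]
  out <- expand.grid(parameter = names(cols), stratum = strata,
                     stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(out)), function(i) {
    v <- as.character(cohort[[cols[[out$parameter[i]]]]][stratum == out$stratum[i]])
    n <- length(v)
    data.frame(n = n, green = sum(v == "GREEN"), yellow = sum(v == "YELLOW"),
               red = sum(v == "RED"),
               red_pct = round(100 * sum(v == "RED") / n, 1),
               red_or_yellow_pct = round(100 * sum(v != "GREEN") / n, 1))
  })
  cbind(out, do.call(rbind, rows))
}

#' Profile of vaginal-delivery cases
#'
#' Lists every case delivered vaginally with its stratum, AIDA class and
#' number of GREEN (favorable) parameters; the attribute
#' `frac_at_least_one_green` gives the fraction with at least one favorable
#' parameter.
#'
#' @param cohort An `aida_cohort`.
#' @return Data frame (possibly empty) with columns `patient_id`, `mla_deg`,
#'   `stratum`, `aida_class`, `n_green`.
#' @export
vaginal_profile <- function(cohort) {
  idx <- binary_outcome(cohort) == "VAGINAL"
  df <- as.data.frame(cohort)[idx, , drop = FALSE]
  color_cols <- c("aida_mla", "aida_aop", "aida_spd", "aida_ad")
  m <- vapply(df[color_cols], as.character, character(nrow(df)))
  n_green <- if (nrow(df)) rowSums(matrix(m == "GREEN", nrow = nrow(df)))
             else integer()
  out <- data.frame(patient_id = df$patient_id, mla_deg = df$mla_deg,
                    stratum = mla_stratum(df$mla_deg),
                    aida_class = .cohort_class(df),
                    n_green = as.integer(n_green))
  rownames(out) <- NULL
  attr(out, "frac_at_least_one_green") <-
    if (nrow(out)) mean(out$n_green >= 1) else NA_real_
  out
}
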