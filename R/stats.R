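#' Confusion summary of a binary prediction
#'
#' Tabulates predicted vs actual labels with cesarean (`ICD`) as the
#' positive class.
#'
#' @param predicted,actual Vectors of labels (`ICD`/`NOICD`, or any two
#'   labels with `positive` naming the positive one).
#' @param positive The positive-class label.
#' @return Object of class `confusion_summary`: list with integer `tp`,
#'   `tn`, `fp`, `fn`.
#' @export
confusion_summary <- function(predicted, actual, positive = "ICD") {
  stopifnot(length(predicted) == length(actual))
  p <- as.character(predicted) == positive
  a <- as.character(actual) == positive
  structure(list(tp = sum(p & a), tn = sum(!p & !a),
                 fp = sum(p & !a), fn = sum(!p & a)),
            class = "confusion_summary")
}

#' Metric family of a confusion summary
#'
#' Accuracy, sensitivity, specificity, PPV, NPV and F1 from TP/TN/FP/FN.
#' A metric whose denominator is zero is undefined and reported as `NA`,
#' never coerced to 0 — e.g. specificity on an all-positive stratum.
#'
#' @param s A `confusion_summary`, or a list with elements `tp`, `tn`, `fp`,
#'   `fn`.
#' @return Named numeric vector with elements `accuracy`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `f1`.
#' @examples
#' confusion_metrics(list(tp = 27, tn = 0, fp = 2, fn = 0))
#' @export
confusion_metrics <- function(s) {
  tp <- s$tp; tn <- s$tn; fp <- s$fp; fn <- s$fn
  stopifnot(all(c(tp, tn, fp, fn) >= 0))
  total <- tp + tn + fp + fn
  if (total == 0) stop("empty confusion summary")
  frac <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- frac(tp, tp + fn)
  ppv <- frac(tp, tp + fp)
  f1 <- if (is.na(sens) || is.na(ppv) || (ppv + sens) == 0) NA_real_
        else 2 * ppv * sens / (ppv + sens)
  c(accuracy = (tp + tn) / total,
    sensitivity = sens,
    specificity = frac(tn, tn + fp),
    ppv = ppv,
    npv = frac(tn, tn + fn),
    f1 = f1)
}

#' Wilson score interval for a binomial proportion
#'
#' Confidence interval obtained by inverting the normal-approximation score
#' test, with the exact normal quantile for the stated confidence. Bounds
#' are always inside `[0, 1]` and behave sensibly at 0 and n successes.
#'
#' @param successes Number of successes (0..n).
#' @param n Number of trials (>= 1).
#' @param confidence Confidence level in (0, 1); default 0.95.
#' @return List with `point` (the raw proportion), `lower`, `upper`,
#'   `confidence`.
#' @examples
#' wilson_interval(60, 66)
#' @export
wilson_interval <- function(successes, n, confidence = 0.95) {
  stopifnot(length(successes) == 1, length(n) == 1)
  if (n < 1) stop("n must be >= 1")
  if (successes < 0 || successes > n) stop("successes must be in 0..n")
  if (confidence <= 0 || confidence >= 1) stop("confidence must be in (0, 1)")
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(point = p, lower = max(0, center - half),
       upper = min(1, center + half), confidence = confidence)
}

#' McNemar test on discordant pairs
#'
#' Paired comparison of two classifiers on the same cases from the
#' discordant-pair counts `b` (first right, second wrong) and `c` (first
#' wrong, second right). The statistic is `(|b - c| - 1)^2 / (b + c)` with
#' continuity correction (the default) or `(b - c)^2 / (b + c)` without,
#' referred to chi-squared with 1 degree of freedom; it is symmetric in
#' `b` and `c`. With no discordant pairs the test is degenerate and reported
#' as statistic 0, p-value 1, with `degenerate = TRUE`.
#'
#' @param b,c Non-negative discordant-pair counts.
#' @param correct Apply the continuity correction? Default `TRUE`.
#' @return List with `b`, `c`, `chi2`, `p`, `corrected`, `degenerate`.
#' @examples
#' mcnemar_paired(10, 2, correct = FALSE)  # chi2 = 64/12
#' @export
mcnemar_paired <- function(b, c, correct = TRUE) {
  stopifnot(b >= 0, c >= 0, b == as.integer(b), c == as.integer(c))
  if (b + c == 0)
    return(list(b = b, c = c, chi2 = 0, p = 1, corrected = correct,
                degenerate = TRUE))
  num <- if (correct) max(0, abs(b - c) - 1)^2 else (b - c)^2
  chi2 <- num / (b + c)
  list(b = b, c = c, chi2 = chi2,
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       corrected = correct, degenerate = FALSE)
}

#' McNemar comparison of two prediction columns
#'
#' Convenience wrapper computing the discordant-pair counts of two paired
#' prediction vectors against the shared truth, then [mcnemar_paired()].
#'
#' @param pred1,pred2 Paired predicted labels.
#' @param actual True labels.
#' @param correct Continuity correction flag.
#' @return As [mcnemar_paired()].
#' @export
mcnemar_predictions <- function(pred1, pred2, actual, correct = TRUE) {
  stopifnot(length(pred1) == length(actual), length(pred2) == length(actual))
  ok1 <- as.character(pred1) == as.character(actual)
  ok2 <- as.character(pred2) == as.character(actual)
  mcnemar_paired(sum(ok1 & !ok2), sum(!ok1 & ok2), correct = correct)
}

#' Pearson correlation with significance test
#'
#' Sample Pearson correlation with the two-sided p-value from the t
#' transform on n - 2 degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant vector")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Area under the ROC curve (rank-based)
#'
#' Mann-Whitney form of the AUC: the probability that a random positive
#' scores above a random negative, ties counted half.
#'
#' @param scores Numeric prediction scores (larger = more positive).
#' @param labels Labels, with `positive` naming the positive class.
#' @param positive Positive-class label.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels, positive = "ICD") {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  pos <- as.character(labels) == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)                      # midranks handle ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
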