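test_that("confusion metrics follow the printed formulas, NA when undefined", {
  # SVM column vs outcomes in the classic stratum: predicts cesarean for all 29
  m <- confusion_metrics(list(tp = 27, tn = 0, fp = 2, fn = 0))
  expect_equal(m[["accuracy"]], 27 / 29)
  expect_equal(m[["sensitivity"]], 1)
  expect_equal(m[["specificity"]], 0)
  m <- confusion_metrics(list(tp = 10, tn = 10, fp = 0, fn = 0))
  expect_true(all(m == 1))
  m <- confusion_metrics(list(tp = 0, tn = 5, fp = 0, fn = 5))
  expect_equal(m[["sensitivity"]], 0)
  expect_equal(m[["specificity"]], 1)
  expect_true(is.na(m[["ppv"]]))    # 0/0: undefined, not 0
  expect_error(confusion_metrics(list(tp = 0, tn = 0, fp = 0, fn = 0)), "empty")
})

test_that("accuracy equals mean per-case correctness on random pairings", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    pred <- sample(c("ICD", "NOICD"), n, replace = TRUE)
    act <- sample(c("ICD", "NOICD"), n, replace = TRUE)
    cs <- confusion_summary(pred, act)
    expect_equal(cs$tp + cs$tn + cs$fp + cs$fn, n)
    expect_equal(confusion_metrics(cs)[["accuracy"]], mean(pred == act))
  }
})

test_that("Wilson interval matches its closed form and the score-test oracle", {
  z <- qnorm(0.975)
  w <- wilson_interval(0, 10)
  expect_equal(w$lower, 0)
  expect_equal(w$upper, z^2 / (10 + z^2), tolerance = 1e-12)
  expect_equal(w$upper, 0.2775, tolerance = 1e-3)
  w <- wilson_interval(10, 10)
  expect_equal(w$upper, 1)
  w <- wilson_interval(5, 10)
  expect_equal(w$lower + w$upper, 1)   # symmetric about 1/2
  # prop.test without continuity correction inverts the same score test
  for (n in c(10, 66, 135)) for (x in unique(c(0, 1, n %/% 3, n))) {
    w <- wilson_interval(x, n)
    pt <- prop.test(x, n, correct = FALSE)$conf.int
    expect_equal(c(w$lower, w$upper), as.numeric(pt), tolerance = 1e-9)
  }
  expect_error(wilson_interval(5, 0), "n")
})

test_that("Wilson interval shrinks with n and stays inside [0, 1]", {
  widths <- sapply(c(10, 40, 160, 640), function(n) {
    w <- wilson_interval(round(0.3 * n), n)
    expect_true(w$lower >= 0 && w$upper <= 1)
    w$upper - w$lower
  })
  expect_true(all(diff(widths) < 0))
})

test_that("McNemar statistic follows the discordant-pair formulas", {
  r <- mcnemar_paired(7, 7, correct = FALSE)
  expect_equal(r$chi2, 0); expect_equal(r$p, 1)
  expect_equal(mcnemar_paired(10, 2, correct = FALSE)$chi2, 64 / 12)
  expect_equal(mcnemar_paired(2, 1, correct = TRUE)$chi2, 0)
  d <- mcnemar_paired(0, 0)
  expect_true(d$degenerate); expect_equal(d$p, 1)
  # symmetry in b and c; agreement with stats::mcnemar.test
  set.seed(3)
  for (i in 1:20) {
    b <- sample(0:15, 1); c <- sample(0:15, 1)
    if (b + c == 0) next
    for (corr in c(TRUE, FALSE)) {
      r1 <- mcnemar_paired(b, c, corr)
      r2 <- mcnemar_paired(c, b, corr)
      expect_equal(r1$chi2, r2$chi2); expect_equal(r1$p, r2$p)
      ref <- mcnemar.test(matrix(c(5, b, c, 5), 2), correct = corr)
      expect_equal(r1$chi2, unname(ref$statistic))
      expect_equal(r1$p, ref$p.value)
    }
  }
})

test_that("mcnemar_predictions counts discordant pairs against shared truth", {
  act <- c("ICD", "ICD", "ICD", "NOICD", "NOICD")
  p1 <- c("ICD", "ICD", "NOICD", "NOICD", "ICD")   # right on 1,2,4
  p2 <- c("ICD", "NOICD", "ICD", "ICD", "ICD")     # right on 1,3
  r <- mcnemar_predictions(p1, p2, act, correct = FALSE)
  expect_equal(r$b, 2)   # p1 right, p2 wrong: cases 2, 4
  expect_equal(r$c, 1)   # p2 right, p1 wrong: case 3
})

test_that("Pearson correlation is exact on linear data and affine invariant", {
  x <- c(1, 2, 4, 7, 11)
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_cor(x, -x)$r, -1)
  expect_error(pearson_cor(x, rep(2, 5)), "constant")
  set.seed(5)
  a <- rnorm(30); b <- rnorm(30)
  r0 <- pearson_cor(a, b)
  r1 <- pearson_cor(3 * a - 2, 0.5 * b + 7)
  expect_equal(r1$r, r0$r); expect_equal(r1$p, r0$p)
  expect_equal(pearson_cor(3 - a, b)$r, -r0$r)
})

test_that("sample correlation recovers a population rho of 0.36", {
  set.seed(21)
  n <- 5000; rho <- 0.36
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  r <- pearson_cor(x, y)
  expect_equal(r$r, rho, tolerance = 0.05)
  expect_lt(r$p, 0.001)
})

test_that("rank AUC equals the brute-force pairwise oracle, ties half", {
  brute <- function(s, l) {
    ps <- s[l == "ICD"]; ns <- s[l == "NOICD"]
    mean(outer(ps, ns, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  expect_equal(auc_score(c(1, 2, 3, 4), c("NOICD", "NOICD", "ICD", "ICD")), 1)
  expect_equal(auc_score(rep(0.3, 10), rep(c("ICD", "NOICD"), 5)), 0.5)
  set.seed(9)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    s <- sample(round(runif(n), 2))   # rounding forces ties
    l <- sample(c("ICD", "NOICD"), n, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(l)) < 2) next
    expect_equal(auc_score(s, l), brute(s, l))
  }
  expect_error(auc_score(1:4, rep("ICD", 4)), "both classes")
})

test_that("rank AUC agrees with an independent ROC implementation", {
  set.seed(13)
  n <- 150
  l <- sample(c("ICD", "NOICD"), n, replace = TRUE)
  s <- rnorm(n, mean = ifelse(l == "ICD", 0.8, 0))
  expect_equal(auc_score(s, l),
               as.numeric(pROC::auc(pROC::roc(l, s, levels = c("NOICD", "ICD"),
                                              direction = "<", quiet = TRUE))))
})

test_that("label-independent scores give AUC near one half", {
  set.seed(17)
  s <- runif(2000)
  l <- sample(c("ICD", "NOICD"), 2000, replace = TRUE)
  expect_equal(auc_score(s, l), 0.5, tolerance = 0.05)
})
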