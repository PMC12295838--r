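.backends <- c("svm", "rf", "mlp")
.default_seeds <- c(1, 0, 250, 500, 750)

#' Seeded 70/30 train/test split
#'
#' Deterministic random partition of a cohort given its row order and a
#' seed. Train size is `floor(n * train_fraction + 0.5)` (round half up), so
#' a cohort of 135 at the default fraction splits 95/40 and one of 10
#' splits 7/3.
#'
#' @param cohort An `aida_cohort` (or any data frame of cases).
#' @param seed Integer random seed.
#' @param train_fraction Fraction allocated to training; default 0.7.
#' @return List with elements `train` and `test`; every case lands in
#'   exactly one part.
#' @export
split_cohort <- function(cohort, seed, train_fraction = 0.7) {
  n <- nrow(cohort)
  if (n < 2) stop("cohort must have at least 2 cases")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  n_train <- floor(n * train_fraction + 0.5)
  n_train <- min(max(n_train, 1L), n - 1L)
  set.seed(seed)
  idx <- sample.int(n, n_train)
  train <- cohort[idx, , drop = FALSE]
  test <- cohort[-idx, , drop = FALSE]
  if (length(unique(binary_outcome(train))) < 2)
    warning("training part contains a single outcome class")
  list(train = train, test = test)
}

# Feature matrix under an encoding mode.
#   raw:   the four raw geometric measurements (aop, hsd, ad) + mla degrees
#   color: per-parameter ordinal color (GREEN=0, YELLOW=1, RED=2) + mla degrees
#   class: the AIDA class alone
.encode_features <- function(cohort, encoding) {
  encoding <- match.arg(encoding, c("color", "raw", "class"))
  df <- as.data.frame(cohort)
  if (encoding == "raw") {
    need <- c("aop", "hsd", "ad")
    if (!all(need %in% names(df)))
      stop("raw feature encoding needs columns aop, hsd, ad; ",
           "use encoding = \"color\" for color-coded cohorts")
    m <- cbind(mla = canonical_mla(df$mla_deg)$value,
               aop = df$aop, hsd = df$hsd, ad = df$ad)
  } else if (encoding == "color") {
    ord <- function(v) match(as.character(v), .color_levels) - 1L
    m <- cbind(mla_deg = canonical_mla(df$mla_deg)$value,
               mla = ord(df$aida_mla), aop = ord(df$aida_aop),
               spd = ord(df$aida_spd), ad = ord(df$aida_ad))
  } else {
    m <- cbind(aida_class = .cohort_class(df))
  }
  storage.mode(m) <- "double"
  m
}

#' Train a classifier backend and predict the test part
#'
#' Fits one of the three backends — support vector machine
#' (`e1071::svm`, RBF kernel, probability model), random forest
#' (`randomForest::randomForest`) or multilayer perceptron (`nnet::nnet`,
#' one hidden layer, standardized inputs) — on the training part and
#' returns a scored, labeled prediction per test case. All backend
#' randomness is seeded, so identical inputs give identical predictions.
#'
#' @param backend One of `"svm"`, `"rf"`, `"mlp"`.
#' @param train,test Cohort parts as returned by [split_cohort()].
#' @param encoding Feature encoding: `"color"` (ordinal colors plus midline
#'   angle; works on color-coded cohorts such as the fixture), `"raw"` (the
#'   four raw measurements; needs `aop`, `hsd`, `ad` columns) or `"class"`
#'   (AIDA class only).
#' @param seed Integer seed.
#' @param threshold Decision threshold on the cesarean probability score;
#'   default 0.5.
#' @return Data frame with columns `patient_id`, `algorithm`, `seed`,
#'   `score` (probability of cesarean), `label` (`ICD`/`NOICD`).
#' @export
train_predict <- function(backend, train, test, encoding = "color",
                          seed = 1, threshold = 0.5) {
  backend <- match.arg(backend, .backends)
  x_train <- .encode_features(train, encoding)
  x_test <- .encode_features(test, encoding)
  y <- factor(binary_outcome(train) == "CESAREAN", levels = c(FALSE, TRUE),
              labels = c("NOICD", "ICD"))
  if (length(unique(y)) < 2)
    stop("training part must contain both outcome classes")
  set.seed(seed)
  score <- switch(backend,
    svm = {
      fit <- e1071::svm(x_train, y, probability = TRUE, kernel = "radial")
      pr <- attr(stats::predict(fit, x_test, probability = TRUE), "probabilities")
      pr[, "ICD"]
    },
    rf = {
      fit <- randomForest::randomForest(x_train, y)
      stats::predict(fit, x_test, type = "prob")[, "ICD"]
    },
    mlp = {
      mu <- colMeans(x_train); sd <- apply(x_train, 2, stats::sd)
      sd[sd == 0] <- 1
      xs <- scale(x_train, mu, sd)
      fit <- nnet::nnet(xs, as.numeric(y == "ICD"), size = 8, decay = 0.01,
                        maxit = 500, entropy = TRUE, trace = FALSE)
      drop(stats::predict(fit, scale(x_test, mu, sd)))
    })
  score <- unname(score)
  data.frame(patient_id = as.character(test$patient_id),
             algorithm = backend, seed = seed, score = score,
             label = ifelse(score >= threshold, "ICD", "NOICD"))
}

#' Multi-seed evaluation of the classifier backends
#'
#' Repeats the seeded split / train / predict cycle over a list of seeds
#' (default `1, 0, 250, 500, 750`) and summarizes per-seed
#' confusion metrics on the test part, plus their unweighted mean per
#' backend. Per-seed detail is always retained.
#'
#' @param cohort An `aida_cohort`.
#' @param backends Character vector of backends; default all three.
#' @param seeds Integer seeds; default `c(1, 0, 250, 500, 750)`.
#' @param encoding Feature encoding, see [train_predict()].
#' @param train_fraction Training fraction; default 0.7.
#' @param threshold Decision threshold; default 0.5.
#' @return List with `per_seed` (one row per backend x seed with test-set
#'   confusion counts and metrics) and `summary` (per backend, the
#'   unweighted mean of each metric over seeds).
#' @export
multi_seed_evaluate <- function(cohort, backends = .backends,
                                seeds = .default_seeds, encoding = "color",
                                train_fraction = 0.7, threshold = 0.5) {
  if (!length(seeds)) stop("seeds must be non-empty")
  rows <- list()
  for (backend in backends) {
    for (seed in seeds) {
      parts <- split_cohort(cohort, seed, train_fraction)
      pred <- train_predict(backend, parts$train, parts$test,
                            encoding = encoding, seed = seed,
                            threshold = threshold)
      cs <- confusion_summary(pred$label,
                              ifelse(binary_outcome(parts$test) == "CESAREAN",
                                     "ICD", "NOICD"))
      met <- confusion_metrics(cs)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(algorithm = backend, seed = seed, n_test = nrow(parts$test),
                   tp = cs$tp, tn = cs$tn, fp = cs$fp, fn = cs$fn),
        as.data.frame(t(met)))
    }
  }
  per_seed <- do.call(rbind, rows)
  metric_cols <- c("accuracy", "sensitivity", "specificity", "ppv", "npv", "f1")
  summary <- do.call(rbind, lapply(unique(per_seed$algorithm), function(a) {
    sub <- per_seed[per_seed$algorithm == a, metric_cols, drop = FALSE]
    cbind(data.frame(algorithm = a, n_seeds = nrow(sub)),
          as.data.frame(t(colMeans(sub))))
  }))
  list(per_seed = per_seed, summary = summary)
}

#' Accuracy of recorded algorithm predictions
#'
#' Scores the recorded per-case prediction columns (`pred_svm`, `pred_rf`,
#' `pred_mlp`) of a cohort against the recorded outcomes, optionally within
#' subgroups. This evaluation path involves no retraining: it reproduces the
#' published subset accuracies directly from the printed predictions.
#'
#' @param cohort An `aida_cohort` carrying recorded prediction columns.
#' @param by Grouping: `"overall"`, `"stratum"` (midline-angle stratum) or
#'   `"class"` (AIDA class).
#' @return Data frame with columns `group`, `algorithm`, `n`, `correct`,
#'   `accuracy`, `pct` (percentage to one decimal).
#' @examples
#' recorded_accuracy(aida_fixture(), by = "stratum")
#' @export
recorded_accuracy <- function(cohort, by = c("overall", "stratum", "class")) {
  by <- match.arg(by)
  if (!all(.pred_cols %in% names(cohort)))
    stop("cohort has no recorded prediction columns")
  group <- switch(by,
    overall = factor(rep("overall", nrow(cohort))),
    stratum = mla_stratum(cohort$mla_deg),
    class = factor(.cohort_class(cohort), levels = 0:4))
  actual <- ifelse(binary_outcome(cohort) == "CESAREAN", "ICD", "NOICD")
  algos <- c(svm = "pred_svm", rf = "pred_rf", mlp = "pred_mlp")
  out <- list()
  for (g in levels(group)) {
    idx <- group == g
    if (!any(idx)) next
    for (a in names(algos)) {
      correct <- sum(as.character(cohort[[algos[[a]]]][idx]) == actual[idx])
      out[[length(out) + 1L]] <- data.frame(
        group = g, algorithm = a, n = sum(idx), correct = correct,
        accuracy = correct / sum(idx),
        pct = round(100 * correct / sum(idx), 1))
    }
  }
  do.call(rbind, out)
}
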