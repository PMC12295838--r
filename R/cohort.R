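.mandatory_cols <- c("patient_id", "mla_deg", "outcome",
                     "aida_mla", "aida_aop", "aida_spd", "aida_ad")
.binary_outcomes   <- c("ICD", "NOICD")
.detailed_outcomes <- c("SPONTANEOUS", "OPERATIVE_VD", "ICD_AFTER_FAILURE", "ICD")
.pred_cols <- c("pred_svm", "pred_rf", "pred_mlp")

# md5 of the packaged reference cohort CSV; guards against fixture corruption
.fixture_md5 <- "7485142ebcb35189a5cd973af7877ea3"

#' Construct a labor cohort from a data frame
#'
#' A cohort is a data frame of case records — one row per labor case — with
#' mandatory columns `patient_id`, `mla_deg` (rotation angle, degrees),
#' `outcome` (`ICD`/`NOICD` or a detailed label), and the four color columns
#' `aida_mla`, `aida_aop`, `aida_spd`, `aida_ad`. Optional columns:
#' `aida_class`, recorded per-algorithm predictions `pred_svm`, `pred_rf`,
#' `pred_mlp` (all three or none), and raw measurements `aop`, `hsd`, `ad`.
#' `aida_spd` is the color of the head-symphysis distance (HSD); the `SPD`
#' naming is kept as the field's column alias for the same quantity.
#'
#' @param df Data frame of case records.
#' @param provenance One of `"USER"`, `"FIXTURE"`, `"SYNTHETIC"`.
#' @return The data frame with class `aida_cohort` and a `provenance`
#'   attribute.
#' @export
as_cohort <- function(df, provenance = "USER") {
  df <- as.data.frame(df)
  .check_cohort_strict(df)
  provenance <- match.arg(provenance, c("USER", "FIXTURE", "SYNTHETIC"))
  structure(df, class = c("aida_cohort", "data.frame"),
            provenance = provenance)
}

# strict structural validation used on construction and CSV read;
# row-addressed messages
.check_cohort_strict <- function(df, where = "cohort") {
  missing_cols <- setdiff(.mandatory_cols, names(df))
  if (length(missing_cols))
    stop(where, ": missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  rep_err <- function(rows, msg)
    stop(where, ", row(s) ", paste(rows, collapse = ", "), ": ", msg)
  dup <- duplicated(df$patient_id)
  if (any(dup)) rep_err(which(dup), "duplicate patient_id")
  bad <- !is.finite(df$mla_deg) | df$mla_deg < 0 | df$mla_deg >= 360
  if (any(bad)) rep_err(which(bad), "mla_deg must be in [0, 360)")
  for (col in c("aida_mla", "aida_aop", "aida_spd", "aida_ad")) {
    v <- as.character(df[[col]])
    bad <- !(v %in% .color_levels)
    if (any(bad))
      rep_err(which(bad), paste0("unparseable color '", v[which(bad)[1]],
                                 "' in column ", col))
  }
  v <- as.character(df$outcome)
  bad <- !(v %in% c(.binary_outcomes, .detailed_outcomes))
  if (any(bad))
    rep_err(which(bad), paste0("unparseable outcome token '", v[which(bad)[1]], "'"))
  have_pred <- intersect(.pred_cols, names(df))
  if (length(have_pred) && length(have_pred) != 3L)
    stop(where, ": recorded predictions must cover all of ",
         paste(.pred_cols, collapse = ", "))
  for (col in have_pred) {
    v <- as.character(df[[col]])
    bad <- !(v %in% .binary_outcomes)
    if (any(bad))
      rep_err(which(bad), paste0("unparseable prediction token '",
                                 v[which(bad)[1]], "' in column ", col))
  }
  invisible(df)
}

#' @export
print.aida_cohort <- function(x, ...) {
  cat(sprintf("AIDA cohort: %d cases (provenance %s)\n",
              nrow(x), attr(x, "provenance")))
  tab <- table(mla_stratum(x$mla_deg))
  cat("  strata:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  cat("  cesarean:", sum(binary_outcome(x) == "CESAREAN"), "of", nrow(x), "\n")
  NextMethod()
  invisible(x)
}

#' Binary delivery outcome of each case
#'
#' Collapses the outcome column to `CESAREAN` (table label `ICD`, which
#' includes cesarean after a failed operative attempt) versus `VAGINAL`
#' (`NOICD`, spontaneous or operative vaginal delivery).
#'
#' @param cohort An `aida_cohort` or its outcome column.
#' @return Factor with levels `CESAREAN`, `VAGINAL`.
#' @export
binary_outcome <- function(cohort) {
  v <- if (is.data.frame(cohort)) as.character(cohort$outcome) else as.character(cohort)
  bad <- !(v %in% c(.binary_outcomes, .detailed_outcomes))
  if (any(bad)) stop("unparseable outcome token '", v[which(bad)[1]], "'")
  ces <- v %in% c("ICD", "ICD_AFTER_FAILURE")
  factor(ifelse(ces, "CESAREAN", "VAGINAL"), levels = c("CESAREAN", "VAGINAL"))
}

#' Load the packaged 66-case transverse-position reference cohort
#'
#' The package ships a transcription of the published per-case records for
#' 66 transverse and near/transitional fetal head positions: patient id,
#' midline angle in degrees, the four parameter colors, the AIDA class, the
#' binary delivery outcome (`ICD`/`NOICD`), and the recorded predictions of
#' the three machine-learning algorithms. The file's checksum is verified at
#' load time.
#'
#' @return An `aida_cohort` with 66 rows and provenance `FIXTURE`.
#' @export
aida_fixture <- function() {
  path <- system.file("extdata", "transverse_cohort.csv", package = "aida",
                      mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, .fixture_md5))
    stop("packaged reference cohort is corrupted (checksum mismatch)")
  read_cohort(path, provenance = "FIXTURE")
}

#' Load the packaged detailed-outcome summary
#'
#' The published per-case tables print only the binary outcome; the detailed
#' delivery categories (spontaneous, operative vaginal, cesarean after
#' failure, cesarean) are printed only as aggregate counts by AIDA class and
#' midline-angle stratum. Those aggregates are packaged verbatim here rather
#' than invented per case.
#'
#' @return Data frame with columns `aida_class`, `detailed_outcome`,
#'   `stratum`, `n` (grand total 66).
#' @export
outcome_summary <- function() {
  path <- system.file("extdata", "transverse_outcome_summary.csv",
                      package = "aida", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read / write a cohort CSV
#'
#' Comma-separated, UTF-8, mandatory header with the documented column names
#' (see [as_cohort()]); colors serialized as `GREEN`/`YELLOW`/`RED`, outcomes
#' as `ICD`/`NOICD` or detailed labels. Unknown columns are preserved on a
#' round trip. Structural problems (missing mandatory column, duplicate id,
#' unparseable token) raise row-addressed errors.
#'
#' @param path CSV file path.
#' @param provenance Provenance tag for the loaded cohort.
#' @return `read_cohort()` returns an `aida_cohort`; `write_cohort()`
#'   returns `path` invisibly.
#' @export
read_cohort <- function(path, provenance = "USER") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character"))
  .check_cohort_strict(df, where = path)
  as_cohort(df, provenance = provenance)
}

#' @rdname read_cohort
#' @param cohort An `aida_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a cohort and report invariant violations
#'
#' Non-throwing companion to the strict checks of [read_cohort()]: returns a
#' report of violations instead of raising. Checked: midline angle in range,
#' unique patient ids, valid color and outcome tokens, and — when an
#' `aida_class` column is present — agreement of that column with the
#' non-GREEN counting rule.
#'
#' @param cohort A data frame of case records (need not be a valid cohort).
#' @return Data frame with columns `row`, `field`, `message`; zero rows when
#'   no violation is found.
#' @export
validate_cohort <- function(cohort) {
  df <- as.data.frame(cohort)
  report <- data.frame(row = integer(), field = character(),
                       message = character())
  add <- function(rows, field, message)
    rbind(report, data.frame(row = rows, field = field, message = message))
  missing_cols <- setdiff(.mandatory_cols, names(df))
  for (col in missing_cols)
    report <- add(NA_integer_, col, "missing mandatory column")
  if ("patient_id" %in% names(df)) {
    dup <- duplicated(df$patient_id)
    if (any(dup)) report <- add(which(dup), "patient_id", "duplicate patient_id")
  }
  if ("mla_deg" %in% names(df)) {
    bad <- !is.finite(df$mla_deg) | df$mla_deg < 0 | df$mla_deg >= 360
    if (any(bad)) report <- add(which(bad), "mla_deg", "mla_deg outside [0, 360)")
  }
  for (col in intersect(c("aida_mla", "aida_aop", "aida_spd", "aida_ad"), names(df))) {
    bad <- !(as.character(df[[col]]) %in% .color_levels)
    if (any(bad)) report <- add(which(bad), col, "unparseable color token")
  }
  if ("outcome" %in% names(df)) {
    bad <- !(as.character(df$outcome) %in% c(.binary_outcomes, .detailed_outcomes))
    if (any(bad)) report <- add(which(bad), "outcome", "unparseable outcome token")
  }
  color_cols <- c("aida_mla", "aida_aop", "aida_spd", "aida_ad")
  if ("aida_class" %in% names(df) && all(color_cols %in% names(df))) {
    m <- vapply(df[color_cols], as.character, character(nrow(df)))
    ok_rows <- rowSums(matrix(m %in% .color_levels, nrow = nrow(df))) == 4
    if (any(ok_rows)) {
      computed <- assign_aida_class(df[ok_rows, , drop = FALSE])
      bad <- which(ok_rows)[computed != df$aida_class[ok_rows]]
      if (length(bad))
        report <- add(bad, "aida_class",
                      "class column disagrees with non-GREEN counting rule")
    }
  }
  report
}
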