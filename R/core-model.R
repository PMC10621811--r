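# Cohort container and CSV round-trip.
#
# A cohort is a data frame with one row per (child, version): five level
# times, five dwell times (time to the first matched pair of each level),
# five correct-pair counts, and the derived per-run summaries stored
# redundantly for human readability and re-validated on ingest.

level_cols <- function(prefix) paste0(prefix, "_l", 1:5)

#' Column names of the cohort table
#'
#' @return Character vector with the canonical column order of a cohort CSV.
#' @export
cohort_columns <- function() {
  c("child_id", "age_years", "gender", "conditions", "truth_label", "version",
    level_cols("level_time"), level_cols("dwell"), level_cols("correct_pairs"),
    "overall_time_s", "mean_dwell_s", "accurate_rounds")
}

# Tolerance for re-derived summary columns: values are stored at millisecond
# resolution, so the mean of five dwell times can differ from its 3 dp
# representation by up to 5e-4.
DERIVED_TOL <- 5.1e-4

.derive_run_summaries <- function(df) {
  lt <- as.matrix(df[level_cols("level_time")])
  dw <- as.matrix(df[level_cols("dwell")])
  cp <- as.matrix(df[level_cols("correct_pairs")])
  acc <- cp == matrix(LEVEL_PAIRS, nrow(df), 5, byrow = TRUE)
  data.frame(
    overall_time_s = round(rowSums(lt), 3),
    mean_dwell_s = round(rowMeans(dw), 3),
    accurate_rounds = as.integer(rowSums(acc))
  )
}

.row_field_error <- function(rows, field, what) {
  stop(sprintf("invalid cohort row %s, field '%s': %s",
               paste(rows, collapse = ", "), field, what), call. = FALSE)
}

#' Validate a cohort table
#'
#' Checks every structural invariant of the cohort schema: age range 5-18,
#' known version and gender codes, per-level time ordering (a level's dwell
#' time cannot exceed its total time), correct-pair counts within the level's
#' pair count, uniqueness of (child, version), and consistency of the
#' redundantly stored summary columns (`overall_time_s`, `mean_dwell_s`,
#' `accurate_rounds`) with the per-level columns.  A mismatch is an error,
#' never a silent fix.
#'
#' @param df A data frame with the columns of [cohort_columns()].
#' @return `df`, invisibly, if valid; otherwise an error naming the first
#'   offending row(s) and field.
#' @export
validate_cohort <- function(df) {
  missing <- setdiff(cohort_columns(), names(df))
  if (length(missing)) {
    stop("cohort is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) return(invisible(df))

  bad <- function(cond) which(cond)

  if (length(i <- bad(is.na(df$child_id) | !nzchar(df$child_id))))
    .row_field_error(i, "child_id", "empty identifier")
  if (length(i <- bad(is.na(df$age_years) | df$age_years != round(df$age_years))))
    .row_field_error(i, "age_years", "must be an integer number of completed years")
  if (length(i <- bad(df$age_years < AGE_MIN | df$age_years > AGE_MAX)))
    .row_field_error(i, "age_years", sprintf("outside %d-%d", AGE_MIN, AGE_MAX))
  if (length(i <- bad(!df$version %in% VERSIONS)))
    .row_field_error(i, "version", "must be 'multi' or 'single'")
  if (length(i <- bad(!df$gender %in% GENDERS)))
    .row_field_error(i, "gender", "must be female/male/unspecified")
  if (length(i <- bad(!is.na(df$truth_label) & !df$truth_label %in% c("typical", "deficit"))))
    .row_field_error(i, "truth_label", "must be typical/deficit or empty")

  key <- paste(df$child_id, df$version)
  if (anyDuplicated(key))
    .row_field_error(which(duplicated(key)), "version",
                     "duplicate (child_id, version) pair")

  for (k in 1:5) {
    ltc <- paste0("level_time_l", k)
    dwc <- paste0("dwell_l", k)
    cpc <- paste0("correct_pairs_l", k)
    if (length(i <- bad(is.na(df[[ltc]]) | df[[ltc]] <= 0)))
      .row_field_error(i, ltc, "level time must be positive")
    if (length(i <- bad(is.na(df[[dwc]]) | df[[dwc]] <= 0)))
      .row_field_error(i, dwc, "dwell time must be positive")
    if (length(i <- bad(df[[dwc]] > df[[ltc]] + 1e-9)))
      .row_field_error(i, dwc, "dwell time exceeds the level's total time")
    cp <- df[[cpc]]
    if (length(i <- bad(is.na(cp) | cp != round(cp) | cp < 0 | cp > LEVEL_PAIRS[k])))
      .row_field_error(i, cpc, sprintf("must be an integer in 0..%d", LEVEL_PAIRS[k]))
  }

  derived <- .derive_run_summaries(df)
  if (length(i <- bad(abs(df$overall_time_s - derived$overall_time_s) > DERIVED_TOL)))
    .row_field_error(i, "overall_time_s", "does not equal the sum of the level times")
  if (length(i <- bad(abs(df$mean_dwell_s - derived$mean_dwell_s) > DERIVED_TOL)))
    .row_field_error(i, "mean_dwell_s", "does not equal the mean of the dwell times")
  if (length(i <- bad(df$accurate_rounds != derived$accurate_rounds)))
    .row_field_error(i, "accurate_rounds",
                     "does not equal the count of fully correct levels")
  invisible(df)
}

#' Construct a cohort object
#'
#' @param df Data frame conforming to the cohort schema; see
#'   [cohort_columns()].
#' @return A `cohort` object (a validated data frame).
#' @export
new_cohort <- function(df) {
  df <- as.data.frame(df)[cohort_columns()]
  df$child_id <- as.character(df$child_id)
  df$age_years <- as.integer(df$age_years)
  df$gender <- as.character(df$gender)
  df$conditions <- as.character(df$conditions)
  df$truth_label <- as.character(df$truth_label)
  df$version <- as.character(df$version)
  for (col in c(level_cols("level_time"), level_cols("dwell"),
                "overall_time_s", "mean_dwell_s")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  for (col in c(level_cols("correct_pairs"), "accurate_rounds")) {
    df[[col]] <- as.integer(df[[col]])
  }
  rownames(df) <- NULL
  validate_cohort(df)
  class(df) <- c("cohort", "data.frame")
  df
}

#' Read a cohort CSV
#'
#' Reads a UTF-8, "."-decimal cohort file with one row per (child, version)
#' and re-validates every invariant, including the redundantly stored derived
#' columns.
#'
#' @param path Path to a cohort CSV.
#' @return A `cohort` object.
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(cohort_columns(), names(df))
  if (length(missing)) {
    stop("cohort file ", path, " is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  num_cols <- c(level_cols("level_time"), level_cols("dwell"),
                "overall_time_s", "mean_dwell_s")
  int_cols <- c("age_years", level_cols("correct_pairs"), "accurate_rounds")
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (nrow(df) && anyNA(v))
      .row_field_error(which(is.na(v)), col, "not a number")
    df[[col]] <- v
  }
  for (col in int_cols) {
    v <- suppressWarnings(as.integer(df[[col]]))
    if (nrow(df) && anyNA(v))
      .row_field_error(which(is.na(v)), col, "not an integer")
    df[[col]] <- v
  }
  df$truth_label[!nzchar(df$truth_label %||% "")] <- NA_character_
  new_cohort(df)
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, f))` reproduces
#' `x` field-for-field.  Times are written at millisecond resolution.
#'
#' @param cohort A `cohort` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  out <- as.data.frame(cohort)
  for (col in c(level_cols("level_time"), level_cols("dwell"),
                "overall_time_s", "mean_dwell_s")) {
    out[[col]] <- sprintf("%.3f", out[[col]])
  }
  out$truth_label[is.na(out$truth_label)] <- ""
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Extract one assessment run from a cohort row
#'
#' @param row A single cohort row (data frame of one row).
#' @return An `assessment_run` object: child fields, version, a 5-row level
#'   table and the derived summaries.
#' @export
assessment_run <- function(row) {
  stopifnot(nrow(row) == 1L)
  levels <- data.frame(
    level = 1:5,
    n_cards = LEVEL_CARDS,
    n_pairs = LEVEL_PAIRS,
    dwell_time_s = as.numeric(row[level_cols("dwell")]),
    level_time_s = as.numeric(row[level_cols("level_time")]),
    n_correct_pairs = as.integer(row[level_cols("correct_pairs")])
  )
  levels$accurate <- levels$n_correct_pairs == levels$n_pairs
  structure(
    list(child_id = row$child_id, age_years = row$age_years,
         gender = row$gender, conditions = row$conditions,
         truth_label = row$truth_label, version = row$version,
         levels = levels,
         overall_time_s = row$overall_time_s,
         mean_dwell_s = row$mean_dwell_s,
         accurate_rounds = row$accurate_rounds),
    class = "assessment_run"
  )
}

#' Group a cohort into paired assessments
#'
#' Each child completed the task up to twice, once per color version; a
#' paired assessment holds whichever runs are present.
#'
#' @param cohort A `cohort` object.
#' @return Named list of `paired_assessment` objects (one per child, in
#'   first-appearance order), each with `run_multi` and/or `run_single`.
#' @export
as_paired <- function(cohort) {
  validate_cohort(cohort)
  ids <- unique(cohort$child_id)
  out <- lapply(ids, function(id) {
    rows <- cohort[cohort$child_id == id, , drop = FALSE]
    pa <- list(child_id = id, age_years = rows$age_years[1L],
               run_multi = NULL, run_single = NULL)
    for (i in seq_len(nrow(rows))) {
      run <- assessment_run(rows[i, , drop = FALSE])
      if (run$version == "multi") pa$run_multi <- run else pa$run_single <- run
    }
    structure(pa, class = "paired_assessment")
  })
  names(out) <- ids
  out
}

#' @export
print.assessment_run <- function(x, ...) {
  cat(sprintf("<assessment_run> child %s, age %d, %s-colored version\n",
              x$child_id, x$age_years, x$version))
  cat(sprintf("  overall %.3f s, mean dwell %.3f s, %d/5 accurate rounds\n",
              x$overall_time_s, x$mean_dwell_s, x$accurate_rounds))
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d runs, %d children, ages %d-%d\n",
              nrow(x), length(unique(x$child_id)),
              min(x$age_years), max(x$age_years)))
  NextMethod()
}
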