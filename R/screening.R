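# The screening decision rule: six thresholds (two versions x three
# variables), any one of which flags the child for further visual
# assessment.  Time triggers are strict (> threshold), so a child exactly
# at the normative percentile is not flagged; accuracy triggers when fewer
# than `accuracy_cutoff` rounds are fully correct.

.threshold_cell <- function(thresholds, age_group, version) {
  cell <- thresholds[thresholds$age_group == as.character(age_group) &
                       thresholds$version == version, , drop = FALSE]
  if (nrow(cell) != 1L)
    stop(sprintf("no threshold cell for age group %s, %s-colored version",
                 age_group, version), call. = FALSE)
  cell
}

#' Evaluate one run against the normative thresholds
#'
#' @param run An `assessment_run` (see [assessment_run()] / [as_paired()]).
#' @param thresholds A `threshold_set` containing the run's
#'   (age group, version) cell.
#' @return Character vector: the subset of
#'   `c("overall_time", "dwell", "accuracy")` the run triggers.
#' @export
evaluate_run <- function(run, thresholds) {
  stopifnot(inherits(run, "assessment_run"))
  cell <- .threshold_cell(thresholds, assign_age_group(run$age_years),
                          run$version)
  triggered <- c(
    if (run$overall_time_s > cell$overall_time_threshold_s) "overall_time",
    if (run$mean_dwell_s > cell$dwell_threshold_s) "dwell",
    if (run$accurate_rounds < cell$accuracy_cutoff) "accuracy")
  triggered %||% character()
}

#' Screen one child
#'
#' Applies [evaluate_run()] to whichever versions the child completed and
#' takes the union: one triggered threshold out of the six suffices to
#' flag.  A child with only one version is screened on it and marked
#' `partial`.
#'
#' @param paired A `paired_assessment` (see [as_paired()]).
#' @param thresholds A `threshold_set`.
#' @return A `screening_outcome`: `child_id`, `flagged`, `triggered` (data
#'   frame of version/variable pairs) and `partial`.
#' @export
screen_child <- function(paired, thresholds) {
  stopifnot(inherits(paired, "paired_assessment"))
  runs <- Filter(Negate(is.null), list(paired$run_multi, paired$run_single))
  if (!length(runs)) stop("paired assessment holds no runs", call. = FALSE)
  triggered <- do.call(rbind, lapply(runs, function(run) {
    vars <- evaluate_run(run, thresholds)
    if (length(vars)) data.frame(version = run$version, variable = vars)
    else NULL
  }))
  if (is.null(triggered))
    triggered <- data.frame(version = character(), variable = character())
  structure(list(child_id = paired$child_id,
                 flagged = nrow(triggered) > 0L,
                 triggered = triggered,
                 partial = length(runs) < 2L),
            class = "screening_outcome")
}

#' Screen a whole cohort
#'
#' @param cohort A `cohort` object.
#' @param thresholds A `threshold_set`.
#' @return Data frame with one row per child: `child_id`, `age_years`,
#'   `flagged`, `triggered` (semicolon-joined `version:variable` pairs),
#'   `partial`.
#' @export
screen_cohort <- function(cohort, thresholds) {
  validate_cohort(cohort)
  grp <- as.character(assign_age_group(cohort$age_years))
  flags <- matrix(FALSE, nrow(cohort), 3L,
                  dimnames = list(NULL, SCREEN_VARIABLES))
  for (g in AGE_GROUPS) {
    for (v in VERSIONS) {
      sel <- grp == g & cohort$version == v
      if (!any(sel)) next
      cell <- .threshold_cell(thresholds, g, v)
      flags[sel, "overall_time"] <-
        cohort$overall_time_s[sel] > cell$overall_time_threshold_s
      flags[sel, "dwell"] <- cohort$mean_dwell_s[sel] > cell$dwell_threshold_s
      flags[sel, "accuracy"] <- cohort$accurate_rounds[sel] < cell$accuracy_cutoff
    }
  }
  trig <- vapply(seq_len(nrow(cohort)), function(i) {
    vars <- SCREEN_VARIABLES[flags[i, ]]
    if (!length(vars)) return("")
    paste(paste(cohort$version[i], vars, sep = ":"), collapse = ";")
  }, character(1))
  ids <- unique(cohort$child_id)
  per_child <- lapply(ids, function(id) {
    sel <- cohort$child_id == id
    parts <- trig[sel][nzchar(trig[sel])]
    data.frame(child_id = id, age_years = cohort$age_years[sel][1L],
               flagged = any(nzchar(parts)),
               triggered = paste(parts, collapse = ";"),
               partial = sum(sel) < 2L)
  })
  do.call(rbind, per_child)
}

#' Questionnaire-score flag
#'
#' Rapid parental-report screen: flags when the total score over the
#' 11-question inventory subset exceeds the cutoff, i.e. several responses
#' were "always" or "often".  The strict reading (`> 15`) is the default;
#' the cutoff is configurable because the source material is ambiguous at
#' exactly 15.
#'
#' @param total_score Non-negative integer score(s).
#' @param cutoff Strict cutoff (default 15).
#' @return Logical vector: `total_score > cutoff`.
#' @export
hvfqi_flag <- function(total_score, cutoff = 15) {
  if (any(total_score < 0, na.rm = TRUE))
    stop("questionnaire score cannot be negative", call. = FALSE)
  total_score > cutoff
}

#' Classify a CVI checklist count
#'
#' Three-criterion checklist (risk factors, atypical visual behaviors,
#' verifiable dysfunction on examination): CVI is possible when two
#' criteria are met and highly likely when all three are.
#'
#' @param n_criteria_met Integer(s) in 0-3.
#' @return Factor with levels `unlikely`, `possible`, `highly_likely`.
#' @export
checklist_classify <- function(n_criteria_met) {
  ok <- is.na(n_criteria_met) |
    (n_criteria_met %in% 0:3)
  if (!all(ok))
    stop("checklist criteria met must be an integer in 0-3", call. = FALSE)
  factor(ifelse(n_criteria_met <= 1, "unlikely",
                ifelse(n_criteria_met == 2, "possible", "highly_likely")),
         levels = c("unlikely", "possible", "highly_likely"))
}

#' @export
print.screening_outcome <- function(x, ...) {
  cat(sprintf("<screening_outcome> child %s: %s%s\n", x$child_id,
              if (x$flagged) "FLAGGED for further assessment" else "within norms",
              if (x$partial) " (one version only)" else ""))
  if (nrow(x$triggered)) {
    cat("  triggered:",
        paste(x$triggered$version, x$triggered$variable, sep = ":",
              collapse = ", "), "\n")
  }
  invisible(x)
}
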