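# Scoring of the two paper-and-pencil cancellation tests used as reference
# visual-search instruments:
#
# * Teddy bear cancellation test (TBCT), untimed, ages 5-8: 15 targets and
#   60 distractors in five columns numbered 1-5 left to right.  Columns
#   carry nominal values -1, -1, 0, +1, +1.  Scores: omissions O, location
#   of omissions LO-S (sum of nominal values over omitted targets), start
#   location START-S (sum over the first three marked targets).  A result
#   is outside the normative range iff there is one or more omission.
# * Six-letter cancellation task (SLCT), ages 9+: cancel cells showing any
#   of six target letters in a 22 x 14 letter grid within 90 seconds.  Net
#   score = total cancellations - wrong cancellations; out of norm iff the
#   net score is at the reference 5th percentile or less.

TBCT_N_TARGETS <- 15L
TBCT_N_DISTRACTORS <- 60L
TBCT_N_COLUMNS <- 5L
TBCT_COLUMN_NOMINAL <- c(-1L, -1L, 0L, 1L, 1L)

SLCT_N_ROWS <- 22L
SLCT_N_COLS <- 14L
SLCT_N_TARGET_LETTERS <- 6L
SLCT_TIME_BUDGET_S <- 90

#' Construct a teddy-bear cancellation sheet
#'
#' @param items Data frame with columns `item_id` (unique), `column` (1-5),
#'   `row` (vertical position within the column) and `is_target` (logical);
#'   must hold 15 targets and 60 distractors with 3 targets and 12
#'   distractors per column.
#' @return A `tbct_sheet` object.
#' @export
tbct_sheet <- function(items) {
  items <- as.data.frame(items)
  stopifnot(all(c("item_id", "column", "row", "is_target") %in% names(items)))
  if (anyDuplicated(items$item_id)) stop("duplicate item_id", call. = FALSE)
  if (nrow(items) != TBCT_N_TARGETS + TBCT_N_DISTRACTORS)
    stop("sheet must hold 75 items", call. = FALSE)
  if (!all(items$column %in% 1:TBCT_N_COLUMNS))
    stop("columns must be 1..5", call. = FALSE)
  per_col <- table(factor(items$column, 1:TBCT_N_COLUMNS), items$is_target)
  if (!all(per_col[, "TRUE"] == 3L) || !all(per_col[, "FALSE"] == 12L))
    stop("each column must hold 3 targets and 12 distractors", call. = FALSE)
  structure(list(items = items), class = "tbct_sheet")
}

#' Construct a TBCT response
#'
#' @param marks Character vector of item ids in the order the child crossed
#'   them out; duplicates are rejected.
#' @return A `tbct_response` object.
#' @export
tbct_response <- function(marks) {
  marks <- as.character(marks)
  if (anyDuplicated(marks)) stop("duplicate marks in response", call. = FALSE)
  structure(list(marks = marks), class = "tbct_response")
}

#' Score a teddy-bear cancellation response
#'
#' @param sheet A [tbct_sheet()].
#' @param response A [tbct_response()]; every mark must reference an item on
#'   the sheet.
#' @return A `tbct_score` object with fields `O` (omissions), `LO_S`
#'   (location-of-omissions score, the sum of column nominal values over
#'   omitted targets), `START_S` (sum over the columns of the first three
#'   marked targets; marks on distractors do not count towards the first
#'   three) and `out_of_norm` (TRUE iff `O >= 1`).
#' @export
score_tbct <- function(sheet, response) {
  stopifnot(inherits(sheet, "tbct_sheet"), inherits(response, "tbct_response"))
  items <- sheet$items
  unknown <- setdiff(response$marks, items$item_id)
  if (length(unknown))
    stop("response marks unknown item(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  idx <- match(response$marks, items$item_id)
  marked_target <- items$is_target[idx]
  target_ids <- items$item_id[items$is_target]
  omitted <- setdiff(target_ids, response$marks)
  omit_cols <- items$column[match(omitted, items$item_id)]
  first3 <- idx[marked_target][seq_len(min(3L, sum(marked_target)))]
  structure(list(
    O = length(omitted),
    LO_S = sum(TBCT_COLUMN_NOMINAL[omit_cols]),
    START_S = sum(TBCT_COLUMN_NOMINAL[items$column[first3]]),
    out_of_norm = length(omitted) >= 1L
  ), class = "tbct_score")
}

#' Construct a six-letter cancellation grid
#'
#' @param cells 22 x 14 character matrix of upper-case letters.
#' @param target_letters Character vector of 6 distinct target letters.
#' @return An `slct_grid` object.
#' @export
slct_grid <- function(cells, target_letters) {
  cells <- as.matrix(cells)
  if (!all(dim(cells) == c(SLCT_N_ROWS, SLCT_N_COLS)))
    stop("grid must be 22 rows x 14 columns", call. = FALSE)
  target_letters <- as.character(target_letters)
  if (length(unique(target_letters)) != SLCT_N_TARGET_LETTERS)
    stop("exactly 6 distinct target letters required", call. = FALSE)
  structure(list(cells = cells, target_letters = target_letters),
            class = "slct_grid")
}

#' Construct an SLCT response
#'
#' @param cancellations Data frame with columns `row` and `col`, the grid
#'   coordinates marked within the 90-second window, in marking order;
#'   duplicates and off-grid coordinates are rejected.
#' @return An `slct_response` object.
#' @export
slct_response <- function(cancellations) {
  cancellations <- as.data.frame(cancellations)
  if (nrow(cancellations) == 0L)
    cancellations <- data.frame(row = integer(), col = integer())
  stopifnot(all(c("row", "col") %in% names(cancellations)))
  if (nrow(cancellations)) {
    if (!all(cancellations$row %in% 1:SLCT_N_ROWS) ||
        !all(cancellations$col %in% 1:SLCT_N_COLS))
      stop("cancellation coordinates off-grid", call. = FALSE)
    if (anyDuplicated(cancellations[c("row", "col")]))
      stop("duplicate cancellation of the same cell", call. = FALSE)
  }
  structure(list(cancellations = cancellations), class = "slct_response")
}

#' Build an empirical SLCT normative reference
#'
#' Stores, per completed age, the empirical distribution of net scores of a
#' reference (typical) population, together with the 5th-percentile cutoff
#' used for the out-of-norm decision.  The published normative tables for
#' the instrument are not redistributable; users who hold them can write
#' them in the same JSON layout, otherwise a simulated typical reference is
#' built and labelled synthetic.
#'
#' @param scores Data frame with columns `age` and `net`.
#' @param min_per_age Minimum reference sample size per age (default 20).
#' @param synthetic Logical; TRUE when the reference was simulated rather
#'   than observed (recorded in the provenance and echoed in reports).
#' @return An `slct_reference` object.
#' @export
build_slct_reference <- function(scores, min_per_age = 20L, synthetic = TRUE) {
  scores <- as.data.frame(scores)
  stopifnot(all(c("age", "net") %in% names(scores)))
  counts <- table(scores$age)
  small <- names(counts)[counts < min_per_age]
  if (length(small))
    stop("undersized SLCT reference band for age(s): ",
         paste(small, collapse = ", "), call. = FALSE)
  ages <- sort(unique(scores$age))
  bands <- lapply(ages, function(a) {
    nets <- sort(scores$net[scores$age == a])
    list(age = a, n = length(nets), nets = nets,
         cutoff_5th = as.numeric(quantile(nets, 0.05, type = 7, names = FALSE)))
  })
  names(bands) <- as.character(ages)
  structure(list(bands = bands, synthetic = synthetic,
                 convention = "linear interpolation between closest ranks, h = (n-1)p/100 + 1"),
            class = "slct_reference")
}

#' Score a six-letter cancellation response
#'
#' Net score = total cancellations minus wrong cancellations (marks on
#' non-target letters).  The percentile of the net score within the age's
#' reference distribution is computed with midpoint tie correction
#' (fraction strictly below plus half the ties, times 100).  The
#' out-of-norm decision follows the instrument's rule -- a net score at the
#' reference 5th percentile or less -- implemented as
#' `net <= cutoff_5th(age)`; on heavily tied references this rule, not the
#' midpoint rank percentile, governs.
#'
#' @param grid An [slct_grid()].
#' @param response An [slct_response()].
#' @param reference An [build_slct_reference()] object covering the age.
#' @param age Completed age in years.
#' @return An `slct_score` object with fields `total`, `wrong`, `net`,
#'   `percentile_in_reference` and `out_of_norm`.
#' @export
score_slct <- function(grid, response, reference, age) {
  stopifnot(inherits(grid, "slct_grid"), inherits(response, "slct_response"),
            inherits(reference, "slct_reference"))
  band <- reference$bands[[as.character(age)]]
  if (is.null(band))
    stop("no SLCT reference for age ", age,
         "; supply a published table or build one with build_slct_reference()",
         call. = FALSE)
  cc <- response$cancellations
  total <- nrow(cc)
  letters_marked <- grid$cells[cbind(cc$row, cc$col)]
  wrong <- sum(!letters_marked %in% grid$target_letters)
  net <- total - wrong
  nets <- band$nets
  pct <- 100 * (sum(nets < net) + 0.5 * sum(nets == net)) / length(nets)
  structure(list(total = total, wrong = as.integer(wrong), net = as.integer(net),
                 percentile_in_reference = pct,
                 out_of_norm = net <= band$cutoff_5th,
                 reference_synthetic = reference$synthetic),
            class = "slct_score")
}

#' Serialize an SLCT reference to JSON
#'
#' @param reference An `slct_reference`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_slct_reference <- function(reference, path) {
  jsonlite::write_json(unclass(reference), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an SLCT reference from JSON
#'
#' @param path Path written by [write_slct_reference()] (or a published
#'   normative table in the same layout).
#' @return An `slct_reference` object.
#' @export
read_slct_reference <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  bands <- lapply(x$bands, function(b) {
    list(age = b$age, n = b$n, nets = as.numeric(b$nets),
         cutoff_5th = b$cutoff_5th)
  })
  structure(list(bands = bands, synthetic = isTRUE(x$synthetic),
                 convention = x$convention),
            class = "slct_reference")
}

#' @export
print.tbct_score <- function(x, ...) {
  cat(sprintf("<tbct_score> O = %d, LO-S = %+d, START-S = %+d, %s\n",
              x$O, x$LO_S, x$START_S,
              if (x$out_of_norm) "outside normative range" else "within norms"))
  invisible(x)
}

#' @export
print.slct_score <- function(x, ...) {
  cat(sprintf("<slct_score> net = %d (total %d - wrong %d), percentile %.1f, %s%s\n",
              x$net, x$total, x$wrong, x$percentile_in_reference,
              if (x$out_of_norm) "outside normative range" else "within norms",
              if (isTRUE(x$reference_synthetic)) " [synthetic reference]" else ""))
  invisible(x)
}
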