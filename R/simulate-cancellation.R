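# Response simulators for the two cancellation tests, driven by the same
# latent deficit profile as the card-matching simulator.  These are response
# models of the package's own design: the published instruments specify the
# layouts and scoring, not a generative mechanism.

#' Generate a teddy-bear cancellation sheet
#'
#' Lays out 15 targets and 60 distractors proportionally over five columns
#' (3 targets and 12 distractors each) in a pseudo-random vertical order.
#' Only the counts and the column structure of the published instrument are
#' preserved; the exact printed layout is not reproduced.
#'
#' @return A [tbct_sheet()].
#' @export
generate_tbct_sheet <- function() {
  per_col <- TBCT_N_TARGETS / TBCT_N_COLUMNS + TBCT_N_DISTRACTORS / TBCT_N_COLUMNS
  items <- do.call(rbind, lapply(1:TBCT_N_COLUMNS, function(col) {
    is_target <- sample(c(rep(TRUE, 3L), rep(FALSE, 12L)))
    data.frame(item_id = sprintf("c%d_r%02d", col, seq_len(per_col)),
               column = col, row = seq_len(per_col), is_target = is_target)
  }))
  tbct_sheet(items)
}

#' Simulate a TBCT response
#'
#' Each target is omitted with a probability increasing in deficit severity
#' and optionally biased laterally; the marking order follows a noisy
#' column-wise scan from a start column whose draw is biased away from the
#' left margin as severity grows (typical children start at the left, as
#' the examiner models on the top-left target).
#'
#' @param sheet A [tbct_sheet()].
#' @param profile A [latent_profile()].
#' @param base_omit_prob Omission probability of a typical child per target
#'   (default 0.02).
#' @param omit_severity_logit Logit-scale increase of the omission
#'   probability at severity 1 (default 2.5).
#' @param lateral_bias Rightward attention bias: positive values
#'   concentrate omissions in the left (nominal value -1) columns
#'   (default 0).
#' @param order_noise_sd Standard deviation of the vertical scan noise, in
#'   row units, added on top of a severity-dependent term (default 0.5).
#' @return A [tbct_response()].
#' @export
simulate_tbct_response <- function(sheet, profile,
                                   base_omit_prob = 0.02,
                                   omit_severity_logit = 2.5,
                                   lateral_bias = 0,
                                   order_noise_sd = 0.5) {
  stopifnot(inherits(sheet, "tbct_sheet"), inherits(profile, "latent_profile"))
  items <- sheet$items
  sev <- profile$severity
  targets <- items[items$is_target, , drop = FALSE]
  p_omit <- plogis(qlogis(base_omit_prob) + omit_severity_logit * sev -
                     lateral_bias * TBCT_COLUMN_NOMINAL[targets$column])
  omitted <- runif(nrow(targets)) < p_omit
  marked <- targets[!omitted, , drop = FALSE]
  if (nrow(marked) == 0L) return(tbct_response(character()))

  start_col <- sample(1:TBCT_N_COLUMNS, 1L,
                      prob = exp(-(2 - 1.5 * sev) * (0:(TBCT_N_COLUMNS - 1L))))
  # visit columns by distance from the start column, right before left on ties
  col_order <- order(abs(1:TBCT_N_COLUMNS - start_col),
                     -(1:TBCT_N_COLUMNS))
  scan_key <- match(marked$column, col_order) * 100 +
    marked$row + stats::rnorm(nrow(marked), sd = order_noise_sd + 2 * sev)
  tbct_response(marked$item_id[order(scan_key)])
}

#' Generate a six-letter cancellation grid
#'
#' 22 x 14 cells of uniformly drawn upper-case letters with six distinct
#' target letters.
#'
#' @param target_letters Optional character vector of 6 distinct letters;
#'   sampled from the alphabet when `NULL`.
#' @return An [slct_grid()].
#' @export
generate_slct_grid <- function(target_letters = NULL) {
  if (is.null(target_letters))
    target_letters <- sample(LETTERS, SLCT_N_TARGET_LETTERS)
  cells <- matrix(sample(LETTERS, SLCT_N_ROWS * SLCT_N_COLS, replace = TRUE),
                  nrow = SLCT_N_ROWS)
  slct_grid(cells, target_letters)
}

#' Simulate an SLCT response
#'
#' The child scans the grid in reading order, spending a lognormal time per
#' cell whose median scales with the same age speed factor and deficit
#' multiplier as the card-matching simulator, until the 90-second budget is
#' exhausted.  Scanned target cells are cancelled unless missed; scanned
#' non-target cells are wrongly cancelled with a severity-dependent
#' confusion probability.
#'
#' @param grid An [slct_grid()].
#' @param profile A [latent_profile()].
#' @param age Completed age in years (default 11, the simulator's reference
#'   age).
#' @param config A [sim_config()]; supplies the age speed factor (via the
#'   single-colored slope) and the deficit time multiplier.
#' @param item_scan_median_s Median per-cell scan time of a typical child
#'   at the reference age (default 0.5 s).
#' @param scan_sigma Lognormal sigma of per-cell scan times (default 0.4).
#' @param base_miss_prob Probability a typical child fails to cancel a
#'   scanned target (default 0.02).
#' @param miss_severity_logit Logit-scale increase of the miss probability
#'   at severity 1 (default 2).
#' @param base_confusion_prob Probability a typical child wrongly cancels a
#'   scanned non-target (default 0.005).
#' @param confusion_severity_logit Logit-scale increase of the confusion
#'   probability at severity 1 (default 2.5).
#' @param time_budget_s Scanning budget in seconds (default 90).
#' @return An [slct_response()].
#' @export
simulate_slct_response <- function(grid, profile, age = 11,
                                   config = sim_config(),
                                   item_scan_median_s = 0.5,
                                   scan_sigma = 0.4,
                                   base_miss_prob = 0.02,
                                   miss_severity_logit = 2,
                                   base_confusion_prob = 0.005,
                                   confusion_severity_logit = 2.5,
                                   time_budget_s = SLCT_TIME_BUDGET_S) {
  stopifnot(inherits(grid, "slct_grid"), inherits(profile, "latent_profile"))
  if (age < AGE_MIN || age > AGE_MAX)
    stop(sprintf("age %s outside %d-%d", age, AGE_MIN, AGE_MAX), call. = FALSE)
  sev <- profile$severity
  n_cells <- SLCT_N_ROWS * SLCT_N_COLS
  med <- item_scan_median_s *
    .age_factor(age, config$age_slope_single_s_per_year, config) *
    (1 + sev * (config$deficit_time_multiplier - 1))
  scan_t <- if (med == 0) rep(0, n_cells)
            else rlnorm(n_cells, meanlog = log(med), sdlog = scan_sigma)
  # reading order: row-major across the grid
  rows <- rep(1:SLCT_N_ROWS, each = SLCT_N_COLS)
  cols <- rep(1:SLCT_N_COLS, times = SLCT_N_ROWS)
  scanned <- cumsum(scan_t) <= time_budget_s
  is_target <- grid$cells[cbind(rows, cols)] %in% grid$target_letters
  p_miss <- plogis(qlogis(base_miss_prob) + miss_severity_logit * sev)
  p_conf <- plogis(qlogis(base_confusion_prob) + confusion_severity_logit * sev)
  u <- runif(n_cells)
  cancel <- scanned & ((is_target & u >= p_miss) | (!is_target & u < p_conf))
  slct_response(data.frame(row = rows[cancel], col = cols[cancel]))
}

#' Simulate a typical-population SLCT reference
#'
#' Convenience wrapper: simulates `n_per_age` typical responses per age on
#' fresh grids and builds the per-age normative reference from the net
#' scores.  The result is flagged synthetic.
#'
#' @param ages Integer ages to cover (default 9:18).
#' @param n_per_age Simulated children per age (default 200).
#' @param config A [sim_config()].
#' @param ... Passed on to [simulate_slct_response()].
#' @return An `slct_reference` object.
#' @export
simulate_slct_reference <- function(ages = 9:18, n_per_age = 200L,
                                    config = sim_config(), ...) {
  typical <- latent_profile(FALSE)
  scores <- do.call(rbind, lapply(ages, function(a) {
    nets <- vapply(seq_len(n_per_age), function(i) {
      grid <- generate_slct_grid()
      resp <- simulate_slct_response(grid, typical, age = a, config = config, ...)
      cc <- resp$cancellations
      wrong <- sum(!grid$cells[cbind(cc$row, cc$col)] %in% grid$target_letters)
      as.integer(nrow(cc) - wrong)
    }, integer(1))
    data.frame(age = a, net = nets)
  }))
  build_slct_reference(scores, min_per_age = min(n_per_age, 20L),
                       synthetic = TRUE)
}
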