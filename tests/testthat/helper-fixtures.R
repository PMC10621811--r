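# In-code fixtures and independent oracles shared across the suite.

# One valid cohort row.  Defaults: fully accurate run, level times 5..13 s,
# dwell 1 s per level.
make_run_row <- function(child_id = "c1", age = 10L, version = "single",
                         gender = "female", conditions = "none",
                         truth_label = NA_character_,
                         dwell = rep(1, 5),
                         level_time = c(5, 7, 9, 11, 13),
                         correct = 1:5) {
  row <- data.frame(child_id = child_id, age_years = as.integer(age),
                    gender = gender, conditions = conditions,
                    truth_label = truth_label, version = version,
                    stringsAsFactors = FALSE)
  for (k in 1:5) {
    row[[paste0("level_time_l", k)]] <- level_time[k]
    row[[paste0("dwell_l", k)]] <- dwell[k]
    row[[paste0("correct_pairs_l", k)]] <- as.integer(correct[k])
  }
  row$overall_time_s <- round(sum(level_time), 3)
  row$mean_dwell_s <- round(mean(dwell), 3)
  row$accurate_rounds <- as.integer(sum(correct == 1:5))
  row
}

make_cohort <- function(...) new_cohort(do.call(rbind, list(...)))

# Cohort in which every (age group x version) cell carries the same given
# overall times (one child per value); level times are overall/5 each so the
# derived columns are exact at millisecond resolution.
make_percentile_cohort <- function(overall_times) {
  stopifnot(all(abs(overall_times * 200 - round(overall_times * 200)) < 1e-9))
  ages <- c(`5-8` = 6L, `9-12` = 10L, `13-18` = 15L)
  rows <- list()
  for (g in names(ages)) {
    for (v in c("multi", "single")) {
      for (i in seq_along(overall_times)) {
        lt <- rep(overall_times[i] / 5, 5)
        rows[[length(rows) + 1L]] <- make_run_row(
          child_id = sprintf("%s_%s_%03d", g, v, i), age = ages[[g]],
          version = v, dwell = rep(min(0.1, lt[1]), 5), level_time = lt)
      }
    }
  }
  new_cohort(do.call(rbind, rows))
}

# Hand-built threshold set covering all six cells with the same cutoffs.
make_thresholds <- function(overall = 30, dwell = 3, accuracy = 4L,
                            percentile = c(`5-8` = 85, `9-12` = 95, `13-18` = 95)) {
  cells <- expand.grid(age_group = c("5-8", "9-12", "13-18"),
                       version = c("multi", "single"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ts <- data.frame(cells,
                   percentile_level = percentile[cells$age_group],
                   overall_time_threshold_s = overall,
                   dwell_threshold_s = dwell,
                   accuracy_cutoff = as.integer(accuracy),
                   n = NA_integer_)
  class(ts) <- c("threshold_set", "data.frame")
  ts
}

# Brute-force percentile oracle: sort and interpolate between closest ranks
# with h = (n - 1) * p / 100 + 1.
pct_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p / 100 + 1
  fl <- floor(h)
  if (fl >= n) return(x[n])
  x[fl] + (h - fl) * (x[fl + 1] - x[fl])
}

# Expand a 2x2 table's counts into aligned reference/index flag vectors.
flags_from_counts <- function(a, b, c, d) {
  ref <- c(rep(TRUE, a + b), rep(FALSE, c + d))
  idx <- c(rep(TRUE, a), rep(FALSE, b), rep(TRUE, c), rep(FALSE, d))
  names(ref) <- names(idx) <- sprintf("k%03d", seq_along(ref))
  list(reference = ref, index = idx)
}
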