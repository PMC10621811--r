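# Age-stratified normative thresholds and the age trend of overall time.
#
# Published threshold values for the screener are proprietary; thresholds
# here are always an artifact of the supplied reference cohort.  Percentile
# convention: linear interpolation between closest ranks with
# h = (n - 1) * p / 100 + 1 (stats::quantile type 7), recorded in the
# threshold set's provenance so thresholds are reproducible bit-for-bit.

#' Assign the normative age group
#'
#' The reference cohort's overall-time scatter separates into three
#' groupings: ages 5-8, 9-12 and 13-18.
#'
#' @param age Integer age(s) in completed years.
#' @return Factor with levels `"5-8"`, `"9-12"`, `"13-18"`.
#' @export
assign_age_group <- function(age) {
  if (any(is.na(age)) || any(age != round(age)))
    stop("age must be given in whole completed years", call. = FALSE)
  if (any(age < AGE_MIN | age > AGE_MAX))
    stop(sprintf("age outside the studied range %d-%d: %s", AGE_MIN, AGE_MAX,
                 paste(age[age < AGE_MIN | age > AGE_MAX], collapse = ", ")),
         call. = FALSE)
  cut(age, breaks = c(4, 8, 12, 18), labels = AGE_GROUPS)
}

#' Percentile levels per age group
#'
#' Default normative policy: the 5-8 group uses the 85th percentile (its
#' time distribution is much more spread out), the older groups the 95th.
#'
#' @return Named numeric vector over the three age groups.
#' @export
default_percentile_levels <- function() {
  c(`5-8` = 85, `9-12` = 95, `13-18` = 95)
}

#' Estimate age-stratified normative thresholds
#'
#' For each (age group x version) cell, the overall-time threshold is the
#' cell's configured percentile of `overall_time_s` and the dwell threshold
#' the same percentile of `mean_dwell_s`.  The accuracy cutoff (fewer than
#' `accuracy_cutoff` accurate rounds flags) applies identically to every
#' cell.
#'
#' @param cohort A `cohort` object (the normative reference population).
#' @param percentile_levels Named vector of percentile levels per age group;
#'   see [default_percentile_levels()].
#' @param accuracy_cutoff Integer; a run with fewer accurate rounds than
#'   this is outside the norm (default 4).
#' @param min_cell_size Minimum runs per cell (default 20).
#' @return A `threshold_set`: a data frame with one row per cell
#'   (`age_group`, `version`, `percentile_level`,
#'   `overall_time_threshold_s`, `dwell_threshold_s`, `accuracy_cutoff`)
#'   plus a `provenance` attribute (cell sizes, percentile convention,
#'   reference-cohort MD5 hash).
#' @export
estimate_thresholds <- function(cohort,
                                percentile_levels = default_percentile_levels(),
                                accuracy_cutoff = 4L,
                                min_cell_size = 20L) {
  validate_cohort(cohort)
  if (!setequal(names(percentile_levels), AGE_GROUPS))
    stop("percentile_levels must be named over ", paste(AGE_GROUPS, collapse = ", "),
         call. = FALSE)
  grp <- assign_age_group(cohort$age_years)
  cells <- expand.grid(age_group = AGE_GROUPS, version = VERSIONS,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    g <- cells$age_group[i]; v <- cells$version[i]
    sel <- grp == g & cohort$version == v
    n <- sum(sel)
    if (n < min_cell_size)
      stop(sprintf("normative cell (%s, %s) has %d run(s); need at least %d",
                   g, v, n, min_cell_size), call. = FALSE)
    p <- percentile_levels[[g]] / 100
    data.frame(age_group = g, version = v,
               percentile_level = percentile_levels[[g]],
               overall_time_threshold_s =
                 quantile(cohort$overall_time_s[sel], p, type = 7, names = FALSE),
               dwell_threshold_s =
                 quantile(cohort$mean_dwell_s[sel], p, type = 7, names = FALSE),
               accuracy_cutoff = as.integer(accuracy_cutoff),
               n = n)
  })
  ts <- do.call(rbind, rows)
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write_cohort(cohort, tmp)
  attr(ts, "provenance") <- list(
    convention = "linear interpolation between closest ranks, h = (n-1)p/100 + 1",
    reference_cohort_md5 = unname(tools::md5sum(tmp)),
    n_runs = nrow(cohort))
  class(ts) <- c("threshold_set", "data.frame")
  ts
}

#' Serialize a threshold set to JSON
#'
#' @param thresholds A `threshold_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_threshold_set <- function(thresholds, path) {
  payload <- list(cells = as.data.frame(thresholds),
                  provenance = attr(thresholds, "provenance"))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a threshold set from JSON
#'
#' @param path Path written by [write_threshold_set()].
#' @return A `threshold_set` object.
#' @export
read_threshold_set <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ts <- as.data.frame(x$cells)
  attr(ts, "provenance") <- x$provenance
  class(ts) <- c("threshold_set", "data.frame")
  ts
}

#' Fit the age trend of overall completion time
#'
#' Ordinary least squares of overall time (seconds) on age (years) over one
#' version's runs, reporting the slope, intercept, F statistic, degrees of
#' freedom, R-squared and the slope's two-sided p-value.
#'
#' @param cohort A `cohort` object.
#' @param version `"multi"` or `"single"`.
#' @return An `age_trend_fit` object.
#' @export
fit_age_trend <- function(cohort, version = c("multi", "single")) {
  version <- match.arg(version)
  validate_cohort(cohort)
  d <- cohort[cohort$version == version, , drop = FALSE]
  if (length(unique(d$age_years)) < 3L)
    stop("need at least 3 distinct ages to fit an age trend", call. = FALSE)
  fit <- lm(overall_time_s ~ age_years, data = d)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  structure(list(
    version = version,
    slope_s_per_year = unname(coef(fit)["age_years"]),
    intercept_s = unname(coef(fit)["(Intercept)"]),
    F_statistic = unname(fstat["value"]),
    df = unname(fstat[c("numdf", "dendf")]),
    R_squared = sm$r.squared,
    p_value = unname(sm$coefficients["age_years", "Pr(>|t|)"]),
    n = nrow(d)
  ), class = "age_trend_fit")
}

#' @export
print.age_trend_fit <- function(x, ...) {
  cat(sprintf("<age_trend_fit> %s-colored version, n = %d\n", x$version, x$n))
  cat(sprintf("  overall time changes by %.2f s per year of age\n",
              x$slope_s_per_year))
  cat(sprintf("  F(%d, %d) = %.3f, R^2 = %.3f, p = %.3g\n",
              x$df[1], x$df[2], x$F_statistic, x$R_squared, x$p_value))
  invisible(x)
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("<threshold_set> normative cutoffs per (age group x version)\n")
  print(as.data.frame(x))
  prov <- attr(x, "provenance")
  if (!is.null(prov)) cat("  percentile convention:", prov$convention, "\n")
  invisible(x)
}
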