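# Cohort simulator.
#
# Generative mechanism: serial self-terminating visual search.  A child
# inspects cards one at a time; each inspection consumes a lognormal time
# whose median is the product of a per-card baseline, an age speed factor, a
# between-child speed factor, and a deficit multiplier.  Locating pair k of a
# level with C cards costs C - 2(k-1) inspections (every still-unmatched card
# is inspected once on average before the pair closes), so the five levels
# cost 4, 10, 18, 28 and 40 inspections and a full run costs 100.  The dwell
# time of a level is the first pair's search time; the level time is the sum
# over its pairs.
#
# The age factor is calibrated so the cohort-level expectation of overall
# time is exactly linear in age with the configured slope:
#   E[overall | age] = T_ref + slope * (age - reference_age),
# where T_ref = 100 * per_card_median * exp(sigma^2 / 2) is the within-child
# expected run time at the reference age.  A deficit child's inspection
# median is multiplied by 1 + severity * (deficit_time_multiplier - 1), i.e.
# a severity-1 deficit doubles expected times under the default multiplier 2.
#
# Pair placements are incorrect with a logistic probability in severity and
# card count, so deficit children are both slower and less accurate, and
# accuracy worsens with display complexity.

# Age composition of the 724-child reference cohort used to develop the
# screener's norms (counts for completed ages 5..18); the default sampling
# weights for simulated cohorts.
REFERENCE_AGE_COUNTS <- c(`5` = 58, `6` = 97, `7` = 67, `8` = 70, `9` = 70,
                          `10` = 50, `11` = 77, `12` = 72, `13` = 43,
                          `14` = 35, `15` = 28, `16` = 24, `17` = 27, `18` = 6)

# Gender split of the same reference cohort (334 / 385 / 5 of 724).
REFERENCE_GENDER_PROBS <- c(female = 334, male = 385, unspecified = 5) / 724

#' Simulation configuration
#'
#' Bundles and validates every knob of the cohort simulator.  Defaults state
#' the conditions the screener's development cohort reported: overall
#' completion time falling by 3.34 s per year of age on the single-colored
#' version and 2.83 s per year on the multi-colored version, a deficit group
#' that takes twice as long at every level and mismatches more pairs, a CVI
#' prevalence of 3.4% in mainstream education, and the reference cohort's
#' age and gender composition.
#'
#' @param n_children Number of simulated children.
#' @param age_weights Named non-negative weights over integer ages 5-18
#'   (default: the reference cohort's age counts).
#' @param deficit_prevalence Probability that a child carries the latent
#'   visual-search deficit (default 0.034).
#' @param deficit_severity Severity in `[0, 1]` assigned to deficit children
#'   (default 1; scales both the time multiplier and the mismatch boost).
#' @param deficit_time_multiplier Factor by which a severity-1 deficit
#'   multiplies expected search times (default 2).
#' @param deficit_mismatch_boost Logit-scale increase of the per-pair
#'   mismatch probability at severity 1 (default 3).
#' @param age_slope_single_s_per_year,age_slope_multi_s_per_year Target
#'   cohort-level slopes of overall time on age, in seconds per year
#'   (defaults -3.34 and -2.83).
#' @param per_card_inspection_median_s Median single-card inspection time of
#'   a typical child at the reference age (default 0.38 s, giving a ~40 s
#'   expected run).
#' @param inspection_lognormal_sigma Within-run lognormal sigma of
#'   inspection times (default 0.35).
#' @param child_speed_sigma Between-child lognormal sigma of the shared
#'   latent speed factor (default 0.30; both versions of a child's
#'   assessment share the factor).
#' @param base_mismatch_prob Per-pair mismatch probability of a typical
#'   child at 4 cards (default 0.01).
#' @param mismatch_card_logit Logit increase in mismatch probability per
#'   card beyond 4 (default 0.12).
#' @param reference_age Age (years) at which the per-card baseline is
#'   anchored (default 11).
#' @param seed Integer seed; identical configs reproduce byte-identical
#'   cohorts.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(n_children = 724L,
                       age_weights = REFERENCE_AGE_COUNTS,
                       deficit_prevalence = 0.034,
                       deficit_severity = 1,
                       deficit_time_multiplier = 2,
                       deficit_mismatch_boost = 3,
                       age_slope_single_s_per_year = -3.34,
                       age_slope_multi_s_per_year = -2.83,
                       per_card_inspection_median_s = 0.38,
                       inspection_lognormal_sigma = 0.35,
                       child_speed_sigma = 0.30,
                       base_mismatch_prob = 0.01,
                       mismatch_card_logit = 0.12,
                       reference_age = 11,
                       seed = 1L) {
  cfg <- list(n_children = as.integer(n_children), age_weights = age_weights,
              deficit_prevalence = deficit_prevalence,
              deficit_severity = deficit_severity,
              deficit_time_multiplier = deficit_time_multiplier,
              deficit_mismatch_boost = deficit_mismatch_boost,
              age_slope_single_s_per_year = age_slope_single_s_per_year,
              age_slope_multi_s_per_year = age_slope_multi_s_per_year,
              per_card_inspection_median_s = per_card_inspection_median_s,
              inspection_lognormal_sigma = inspection_lognormal_sigma,
              child_speed_sigma = child_speed_sigma,
              base_mismatch_prob = base_mismatch_prob,
              mismatch_card_logit = mismatch_card_logit,
              reference_age = reference_age, seed = as.integer(seed))
  if (cfg$n_children < 1L) stop("n_children must be positive", call. = FALSE)
  if (!setequal(names(cfg$age_weights), as.character(AGE_MIN:AGE_MAX)))
    stop("age_weights must be named with every age 5..18", call. = FALSE)
  if (any(cfg$age_weights < 0) || sum(cfg$age_weights) <= 0)
    stop("age_weights must be non-negative with positive sum", call. = FALSE)
  for (p in c("deficit_prevalence", "deficit_severity")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop(p, " must lie in [0, 1]", call. = FALSE)
  }
  for (p in c("deficit_time_multiplier", "per_card_inspection_median_s",
              "inspection_lognormal_sigma")) {
    if (cfg[[p]] <= 0) stop(p, " must be positive", call. = FALSE)
  }
  if (cfg$child_speed_sigma < 0)
    stop("child_speed_sigma must be non-negative", call. = FALSE)
  if (cfg$base_mismatch_prob <= 0 || cfg$base_mismatch_prob >= 1)
    stop("base_mismatch_prob must lie in (0, 1)", call. = FALSE)
  # the age factor must stay positive across 5..18 for both versions
  for (sl in c(cfg$age_slope_single_s_per_year, cfg$age_slope_multi_s_per_year)) {
    if (any(.age_factor(AGE_MIN:AGE_MAX, sl, cfg) <= 0))
      stop("age slope too steep: expected time non-positive inside 5..18",
           call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Latent visual-search profile
#'
#' @param deficit Logical; does the child carry the latent deficit?
#' @param severity Severity in `[0, 1]`; must be 0 when `deficit` is FALSE.
#' @return A `latent_profile` object.
#' @export
latent_profile <- function(deficit = FALSE, severity = if (deficit) 1 else 0) {
  if (!deficit && severity != 0)
    stop("severity must be 0 for a non-deficit profile", call. = FALSE)
  if (severity < 0 || severity > 1)
    stop("severity must lie in [0, 1]", call. = FALSE)
  structure(list(deficit = isTRUE(deficit), severity = severity),
            class = "latent_profile")
}

# Expected run time (s) of a typical child at the reference age.
.reference_run_time <- function(cfg) {
  100 * cfg$per_card_inspection_median_s *
    exp(cfg$inspection_lognormal_sigma^2 / 2)
}

# Multiplicative age speed factor making E[overall | age] linear with the
# configured slope.
.age_factor <- function(age, slope, cfg) {
  1 + slope * (age - cfg$reference_age) / .reference_run_time(cfg)
}

# Inspections needed per pair, and the level each pair belongs to.
PAIR_INSPECTIONS <- unlist(lapply(1:5, function(L) LEVEL_CARDS[L] - 2 * (0:(L - 1))))
PAIR_LEVEL <- rep(1:5, times = 1:5)

# Vectorised run generator: one version, n children.
.sim_runs <- function(child_id, age, severity, speed, version, cfg) {
  n <- length(age)
  slope <- if (version == "single") cfg$age_slope_single_s_per_year
           else cfg$age_slope_multi_s_per_year
  med <- cfg$per_card_inspection_median_s * .age_factor(age, slope, cfg) *
    (1 + severity * (cfg$deficit_time_multiplier - 1)) * speed
  insp <- matrix(rlnorm(n * 100L, meanlog = log(med),
                        sdlog = cfg$inspection_lognormal_sigma), nrow = n)
  # sum inspections into the 15 pair-search times
  stop_idx <- cumsum(PAIR_INSPECTIONS)
  start_idx <- c(1L, stop_idx[-length(stop_idx)] + 1L)
  pair_time <- vapply(seq_along(PAIR_INSPECTIONS), function(j) {
    rowSums(insp[, start_idx[j]:stop_idx[j], drop = FALSE])
  }, numeric(n))
  if (n == 1L) pair_time <- matrix(pair_time, nrow = 1L)

  out <- data.frame(child_id = child_id, age_years = as.integer(age),
                    stringsAsFactors = FALSE)
  for (L in 1:5) {
    cols <- which(PAIR_LEVEL == L)
    out[[paste0("level_time_l", L)]] <-
      round(rowSums(pair_time[, cols, drop = FALSE]), 3)
    out[[paste0("dwell_l", L)]] <- round(pair_time[, cols[1L]], 3)
    p_mis <- plogis(qlogis(cfg$base_mismatch_prob) +
                      cfg$deficit_mismatch_boost * severity +
                      cfg$mismatch_card_logit * (LEVEL_CARDS[L] - 4))
    out[[paste0("correct_pairs_l", L)]] <-
      LEVEL_PAIRS[L] - rbinom(n, LEVEL_PAIRS[L], p_mis)
  }
  out$version <- version
  out
}

#' Simulate one assessment run
#'
#' Draws a single run of the card-matching task from the serial-search model
#' for a child with the given latent profile.
#'
#' @param profile A [latent_profile()].
#' @param age Completed age in years, 5-18.
#' @param version `"multi"` or `"single"`.
#' @param config A [sim_config()].
#' @param speed_factor Optional between-child speed factor; drawn from the
#'   configured lognormal when `NULL`.
#' @return An `assessment_run` object.
#' @export
simulate_run <- function(profile, age, version = c("multi", "single"),
                         config = sim_config(), speed_factor = NULL) {
  version <- match.arg(version)
  if (age < AGE_MIN || age > AGE_MAX)
    stop(sprintf("age %s outside %d-%d", age, AGE_MIN, AGE_MAX), call. = FALSE)
  if (is.null(speed_factor)) {
    sc <- config$child_speed_sigma
    speed_factor <- rlnorm(1L, meanlog = -sc^2 / 2, sdlog = sc)
  }
  df <- .sim_runs("sim", age, profile$severity, speed_factor, version, config)
  df$gender <- "unspecified"
  df$conditions <- if (profile$deficit) "cvi" else "none"
  df$truth_label <- if (profile$deficit) "deficit" else "typical"
  df <- cbind(df, .derive_run_summaries(df))
  assessment_run(new_cohort(df)[1L, , drop = FALSE])
}

#' Simulate a paired-assessment cohort
#'
#' Generates `n_children` children, each assessed with both the
#' multi-colored and single-colored versions of the task.  Both versions of
#' a child share one latent speed factor and one latent deficit profile.
#' Deficit children are tagged `cvi` in the conditions field and `deficit`
#' in the truth label.
#'
#' @param config A [sim_config()].
#' @return A list with elements `cohort` (a `cohort` object, 2 rows per
#'   child) and `manifest` (the full configuration plus package version,
#'   suitable for JSON serialization).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_children
  ages <- sample(AGE_MIN:AGE_MAX, n, replace = TRUE,
                 prob = config$age_weights[as.character(AGE_MIN:AGE_MAX)])
  deficit <- runif(n) < config$deficit_prevalence
  severity <- ifelse(deficit, config$deficit_severity, 0)
  sc <- config$child_speed_sigma
  speed <- rlnorm(n, meanlog = -sc^2 / 2, sdlog = sc)
  gender <- sample(names(REFERENCE_GENDER_PROBS), n, replace = TRUE,
                   prob = REFERENCE_GENDER_PROBS)
  ids <- sprintf("C%04d", seq_len(n))

  runs <- rbind(.sim_runs(ids, ages, severity, speed, "multi", config),
                .sim_runs(ids, ages, severity, speed, "single", config))
  runs$gender <- rep(gender, 2L)
  runs$conditions <- rep(ifelse(deficit, "cvi", "none"), 2L)
  runs$truth_label <- rep(ifelse(deficit, "deficit", "typical"), 2L)
  runs <- cbind(runs, .derive_run_summaries(runs))
  runs <- runs[order(match(runs$child_id, ids), runs$version), ]
  cohort <- new_cohort(runs)

  manifest <- list(config = unclass(config),
                   package = "cviscreen",
                   package_version = as.character(utils::packageVersion("cviscreen")))
  list(cohort = cohort, manifest = manifest)
}
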