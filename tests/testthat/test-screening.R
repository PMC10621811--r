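run_from_row <- function(...) assessment_run(make_run_row(...))

test_that("single-run evaluation honours all three triggers and strictness", {
  ts <- make_thresholds(overall = 45, dwell = 1)
  # accuracy: fewer than 4 accurate rounds flags even with times in norm
  slow_hands <- run_from_row(correct = c(1, 1, 2, 4, 5), dwell = rep(1, 5))
  expect_equal(evaluate_run(slow_hands, ts), "accuracy")

  # boundary: values exactly at threshold do not flag (strict inequality)
  at_threshold <- run_from_row()  # overall 45, mean dwell 1, 5 accurate
  expect_length(evaluate_run(at_threshold, ts), 0L)

  # overall time above the cell threshold flags on that variable alone
  slow <- run_from_row(level_time = c(6, 8, 10, 12, 14), dwell = rep(1, 5))
  expect_equal(evaluate_run(slow, ts), "overall_time")

  # missing cell is an error
  expect_error(evaluate_run(at_threshold, ts[ts$version == "multi", ]),
               "no threshold cell")
})

test_that("a child is flagged when any of the six thresholds triggers", {
  ts <- make_thresholds(overall = 45, dwell = 1)
  both_ok <- as_paired(make_cohort(make_run_row("c1", version = "multi"),
                                   make_run_row("c1", version = "single")))$c1
  out <- screen_child(both_ok, ts)
  expect_false(out$flagged)
  expect_false(out$partial)

  single_only <- as_paired(make_cohort(
    make_run_row("c2", version = "single",
                 level_time = c(6, 8, 10, 12, 14))))$c2
  out <- screen_child(single_only, ts)
  expect_true(out$flagged)
  expect_true(out$partial)
  expect_equal(out$triggered,
               data.frame(version = "single", variable = "overall_time"))

  # union semantics across versions and variables
  two_hits <- as_paired(make_cohort(
    make_run_row("c3", version = "multi", correct = c(0, 1, 2, 3, 4)),
    make_run_row("c3", version = "single", dwell = rep(1.5, 5))))$c3
  out <- screen_child(two_hits, ts)
  expect_true(out$flagged)
  expect_equal(nrow(out$triggered), 2L)
  expect_setequal(out$triggered$variable, c("accuracy", "dwell"))
})

test_that("worsening performance never removes a trigger", {
  ts <- make_thresholds(overall = 40, dwell = 1.2)
  set.seed(42)
  for (i in 1:25) {
    lt <- round(runif(5, 5, 12), 3)
    dw <- round(pmin(runif(5, 0.5, 3), lt), 3)
    correct <- pmin(1:5, rpois(5, 4))
    base <- run_from_row(level_time = lt, dwell = dw, correct = correct)
    worse <- run_from_row(level_time = lt + 2, dwell = dw + 0.5,
                          correct = pmax(correct - 1L, 0L))
    expect_true(all(evaluate_run(base, ts) %in% evaluate_run(worse, ts)))
  }
})

test_that("screen_cohort agrees with per-child screening", {
  sim <- simulate_cohort(sim_config(n_children = 80, seed = 9,
                                    deficit_prevalence = 0.2))
  ts <- estimate_thresholds(sim$cohort, min_cell_size = 2)
  report <- screen_cohort(sim$cohort, ts)
  paired <- as_paired(sim$cohort)
  for (i in seq_len(nrow(report))) {
    expect_identical(report$flagged[i],
                     screen_child(paired[[report$child_id[i]]], ts)$flagged)
  }
})

test_that("in-sample flag rates match the nominal percentile tails", {
  sim <- simulate_cohort(sim_config(n_children = 900, seed = 16,
                                    deficit_prevalence = 0))
  co <- sim$cohort
  ts <- estimate_thresholds(co)
  grp <- as.character(assign_age_group(co$age_years))
  for (g in c("5-8", "9-12")) {
    for (v in c("multi", "single")) {
      sel <- grp == g & co$version == v
      cell <- ts[ts$age_group == g & ts$version == v, ]
      rate <- mean(co$overall_time_s[sel] > cell$overall_time_threshold_s)
      nominal <- 1 - cell$percentile_level / 100
      expect_lt(abs(rate - nominal), 3 * sqrt(nominal * (1 - nominal) / sum(sel)))
    }
  }
})

test_that("screening separates severity-1 deficit from typical children", {
  norm <- simulate_cohort(sim_config(n_children = 400, seed = 61,
                                     deficit_prevalence = 0))$cohort
  ts <- estimate_thresholds(norm)
  deficit <- simulate_cohort(sim_config(n_children = 200, seed = 62,
                                        deficit_prevalence = 1))$cohort
  typical <- simulate_cohort(sim_config(n_children = 200, seed = 63,
                                        deficit_prevalence = 0))$cohort
  sens <- mean(screen_cohort(deficit, ts)$flagged)
  expect_gte(sens, 0.9)
  # typical false-positive rate stays near the union of the nominal tails
  fpr <- mean(screen_cohort(typical, ts)$flagged)
  expect_lt(fpr, 0.35)
})

test_that("questionnaire flag is strict and the checklist map is fixed", {
  expect_true(hvfqi_flag(30))
  expect_false(hvfqi_flag(15))
  expect_false(hvfqi_flag(0))
  expect_error(hvfqi_flag(-1), "negative")

  expect_equal(as.character(checklist_classify(3)), "highly_likely")
  expect_equal(as.character(checklist_classify(2)), "possible")
  expect_equal(as.character(checklist_classify(c(0, 1))), rep("unlikely", 2))
  expect_error(checklist_classify(4), "0-3")

  # among the screening follow-up children with checklist >= 2, the strict
  # score cutoff (> 15) captures 7 and the inclusive one (>= 15) captures 8
  fx <- screening_findings()
  likely <- fx[!is.na(fx$checklist_met) & fx$checklist_met >= 2, ]
  expect_equal(nrow(likely), 10L)
  expect_equal(sum(hvfqi_flag(likely$hvfqi_score), na.rm = TRUE), 7L)
  expect_equal(sum(hvfqi_flag(likely$hvfqi_score, cutoff = 14), na.rm = TRUE), 8L)
})
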