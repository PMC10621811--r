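test_that("simulation configs are validated", {
  expect_error(sim_config(n_children = 0), "n_children")
  expect_error(sim_config(deficit_prevalence = 1.2), "deficit_prevalence")
  expect_error(sim_config(deficit_time_multiplier = 0), "deficit_time_multiplier")
  expect_error(sim_config(age_weights = c(`5` = 1)), "age_weights")
  expect_error(latent_profile(FALSE, severity = 0.5), "severity")
})

test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- sim_config(n_children = 25, seed = 123, deficit_prevalence = 0.3)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(as.data.frame(a$cohort), as.data.frame(b$cohort))

  set.seed(5)
  r1 <- simulate_run(latent_profile(FALSE), age = 9, version = "single")
  set.seed(5)
  r2 <- simulate_run(latent_profile(FALSE), age = 9, version = "single")
  expect_identical(r1, r2)
})

test_that("every generated record passes cohort validation", {
  sim <- simulate_cohort(sim_config(n_children = 60, seed = 4,
                                    deficit_prevalence = 0.25))
  expect_invisible(validate_cohort(sim$cohort))
  expect_equal(nrow(sim$cohort), 120L)
  expect_setequal(unique(table(sim$cohort$child_id)), 2L)
})

test_that("deficit profiles double expected completion time", {
  # same seed => matched ages and matched latent speed factors across arms
  base <- function(prev) sim_config(n_children = 300, seed = 11,
                                    deficit_prevalence = prev)
  typical <- simulate_cohort(base(0))$cohort
  deficit <- simulate_cohort(base(1))$cohort
  ratio <- mean(deficit$overall_time_s) / mean(typical$overall_time_s)
  expect_gt(ratio, 1.85)
  expect_lt(ratio, 2.15)
})

test_that("deficit accuracy is stochastically dominated by typical accuracy", {
  cfg0 <- sim_config(n_children = 1000, seed = 21, deficit_prevalence = 0)
  cfg1 <- sim_config(n_children = 1000, seed = 21, deficit_prevalence = 1)
  acc0 <- simulate_cohort(cfg0)$cohort$accurate_rounds
  acc1 <- simulate_cohort(cfg1)$cohort$accurate_rounds
  cdf0 <- ecdf(acc0); cdf1 <- ecdf(acc1)
  for (k in 0:5) expect_gte(cdf1(k), cdf0(k))
  expect_lt(mean(acc1), mean(acc0))
})

test_that("cohort age composition follows the configured weights", {
  cfg <- sim_config(n_children = 724, seed = 31)
  co <- simulate_cohort(cfg)$cohort
  ages <- co$age_years[!duplicated(co$child_id)]
  observed <- table(factor(ages, 5:18))
  expected <- 724 * cfg$age_weights[as.character(5:18)] / sum(cfg$age_weights)
  # multinomial sampling error: chi-square should not be extreme
  chi2 <- sum((observed - expected)^2 / expected)
  expect_lt(chi2, qchisq(0.999, df = 13))

  all_typical <- simulate_cohort(sim_config(n_children = 40, seed = 2,
                                            deficit_prevalence = 0))$cohort
  expect_true(all(all_typical$truth_label == "typical"))
})

test_that("teddy-bear sheets hold 3 targets and 12 distractors per column", {
  set.seed(1); s1 <- generate_tbct_sheet()
  set.seed(2); s2 <- generate_tbct_sheet()
  for (s in list(s1, s2)) {
    expect_equal(nrow(s$items), 75L)
    expect_equal(sum(s$items$is_target), 15L)
    tab <- table(s$items$column, s$items$is_target)
    expect_true(all(tab[, "TRUE"] == 3L))
    expect_true(all(tab[, "FALSE"] == 12L))
  }
  expect_false(identical(s1$items$is_target, s2$items$is_target))
})

test_that("TBCT response model separates deficit from typical", {
  set.seed(10)
  sheet <- generate_tbct_sheet()
  # zero omission base rate: every target marked
  perfect <- simulate_tbct_response(sheet, latent_profile(FALSE),
                                    base_omit_prob = 0)
  expect_equal(score_tbct(sheet, perfect)$O, 0L)
  expect_length(perfect$marks, 15L)

  o_mean <- function(profile, n = 150, ...) {
    mean(vapply(seq_len(n), function(i) {
      score_tbct(sheet, simulate_tbct_response(sheet, profile, ...))$O
    }, numeric(1)))
  }
  set.seed(11)
  expect_gt(o_mean(latent_profile(TRUE, 1)), o_mean(latent_profile(FALSE)))

  # rightward attention bias concentrates omissions in the left columns
  set.seed(12)
  lo <- replicate(300, score_tbct(
    sheet, simulate_tbct_response(sheet, latent_profile(TRUE, 1),
                                  base_omit_prob = 0.1, lateral_bias = 2))$LO_S)
  expect_lt(mean(lo), 0)
})

test_that("SLCT grid and scan-time response model behave at the limits", {
  set.seed(3)
  grid <- generate_slct_grid()
  expect_equal(dim(grid$cells), c(22L, 14L))
  expect_length(grid$cells, 308L)
  expect_length(grid$target_letters, 6L)

  # infinite scan speed and zero error: net equals the number of target cells
  resp <- simulate_slct_response(grid, latent_profile(FALSE),
                                 item_scan_median_s = 0,
                                 base_miss_prob = 0, base_confusion_prob = 0)
  n_target_cells <- sum(grid$cells %in% grid$target_letters)
  ref <- build_slct_reference(data.frame(age = 11, net = c(rep(10, 19), 11)),
                              min_per_age = 20)
  sc <- score_slct(grid, resp, ref, age = 11)
  expect_equal(sc$net, n_target_cells)
  expect_equal(sc$wrong, 0L)

  set.seed(4)
  net_mean <- function(profile, n = 120) {
    mean(vapply(seq_len(n), function(i) {
      r <- simulate_slct_response(grid, profile)
      cc <- r$cancellations
      nrow(cc) - sum(!grid$cells[cbind(cc$row, cc$col)] %in% grid$target_letters)
    }, numeric(1)))
  }
  expect_lt(net_mean(latent_profile(TRUE, 1)), net_mean(latent_profile(FALSE)))
})
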