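# Deterministic TBCT fixture: targets at known rows, 3 per column.
fixed_tbct_sheet <- function() {
  items <- do.call(rbind, lapply(1:5, function(col) {
    data.frame(item_id = sprintf("c%d_r%02d", col, 1:15), column = col,
               row = 1:15, is_target = c(rep(TRUE, 3), rep(FALSE, 12)))
  }))
  tbct_sheet(items)
}
tbct_targets <- function(sheet) sheet$items$item_id[sheet$items$is_target]

test_that("TBCT scoring follows the omission and location rules", {
  sheet <- fixed_tbct_sheet()
  targets <- tbct_targets(sheet)

  all_marked <- score_tbct(sheet, tbct_response(targets))
  expect_equal(all_marked$O, 0L)
  expect_equal(all_marked$LO_S, 0)
  expect_false(all_marked$out_of_norm)

  # one omission in column 5 (nominal value +1)
  omit5 <- score_tbct(sheet, tbct_response(setdiff(targets, "c5_r01")))
  expect_equal(omit5$O, 1L)
  expect_equal(omit5$LO_S, 1)
  expect_true(omit5$out_of_norm)

  # first three marked targets in columns 1, 2, 3: START-S = -1 -1 +0 = -2
  marks <- c("c1_r01", "c2_r01", "c3_r01", "c4_r01", "c5_r01")
  expect_equal(score_tbct(sheet, tbct_response(marks))$START_S, -2)

  # distractor marks do not count towards the first three targets
  with_distractors <- c("c1_r01", "c4_r04", "c4_r05", "c2_r01", "c3_r01")
  expect_equal(score_tbct(sheet, tbct_response(with_distractors))$START_S, -2)

  expect_error(score_tbct(sheet, tbct_response("nope")), "unknown item")
  expect_error(tbct_response(c("c1_r01", "c1_r01")), "duplicate")
})

test_that("TBCT scores are order-invariant where the rules demand it", {
  sheet <- fixed_tbct_sheet()
  targets <- tbct_targets(sheet)
  set.seed(8)
  for (i in 1:20) {
    marked <- sample(targets, sample(4:15, 1))
    s1 <- score_tbct(sheet, tbct_response(marked))
    # O via set difference equals 15 minus the distinct marked targets
    expect_equal(s1$O, 15L - length(marked))
    # permuting marks beyond the first three changes neither LO-S nor START-S
    perm <- c(marked[1:3], sample(marked[-(1:3)]))
    s2 <- score_tbct(sheet, tbct_response(perm))
    expect_equal(s2$LO_S, s1$LO_S)
    expect_equal(s2$START_S, s1$START_S)
    # full permutation leaves LO-S (but not necessarily START-S) unchanged
    s3 <- score_tbct(sheet, tbct_response(sample(marked)))
    expect_equal(s3$LO_S, s1$LO_S)
  }
})

# SLCT fixture: grid of "A" with target letters A..F placed deterministically.
fixed_slct_grid <- function() {
  cells <- matrix("Z", 22, 14)
  cells[1:10, 1:5] <- "A"  # 50 target cells
  slct_grid(cells, LETTERS[1:6])
}

test_that("SLCT net score subtracts wrong cancellations", {
  grid <- fixed_slct_grid()
  ref <- build_slct_reference(data.frame(age = 10, net = 1:40), min_per_age = 20)

  # 40 cancellations, 4 on non-target letters -> net 36
  marks <- rbind(data.frame(row = rep(1:9, each = 4), col = rep(1:4, 9)),
                 data.frame(row = 11:14, col = 6))
  sc <- score_slct(grid, slct_response(marks), ref, age = 10)
  expect_equal(sc$total, 40L)
  expect_equal(sc$wrong, 4L)
  expect_equal(sc$net, 36L)

  none <- score_slct(grid, slct_response(data.frame(row = integer(),
                                                    col = integer())),
                     ref, age = 10)
  expect_equal(c(none$total, none$wrong, none$net), c(0L, 0L, 0L))

  expect_error(slct_response(data.frame(row = 30, col = 1)), "off-grid")
  expect_error(slct_response(data.frame(row = c(1, 1), col = c(1, 1))),
               "duplicate")
  expect_error(score_slct(grid, slct_response(marks), ref, age = 7),
               "no SLCT reference")
})

test_that("the out-of-norm rule is 'at the 5th percentile or less'", {
  grid <- fixed_slct_grid()
  # reference nets 1..100: 5th-percentile cutoff = 5.95
  ref <- build_slct_reference(data.frame(age = 10, net = 1:100), min_per_age = 20)
  resp_net <- function(net) {
    slct_response(data.frame(row = rep(1:10, 5)[seq_len(net)],
                             col = rep(1:5, each = 10)[seq_len(net)]))
  }
  expect_true(score_slct(grid, resp_net(5), ref, 10)$out_of_norm)
  expect_false(score_slct(grid, resp_net(6), ref, 10)$out_of_norm)

  # degenerate reference (all nets equal): equal or lower is out of norm
  flat <- build_slct_reference(data.frame(age = 10, net = rep(20, 30)),
                               min_per_age = 20)
  expect_true(score_slct(grid, resp_net(20), flat, 10)$out_of_norm)
  expect_true(score_slct(grid, resp_net(19), flat, 10)$out_of_norm)
  expect_false(score_slct(grid, resp_net(21), flat, 10)$out_of_norm)

  # midpoint tie correction on the reported percentile
  tied <- build_slct_reference(data.frame(age = 10, net = c(rep(10, 10),
                                                            rep(20, 10))),
                               min_per_age = 20)
  expect_equal(score_slct(grid, resp_net(10), tied, 10)$percentile_in_reference,
               100 * (0 + 0.5 * 10) / 20)
})

test_that("net never exceeds the grid's target-cell count", {
  set.seed(19)
  for (i in 1:10) {
    grid <- generate_slct_grid()
    resp <- simulate_slct_response(grid, latent_profile(FALSE),
                                   item_scan_median_s = 0.2)
    cc <- resp$cancellations
    wrong <- sum(!grid$cells[cbind(cc$row, cc$col)] %in% grid$target_letters)
    expect_lte(nrow(cc) - wrong, sum(grid$cells %in% grid$target_letters))
  }
})

test_that("simulated SLCT reference cutoffs rise with age and round-trip", {
  set.seed(23)
  ref <- simulate_slct_reference(ages = 9:16, n_per_age = 400)
  cutoffs <- vapply(ref$bands, function(b) b$cutoff_5th, numeric(1))
  expect_true(all(diff(cutoffs) >= 0))
  expect_true(ref$synthetic)

  f <- withr::local_tempfile(fileext = ".json")
  write_slct_reference(ref, f)
  back <- read_slct_reference(f)
  back_cut <- vapply(back$bands, function(b) b$cutoff_5th, numeric(1))
  expect_equal(back_cut, cutoffs)
  expect_equal(back$bands[["12"]]$nets, ref$bands[["12"]]$nets)
})
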