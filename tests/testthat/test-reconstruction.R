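# Circular reconstruction error, manipulation-check summaries, increments
# and the task-difficulty bootstrap.

test_that("circular error is the wrapped distance, bounded by 180", {
  expect_equal(circular_error(90, 360), 90)
  expect_equal(circular_error(123.4, 123.4), 0)
  expect_equal(circular_error(10, 200), 170)
  # symmetry and 360-periodicity
  set.seed(2)
  a <- runif(200, 0, 720); b <- runif(200, -360, 360)
  expect_equal(circular_error(a, b), circular_error(b, a))
  expect_equal(circular_error(a + 360, b), circular_error(a, b - 720))
  expect_true(all(circular_error(a, b) <= 180))
  # the literal printed formula is kept for audit and differs at identity
  expect_equal(circular_error_literal(90, 360), 90)
  expect_equal(circular_error_literal(50, 50), 180)
})

test_that("manipulation summaries report cell means, SEs and the RI trend", {
  rec <- simulate_reconstruction(n_per_cell = 200, seed = 12)
  s <- manipulation_summary(rec)
  expect_equal(s$by_ri$level, c(1, 5, 10, 30))
  expect_equal(s$by_pt$level, c(1, 5, 10, 30))
  expect_true(all(s$by_ri$n == 200 * 4))
  expect_true(s$monotone_in_ri)
  expect_false(is.unsorted(s$by_ri$mean_error))
  # presentation time works the other way around
  expect_false(is.unsorted(rev(s$by_pt$mean_error)))
  # single-trial cells get flagged SEs
  one <- rec[1, ]
  s1 <- manipulation_summary(one)
  expect_true(is.na(s1$by_ri$se))
  # all-perfect responses give all-zero means
  perfect <- rec[1:10, ]
  perfect$response_deg <- perfect$exemplar_deg
  expect_true(all(manipulation_summary(perfect)$by_ri$mean_error == 0))
})

test_that("increment steps convert token spacing to degrees", {
  expect_equal(increment_step(1), 7.5)
  expect_equal(increment_step(10), 0.75)
  prices <- seq(1, 10, by = 0.5)
  expect_true(all(diff(increment_step(prices)) < 0))
  expect_error(increment_step(0), "positive")
})

test_that("difficulty bootstrap is deterministic with ordered percentile CIs", {
  set.seed(6)
  errors <- abs(rnorm(200, 0, 20))
  increments <- runif(300, 0.75, 7.5)
  bt <- bootstrap_difficulty(errors, increments, n_boot = 2000, seed = 10)
  expect_equal(bt$mean_diff, mean(errors) - mean(increments))
  expect_lt(bt$ci95[["lo"]], bt$ci95[["hi"]])
  expect_gte(bt$mean_diff, bt$ci95[["lo"]])
  expect_lte(bt$mean_diff, bt$ci95[["hi"]])
  bt2 <- bootstrap_difficulty(errors, increments, n_boot = 2000, seed = 10)
  expect_identical(bt$boot, bt2$boot)
  # same list on both sides: difference centred at zero
  bt0 <- bootstrap_difficulty(errors, errors, n_boot = 2000, seed = 11)
  expect_equal(bt0$mean_diff, 0)
  expect_lte(bt0$ci95[["lo"]], 0)
  expect_gte(bt0$ci95[["hi"]], 0)
  expect_error(bootstrap_difficulty(numeric(0), increments), "non-empty")
})

test_that("bootstrap CIs achieve near-nominal coverage on a known truth", {
  set.seed(30)
  truth <- 5
  hits <- vapply(1:200, function(i) {
    e <- rnorm(40, 10, 4)
    inc <- rnorm(40, 10 - truth, 4)
    bt <- bootstrap_difficulty(e, inc, n_boot = 400)
    bt$ci95[["lo"]] <= truth && truth <= bt$ci95[["hi"]]
  }, logical(1))
  expect_gte(mean(hits), 0.85)
  expect_lte(mean(hits), 1)
})
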