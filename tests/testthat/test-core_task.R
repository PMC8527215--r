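# Choice-set construction and the token-to-orientation mapping.

test_that("price draws stay on their assigned ranges and never exceed them", {
  set.seed(42)
  draws <- t(replicate(2000, draw_prices()))
  expect_true(all(draws >= 1))
  expect_true(all(draws <= 10))
  # at least one component of every pair lies in the narrow range
  expect_true(all(apply(draws, 1, min) <= 3))
  # both components above 3 would require both on the wide range
  expect_equal(sum(draws[, 1] > 3 & draws[, 2] > 3), 0)
  # integer mode produces integers in range
  ints <- t(replicate(200, draw_prices(integer_prices = TRUE)))
  expect_true(all(ints == round(ints)))
})

test_that("choice sets are equidistant budget-line points with both extremes", {
  cs <- make_choice_set(1, 1, 100)
  expect_equal(unname(cs[, "x"]), c(0, 25, 50, 75, 100))
  expect_equal(unname(cs[, "y"]), c(100, 75, 50, 25, 0))
  cs2 <- make_choice_set(3, 10, 100)
  expect_equal(unname(cs2[5, ]), c(100 / 3, 0))
  expect_equal(unname(cs2[1, ]), c(0, 10))
  # budget identity and equidistance hold for arbitrary positive prices
  set.seed(7)
  for (i in 1:50) {
    p <- draw_prices()
    cs <- make_choice_set(p[["x"]], p[["y"]])
    expect_true(all(abs(cs[, 1] * p[["x"]] + cs[, 2] * p[["y"]] - 100) < 1e-9))
    expect_equal(diff(cs[, "x"]), rep((100 / p[["x"]]) / 4, 4))
  }
  expect_error(make_choice_set(-1, 2), "positive")
  expect_error(make_choice_set(1, 2, 0), "positive")
})

test_that("token-to-orientation mapping is affine, -0.3 deg/token from 30 deg", {
  expect_equal(bundle_to_orientation(0, 120), 150)
  expect_equal(bundle_to_orientation(100, 120), 120)
  expect_equal(bundle_to_orientation(50, 120), 135)
  # other side and wrapping
  expect_equal(bundle_to_orientation(0, 10, side = -1), 340)
  expect_error(bundle_to_orientation(120, 10), "100")
})

test_that("generated blocks respect the design and are seed-deterministic", {
  b <- generate_block("p1", t = 12, seed = 99)
  expect_equal(nrow(b), 20)
  expect_true(all(b$exemplar_x_deg %in% exemplar_orientations()))
  expect_true(all(b$exemplar_y_deg %in% exemplar_orientations()))
  expect_true(all(b$retention_interval_s == 12))
  opt_cost <- as.matrix(b[paste0("opt", 1:5, "_x")]) * b$price_x +
    as.matrix(b[paste0("opt", 1:5, "_y")]) * b$price_y
  expect_true(max(abs(opt_cost - 100)) < 1e-9)
  expect_identical(b, generate_block("p1", t = 12, seed = 99))
  expect_error(generate_block("p1", t = 31), "\\[0, 30\\]")
})

test_that("sessions draw two independent in-range retention intervals", {
  s <- generate_session("p9", seed = 5)
  ts <- unique(s[c("block_role", "retention_interval_s")])
  expect_equal(nrow(ts), 2)
  expect_true(all(ts$retention_interval_s >= 0 & ts$retention_interval_s <= 30))
  b1 <- s[s$block_role == "block1", ]
  b2 <- s[s$block_role == "block2", ]
  expect_false(isTRUE(all.equal(b1$price_x, b2$price_x)))
  expect_identical(s, generate_session("p9", seed = 5))
})

test_that("trials survive a CSV round-trip at full precision", {
  s <- generate_session("p1", seed = 31)
  s$choice_index <- sample.int(5L, nrow(s), replace = TRUE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials_csv(s, path)
  back <- read_trials_csv(path)
  expect_equal(back$price_x, s$price_x, tolerance = 1e-12)
  expect_equal(back$opt3_y, s$opt3_y, tolerance = 1e-12)
  expect_identical(back$choice_index, s$choice_index)
})
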