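test_that("water correction flags a sharp drop and its recovery tail only", {
  x <- make_rrt(c(38.6, 38.6, 38.6, 37.0, 37.9, 38.6, 38.6))
  out <- correct_water_intake(x, drop_threshold = 0.8)
  expect_equal(out$water_flag, c(F, F, F, T, T, F, F))
  expect_equal(out$valid, c(T, T, T, F, F, T, T))
  expect_equal(out$temp, x$temp) # temperatures never modified

  const <- correct_water_intake(make_rrt(rep(38.6, 24)))
  expect_false(any(const$water_flag))

  shallow <- correct_water_intake(make_rrt(c(38.6, 38.6, 38.6, 38.1, 38.6)))
  expect_false(any(shallow$water_flag))
})

test_that("a transient times out after the recovery limit", {
  # slow return: readings stay > 0.2 degC off for more than 3 h
  x <- make_rrt(c(38.6, 38.6, 38.6, 37.0, 37.2, 37.5, 37.8, 38.0, 38.6))
  out <- correct_water_intake(x, drop_threshold = 0.8, recovery_limit = 3)
  expect_equal(which(out$water_flag), 4:7) # trigger reading + 3 h
})

test_that("water correction warns and skips cows with under 3 valid readings", {
  x <- make_rrt(c(38.6, 37.0), valid = c(TRUE, TRUE))
  expect_warning(out <- correct_water_intake(x), "fewer than 3")
  expect_false(any(out$water_flag))
})

test_that("water correction is idempotent and recovers injected transients", {
  p <- signal_params(noise_sd = 0.12, drink_rate = 0.5)
  truth <- make_truth(60 * 24, 12, ovulation_h = 60 * 24 + 28, cow = "cow1")
  n_hit <- 0
  n_caught <- 0
  for (s in 31:36) {
    sim <- simulate_cow(p, truth, seed = s, n_hours = 24 * 62)
    once <- correct_water_intake(sim$rrt)
    if (s == 31) {
      twice <- correct_water_intake(once)
      expect_identical(once$water_flag, twice$water_flag)
    }
    n_hit <- n_hit + sum(sim$drink$affected)
    n_caught <- n_caught + sum(once$water_flag & sim$drink$affected)
  }
  expect_gt(n_hit, 200) # enough transients for a stable recall estimate
  expect_gte(n_caught / n_hit, 0.9)
})

test_that("rolling baseline of a constant series is that constant with zero SD", {
  x <- make_rrt(rep(38.6, 24 * 6))
  b <- rolling_baseline(x, window = 120, min_window_points = 120)
  expect_true(all(is.na(b$baseline_mean[1:120]))) # boundary: window unfilled
  defined <- !is.na(b$baseline_mean)
  expect_equal(sum(defined), 24 * 6 - 120)
  expect_equal(b$baseline_mean[defined], rep(38.6, sum(defined)))
  expect_equal(b$baseline_sd[defined], rep(0, sum(defined)))
  expect_error(rolling_baseline(x, window = 0), "positive")
})

test_that("rolling baseline matches the closed form of an alternating series", {
  x <- make_rrt(rep(c(38.5, 38.7), 120))
  b <- rolling_baseline(x, window = 120, min_window_points = 120)
  defined <- !is.na(b$baseline_mean)
  expect_equal(b$baseline_mean[defined], rep(38.6, sum(defined)))
  # population SD of 60 readings at -0.1 and 60 at +0.1
  expect_equal(b$baseline_sd[defined], rep(0.1, sum(defined)), tolerance = 1e-9)
})

test_that("the baseline window is trailing and half-open", {
  # step series: constant 38.6 then a jump; the reading at the jump hour must
  # not contribute to its own baseline
  x <- make_rrt(c(rep(38.6, 120), 40))
  b <- rolling_baseline(x, window = 120, min_window_points = 120)
  expect_equal(b$baseline_mean[121], 38.6)
  expect_equal(b$baseline_sd[121], 0)
})

test_that("invalid readings are excluded from the baseline and count", {
  x <- make_rrt(rep(38.6, 24 * 6))
  x$valid[1:40] <- FALSE
  b <- rolling_baseline(x, window = 120, min_window_points = 90)
  expect_true(is.na(b$baseline_mean[121])) # only 80 valid points in window
  expect_equal(b$n_used[121], 80L)
  expect_equal(b$baseline_mean[135], 38.6) # 94 valid points by then
})

test_that("standardization follows (temp - mean) / max(sd, floor)", {
  x <- make_rrt(c(39.2, 38.6, 38.7))
  b <- flat_baseline(x, mean = 38.6, sd = 0.3)
  z <- standardize(x, b, sd_floor = 0.05)
  expect_equal(z$z, c(2, 0, 1 / 3), tolerance = 1e-12)

  b0 <- flat_baseline(x, mean = 38.6, sd = 0)
  z0 <- standardize(x, b0, sd_floor = 0.05)
  expect_equal(z0$z[1], 0.6 / 0.05) # floor engages
  x$valid[2] <- FALSE
  expect_true(is.na(standardize(x, b, sd_floor = 0.05)$z[2]))
})

test_that("standardization is invariant to a constant shift of series and baseline", {
  set.seed(4)
  temps <- 38.6 + rnorm(24 * 7, 0, 0.2)
  x <- make_rrt(temps)
  xs <- make_rrt(temps + 1.3)
  z1 <- standardize(x, rolling_baseline(x, min_window_points = 100))
  z2 <- standardize(xs, rolling_baseline(xs, min_window_points = 100))
  expect_equal(z1$z, z2$z, tolerance = 1e-8)
})
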