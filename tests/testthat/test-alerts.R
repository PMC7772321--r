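make_z <- function(z, cow = "c1", start = T0) {
  tibble::tibble(cow_id = cow, timestamp = start + 3600 * (seq_along(z) - 1), z = z)
}

test_that("an alert needs two consecutive readings beyond the threshold", {
  z <- make_z(c(0.8, 1.2, 1.6, 1.7, 0.9))
  a <- detect_temp_alerts(z, aam_alert_time = T0, ovulation_time = T0 + 4 * 3600,
                          thresholds = 1.5)
  expect_equal(nrow(a), 1)
  expect_equal(a$direction, "estrus")
  expect_equal(a$alert_time, T0 + 2 * 3600) # first reading of the pair
  expect_equal(c(a$z1, a$z2), c(1.6, 1.7))

  lone <- make_z(c(0, 0, 3.2, 0, 0))
  a2 <- detect_temp_alerts(lone, T0, T0 + 4 * 3600)
  expect_equal(nrow(a2), 0)

  neg <- make_z(c(0, -1.1, -1.2, 0))
  a3 <- detect_temp_alerts(neg, T0, T0 + 3 * 3600, thresholds = 1)
  expect_equal(a3$direction, "ovulation")
  expect_equal(a3$alert_time, T0 + 3600)
})

test_that("NA readings and grid gaps break qualifying runs", {
  z <- make_z(c(2, NA, 2, 2.5))
  a <- detect_temp_alerts(z, T0, T0 + 3 * 3600, thresholds = 1.5)
  expect_equal(nrow(a), 1)
  expect_equal(a$alert_time, T0 + 2 * 3600)

  gap <- make_z(c(2, 2.5))
  gap$timestamp[2] <- gap$timestamp[2] + 3600 # 2-h gap between readings
  expect_equal(nrow(detect_temp_alerts(gap, T0, T0 + 5 * 3600, thresholds = 1.5)), 0)
})

test_that("alerts are confined to 12 h before the AAM alert until 12 h after ovulation", {
  z <- make_z(c(3, 3, rep(0, 38), 3, 3, rep(0, 7), -3, -3))
  # window [24 - 12, 30 + 12] h: the leading pair (hours 0-1) and the trailing
  # negative pair (hours 49-50) fall outside it
  a <- detect_temp_alerts(z, aam_alert_time = T0 + 24 * 3600,
                          ovulation_time = T0 + 30 * 3600, thresholds = 2)
  expect_equal(nrow(a), 1)
  expect_equal(a$direction, "estrus")
  expect_equal(a$alert_time, T0 + 40 * 3600)
  # unknown ovulation time: no window, no alerts
  expect_equal(nrow(detect_temp_alerts(z, T0 + 24 * 3600,
                                       as.POSIXct(NA_character_, tz = "UTC"),
                                       thresholds = 2)), 0)
})

test_that("a long run yields one alert and the first alert wins downstream", {
  z <- make_z(c(0, 2, 2, 2, 2, 0, 2, 2, 0))
  a <- detect_temp_alerts(z, T0, T0 + 8 * 3600, thresholds = 1.5)
  expect_equal(nrow(a), 2) # one per maximal run
  a$episode_id <- "e1"
  fa <- first_alerts(a)
  expect_equal(nrow(fa), 1)
  expect_equal(fa$alert_time, T0 + 3600)
})

test_that("interval records follow the alert-minus-anchor sign convention", {
  fa <- tibble::tibble(episode_id = "e1", direction = c("estrus", "ovulation"),
                       threshold = 1, alert_time = T0 + c(96, 110) * 3600)
  iv <- compute_intervals(fa, aam_alert_time = T0 + 100 * 3600,
                          ovulation_time = T0 + 128 * 3600, thresholds = c(1, 3))
  expect_equal(iv$aam_to_estrus_alert, c(-4, NA))
  expect_equal(iv$estrus_alert_to_ovulation, c(-32, NA))
  expect_equal(iv$aam_to_ovulation_alert, c(10, NA))
  expect_equal(iv$ovulation_alert_to_ovulation, c(-18, NA))
})

test_that("summaries report percent alerted and sample statistics", {
  iv <- tibble::tibble(
    episode_id = paste0("e", 1:4), threshold = 1,
    aam_to_estrus_alert = c(-4, -2, NA, NA),
    estrus_alert_to_ovulation = c(-30, -20, NA, NA),
    aam_to_ovulation_alert = NA_real_,
    ovulation_alert_to_ovulation = NA_real_
  )
  s <- summarize_alerts(iv, n_events = 4)
  est <- s[s$interval == "aam_to_estrus_alert", ]
  expect_equal(est$pct_alerted, 50)
  expect_equal(est$mean_h, -3)
  expect_equal(est$sd_h, sqrt(2)) # sample convention on {-4, -2}
  expect_equal(est$min_h, -4)
  expect_equal(est$max_h, -2)
  expect_equal(s$pct_alerted[s$interval == "aam_to_ovulation_alert"], 0)
  expect_true(is.na(s$mean_h[s$interval == "aam_to_ovulation_alert"]))
  expect_error(summarize_alerts(iv, n_events = 0))
})

test_that("alerts nest across thresholds on random standardized series", {
  set.seed(12)
  thresholds <- c(0.5, 1, 1.5, 2, 2.5, 3)
  for (i in 1:20) {
    z <- make_z(cumsum(rnorm(60, 0, 0.8)) * 0.3)
    ov <- T0 + 40 * 3600
    a <- detect_temp_alerts(z, T0 + 12 * 3600, ov, thresholds)
    for (dir in c("estrus", "ovulation")) {
      ad <- a[a$direction == dir, ]
      alerted <- vapply(thresholds, function(th) any(ad$threshold == th), logical(1))
      # if alerted at k, alerted at every threshold below k
      expect_true(all(diff(rev(alerted)) >= 0 | !rev(alerted)[-1]))
      expect_true(all(which(alerted) == seq_len(sum(alerted))))
    }
  }
})
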