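#' Flag water-intake transients in an hourly temperature series
#'
#' Drinking cold water transiently depresses rumen-reticular temperature. A
#' reading is treated as the start of a drinking transient when it drops at
#' least `drop_threshold` degC below the median of the previous 3 valid
#' readings; subsequent readings stay flagged until one returns to within
#' `recovery_tol` degC of that pre-drop median or `recovery_limit` hours have
#' elapsed. Flagged readings are marked invalid; temperatures are never
#' modified. The correction is idempotent: running it on an already corrected
#' series flags nothing new.
#'
#' @param rrt Tibble with `cow_id`, `timestamp`, `temp`, `valid`.
#' @param drop_threshold Minimum drop below the prior median to open a
#'   transient, degC.
#' @param recovery_limit Maximum duration of a transient, hours.
#' @param recovery_tol Return-to-baseline tolerance that closes a transient,
#'   degC.
#' @return `rrt` with a logical `water_flag` column and `valid` set to FALSE
#'   on flagged readings. Cows with fewer than 3 valid readings are returned
#'   unchanged with a warning.
#' @examples
#' x <- tibble::tibble(
#'   cow_id = "c1",
#'   timestamp = as.POSIXct("2019-06-01", tz = "UTC") + 3600 * (0:5),
#'   temp = c(38.6, 38.6, 38.6, 37.0, 37.9, 38.6), valid = TRUE
#' )
#' correct_water_intake(x)$water_flag
#' @export
correct_water_intake <- function(rrt, drop_threshold = 0.8, recovery_limit = 3,
                                 recovery_tol = 0.2) {
  stopifnot(drop_threshold > 0, recovery_limit > 0)
  if (!"water_flag" %in% names(rrt)) rrt$water_flag <- FALSE
  out <- rrt |>
    group_by(.data$cow_id) |>
    group_modify(~ flag_transients_cow(.x, drop_threshold, recovery_limit,
                                       recovery_tol)) |>
    ungroup()
  out$valid <- out$valid & !out$water_flag
  out
}

flag_transients_cow <- function(df, drop_threshold, recovery_limit, recovery_tol) {
  df <- arrange(df, .data$timestamp)
  n <- nrow(df)
  if (sum(df$valid) < 3) {
    warning("fewer than 3 valid readings; water correction skipped for a cow")
    return(df)
  }
  flag <- df$water_flag
  temp <- df$temp
  tt <- as.numeric(df$timestamp) / 3600
  recent <- numeric(0) # last 3 retained valid temps
  in_trans <- FALSE
  t0 <- NA_real_
  ref_med <- NA_real_
  for (i in seq_len(n)) {
    if (!df$valid[i] || is.na(temp[i])) next
    if (in_trans) {
      if (abs(temp[i] - ref_med) <= recovery_tol) {
        in_trans <- FALSE # recovered; reading kept
      } else if (tt[i] - t0 <= recovery_limit) {
        flag[i] <- TRUE
        next
      } else {
        in_trans <- FALSE # timed out; reading kept
      }
    }
    if (length(recent) == 3) {
      med <- median(recent)
      if (med - temp[i] >= drop_threshold) {
        flag[i] <- TRUE
        in_trans <- TRUE
        t0 <- tt[i]
        ref_med <- med
        next
      }
    }
    recent <- c(tail(recent, 2), temp[i])
  }
  df$water_flag <- flag
  df
}

#' Rolling trailing baseline mean and SD of an hourly temperature series
#'
#' For every hour t the baseline is the mean and population SD of the valid
#' readings in the half-open trailing window `[t - window, t)` — the previous
#' 5 days of hourly readings by default. The current reading never contributes
#' to its own baseline, so a developing estrus rise does not inflate its
#' baseline at onset. The baseline is undefined (NA) wherever fewer than
#' `min_window_points` valid readings fall in the window (default 90 of 120,
#' mirroring a 25 % missingness tolerance). The series is completed onto a
#' full hourly grid per cow before windowing.
#'
#' @param rrt Tibble with `cow_id`, `timestamp`, `temp`, `valid` (typically
#'   water-corrected first).
#' @param window Window length, hours (> 0).
#' @param min_window_points Minimum valid readings for a defined baseline.
#' @return Tibble with `cow_id`, `timestamp`, `baseline_mean`, `baseline_sd`
#'   (population convention), `n_used`.
#' @export
rolling_baseline <- function(rrt, window = 120, min_window_points = 90) {
  if (length(window) != 1 || is.na(window) || window <= 0) {
    stop("`window` must be a positive number of hours")
  }
  window <- as.integer(window)
  rrt |>
    group_by(.data$cow_id) |>
    group_modify(~ baseline_cow(.x, window, min_window_points)) |>
    ungroup()
}

baseline_cow <- function(df, window, min_pts) {
  df <- arrange(df, .data$timestamp)
  grid <- tibble(timestamp = seq(min(df$timestamp), max(df$timestamp), by = 3600))
  df <- left_join(grid, df, by = "timestamp")
  df$valid[is.na(df$valid)] <- FALSE
  n <- nrow(df)
  v <- df$valid & !is.na(df$temp)
  m0 <- median(df$temp[v]) # centring guards against cancellation in the SD
  r <- ifelse(v, df$temp - m0, 0)
  c1 <- cumsum(v)
  s1 <- cumsum(r)
  s2 <- cumsum(r * r)
  lagk <- function(x, k) c(rep(0, k), x)[seq_len(n)]
  n_used <- lagk(c1, 1) - lagk(c1, window + 1)
  sw1 <- lagk(s1, 1) - lagk(s1, window + 1)
  sw2 <- lagk(s2, 1) - lagk(s2, window + 1)
  ok <- n_used >= min_pts
  mu <- ifelse(ok, sw1 / n_used, NA_real_)
  varp <- ifelse(ok, pmax(sw2 / n_used - mu^2, 0), NA_real_)
  tibble(
    timestamp = df$timestamp,
    baseline_mean = mu + m0,
    baseline_sd = sqrt(varp),
    n_used = as.integer(n_used)
  )
}

#' Standardized temperature change relative to the rolling baseline
#'
#' Computes z = (temperature - baseline mean) / max(baseline SD, `sd_floor`)
#' at every reading; invalid readings and hours with an undefined baseline
#' propagate as NA. The SD floor prevents unbounded scores on flat baseline
#' stretches.
#'
#' @param rrt Tibble with `cow_id`, `timestamp`, `temp`, `valid`.
#' @param baseline Output of [rolling_baseline()].
#' @param sd_floor Minimum SD used in the denominator, degC.
#' @return Tibble with `cow_id`, `timestamp`, `z`.
#' @export
standardize <- function(rrt, baseline, sd_floor = 0.05) {
  stopifnot(sd_floor >= 0)
  baseline |>
    left_join(select(rrt, "cow_id", "timestamp", "temp", "valid"),
              by = c("cow_id", "timestamp")) |>
    mutate(
      z = ifelse(!is.na(.data$temp) & .data$valid & !is.na(.data$baseline_mean),
                 (.data$temp - .data$baseline_mean) /
                   pmax(.data$baseline_sd, sd_floor),
                 NA_real_)
    ) |>
    select("cow_id", "timestamp", "z")
}
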