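#' Simulate hourly weather with a controlled fraction of heat-stress days
#'
#' Generates an hourly air temperature / relative humidity series with a
#' diurnal cycle (warmest mid-afternoon) in which a stated fraction of days is
#' guaranteed, by construction, to reach a daily maximum THI above 72 while
#' the remaining days are guaranteed to stay below it: cool-day temperatures
#' are capped at 21.5 degC (THI < 72 even at 100 % humidity) and hot days have
#' their 15:00 reading floored at 28 degC with at least 40 % humidity
#' (THI > 74).
#'
#' @param n_days Number of days (>= 1).
#' @param seed Integer seed.
#' @param summer_fraction Fraction of days that are heat-stress days; the
#'   count is `round(n_days * summer_fraction)`, the days are drawn at random.
#' @param start Start date (midnight), ISO string or Date.
#' @return A tibble with `timestamp`, `air_temp` (degC), `rel_humidity` (%).
#' @examples
#' w <- simulate_weather(2, seed = 1, summer_fraction = 0.5)
#' range(w$air_temp)
#' @export
simulate_weather <- function(n_days, seed = 1, summer_fraction = 0.3,
                             start = "2019-06-01") {
  if (length(n_days) != 1 || is.na(n_days) || n_days < 1) {
    stop("`n_days` must be a positive number of days")
  }
  n_days <- as.integer(n_days)
  set.seed(seed)
  origin <- parse_ts(paste(start, "00:00:00"))
  n <- n_days * 24L
  hr <- 0:(n - 1)
  day <- hr %/% 24L + 1L
  hod <- hr %% 24L

  n_hot <- round(n_days * summer_fraction)
  hot_days <- if (n_hot > 0) sample.int(n_days, n_hot) else integer(0)
  hot <- day %in% hot_days

  mean_t <- ifelse(hot, 25, 14)
  amp <- ifelse(hot, 6, 5)
  temp <- mean_t + amp * cos(2 * pi * (hod - 15) / 24) + rnorm(n, 0, 0.5)
  # construction guarantees on the daily THI maximum
  temp[!hot] <- pmin(temp[!hot], 21.5)
  peak <- hot & hod == 15L
  temp[peak] <- pmax(temp[peak], 28)

  rh <- 70 - 1.2 * (temp - mean_t) + rnorm(n, 0, 3)
  rh <- pmin(pmax(rh, 30), 95)
  rh[peak] <- pmax(rh[peak], 40)

  tibble(
    timestamp = origin + hr * 3600,
    air_temp = temp,
    rel_humidity = rh
  )
}

#' Simulate one cow's hourly temperature and 2-h activity series
#'
#' Builds the rumen-reticular temperature as
#' basal + circadian sinusoid + noise + drinking transients + estrus rises +
#' ovulation dips, and a 2-h-block activity index that exceeds the 35-index
#' alert threshold exactly during each episode and peaks at the injected peak
#' index. Episode rises are raised-cosine pulses spanning
#' `[episode_onset, episode_end]` whose sampled maximum equals the injected
#' amplitude exactly (episode midpoints fall on the hourly grid); ovulation
#' dips are raised-cosine troughs centred on `ovulation_time`.
#'
#' @param params A [signal_params()] object.
#' @param truth A tibble with one row per episode for this cow: columns
#'   `episode_onset`, `episode_end` (POSIXct, on the 2-h block grid),
#'   `true_peak_index`, `ovulated` (logical), `ovulation_time` (POSIXct, NA
#'   when not ovulated), and optionally `injected_rise_amp`,
#'   `injected_dip_amp` (defaulting to the values in `params`).
#' @param seed Integer seed.
#' @param start Simulation start (midnight), ISO string or POSIXct.
#' @param n_hours Length of the hourly series.
#' @param cow_id Cow identifier.
#' @param missing_fraction Fraction of readings dropped completely at random
#'   (marked invalid, temperature NA).
#' @return A list with tibbles `rrt` (`cow_id`, `timestamp`, `temp`, `valid`),
#'   `activity` (`cow_id`, `block_start`, `index`) and `drink` (`cow_id`,
#'   `timestamp`, `drink_dev`, `affected`), where `affected` marks readings
#'   depressed by at least 0.3 degC by drinking (the ground truth for the
#'   water-intake correction).
#' @export
simulate_cow <- function(params, truth, seed = 1, start = "2019-06-01",
                         n_hours = 24 * 14, cow_id = "cow1",
                         missing_fraction = 0) {
  stopifnot(inherits(params, "signal_params"), nrow(truth) >= 1)
  truth <- arrange(truth, .data$episode_onset)
  if (nrow(truth) > 1 &&
      any(truth$episode_onset[-1] < truth$episode_end[-nrow(truth)])) {
    stop("overlapping estrus episodes for one cow")
  }
  origin <- if (inherits(start, "POSIXct")) start else parse_ts(paste(start, "00:00:00"))
  horizon_end <- origin + n_hours * 3600
  if (any(truth$episode_onset < origin) || any(truth$episode_end > horizon_end)) {
    stop("truth episode times fall outside the simulated horizon")
  }
  if (!all(c("injected_rise_amp", "injected_dip_amp") %in% names(truth))) {
    truth$injected_rise_amp <- params$estrus_rise_amp
    truth$injected_dip_amp <- params$ovulation_dip_amp
  }
  set.seed(seed)

  ts <- origin + (0:(n_hours - 1)) * 3600
  hod <- as.numeric(format(ts, "%H", tz = "UTC"))
  temp <- params$basal_temp +
    params$circadian_amplitude * cos(2 * pi * (hod - params$circadian_acrophase) / 24) +
    rnorm(n_hours, 0, params$noise_sd)

  # drinking transients: instantaneous drop at a reading hour, exponential
  # recovery; bouts restricted to 05:00-22:00
  drink_dev <- numeric(n_hours)
  n_days <- n_hours / 24
  n_ev <- rpois(1, params$drink_rate * n_days)
  if (n_ev > 0) {
    ev_day <- sample.int(ceiling(n_days), n_ev, replace = TRUE) - 1L
    ev_hod <- sample(5:21, n_ev, replace = TRUE)
    ev_idx <- ev_day * 24L + ev_hod + 1L
    ev_idx <- ev_idx[ev_idx <= n_hours]
    for (i0 in ev_idx) {
      span <- i0:min(n_hours, i0 + 12L)
      drink_dev[span] <- drink_dev[span] +
        params$drink_depth * exp(-(span - i0) / params$drink_recovery)
    }
  }
  temp <- temp + drink_dev

  rel_h <- as.numeric(difftime(ts, origin, units = "hours"))
  for (k in seq_len(nrow(truth))) {
    on_h <- hours_between(truth$episode_onset[k], origin)
    dur <- hours_between(truth$episode_end[k], origin) - on_h
    in_ep <- rel_h >= on_h & rel_h <= on_h + dur
    temp[in_ep] <- temp[in_ep] + truth$injected_rise_amp[k] *
      0.5 * (1 - cos(2 * pi * (rel_h[in_ep] - on_h) / dur))
    if (isTRUE(truth$ovulated[k]) && !is.na(truth$ovulation_time[k])) {
      ov_h <- hours_between(truth$ovulation_time[k], origin)
      half <- params$ovulation_dip_duration / 2
      in_dip <- abs(rel_h - ov_h) <= half
      temp[in_dip] <- temp[in_dip] + truth$injected_dip_amp[k] *
        0.5 * (1 + cos(2 * pi * (rel_h[in_dip] - ov_h) / params$ovulation_dip_duration))
    }
  }

  valid <- rep(TRUE, n_hours)
  if (missing_fraction > 0) {
    drop <- runif(n_hours) < missing_fraction
    valid[drop] <- FALSE
    temp[drop] <- NA_real_
  }

  # activity: 2-h blocks, baseline 5-30 index, raised-cosine episode profile
  # rescaled so the block maximum equals the injected peak exactly
  n_blocks <- n_hours %/% 2L
  block_start <- origin + (0:(n_blocks - 1)) * 7200
  index <- sample(5:30, n_blocks, replace = TRUE)
  block_h <- as.numeric(difftime(block_start, origin, units = "hours"))
  for (k in seq_len(nrow(truth))) {
    on_h <- hours_between(truth$episode_onset[k], origin)
    end_h <- hours_between(truth$episode_end[k], origin)
    jb <- which(block_h >= on_h & block_h < end_h)
    nb <- length(jb)
    if (nb == 0) next
    w <- 0.5 * (1 - cos(2 * pi * ((seq_len(nb) - 0.5) / nb)))
    v <- round(36 + (truth$true_peak_index[k] - 36) * w / max(w))
    v[which.max(w)] <- truth$true_peak_index[k]
    index[jb] <- v
  }

  list(
    rrt = tibble(cow_id = cow_id, timestamp = ts, temp = temp, valid = valid),
    activity = tibble(cow_id = cow_id, block_start = block_start, index = index),
    drink = tibble(cow_id = cow_id, timestamp = ts, drink_dev = drink_dev,
                   affected = drink_dev <= -0.3)
  )
}

# twice-daily ultrasound slots (08:00 and 17:00) covering [from, to]
exam_slots <- function(from, to) {
  d0 <- as.Date(from, tz = "UTC") - 1
  d1 <- as.Date(to, tz = "UTC") + 1
  days <- seq(d0, d1, by = "day")
  slots <- sort(c(
    parse_ts(paste(days, "08:00:00")),
    parse_ts(paste(days, "17:00:00"))
  ))
  slots[slots >= from & slots <= to]
}

# ultrasound records for one episode; rng state is the caller's
make_exams <- function(cow_id, episode_id, onset, status, ovulation_time) {
  fol_row <- function(t, dom, day7 = FALSE, cl_new = FALSE, cl_old = NA_real_) {
    fol <- sort(c(dom, runif(2, 4, 9)), decreasing = TRUE)
    fol <- c(fol, rep(NA_real_, 3 - length(fol)))[1:3]
    cl <- if (cl_new) c(runif(1, 22, 28), NA_real_) else c(cl_old, NA_real_)
    tibble(
      cow_id = cow_id, episode_id = episode_id, exam_time = t,
      fol1 = fol[1], fol2 = fol[2], fol3 = fol[3],
      cl1 = cl[1], cl2 = cl[2], day7 = day7
    )
  }
  slots <- exam_slots(onset, onset + 6 * 86400)
  cl_old <- if (runif(1) < 0.5) runif(1, 5, 12) else NA_real_
  rows <- list()
  if (status == "false") {
    # no dominant pre-ovulatory follicle (or a large retained CL): two exams
    large_cl <- runif(1) < 0.3
    for (j in 1:2) {
      rows[[j]] <- fol_row(slots[j],
                           dom = if (large_cl) runif(1, 16, 19) else runif(1, 8, 13),
                           cl_old = if (large_cl) runif(1, 21, 26) else cl_old)
    }
    last <- slots[2]
    rows[[3]] <- fol_row(last + 7 * 86400, dom = runif(1, 8, 13), day7 = TRUE)
  } else if (status %in% c("failed", "late")) {
    d0 <- runif(1, 16.5, 21)
    for (j in 1:6) rows[[j]] <- fol_row(slots[j], dom = d0 + 0.2 * (j - 1), cl_old = cl_old)
    rows[[7]] <- fol_row(slots[6] + 7 * 86400, dom = runif(1, 6, 11),
                         day7 = TRUE, cl_new = status == "late")
  } else { # ovulated
    d0 <- runif(1, 16.5, 21)
    before <- slots[slots < ovulation_time]
    confirm <- slots[slots > ovulation_time][1]
    for (j in seq_along(before)) {
      rows[[j]] <- fol_row(before[j], dom = d0 + 0.2 * (j - 1), cl_old = cl_old)
    }
    rows[[length(before) + 1]] <- fol_row(confirm, dom = NA_real_, cl_old = cl_old)
    rows[[length(before) + 2]] <- fol_row(confirm + 7 * 86400, dom = runif(1, 6, 11),
                                          day7 = TRUE, cl_new = TRUE)
  }
  bind_rows(rows)
}

#' Simulate a fully ground-truthed herd
#'
#' Schedules `episodes_per_cow` estrus episodes per cow one estrous cycle
#' apart, assigns each episode an outcome (ovulated / false alert / failed /
#' late ovulation), injects the corresponding temperature signal and activity
#' profile with [simulate_cow()], generates twice-daily (08:00 / 17:00)
#' ultrasound exams in which the dominant follicle disappears across the exam
#' pair bracketing each true ovulation plus a day-7 confirmation scan, and
#' simulates weather over the same horizon. Ovulation occurs 24-32 h after
#' episode onset. On episodes whose onset falls in a period with maximum THI
#' above 72 the injected rise amplitude is multiplied by `1 + thi_coupling`.
#'
#' All randomness derives from `config$seed`; a fixed seed reproduces the
#' bundle (and any CSVs written from it) byte for byte.
#'
#' @param config A [herd_config()] object.
#' @param out_dir Optional directory: when given, writes `rrt.csv`,
#'   `activity.csv`, `exams.csv`, `weather.csv` and `truth.csv` there.
#' @return A list of tibbles: `rrt`, `activity`, `exams`, `weather`, `truth`,
#'   `drink`, plus the `config`. `truth` has one row per scheduled episode
#'   with the injected amplitudes and outcome labels.
#' @export
simulate_herd <- function(config = herd_config(), out_dir = NULL) {
  stopifnot(inherits(config, "herd_config"))
  set.seed(config$seed)
  origin <- parse_ts(paste(config$start, "00:00:00"))
  n_hours <- config$n_days * 24L
  sub_seeds <- sample.int(.Machine$integer.max - 1L, config$n_cows + 1L)

  weather <- simulate_weather(config$n_days, seed = sub_seeds[1],
                              summer_fraction = config$summer_fraction,
                              start = config$start)
  periods <- period_max_thi(weather, thi_cut = config$thi_cut)

  set.seed(sub_seeds[1] + 1L) # scheduling stream
  truth <- list()
  p <- config$params
  for (i in seq_len(config$n_cows)) {
    cow <- sprintf("cow%03d", i)
    u <- runif(1, 0, config$cycle_days)
    for (k in seq_len(config$episodes_per_cow)) {
      onset <- origin + (6 + (k - 1) * config$cycle_days + u) * 86400 +
        runif(1, -12, 12) * 3600
      onset <- round_to_block(onset, origin)
      nb <- max(3, min(12, round(rnorm(1, 6, 2)))) # blocks; median 12 h
      peak <- max(40, min(100, round(rnorm(1, 80, 10)))) # median 80 index
      r <- runif(1)
      status <- if (r < config$false_fraction) "false"
        else if (r < config$false_fraction + config$failed_fraction) "failed"
        else if (r < config$false_fraction + config$failed_fraction +
                   config$late_fraction) "late"
        else "ovulated"
      ovulated <- status == "ovulated"
      ov_time <- if (ovulated) onset + round(runif(1, 24, 32)) * 3600 else na_ts()
      hot <- thi_at_event(onset, periods) == "high"
      truth[[length(truth) + 1L]] <- tibble(
        cow_id = cow,
        episode_id = sprintf("%s_e%d", cow, k),
        episode_onset = onset,
        episode_end = onset + nb * 7200,
        duration_h = nb * 2,
        true_peak_index = peak,
        status = status,
        ovulated = ovulated,
        ovulation_time = ov_time,
        injected_rise_amp = if (status == "false") 0 else
          p$estrus_rise_amp * (1 + if (isTRUE(hot)) p$thi_coupling else 0),
        injected_dip_amp = if (ovulated) p$ovulation_dip_amp else 0
      )
    }
  }
  truth <- bind_rows(truth)

  rrt <- vector("list", config$n_cows)
  activity <- vector("list", config$n_cows)
  drink <- vector("list", config$n_cows)
  for (i in seq_len(config$n_cows)) {
    cow <- sprintf("cow%03d", i)
    sim <- simulate_cow(p, truth[truth$cow_id == cow, ], seed = sub_seeds[i + 1],
                        start = origin, n_hours = n_hours, cow_id = cow,
                        missing_fraction = config$missing_fraction)
    rrt[[i]] <- sim$rrt
    activity[[i]] <- sim$activity
    drink[[i]] <- sim$drink
  }
  rrt <- bind_rows(rrt)
  activity <- bind_rows(activity)
  drink <- bind_rows(drink)

  set.seed(sub_seeds[1] + 2L) # exam + dropout stream
  exams <- bind_rows(lapply(seq_len(nrow(truth)), function(j) {
    make_exams(truth$cow_id[j], truth$episode_id[j], truth$episode_onset[j],
               truth$status[j], truth$ovulation_time[j])
  }))

  if (config$dropout_fraction > 0) {
    ov <- which(truth$ovulated)
    burst <- ov[runif(length(ov)) < config$dropout_fraction]
    for (j in burst) {
      ep_ex <- exams[exams$episode_id == truth$episode_id[j] & !exams$day7, ]
      lo <- max(ep_ex$exam_time[ep_ex$exam_time < truth$ovulation_time[j]])
      hi <- min(ep_ex$exam_time[ep_ex$exam_time > truth$ovulation_time[j]])
      span <- hours_between(hi, lo)
      t0 <- lo + runif(1, 0, 0.4 * span) * 3600
      hit <- rrt$cow_id == truth$cow_id[j] &
        rrt$timestamp >= t0 & rrt$timestamp <= t0 + 0.6 * span * 3600
      rrt$valid[hit] <- FALSE
      rrt$temp[hit] <- NA_real_
    }
  }

  bundle <- list(rrt = rrt, activity = activity, exams = exams,
                 weather = weather, truth = truth, drink = drink,
                 config = config)
  if (!is.null(out_dir)) write_herd(bundle, out_dir)
  bundle
}

fmt_ts <- function(x) format(x, "%Y-%m-%d %H:%M:%S", tz = "UTC")

#' Write a simulated herd bundle as headered CSV tables
#'
#' Timestamps are written as local-naive ISO-8601 and temperatures to 0.01 degC.
#'
#' @param bundle A list from [simulate_herd()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_herd <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    df <- mutate(df, across(where(~ inherits(.x, "POSIXct")), fmt_ts))
    readr::write_csv(df, file.path(dir, name), na = "")
  }
  w(mutate(bundle$rrt, temp = round(.data$temp, 2)), "rrt.csv")
  w(bundle$activity, "activity.csv")
  w(mutate(bundle$exams, across(c("fol1", "fol2", "fol3", "cl1", "cl2"),
                                ~ round(.x, 1))), "exams.csv")
  w(mutate(bundle$weather, air_temp = round(.data$air_temp, 2),
           rel_humidity = round(.data$rel_humidity, 1)), "weather.csv")
  w(bundle$truth, "truth.csv")
  invisible(dir)
}

#' Read a herd bundle written by [write_herd()]
#'
#' @param dir Directory containing the CSV tables.
#' @return A list of tibbles `rrt`, `activity`, `exams`, `weather`, `truth`.
#' @export
read_herd <- function(dir) {
  rd <- function(name, types) {
    path <- file.path(dir, name)
    if (!file.exists(path)) stop("missing herd table: ", name)
    readr::read_csv(path, col_types = types, progress = FALSE)
  }
  ts <- readr::col_datetime(format = "%Y-%m-%d %H:%M:%S")
  list(
    rrt = rd("rrt.csv", readr::cols(cow_id = "c", timestamp = ts,
                                    temp = "d", valid = "l")),
    activity = rd("activity.csv", readr::cols(cow_id = "c", block_start = ts,
                                              index = "d")),
    exams = rd("exams.csv", readr::cols(cow_id = "c", episode_id = "c",
                                        exam_time = ts, fol1 = "d", fol2 = "d",
                                        fol3 = "d", cl1 = "d", cl2 = "d",
                                        day7 = "l")),
    weather = rd("weather.csv", readr::cols(timestamp = ts, air_temp = "d",
                                            rel_humidity = "d")),
    truth = rd("truth.csv", readr::cols(cow_id = "c", episode_id = "c",
                                        episode_onset = ts, episode_end = ts,
                                        duration_h = "d", true_peak_index = "d",
                                        status = "c", ovulated = "l",
                                        ovulation_time = ts,
                                        injected_rise_amp = "d",
                                        injected_dip_amp = "d"))
  )
}
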