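#' Detect STD-threshold temperature alerts for one event
#'
#' An alert requires two hourly readings in a row whose standardized change
#' exceeds the threshold: z >= +thr for estrus alerts (positive change) and
#' z <= -thr for ovulation alerts (negative change), evaluated on all points
#' from 12 h before the AAM alert until 12 h after ovulation. Three or more
#' qualifying readings in a row form a single alert timed at the first
#' reading of the run; undefined (NA) readings and grid gaps break runs.
#'
#' @param z Tibble with `timestamp` and `z` for one cow, hourly.
#' @param aam_alert_time AAM alert (episode onset) time.
#' @param ovulation_time Ovulation time; NA yields no alerts.
#' @param thresholds Positive STD thresholds.
#' @return Tibble with `direction` (`estrus` / `ovulation`), `threshold`,
#'   `alert_time`, and the two qualifying readings `z1`, `z2`.
#' @export
detect_temp_alerts <- function(z, aam_alert_time, ovulation_time,
                               thresholds = c(0.5, 1, 1.5, 2, 2.5, 3)) {
  empty <- tibble(direction = character(), threshold = numeric(),
                  alert_time = parse_ts(character()), z1 = numeric(),
                  z2 = numeric())
  if (is.na(ovulation_time)) return(empty)
  win <- z |>
    filter(.data$timestamp >= aam_alert_time - 12 * 3600,
           .data$timestamp <= ovulation_time + 12 * 3600) |>
    arrange(.data$timestamp)
  if (nrow(win) < 2) return(empty)
  gap_new <- c(TRUE, diff(as.numeric(win$timestamp)) != 3600)

  run_alerts <- function(ok, thr, direction) {
    ok[is.na(ok)] <- FALSE
    grp <- cumsum(gap_new | c(TRUE, ok[-1] != ok[-length(ok)]))
    starts <- which(!duplicated(grp) & ok)
    lens <- tabulate(grp)[grp[starts]]
    starts <- starts[lens >= 2]
    if (length(starts) == 0) return(NULL)
    tibble(direction = direction, threshold = thr,
           alert_time = win$timestamp[starts],
           z1 = win$z[starts], z2 = win$z[starts + 1])
  }
  bind_rows(lapply(thresholds, function(thr) {
    bind_rows(
      run_alerts(win$z >= thr, thr, "estrus"),
      run_alerts(win$z <= -thr, thr, "ovulation")
    )
  }))
}

#' Keep only the first alert per event, direction and threshold
#'
#' When several temperature alerts arise for one threshold within an event,
#' the first alert issued defines the time intervals.
#'
#' @param alerts Tibble of alerts with an `episode_id` column.
#' @return One row per `episode_id` x `direction` x `threshold`, the earliest.
#' @export
first_alerts <- function(alerts) {
  if (nrow(alerts) == 0) return(alerts)
  alerts |>
    group_by(.data$episode_id, .data$direction, .data$threshold) |>
    slice_min(.data$alert_time, n = 1, with_ties = FALSE) |>
    ungroup()
}

#' Time intervals between AAM alert, temperature alerts and ovulation
#'
#' For each threshold: interval = alert time minus anchor, in hours, so an
#' alert before its anchor is negative. AAM-anchored intervals are bounded
#' below by -12 h (the search-window start); ovulation-anchored intervals are
#' typically negative (alerts precede ovulation).
#'
#' @param falerts First alerts of one event ([first_alerts()] output filtered
#'   to one `episode_id`).
#' @param aam_alert_time,ovulation_time Event anchors.
#' @param thresholds Thresholds to report (rows emitted even when no alert).
#' @return Tibble with one row per threshold and columns
#'   `aam_to_estrus_alert`, `estrus_alert_to_ovulation`,
#'   `aam_to_ovulation_alert`, `ovulation_alert_to_ovulation` (NA when that
#'   direction produced no alert).
#' @export
compute_intervals <- function(falerts, aam_alert_time, ovulation_time,
                              thresholds = c(0.5, 1, 1.5, 2, 2.5, 3)) {
  bind_rows(lapply(thresholds, function(thr) {
    est <- falerts |> filter(.data$direction == "estrus", .data$threshold == thr)
    ov <- falerts |> filter(.data$direction == "ovulation", .data$threshold == thr)
    est_t <- if (nrow(est)) est$alert_time[1] else na_ts()
    ov_t <- if (nrow(ov)) ov$alert_time[1] else na_ts()
    tibble(
      threshold = thr,
      aam_to_estrus_alert = hours_between(est_t, aam_alert_time),
      estrus_alert_to_ovulation = hours_between(est_t, ovulation_time),
      aam_to_ovulation_alert = hours_between(ov_t, aam_alert_time),
      ovulation_alert_to_ovulation = hours_between(ov_t, ovulation_time)
    )
  }))
}

#' Descriptive summary of alert intervals by threshold
#'
#' Emulates a threshold-by-interval descriptive table: percent of eligible
#' events alerted, and mean, sample SD, minimum and maximum of each interval
#' type over the alerted events.
#'
#' @param intervals Tibble of per-event interval rows (with `episode_id` and
#'   `threshold`), one per eligible event and threshold.
#' @param n_events Number of eligible events (denominator for % alerted).
#' @return Tibble with `interval`, `threshold`, `n_alerted`, `pct_alerted`,
#'   `mean_h`, `sd_h`, `min_h`, `max_h` (statistics NA when nothing alerted).
#' @export
summarize_alerts <- function(intervals, n_events) {
  stopifnot(n_events > 0)
  kinds <- c("aam_to_estrus_alert", "estrus_alert_to_ovulation",
             "aam_to_ovulation_alert", "ovulation_alert_to_ovulation")
  intervals |>
    tidyr::pivot_longer(all_of(kinds), names_to = "interval",
                        values_to = "hours") |>
    group_by(.data$interval, .data$threshold) |>
    summarise(
      n_alerted = sum(!is.na(.data$hours)),
      pct_alerted = 100 * .data$n_alerted[1] / n_events,
      mean_h = if (n_alerted[1] > 0) mean(.data$hours, na.rm = TRUE) else NA_real_,
      sd_h = if (n_alerted[1] > 1) sd(.data$hours, na.rm = TRUE) else NA_real_,
      min_h = if (n_alerted[1] > 0) min(.data$hours, na.rm = TRUE) else NA_real_,
      max_h = if (n_alerted[1] > 0) max(.data$hours, na.rm = TRUE) else NA_real_,
      .groups = "drop"
    ) |>
    mutate(interval = factor(.data$interval, levels = kinds)) |>
    arrange(.data$interval, .data$threshold)
}

#' Detect alerts and build interval records for all eligible events
#'
#' @param z Standardized series ([standardize()] output, all cows).
#' @param episodes,ovulations Output of [process_episodes()].
#' @param eligible_ids Episode ids of eligible (true, ovulated, non-excluded)
#'   events.
#' @param thresholds STD thresholds.
#' @return A list with `alerts` (all alerts), `first` (first alerts) and
#'   `intervals` (per event x threshold interval records).
#' @export
alert_pipeline <- function(z, episodes, ovulations, eligible_ids,
                           thresholds = c(0.5, 1, 1.5, 2, 2.5, 3)) {
  eps <- episodes |> filter(.data$episode_id %in% eligible_ids)
  ov <- ovulations |> filter(.data$episode_id %in% eligible_ids)
  eps <- inner_join(eps, select(ov, "episode_id", "ovulation_time"),
                    by = "episode_id")
  z_split <- split(z, z$cow_id)
  alerts <- bind_rows(lapply(seq_len(nrow(eps)), function(j) {
    a <- detect_temp_alerts(z_split[[eps$cow_id[j]]], eps$onset[j],
                            eps$ovulation_time[j], thresholds)
    if (nrow(a)) a$episode_id <- eps$episode_id[j]
    a
  }))
  fa <- first_alerts(alerts)
  intervals <- bind_rows(lapply(seq_len(nrow(eps)), function(j) {
    fj <- if (nrow(fa)) filter(fa, .data$episode_id == eps$episode_id[j]) else fa
    iv <- compute_intervals(fj, eps$onset[j], eps$ovulation_time[j], thresholds)
    iv$episode_id <- eps$episode_id[j]
    iv
  }))
  list(alerts = alerts, first = fa, intervals = intervals)
}
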