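#' Baseline-relative temperature over a time window
#'
#' Extracts y = temperature - baseline mean at every valid hourly reading
#' with a defined baseline inside the closed window `[t_start, t_end]`, and
#' reports the fraction of expected hourly slots
#' (`floor(t_end - t_start) + 1`) that are missing.
#'
#' @param rrt Tibble with `cow_id`, `timestamp`, `temp`, `valid` (one or more
#'   cows).
#' @param baseline Output of [rolling_baseline()].
#' @param cow Cow identifier.
#' @param t_start,t_end Window bounds (POSIXct), inclusive on both sides.
#' @return A list: `rel`, a tibble with `timestamp`, `x_h` (hours from
#'   `t_start`, to the nearest second) and `y` (degC); and `missing_fraction`.
#' @export
window_relative <- function(rrt, baseline, cow, t_start, t_end) {
  n_expected <- floor(hours_between(t_end, t_start)) + 1
  if (n_expected <= 0) stop("window contains no expected hourly points")
  rel <- rrt |>
    filter(.data$cow_id == cow, .data$timestamp >= t_start,
           .data$timestamp <= t_end, .data$valid, !is.na(.data$temp)) |>
    inner_join(
      baseline |>
        filter(.data$cow_id == cow, !is.na(.data$baseline_mean)) |>
        select("timestamp", "baseline_mean"),
      by = "timestamp"
    ) |>
    arrange(.data$timestamp) |>
    transmute(
      timestamp = .data$timestamp,
      x_h = round(as.numeric(difftime(.data$timestamp, t_start, units = "secs"))) / 3600,
      y = .data$temp - .data$baseline_mean
    )
  list(rel = rel, missing_fraction = 1 - nrow(rel) / n_expected)
}

#' Positive area under a baseline-relative temperature curve
#'
#' Trapezoidal integral over observed timestamps where only positive areas
#' are considered: sample values are clamped at zero before integration, so
#' the result is the trapezoidal rule applied to `max(y, 0)`. Units are
#' degC-hours.
#'
#' @param x Observation times, hours (strictly increasing).
#' @param y Baseline-relative temperatures, degC.
#' @return The positive AUC (>= 0), or NA with fewer than 2 points.
#' @examples
#' positive_auc(0:3, c(0, 0.4, 0.4, 0)) # 0.8
#' positive_auc(0:2, c(-0.5, 0.6, -0.5)) # 0.6
#' @export
positive_auc <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2) return(NA_real_)
  if (any(diff(x) <= 0)) stop("`x` must be strictly increasing")
  yc <- pmax(y, 0)
  sum(diff(x) * (head(yc, -1) + tail(yc, -1)) / 2)
}

#' Maximum positive and negative temperature change
#'
#' PTC is the maximum and NTC the minimum of the baseline-relative series
#' within the window. Neither is clamped at zero: a window entirely below
#' baseline yields a negative PTC.
#'
#' @param y Baseline-relative temperatures, degC.
#' @return PTC or NTC in degC; NA for an empty window.
#' @examples
#' ptc(c(-0.1, 0.5, 0.2)) # 0.5
#' ntc(c(-0.1, 0.5, 0.2)) # -0.1
#' @export
ptc <- function(y) if (length(y) == 0) NA_real_ else max(y)

#' @rdname ptc
#' @export
ntc <- function(y) if (length(y) == 0) NA_real_ else min(y)

window_feature_row <- function(rrt, baseline, cow, t_start, t_end, kind,
                               missing_limit) {
  wr <- window_relative(rrt, baseline, cow, t_start, t_end)
  n <- nrow(wr$rel)
  tibble(
    window_kind = kind,
    auc = if (n >= 2) positive_auc(wr$rel$x_h, wr$rel$y) else NA_real_,
    ptc = ptc(wr$rel$y),
    ntc = ntc(wr$rel$y),
    n_points = n,
    missing_fraction = wr$missing_fraction,
    window_excluded = wr$missing_fraction > missing_limit || n < 2
  )
}

#' Thermal features of one estrus event
#'
#' Computes positive AUC, PTC and NTC over the estrus window (AAM onset to
#' end of estrus) and the ovulation window (between the ultrasound exam that
#' confirmed ovulation and the preceding exam), relative to the rolling
#' baseline. The event is excluded from downstream summaries when either
#' window misses more than `missing_limit` (default 25 %) of its expected
#' hourly points.
#'
#' @param episode One-row tibble with `cow_id`, `episode_id`, `onset`,
#'   `end_time`.
#' @param ovulation One-row tibble with `exam_before`, `exam_after` (the
#'   bracketing exam pair), status `ovulated`.
#' @param rrt,baseline Series tibbles as elsewhere.
#' @param missing_limit Missingness exclusion threshold.
#' @return A two-row tibble (window kinds `estrus` and `ovulation`) with
#'   `auc`, `ptc`, `ntc`, `n_points`, `missing_fraction` and the event-level
#'   `excluded` flag.
#' @export
event_features <- function(episode, ovulation, rrt, baseline,
                           missing_limit = 0.25) {
  stopifnot(nrow(episode) == 1, nrow(ovulation) == 1)
  rows <- bind_rows(
    window_feature_row(rrt, baseline, episode$cow_id, episode$onset,
                       episode$end_time, "estrus", missing_limit),
    window_feature_row(rrt, baseline, episode$cow_id, ovulation$exam_before,
                       ovulation$exam_after, "ovulation", missing_limit)
  )
  rows$cow_id <- episode$cow_id
  rows$episode_id <- episode$episode_id
  rows$excluded <- any(rows$window_excluded)
  select(rows, "cow_id", "episode_id", "window_kind", "auc", "ptc", "ntc",
         "n_points", "missing_fraction", "excluded")
}

#' Thermal features for every analyzable event of a herd
#'
#' Restricts to true-estrus episodes with a confirmed (bracketed) ovulation —
#' false alerts and failed ovulations carry no ovulation window — and applies
#' [event_features()] to each.
#'
#' @param episodes,ovulations Output of [process_episodes()].
#' @param rrt,baseline Series tibbles.
#' @param missing_limit Missingness exclusion threshold.
#' @return Tibble of per-event, per-window features.
#' @export
compute_features <- function(episodes, ovulations, rrt, baseline,
                             missing_limit = 0.25) {
  if (nrow(ovulations) == 0) return(tibble())
  ok <- ovulations |>
    filter(.data$status == "ovulated") |>
    inner_join(select(episodes, "episode_id", "onset", "end_time"),
               by = "episode_id")
  rrt_split <- split(rrt, rrt$cow_id)
  base_split <- split(baseline, baseline$cow_id)
  bind_rows(lapply(seq_len(nrow(ok)), function(j) {
    cw <- ok$cow_id[j]
    event_features(
      tibble(cow_id = cw, episode_id = ok$episode_id[j], onset = ok$onset[j],
             end_time = ok$end_time[j]),
      tibble(exam_before = ok$exam_before[j], exam_after = ok$exam_after[j]),
      rrt_split[[cw]], base_split[[cw]], missing_limit
    )
  }))
}
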