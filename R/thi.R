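#' Temperature-humidity index (THI)
#'
#' THI = 0.8 * T + (RH / 100) * (T - 14.3) + 46.4, with T the air temperature
#' in degC and RH the relative humidity in percent. At T = 14.3 degC the
#' humidity term vanishes. Values above 72 are conventionally treated as
#' heat-stress conditions for dairy cattle.
#'
#' @param air_temp Air temperature, degC.
#' @param rel_humidity Relative humidity, percent (0-100).
#' @return The THI (vectorized).
#' @examples
#' thi(30, 60) # 79.82
#' thi(14.3, 85) # 57.84 regardless of humidity
#' @export
thi <- function(air_temp, rel_humidity) {
  if (any(is.na(rel_humidity)) || any(rel_humidity < 0 | rel_humidity > 100)) {
    stop("`rel_humidity` must lie in [0, 100]")
  }
  0.8 * air_temp + (rel_humidity / 100) * (air_temp - 14.3) + 46.4
}

#' Assign a clock time to its THI reporting period
#'
#' Periods are half-open: early morning 00:00-07:59, morning 08:00-15:59,
#' evening 16:00-23:59.
#'
#' @param timestamp POSIXct vector.
#' @return Character vector: `early_morning`, `morning` or `evening`.
#' @export
thi_period <- function(timestamp) {
  hod <- as.integer(format(timestamp, "%H", tz = "UTC"))
  c("early_morning", "morning", "evening")[hod %/% 8L + 1L]
}

#' Maximum THI per calendar date and period, with heat-stress category
#'
#' @param weather Tibble with `timestamp`, `air_temp`, `rel_humidity`.
#' @param thi_cut Category cutoff; a period is `high` when its maximum THI is
#'   strictly above the cutoff (exactly 72 is `low`).
#' @return Tibble with `date`, `period`, `max_thi`, `category`; periods with
#'   no readings emit no row.
#' @export
period_max_thi <- function(weather, thi_cut = 72) {
  weather |>
    mutate(
      date = as.Date(.data$timestamp, tz = "UTC"),
      period = thi_period(.data$timestamp),
      thi_val = thi(.data$air_temp, .data$rel_humidity)
    ) |>
    group_by(.data$date, .data$period) |>
    summarise(max_thi = max(.data$thi_val), .groups = "drop") |>
    mutate(category = ifelse(.data$max_thi > thi_cut, "high", "low"))
}

#' THI category of the period containing an event time
#'
#' @param event_time POSIXct vector of event times (estrus onset, ovulation).
#' @param period_table Output of [period_max_thi()].
#' @return Character vector of categories; `"unknown"` where no weather row
#'   covers the event's date and period.
#' @examples
#' w <- simulate_weather(3, seed = 2, summer_fraction = 1)
#' thi_at_event(w$timestamp[15], period_max_thi(w))
#' @export
thi_at_event <- function(event_time, period_table) {
  q <- tibble(date = as.Date(event_time, tz = "UTC"),
              period = thi_period(event_time))
  out <- left_join(q, period_table, by = c("date", "period"))
  ifelse(is.na(out$category), "unknown", out$category)
}
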