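# small builders shared across tests

T0 <- as.POSIXct("2019-06-01 00:00:00", tz = "UTC")

make_rrt <- function(temps, cow = "c1", start = T0, valid = TRUE) {
  tibble::tibble(
    cow_id = cow,
    timestamp = start + 3600 * (seq_along(temps) - 1),
    temp = temps,
    valid = rep_len(valid, length(temps))
  )
}

flat_baseline <- function(rrt, mean = 38.6, sd = 0) {
  tibble::tibble(
    cow_id = rrt$cow_id,
    timestamp = rrt$timestamp,
    baseline_mean = mean,
    baseline_sd = sd,
    n_used = 120L
  )
}

# one-episode truth row on the 2-h block grid
make_truth <- function(onset_h, duration_h, peak = 85, ovulation_h = NA,
                       rise = 0.55, dip = -0.6, cow = "c1", start = T0) {
  tibble::tibble(
    cow_id = cow,
    episode_onset = start + onset_h * 3600,
    episode_end = start + (onset_h + duration_h) * 3600,
    true_peak_index = peak,
    ovulated = !is.na(ovulation_h),
    ovulation_time = if (is.na(ovulation_h)) {
      as.POSIXct(NA_character_, tz = "UTC")
    } else {
      start + ovulation_h * 3600
    },
    injected_rise_amp = rise,
    injected_dip_amp = dip
  )
}

quiet_params <- function(...) {
  signal_params(noise_sd = 0, drink_rate = 0, circadian_amplitude = 0,
                thi_coupling = 0, ...)
}
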