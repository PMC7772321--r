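#' Signal-shape parameters for the synthetic rumen-reticular temperature model
#'
#' Bundles the physiological signal components that the generator injects into
#' each simulated cow: a circadian sinusoid around a basal temperature,
#' Gaussian sensor noise, drinking-induced transient drops with exponential
#' recovery, a raised-cosine estrus rise spanning the activity episode, and a
#' raised-cosine peri-ovulatory dip centred on the true ovulation time.
#'
#' Defaults follow the magnitudes reported for lactating Holstein cows: a
#' basal reticulorumen temperature of 38.6 degC, an estrus rise of 0.55 degC, an
#' ovulation dip of -0.60 degC, and a high-THI amplification of the estrus rise.
#' Noise, circadian amplitude and drinking dynamics are free parameters chosen
#' as field-realistic (see the methods vignette).
#'
#' @param basal_temp Basal rumen-reticular temperature, degC.
#' @param circadian_amplitude Amplitude of the 24-h sinusoid, degC.
#' @param circadian_acrophase Clock hour of the circadian maximum (early
#'   evening by default).
#' @param noise_sd SD of i.i.d. Gaussian reading noise, degC (>= 0).
#' @param drink_rate Expected number of detectable drinking transients per day.
#' @param drink_depth Instantaneous temperature drop at a drinking bout, degC
#'   (must be negative).
#' @param drink_recovery Exponential recovery time constant of a drinking
#'   transient, hours.
#' @param estrus_rise_amp Peak amplitude of the estrus-associated rise, degC.
#' @param estrus_rise_duration Fallback duration of the rise, hours (> 0); in
#'   herd simulations the rise spans the activity episode itself.
#' @param ovulation_dip_amp Peak (most negative) amplitude of the
#'   peri-ovulatory dip, degC (must be negative).
#' @param ovulation_dip_duration Total width of the dip, hours.
#' @param thi_coupling Dimensionless gain: on heat-stress periods (max THI >
#'   72) the injected rise amplitude is multiplied by `1 + thi_coupling`.
#'
#' @return A list of class `signal_params`.
#' @examples
#' p <- signal_params(noise_sd = 0)
#' p$basal_temp
#' @export
signal_params <- function(basal_temp = 38.6,
                          circadian_amplitude = 0.15,
                          circadian_acrophase = 19,
                          noise_sd = 0.12,
                          drink_rate = 0.5,
                          drink_depth = -1.2,
                          drink_recovery = 1,
                          estrus_rise_amp = 0.55,
                          estrus_rise_duration = 12,
                          ovulation_dip_amp = -0.60,
                          ovulation_dip_duration = 8,
                          thi_coupling = 0.4) {
  stopifnot(
    noise_sd >= 0,
    estrus_rise_duration > 0,
    drink_depth < 0,
    ovulation_dip_amp < 0,
    drink_recovery > 0,
    ovulation_dip_duration > 0,
    drink_rate >= 0
  )
  structure(
    list(
      basal_temp = basal_temp,
      circadian_amplitude = circadian_amplitude,
      circadian_acrophase = circadian_acrophase,
      noise_sd = noise_sd,
      drink_rate = drink_rate,
      drink_depth = drink_depth,
      drink_recovery = drink_recovery,
      estrus_rise_amp = estrus_rise_amp,
      estrus_rise_duration = estrus_rise_duration,
      ovulation_dip_amp = ovulation_dip_amp,
      ovulation_dip_duration = ovulation_dip_duration,
      thi_coupling = thi_coupling
    ),
    class = "signal_params"
  )
}

#' Configuration for a synthetic herd and its analysis
#'
#' Collects everything [simulate_herd()] and [run_pipeline()] need: herd size
#' and episode scheduling, outcome fractions, the signal parameters, and the
#' analysis constants (alert threshold 35 index, median cuts 80 index / 12 h,
#' THI cutoff 72, 25 % missingness limit, 120-h baseline window).
#'
#' @param n_cows Number of cows (>= 1).
#' @param episodes_per_cow Estrus episodes scheduled per cow, one per ~21-d
#'   estrous cycle.
#' @param cycle_days Estrous cycle length used to space episodes, days.
#' @param false_fraction Fraction of activity episodes that are false alerts
#'   (no dominant pre-ovulatory follicle at the alert exam).
#' @param failed_fraction Fraction with a persisting follicle and no new
#'   corpus luteum at the day-7 scan (failed ovulation).
#' @param late_fraction Fraction with a persisting follicle but a new corpus
#'   luteum at day 7 (late ovulation).
#' @param dropout_fraction Fraction of ovulated episodes that receive a
#'   contiguous sensor-dropout burst across the ovulation window, emulating
#'   events later excluded for > 25 % missing readings.
#' @param missing_fraction Fraction of hourly readings missing completely at
#'   random.
#' @param summer_fraction Fraction of simulated days that are heat-stress days
#'   (daily maximum THI > 72).
#' @param params A [signal_params()] object.
#' @param seed Single integer seed driving all randomness.
#' @param start Start date of the simulation (ISO string or Date).
#' @param alert_threshold AAM activity index that triggers enrolment.
#' @param thresholds Ascending STD thresholds for temperature alerts.
#' @param peak_cut,duration_cut Median cuts for estrous-expression categories
#'   (index; hours).
#' @param thi_cut THI above which a period is "high".
#' @param missing_limit Maximum tolerated fraction of missing hourly points in
#'   a feature window before the event is excluded.
#' @param baseline_window Trailing baseline window, hours.
#' @param min_window_points Minimum valid readings for a defined baseline.
#' @param sd_floor Lower bound on the baseline SD used for standardization,
#'   degC.
#' @param drop_threshold,recovery_limit Water-intake correction constants
#'   (degC; hours), see [correct_water_intake()].
#'
#' @return A list of class `herd_config`; `n_days` is derived from the
#'   episode schedule.
#' @export
herd_config <- function(n_cows = 20,
                        episodes_per_cow = 2,
                        cycle_days = 21,
                        false_fraction = 0.13,
                        failed_fraction = 0.03,
                        late_fraction = 0,
                        dropout_fraction = 0.03,
                        missing_fraction = 0.02,
                        summer_fraction = 0.3,
                        params = signal_params(),
                        seed = 1,
                        start = "2019-06-01",
                        alert_threshold = 35,
                        thresholds = c(0.5, 1, 1.5, 2, 2.5, 3),
                        peak_cut = 80,
                        duration_cut = 12,
                        thi_cut = 72,
                        missing_limit = 0.25,
                        baseline_window = 120,
                        min_window_points = 90,
                        sd_floor = 0.05,
                        drop_threshold = 0.8,
                        recovery_limit = 3) {
  stopifnot(
    n_cows >= 1,
    episodes_per_cow >= 1,
    cycle_days > 0,
    false_fraction >= 0, false_fraction <= 1,
    failed_fraction >= 0, late_fraction >= 0,
    false_fraction + failed_fraction + late_fraction <= 1,
    dropout_fraction >= 0, dropout_fraction <= 1,
    missing_fraction >= 0, missing_fraction < 1,
    summer_fraction >= 0, summer_fraction <= 1,
    inherits(params, "signal_params"),
    alert_threshold > 0, peak_cut > 0, duration_cut > 0, thi_cut > 0,
    missing_limit > 0,
    baseline_window > 0, min_window_points > 0,
    !is.unsorted(thresholds), all(thresholds > 0)
  )
  cfg <- list(
    n_cows = n_cows,
    episodes_per_cow = episodes_per_cow,
    cycle_days = cycle_days,
    false_fraction = false_fraction,
    failed_fraction = failed_fraction,
    late_fraction = late_fraction,
    dropout_fraction = dropout_fraction,
    missing_fraction = missing_fraction,
    summer_fraction = summer_fraction,
    params = params,
    seed = as.integer(seed),
    start = as.character(start),
    alert_threshold = alert_threshold,
    thresholds = thresholds,
    peak_cut = peak_cut,
    duration_cut = duration_cut,
    thi_cut = thi_cut,
    missing_limit = missing_limit,
    baseline_window = baseline_window,
    min_window_points = min_window_points,
    sd_floor = sd_floor,
    drop_threshold = drop_threshold,
    recovery_limit = recovery_limit
  )
  # horizon: 6 d of pre-episode baseline, the scheduled cycles, and room for
  # the last ovulation plus its exams
  cfg$n_days <- 6 + episodes_per_cow * cycle_days + 10
  structure(cfg, class = "herd_config")
}

#' Read a herd configuration from a YAML file
#'
#' Top-level keys map to [herd_config()] arguments; a nested `params` mapping
#' maps to [signal_params()] arguments. Missing keys keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `herd_config` object.
#' @export
herd_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  sp <- do.call(signal_params, raw$params %||% list())
  raw$params <- sp
  do.call(herd_config, raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
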