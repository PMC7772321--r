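#' Run the full simulation and analysis pipeline
#'
#' Orchestrates simulate -> water correction -> rolling baseline ->
#' standardization -> episode building -> THI periods -> thermal features ->
#' STD-threshold alerts -> event ledger and group means. Any stage failure
#' aborts with an error naming the stage. When `out_dir` is given, every
#' stage's table is written there as CSV (or JSON for the ledger) together
#' with a manifest recording the seed, a configuration hash and per-table row
#' counts; rerunning with the same configuration reproduces the artifacts
#' byte for byte.
#'
#' @param config A [herd_config()].
#' @param out_dir Optional artifact directory.
#' @return (Invisibly) a list with every intermediate and final table:
#'   `bundle`, `rrt_corrected`, `baseline`, `z`, `episodes`, `ovulations`,
#'   `periods`, `features`, `alerts`, `intervals`, `alert_summary`, `ledger`,
#'   `cell_means`, `median_cuts`, `manifest`.
#' @export
run_pipeline <- function(config = herd_config(), out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(force(expr),
             error = function(e) stop("stage '", name, "' failed: ",
                                      conditionMessage(e), call. = FALSE))
  }

  bundle <- stage("simulate", simulate_herd(config))

  rrt_c <- stage("preprocess", correct_water_intake(
    bundle$rrt, drop_threshold = config$drop_threshold,
    recovery_limit = config$recovery_limit))
  baseline <- stage("preprocess", rolling_baseline(
    rrt_c, window = config$baseline_window,
    min_window_points = config$min_window_points))
  z <- stage("preprocess", standardize(rrt_c, baseline,
                                       sd_floor = config$sd_floor))

  ep <- stage("episodes", process_episodes(
    bundle$activity, bundle$exams, alert_threshold = config$alert_threshold,
    peak_cut = config$peak_cut, duration_cut = config$duration_cut))

  periods <- stage("environment", {
    if (is.null(bundle$weather) || nrow(bundle$weather) == 0) {
      stop("no weather data")
    }
    period_max_thi(bundle$weather, thi_cut = config$thi_cut)
  })

  features <- stage("features", compute_features(
    ep$episodes, ep$ovulations, rrt_c, baseline,
    missing_limit = config$missing_limit))

  ledger <- stage("report", account_events(ep$episodes, ep$ovulations, features))

  al <- stage("alerts", alert_pipeline(z, ep$episodes, ep$ovulations,
                                       ledger$analyzed_ids, config$thresholds))
  alert_summary <- stage("alerts", {
    if (length(ledger$analyzed_ids) > 0) {
      summarize_alerts(al$intervals, n_events = length(ledger$analyzed_ids))
    } else {
      tibble()
    }
  })

  labelled <- stage("report", label_features(features, ep$episodes,
                                             ep$ovulations, periods))
  cell_means <- stage("report", group_means(
    labelled, grouping = c("window_kind", "peak_category", "thi_category")))
  median_cuts <- stage("report", compute_median_cuts(ep$episodes))

  manifest <- list(
    seed = config$seed,
    config_hash = rlang::hash(config),
    rows = list(
      rrt = nrow(bundle$rrt), activity = nrow(bundle$activity),
      exams = nrow(bundle$exams), weather = nrow(bundle$weather),
      truth = nrow(bundle$truth), episodes = nrow(ep$episodes),
      ovulations = nrow(ep$ovulations), features = nrow(features),
      alerts = nrow(al$alerts), intervals = nrow(al$intervals)
    ),
    n_analyzed = ledger$n_analyzed
  )

  out <- list(bundle = bundle, rrt_corrected = rrt_c, baseline = baseline,
              z = z, episodes = ep$episodes, ovulations = ep$ovulations,
              periods = periods, features = features, alerts = al$alerts,
              intervals = al$intervals, alert_summary = alert_summary,
              ledger = ledger, cell_means = cell_means,
              median_cuts = median_cuts, manifest = manifest)

  if (!is.null(out_dir)) {
    stage("write", write_pipeline(out, out_dir))
  }
  invisible(out)
}

#' Join expression and THI labels onto feature rows
#'
#' Attaches the episode's peak and duration categories and the THI category
#' of the matching sampling time: the period containing the estrus onset for
#' estrus-window rows, and the period containing the ovulation time for
#' ovulation-window rows.
#'
#' @param features Output of [compute_features()].
#' @param episodes,ovulations Output of [process_episodes()].
#' @param periods Output of [period_max_thi()].
#' @return `features` with `peak_category`, `duration_category`,
#'   `thi_category` columns.
#' @export
label_features <- function(features, episodes, ovulations, periods) {
  if (nrow(features) == 0) return(features)
  lab <- features |>
    left_join(select(episodes, "episode_id", "peak_category",
                     "duration_category", "onset"), by = "episode_id") |>
    left_join(select(ovulations, "episode_id", "ovulation_time"),
              by = "episode_id") |>
    mutate(
      sampling_time = as.POSIXct(ifelse(.data$window_kind == "estrus",
                                        .data$onset, .data$ovulation_time),
                                 origin = "1970-01-01", tz = "UTC"),
      thi_category = thi_at_event(.data$sampling_time, periods)
    ) |>
    select(-"onset", -"ovulation_time", -"sampling_time")
  lab
}

write_pipeline <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_herd(out$bundle, dir)
  wcsv <- function(df, name) {
    df <- mutate(df, across(where(~ inherits(.x, "POSIXct")), fmt_ts))
    readr::write_csv(df, file.path(dir, name), na = "")
  }
  wcsv(mutate(out$baseline, baseline_mean = round(.data$baseline_mean, 4),
              baseline_sd = round(.data$baseline_sd, 4)), "baseline.csv")
  wcsv(out$episodes, "episodes.csv")
  wcsv(out$ovulations, "ovulations.csv")
  wcsv(out$periods, "thi_periods.csv")
  wcsv(out$features, "features.csv")
  wcsv(out$alerts, "alerts.csv")
  wcsv(out$intervals, "intervals.csv")
  wcsv(out$alert_summary, "alert_summary.csv")
  wcsv(out$cell_means, "group_means.csv")
  ledger <- out$ledger
  ledger$reasons <- NULL
  jsonlite::write_json(unclass(ledger), file.path(dir, "ledger.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(out$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
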