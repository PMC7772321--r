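#' Event accounting ledger
#'
#' Counts every AAM-alerted episode and the reasons events drop out of the
#' analysis: false alerts (no dominant pre-ovulatory follicle), failed
#' ovulations (follicle persists, no day-7 corpus luteum), late ovulations,
#' episodes excluded for more than 25 % missing temperature data, and
#' episodes without a usable exam. Percentages are relative to the total
#' number of alerted episodes, and
#' `n_analyzed = n_alerted_total - n_false - n_failed - n_late -
#' n_missing_excluded - n_no_exam` holds by construction.
#'
#' @param episodes,ovulations Output of [process_episodes()].
#' @param features Output of [compute_features()].
#' @return A list of class `event_ledger`: counts, percentages, the analyzed
#'   episode ids, and a per-episode `reasons` tibble.
#' @export
account_events <- function(episodes, ovulations, features) {
  n_total <- nrow(episodes)
  stopifnot(n_total > 0)
  if (nrow(ovulations) > 0 &&
      !all(ovulations$episode_id %in% episodes$episode_id)) {
    stop("ovulation records reference unknown episodes")
  }
  reasons <- episodes |> select("episode_id", "is_true_estrus", "exclude_reason")
  st <- if (nrow(ovulations)) select(ovulations, "episode_id", "status") else
    tibble(episode_id = character(), status = character())
  reasons <- left_join(reasons, st, by = "episode_id")
  excl <- if (nrow(features)) features |>
    distinct(.data$episode_id, .data$excluded) else
    tibble(episode_id = character(), excluded = logical())
  reasons <- left_join(reasons, excl, by = "episode_id")
  reasons <- reasons |>
    mutate(reason = case_when(
      !is.na(.data$exclude_reason) ~ .data$exclude_reason,
      .data$is_true_estrus %in% FALSE ~ "false_alert",
      .data$status %in% "failed" ~ "failed_ovulation",
      .data$status %in% "late" ~ "late_ovulation",
      .data$status %in% "undetermined" ~ "undetermined",
      .data$excluded %in% TRUE ~ "missing_excluded",
      TRUE ~ "analyzed"
    ))
  cnt <- function(x) sum(reasons$reason == x)
  ledger <- list(
    n_alerted_total = n_total,
    n_false = cnt("false_alert"),
    n_failed_ovulation = cnt("failed_ovulation"),
    n_late = cnt("late_ovulation"),
    n_missing_excluded = cnt("missing_excluded"),
    n_no_exam = cnt("no_exam") + cnt("undetermined"),
    n_analyzed = cnt("analyzed"),
    analyzed_ids = reasons$episode_id[reasons$reason == "analyzed"],
    reasons = reasons |> select("episode_id", "reason")
  )
  ledger$pct_false <- 100 * ledger$n_false / n_total
  ledger$pct_missing_excluded <- 100 * ledger$n_missing_excluded / n_total
  ledger$pct_analyzed <- 100 * ledger$n_analyzed / n_total
  structure(ledger, class = "event_ledger")
}

#' @export
print.event_ledger <- function(x, ...) {
  cat(sprintf(
    paste0("Event ledger: %d alerted episodes\n",
           "  false alerts:      %d (%.1f%%)\n",
           "  failed ovulations: %d\n",
           "  late ovulations:   %d\n",
           "  missing-excluded:  %d (%.1f%%)\n",
           "  no usable exam:    %d\n",
           "  analyzed:          %d (%.1f%%)\n"),
    x$n_alerted_total, x$n_false, x$pct_false, x$n_failed_ovulation,
    x$n_late, x$n_missing_excluded, x$pct_missing_excluded, x$n_no_exam,
    x$n_analyzed, x$pct_analyzed))
  invisible(x)
}

#' Descriptive cell means of thermal features
#'
#' Mean, sample SD and SE of AUC, PTC and NTC per grouping cell (for example
#' sampling window x estrous-expression category x THI category). Cells with
#' no events are emitted with n = 0 and absent statistics when the grouping
#' columns are factors or `complete_cells` combinations are supplied.
#'
#' @param features Feature rows (non-excluded rows are used) joined with any
#'   label columns needed by `grouping`.
#' @param grouping Character vector of grouping column names.
#' @return Tibble with one row per cell: `n`, and `*_mean`, `*_sd`, `*_se`
#'   for each of `auc`, `ptc`, `ntc`.
#' @export
group_means <- function(features, grouping = "window_kind") {
  stopifnot(all(grouping %in% names(features)))
  out <- features |>
    filter(!.data$excluded) |>
    group_by(across(all_of(grouping))) |>
    summarise(
      n = dplyr::n(),
      across(c("auc", "ptc", "ntc"),
             list(mean = ~ mean(.x, na.rm = TRUE),
                  sd = ~ if (dplyr::n() > 1) sd(.x, na.rm = TRUE) else NA_real_,
                  se = ~ if (dplyr::n() > 1)
                    sd(.x, na.rm = TRUE) / sqrt(dplyr::n()) else NA_real_),
             .names = "{.col}_{.fn}"),
      .groups = "drop"
    )
  out
}

#' Empirical median cuts for estrous expression
#'
#' Reports the herd's own medians of peak activity and episode duration over
#' true-estrus episodes. The fixed reference cuts (80 index, 12 h) remain the
#' categorization defaults; the empirical values are reported alongside for
#' comparison.
#'
#' @param episodes Episode tibble with `peak_index`, `duration_h` and
#'   `is_true_estrus`.
#' @return A list with `peak_cut` and `duration_cut`.
#' @export
compute_median_cuts <- function(episodes) {
  keep <- episodes$is_true_estrus %in% TRUE
  stopifnot(any(keep))
  list(
    peak_cut = median(episodes$peak_index[keep]),
    duration_cut = median(episodes$duration_h[keep])
  )
}
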