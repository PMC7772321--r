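#' Detect estrus episodes from 2-h-block activity data
#'
#' Maximal runs of blocks at or above the alert threshold (35 index by
#' default) become episodes; quiet gaps shorter than `gap_blocks` blocks
#' between above-threshold runs are absorbed, so a single-block sensor dropout
#' does not split one estrus in two. Peak is the run maximum, the onset is the
#' start of the first qualifying block (the AAM alert time), and duration is
#' the run length times 2 h.
#'
#' @param activity Tibble with `cow_id`, `block_start`, `index`.
#' @param alert_threshold Activity index that defines an alert.
#' @param gap_blocks Quiet runs shorter than this many blocks are merged into
#'   the surrounding episode.
#' @return Tibble with one row per episode: `cow_id`, `episode_id`, `onset`,
#'   `end` (start of the last qualifying block), `end_time` (`onset` +
#'   duration), `duration_h`, `peak_index`.
#' @examples
#' a <- tibble::tibble(
#'   cow_id = "c1",
#'   block_start = as.POSIXct("2019-06-01", tz = "UTC") + 7200 * (0:4),
#'   index = c(30, 40, 85, 60, 30)
#' )
#' detect_episodes(a)
#' @export
detect_episodes <- function(activity, alert_threshold = 35, gap_blocks = 3) {
  if (nrow(activity) == 0) {
    return(tibble(cow_id = character(), episode_id = character(),
                  onset = parse_ts(character()), end = parse_ts(character()),
                  end_time = parse_ts(character()), duration_h = numeric(),
                  peak_index = numeric()))
  }
  activity |>
    group_by(.data$cow_id) |>
    group_modify(~ detect_episodes_cow(.x, alert_threshold, gap_blocks)) |>
    ungroup() |>
    mutate(episode_id = paste0(.data$cow_id, "_e", .data$episode_seq)) |>
    select("cow_id", "episode_id", "onset", "end", "end_time", "duration_h",
           "peak_index")
}

detect_episodes_cow <- function(df, thr, gap_blocks) {
  df <- arrange(df, .data$block_start)
  above <- df$index >= thr
  r <- rle(above)
  # absorb short interior quiet gaps
  if (length(r$values) > 2) {
    interior <- seq_along(r$values)[-c(1, length(r$values))]
    fill <- interior[!r$values[interior] & r$lengths[interior] < gap_blocks]
    r$values[fill] <- TRUE
  }
  above <- inverse.rle(r)
  r2 <- rle(above)
  ends <- cumsum(r2$lengths)
  starts <- ends - r2$lengths + 1
  keep <- which(r2$values)
  if (length(keep) == 0) {
    return(tibble(episode_seq = integer(), onset = parse_ts(character()),
                  end = parse_ts(character()), end_time = parse_ts(character()),
                  duration_h = numeric(), peak_index = numeric()))
  }
  bind_rows(lapply(seq_along(keep), function(j) {
    i0 <- starts[keep[j]]
    i1 <- ends[keep[j]]
    tibble(
      episode_seq = j,
      onset = df$block_start[i0],
      end = df$block_start[i1],
      end_time = df$block_start[i1] + 7200,
      duration_h = (i1 - i0 + 1) * 2,
      peak_index = max(df$index[i0:i1])
    )
  }))
}

#' Classify an episode as true or false estrus from the alert-time exam
#'
#' True estrus requires at least one dominant pre-ovulatory follicle larger
#' than 15 mm and no large corpus luteum (> 20 mm) at the time of the alert.
#'
#' @param max_follicle Largest follicle diameter at the alert exam, mm.
#' @param max_cl Largest corpus luteum diameter, mm (NA when none recorded).
#' @return Logical (vectorized): TRUE for true estrus.
#' @examples
#' classify_estrus(18, 12) # TRUE
#' classify_estrus(18, 22) # FALSE: retained large CL
#' @export
classify_estrus <- function(max_follicle, max_cl) {
  !is.na(max_follicle) & max_follicle > 15 & (is.na(max_cl) | max_cl <= 20)
}

exam_fol_max <- function(exams) {
  suppressWarnings(apply(as.matrix(exams[, c("fol1", "fol2", "fol3")]), 1,
                         max, na.rm = TRUE)) |>
    (\(x) ifelse(is.finite(x), x, NA_real_))()
}

exam_cl_max <- function(exams) {
  suppressWarnings(apply(as.matrix(exams[, c("cl1", "cl2")]), 1,
                         max, na.rm = TRUE)) |>
    (\(x) ifelse(is.finite(x), x, NA_real_))()
}

#' Time ovulation from serial ultrasound exams
#'
#' The dominant follicle is the largest at the first exam and is tracked
#' across exams by nearest diameter within +/- 25 %. Ovulation is declared at
#' the first consecutive exam pair across which the tracked follicle
#' disappears; its time is the midpoint of that pair. If the follicle persists
#' through all exams (at most 6), the day-7 scan decides: a new corpus luteum
#' (>= 18 mm) means a late ovulation, its absence a failed ovulation.
#'
#' @param exams Tibble of serial exams for one episode (columns `exam_time`,
#'   `fol1`-`fol3`, `cl1`-`cl2`), sorted or sortable by time, day-7 scan
#'   excluded.
#' @param day7_exam Optional single-row tibble with the day-7 scan.
#' @return A one-row tibble: `status` (`ovulated` / `late` / `failed` /
#'   `undetermined`), `ovulation_time`, `exam_before`, `exam_after`, `reason`.
#' @export
time_ovulation <- function(exams, day7_exam = NULL) {
  out <- tibble(status = "undetermined", ovulation_time = na_ts(),
                exam_before = na_ts(), exam_after = na_ts(),
                reason = NA_character_)
  if (is.null(exams) || nrow(exams) < 2) {
    out$reason <- "insufficient_exams"
    return(out)
  }
  exams <- arrange(exams, .data$exam_time)
  fol <- as.matrix(exams[, c("fol1", "fol2", "fol3")])
  dom <- suppressWarnings(max(fol[1, ], na.rm = TRUE))
  if (!is.finite(dom)) {
    out$reason <- "no_follicle_at_first_exam"
    return(out)
  }
  for (j in 2:nrow(exams)) {
    cand <- fol[j, ]
    cand <- cand[!is.na(cand)]
    cand <- cand[abs(cand - dom) / dom <= 0.25]
    if (length(cand) == 0) {
      mid <- exams$exam_time[j - 1] +
        as.numeric(difftime(exams$exam_time[j], exams$exam_time[j - 1],
                            units = "secs")) / 2
      return(tibble(status = "ovulated", ovulation_time = mid,
                    exam_before = exams$exam_time[j - 1],
                    exam_after = exams$exam_time[j], reason = NA_character_))
    }
    dom <- cand[which.min(abs(cand - dom))]
  }
  if (is.null(day7_exam) || nrow(day7_exam) == 0) {
    out$reason <- "no_day7_exam"
    return(out)
  }
  cl <- exam_cl_max(day7_exam)
  out$status <- if (!is.na(cl[1]) && cl[1] >= 18) "late" else "failed"
  out
}

#' Attach estrous-expression categories to episodes
#'
#' Peak activity at or above `peak_cut` (default the reported median, 80
#' index) is "high", below it "low"; duration at or above `duration_cut`
#' (default 12 h) is "long", below it "short". The median value itself belongs
#' to the upper class in both splits.
#'
#' @param episodes Tibble with `peak_index` and `duration_h`.
#' @param peak_cut,duration_cut Positive cut points.
#' @return `episodes` with `peak_category` and `duration_category` columns.
#' @export
categorize_episodes <- function(episodes, peak_cut = 80, duration_cut = 12) {
  stopifnot(peak_cut > 0, duration_cut > 0)
  mutate(
    episodes,
    peak_category = ifelse(.data$peak_index >= peak_cut, "high", "low"),
    duration_category = ifelse(.data$duration_h >= duration_cut, "long", "short")
  )
}

#' Build, classify and time all episodes of a herd
#'
#' Runs [detect_episodes()], matches each episode to its ultrasound exams by
#' cow and time (serial exams within 5 days of onset; the day-7 scan within 14
#' days), classifies true vs false estrus from the alert-time exam with
#' [classify_estrus()], and times ovulation with [time_ovulation()] for true
#' episodes.
#'
#' @param activity Activity tibble (`cow_id`, `block_start`, `index`).
#' @param exams Exams tibble (`cow_id`, `exam_time`, `fol1`-`fol3`,
#'   `cl1`-`cl2`, `day7`).
#' @param alert_threshold,gap_blocks See [detect_episodes()].
#' @param peak_cut,duration_cut See [categorize_episodes()].
#' @return A list with `episodes` (including `is_true_estrus`, categories and
#'   an `exclude_reason` for unclassifiable episodes) and `ovulations` (one
#'   row per true-estrus episode with status, ovulation time, bracketing exam
#'   pair and `ovulation_interval_h` from the AAM alert).
#' @export
process_episodes <- function(activity, exams, alert_threshold = 35,
                             gap_blocks = 3, peak_cut = 80, duration_cut = 12) {
  eps <- detect_episodes(activity, alert_threshold, gap_blocks) |>
    categorize_episodes(peak_cut, duration_cut)
  eps$is_true_estrus <- NA
  eps$exclude_reason <- NA_character_

  ovul <- vector("list", nrow(eps))
  for (j in seq_len(nrow(eps))) {
    serial <- exams |>
      filter(.data$cow_id == eps$cow_id[j], !.data$day7,
             .data$exam_time >= eps$onset[j] - 7200,
             .data$exam_time <= eps$onset[j] + 5 * 86400) |>
      arrange(.data$exam_time)
    day7 <- exams |>
      filter(.data$cow_id == eps$cow_id[j], .data$day7,
             .data$exam_time > eps$onset[j],
             .data$exam_time <= eps$onset[j] + 14 * 86400)
    if (nrow(serial) == 0) {
      eps$exclude_reason[j] <- "no_exam"
      next
    }
    eps$is_true_estrus[j] <- classify_estrus(exam_fol_max(serial[1, ]),
                                             exam_cl_max(serial[1, ]))
    if (!eps$is_true_estrus[j]) next
    ov <- time_ovulation(serial, day7)
    ov$episode_id <- eps$episode_id[j]
    ov$cow_id <- eps$cow_id[j]
    ov$ovulation_interval_h <- hours_between(ov$ovulation_time, eps$onset[j])
    ovul[[j]] <- ov
  }
  ovulations <- bind_rows(ovul)
  if (nrow(ovulations) > 0) {
    ovulations <- select(ovulations, "cow_id", "episode_id", "status",
                         "ovulation_time", "exam_before", "exam_after",
                         "ovulation_interval_h", "reason")
  }
  list(episodes = eps, ovulations = ovulations)
}
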