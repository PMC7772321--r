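make_activity <- function(index, cow = "c1", start = T0) {
  tibble::tibble(cow_id = cow, block_start = start + 7200 * (seq_along(index) - 1),
                 index = index)
}

test_that("episode detection finds maximal above-threshold runs", {
  eps <- detect_episodes(make_activity(c(30, 40, 85, 60, 30)))
  expect_equal(nrow(eps), 1)
  expect_equal(eps$peak_index, 85)
  expect_equal(eps$duration_h, 6)
  expect_equal(eps$onset, T0 + 7200)
  expect_equal(eps$end, T0 + 3 * 7200)

  expect_equal(nrow(detect_episodes(make_activity(rep(20, 10)))), 0)
  expect_equal(nrow(detect_episodes(make_activity(numeric(0)))), 0)
})

test_that("quiet gaps split or merge runs according to the gap rule", {
  # 12 quiet blocks (24 h) between runs: two distinct episodes
  two <- detect_episodes(make_activity(c(50, 60, rep(10, 12), 70, 40)))
  expect_equal(nrow(two), 2)
  expect_equal(two$peak_index, c(60, 70))

  # 2 quiet blocks (< gap_blocks = 3): one merged episode spanning the gap
  one <- detect_episodes(make_activity(c(50, 60, 10, 10, 70, 40)))
  expect_equal(nrow(one), 1)
  expect_equal(one$peak_index, 70)
  expect_equal(one$duration_h, 12)
})

test_that("true estrus requires a >15 mm follicle and no >20 mm CL", {
  expect_true(classify_estrus(18, 12))
  expect_true(classify_estrus(18, NA))
  expect_false(classify_estrus(14, NA))
  expect_false(classify_estrus(15, NA)) # strictly greater than 15
  expect_false(classify_estrus(18, 22)) # CL rule dominates
  expect_true(classify_estrus(18, 20)) # 20 mm itself is tolerated
})

make_exam_rows <- function(times, fol1, cl1 = NA_real_) {
  tibble::tibble(cow_id = "c1", exam_time = times, fol1 = fol1, fol2 = 7,
                 fol3 = NA_real_, cl1 = rep_len(cl1, length(times)),
                 cl2 = NA_real_)
}

test_that("ovulation time is the midpoint of the disappearance exam pair", {
  times <- as.POSIXct(c("2019-06-02 08:00:00", "2019-06-02 17:00:00"), tz = "UTC")
  ov <- time_ovulation(make_exam_rows(times, fol1 = c(18, NA)))
  expect_equal(ov$status, "ovulated")
  expect_equal(ov$ovulation_time, as.POSIXct("2019-06-02 12:30:00", tz = "UTC"))
  expect_equal(ov$exam_before, times[1])
  expect_equal(ov$exam_after, times[2])
})

test_that("dominant-follicle tracking tolerates growth within 25 percent", {
  times <- T0 + c(8, 17, 32, 41) * 3600
  # grows 18 -> 19 -> 20, then replaced by an unrelated 8 mm follicle
  ov <- time_ovulation(make_exam_rows(times, fol1 = c(18, 19, 20, 8)))
  expect_equal(ov$status, "ovulated")
  expect_equal(ov$exam_before, times[3])
})

test_that("persisting follicles resolve to late or failed by the day-7 CL", {
  times <- T0 + seq(8, 8 + 5 * 11, by = 11) * 3600
  persist <- make_exam_rows(times, fol1 = seq(18, by = 0.2, length.out = 6))
  d7_cl <- make_exam_rows(times[6] + 7 * 86400, fol1 = 8, cl1 = 24)
  d7_no <- make_exam_rows(times[6] + 7 * 86400, fol1 = 8, cl1 = NA_real_)
  expect_equal(time_ovulation(persist, d7_cl)$status, "late")
  expect_equal(time_ovulation(persist, d7_no)$status, "failed")
  expect_equal(time_ovulation(persist, NULL)$status, "undetermined")
  expect_equal(time_ovulation(persist[1, ], d7_cl)$reason, "insufficient_exams")
})

test_that("expression categories put the median value in the upper class", {
  eps <- tibble::tibble(peak_index = c(80, 79, 100), duration_h = c(12, 10, 20))
  out <- categorize_episodes(eps)
  expect_equal(out$peak_category, c("high", "low", "high"))
  expect_equal(out$duration_category, c("long", "short", "long"))
})

test_that("herd episodes are recovered with exact onsets, peaks and bracketed ovulations", {
  cfg <- herd_config(n_cows = 12, episodes_per_cow = 2, false_fraction = 0.15,
                     failed_fraction = 0.05, dropout_fraction = 0, seed = 21)
  b <- simulate_herd(cfg)
  pe <- process_episodes(b$activity, b$exams)
  eps <- dplyr::arrange(pe$episodes, cow_id, onset)
  tr <- dplyr::arrange(b$truth, cow_id, episode_onset)

  expect_equal(nrow(eps), nrow(tr))
  expect_equal(eps$onset, tr$episode_onset)
  expect_equal(eps$peak_index, tr$true_peak_index)
  expect_equal(eps$duration_h, tr$duration_h)
  expect_equal(eps$is_true_estrus, tr$status != "false")

  ov <- dplyr::inner_join(pe$ovulations,
                          dplyr::select(tr, episode_id, status_truth = status,
                                        ovulation_true = ovulation_time),
                          by = "episode_id")
  expect_equal(ov$status, ifelse(ov$status_truth == "ovulated", "ovulated",
                                 ov$status_truth))
  ovd <- ov[ov$status == "ovulated", ]
  gap_h <- as.numeric(difftime(ovd$exam_after, ovd$exam_before, units = "hours"))
  err_h <- abs(as.numeric(difftime(ovd$ovulation_time, ovd$ovulation_true,
                                   units = "hours")))
  expect_true(all(err_h <= gap_h / 2))
})
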