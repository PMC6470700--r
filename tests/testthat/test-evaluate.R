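# Ideal fixture: reference cycles at exactly 1 s, beats mid-cycle.
ideal_fixture <- function(n_cycles = 100, offset = 0.5) {
  rpeaks <- 0:n_cycles
  bt <- rpeaks[-length(rpeaks)] + offset
  beats <- tibble::tibble(segment = as.integer(bt %/% 10 + 1),
                          beat_time_s = bt)
  list(rpeaks = rpeaks, beats = beats)
}

test_that("printed counts reproduce the detection percentage", {
  expect_equal(detection_percentage(1050, 19), 98.2)
  expect_equal(detection_percentage(10, 0), 100)
})

test_that("a perfect detection scores 100% with zero error counts", {
  fx <- ideal_fixture()
  rep <- score_recording(fx$beats, fx$rpeaks)
  s <- glance(rep)
  expect_equal(s$pct_correct, 100)
  expect_equal(s$n_not_correct, 0L)
  expect_equal(s$n_false_positive, 0L)
  expect_equal(s$n_false_negative, 0L)
  expect_equal(s$n_misplaced, 0L)
  expect_equal(s$n_detectable, 100L)
})

test_that("duplicated beats in every 10th cycle count as false positives", {
  fx <- ideal_fixture(100)
  dup_cycles <- seq(10, 100, by = 10) - 1   # cycles [9,10), [19,20), ...
  extra <- tibble::tibble(segment = as.integer(dup_cycles %/% 10 + 1),
                          beat_time_s = dup_cycles + 0.15)
  beats <- dplyr::arrange(dplyr::bind_rows(fx$beats, extra), beat_time_s)
  s <- glance(score_recording(beats, fx$rpeaks))
  expect_equal(s$n_false_positive, 10L)
  expect_equal(s$n_not_correct, s$n_false_positive + s$n_false_negative +
                 s$n_misplaced)
})

test_that("missing and shifted lone beats classify as FN and misplaced", {
  fx <- ideal_fixture(60)
  beats <- fx$beats
  beats <- beats[-c(25, 44), ]                       # two missing beats
  beats$beat_time_s[5] <- beats$beat_time_s[5] + 0.3 # one off-phase beat
  s <- glance(score_recording(beats, fx$rpeaks))
  expect_equal(s$n_false_negative, 2L)
  expect_gte(s$n_misplaced, 1L)
  expect_equal(s$n_not_correct,
               s$n_false_positive + s$n_false_negative + s$n_misplaced)
  expect_gte(s$pct_correct, 0); expect_lte(s$pct_correct, 100)
})

test_that("rate disagreements beyond 5 bpm are not correct", {
  # reference at 60 bpm, detections drifting to a 70 bpm spacing
  rpeaks <- 0:30
  bt <- seq(0.5, 29.5, by = 60 / 70)
  beats <- tibble::tibble(segment = as.integer(bt %/% 10 + 1),
                          beat_time_s = bt)
  s <- glance(score_recording(beats, rpeaks))
  expect_lt(s$pct_correct, 100)
})

test_that("cycles straddling segment boundaries are excluded", {
  # beats late in each cycle so cycles straddle the 10 s marks
  rpeaks <- seq(0.4, 60.4, by = 1)
  bt <- rpeaks[-length(rpeaks)] + 0.5
  beats <- tibble::tibble(segment = as.integer(bt %/% 10 + 1),
                          beat_time_s = bt)
  rep <- score_recording(beats, rpeaks)
  s <- glance(rep)
  expect_equal(s$n_boundary_excluded, 6L)
  expect_equal(s$n_detectable, 60L - 6L)
  expect_equal(s$pct_correct, 100)
})

test_that("the reference requires at least two R peaks", {
  fx <- ideal_fixture(10)
  expect_error(score_recording(fx$beats, rpeaks = 1),
               class = "bedvitals_reference_error")
})

test_that("aggregation reproduces the published summary rates", {
  tab <- reference_detection_table()
  expect_equal(nrow(tab), 28L)
  # per-row consistency of the first supine row
  expect_equal(detection_percentage(tab$n_detectable[1],
                                    tab$n_not_correct[1]),
               tab$pct_correct[1])
  overall <- aggregate_reports(tab)
  expect_equal(overall$mean_pct_correct, 83.9)
  expect_equal(overall$n, 28L)
  by_vol <- aggregate_reports(tab, volunteer)
  expect_equal(by_vol$mean_pct_correct[by_vol$volunteer == 1], 95.4)
  by_pos <- aggregate_reports(tab, position)
  expect_equal(
    by_pos$mean_pct_correct[match(c("supine", "prone", "left_lateral",
                                    "right_lateral"), by_pos$position)],
    c(79.8, 82.5, 91.0, 82.3))
})

test_that("aggregation is permutation-invariant and idempotent on ties", {
  tab <- reference_detection_table()
  shuffled <- tab[sample(nrow(tab)), ]
  expect_equal(aggregate_reports(shuffled)$mean_pct_correct,
               aggregate_reports(tab)$mean_pct_correct)
  same <- tibble::tibble(pct_correct = rep(91.2, 5))
  expect_equal(aggregate_reports(same)$mean_pct_correct, 91.2)
})

test_that("report accessors expose summary and per-cycle views", {
  fx <- ideal_fixture(40)
  rep <- score_recording(fx$beats, fx$rpeaks)
  expect_s3_class(glance(rep), "tbl_df")
  cyc <- tidy(rep)
  expect_equal(nrow(cyc), 40L)
  expect_true(all(c("t_start", "t_end", "ecg_rate_bpm", "n_beats", "class")
                  %in% names(cyc)))
  expect_output(print(rep), "detection_report")
})
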