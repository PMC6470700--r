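fs <- 84.8

test_that("segmentation yields the expected windows", {
  sig300 <- sampled_signal(numeric(round(300 * fs)), fs)
  expect_length(segment_stream(sig300), 30L)

  sig1 <- sampled_signal(numeric(round(10.66 * fs)), fs)
  expect_length(segment_stream(sig1), 1L)

  sig25 <- sampled_signal(sin(seq_len(round(25 * fs))), fs)
  segs <- segment_stream(sig25)
  expect_length(segs, 3L)
  expect_equal(vapply(segs, function(s) s$t0, numeric(1)),
               c(0, 10, 20), tolerance = 1 / fs)
  # consecutive segments share the 0.66 s overlap verbatim
  n_shared <- length(segs[[1]]$values) - round(10 * fs)
  expect_equal(n_shared, round(0.66 * fs))
  expect_equal(utils::tail(segs[[1]]$values, n_shared),
               utils::head(segs[[2]]$values, n_shared))
  # each full segment spans seg_len_s
  expect_equal(signal_duration(segs[[1]]), 10.66, tolerance = 2 / fs)
})

test_that("local maxima are rise-to-fall sign changes with plateau handling", {
  t <- (0:(10 * fs - 1)) / fs
  mx <- local_maxima(sampled_signal(sin(2 * pi * t), fs))
  expect_equal(nrow(mx), 10L)
  expect_equal(mx$time_s, 0.25 + 0:9, tolerance = 1.01 / fs)

  expect_equal(nrow(local_maxima(sampled_signal(seq_len(100), fs))), 0L)
  expect_equal(nrow(local_maxima(sampled_signal(rep(1, 100), fs))), 0L)

  bumps <- exp(-(t - 3)^2 / 0.5) + exp(-(t - 7)^2 / 0.5)
  mb <- local_maxima(sampled_signal(bumps, fs))
  expect_equal(nrow(mb), 2L)
  expect_equal(mb$time_s, c(3, 7), tolerance = 1.01 / fs)

  plat <- local_maxima(sampled_signal(c(0, 1, 2, 2, 2, 1, 0), 1))
  expect_equal(plat$index, 3L)
})

test_that("feature vectors hold 28 decimated samples and respect the window", {
  seg <- sampled_signal(sin(2 * pi * (0:(round(10.66 * fs) - 1)) / fs), fs)
  fv <- build_feature_vectors(seg, local_maxima(seg))
  expect_true(all(lengths(fv$features) == 28L))
  expect_equal(round(0.66 * fs / 2), 28)
  # features are every other sample from the maximum onward
  i1 <- local_maxima(seg)$index[1]
  expect_equal(fv$features[[1]], seg$values[i1 + seq(0, 54, by = 2)])
  # a maximum 0.5 s before the segment end cannot host a window
  expect_true(all(fv$t_start <= signal_duration(seg) - 0.5))
  expect_true(all(diff(fv$t_start) > 0))
  expect_equal(fv$idx, seq_len(nrow(fv)))
})

test_that("dissimilarity implements the gated inverse cosine", {
  p <- cluster_params()
  e1 <- c(1, 0, 0); e2 <- c(0, 1, 0)
  # condition 1: magnitude ratio 4 > alpha = 3
  expect_equal(beat_dissimilarity(make_fv_row(e1, 0, 1),
                                  make_fv_row(4 * e1, 1, 5), p), pi)
  # condition 2: time difference below t_min
  expect_equal(beat_dissimilarity(make_fv_row(e1, 0, 1),
                                  make_fv_row(e1, 0.2, 5), p), pi)
  # condition 3: index difference below i_min
  expect_equal(beat_dissimilarity(make_fv_row(e1, 0, 1),
                                  make_fv_row(e1, 1, 2), p), pi)
  # admissible orthogonal pair -> pi/2; parallel scaled pair -> 0
  expect_equal(beat_dissimilarity(make_fv_row(e1, 0, 1),
                                  make_fv_row(e2, 0.8, 4), p), pi / 2)
  expect_equal(beat_dissimilarity(make_fv_row(e1, 0, 1),
                                  make_fv_row(2 * e1, 0.8, 4), p), 0)
  # symmetry and scale invariance on random admissible pairs
  set.seed(4)
  for (k in 1:20) {
    a <- make_fv_row(rnorm(28), 0, 1)
    b <- make_fv_row(rnorm(28), 2, 5)
    expect_equal(beat_dissimilarity(a, b, p), beat_dissimilarity(b, a, p))
    b2 <- b; b2$features <- 1.5 * b$features
    d <- beat_dissimilarity(a, b, p)
    if (d < pi) expect_equal(beat_dissimilarity(a, b2, p), d)
    expect_gte(d, 0); expect_lte(d, pi)
  }
  expect_error(beat_dissimilarity(make_fv_row(c(0, 0, 0), 0, 1),
                                  make_fv_row(e1, 1, 4), p),
               class = "bedvitals_domain_error")
})

test_that("complete link handles degenerate inputs and stays monotone", {
  p <- cluster_params(i_min = 0)
  # two vectors: a single merge at their pairwise dissimilarity
  fv2 <- tibble::tibble(idx = 1:2, t_start = c(0, 1),
                        features = list(c(1, 0), c(1, 1)))
  fv2$magnitude <- vapply(fv2$features, function(f) sqrt(sum(f^2)), numeric(1))
  d2 <- complete_link(fv2, p)
  expect_equal(nrow(d2$merge), 1L)
  expect_equal(d2$height, pi / 4)
  # fully gated set: every merge at height pi
  fvg <- tibble::tibble(idx = 1:4, t_start = c(0, 0.05, 0.1, 0.15),
                        features = replicate(4, c(1, 0), simplify = FALSE))
  fvg$magnitude <- rep(1, 4)
  dg <- complete_link(fvg, cluster_params())
  expect_equal(dg$height, rep(pi, 3))
  # monotone non-decreasing heights on random instances
  for (s in 1:25) {
    fv <- random_feature_vectors(sample(3:10, 1), s)
    dend <- complete_link(fv, cluster_params(i_min = sample(0:3, 1)))
    expect_true(all(diff(dend$height) >= -1e-12))
    expect_true(all(dend$height >= 0 & dend$height <= pi + 1e-12))
  }
})

test_that("theta cut selects the largest, then tightest, then earliest cluster", {
  unit <- function(phi) c(cos(phi), sin(phi))
  p <- cluster_params(i_min = 0, t_min = 0.01, theta = 0.8)
  mk <- function(phis) {
    fv <- tibble::tibble(idx = seq_along(phis),
                         t_start = seq_along(phis) * 0.5,
                         features = lapply(phis, unit))
    fv$magnitude <- rep(1, length(phis))
    fv
  }
  # sizes 4 / 3 / 2: the size-4 cluster wins
  fv <- mk(c(0, 0.1, 0.2, 0.3, 2, 2.1, 2.2, -2, -2.1))
  sel <- cut_and_select(complete_link(fv, p), fv, p)
  expect_equal(nrow(sel$members), 4L)
  expect_equal(sort(sel$members$idx), 1:4)
  # equal sizes: the lower mean dissimilarity wins
  fv <- mk(c(0, 0.3, 0.6, 2, 2.1, 2.2))
  sel <- cut_and_select(complete_link(fv, p), fv, p)
  expect_equal(sort(sel$members$idx), 4:6)
  # all singletons (mutually gated): deterministic earliest-time choice
  fvg <- tibble::tibble(idx = 1:3, t_start = c(0.3, 0.1, 0.2),
                        features = replicate(3, c(1, 0), simplify = FALSE),
                        magnitude = 1)
  fvg <- fvg[order(fvg$t_start), ]
  selg <- cut_and_select(complete_link(fvg, cluster_params()), fvg,
                         cluster_params())
  expect_equal(nrow(selg$members), 1L)
  expect_equal(selg$members$t_start, 0.1)
})

test_that("raising theta never shrinks the chosen cluster", {
  for (s in 1:10) {
    fv <- random_feature_vectors(8, 100 + s)
    dend <- complete_link(fv, cluster_params(i_min = 0))
    sizes <- vapply(seq(0.1, 3.1, by = 0.25), function(th) {
      p <- cluster_params(i_min = 0, theta = th)
      nrow(cut_and_select(dend, fv, p)$members)
    }, numeric(1))
    expect_true(all(diff(sizes) >= 0))
  }
})

test_that("per-segment dual run keeps i_min = 3 on normal morphology", {
  gen <- generate_bcg(bcg_scenario(duration_s = 12, hr_bpm = 60, seed = 21))
  card <- cardiac_component(gen$recording$force)
  seg <- segment_stream(card)[[1]]
  det <- detect_beats_segment(seg)
  expect_true(all(det$i_min_used == 3L))
  expect_equal(nrow(det), 10, tolerance = 0.11)
  # one beat per true cycle, common landmark within 0.15 s
  offs <- vapply(det$beat_time_s, function(b) {
    b - max(gen$truth$beats$beat_time_s[gen$truth$beats$beat_time_s <= b])
  }, numeric(1))
  expect_lt(diff(range(offs)), 0.15)
})

test_that("two-wave superimposed morphology switches the dual run to i_min = 2", {
  gen <- generate_bcg(bcg_scenario(duration_s = 12, hr_bpm = 150,
                                   waves_per_cycle = 2, seed = 21))
  card <- cardiac_component(gen$recording$force)
  seg <- segment_stream(card)[[1]]
  det <- detect_beats_segment(seg)
  expect_true(all(det$i_min_used == 2L))
  true_in_seg <- sum(gen$truth$beats$beat_time_s < 10.66 - 0.66)
  expect_equal(nrow(det), true_in_seg, tolerance = 0.06)
})

test_that("a flat segment yields an empty result with a warning", {
  seg <- sampled_signal(rep(0.5, round(10.66 * fs)), fs)
  expect_warning(det <- detect_beats_segment(seg),
                 class = "bedvitals_empty_segment")
  expect_equal(nrow(det), 0L)
})

test_that("beat-to-beat rates are integer bpm with boundary flags", {
  b <- tibble::tibble(segment = c(1L, 1L, 1L), beat_time_s = c(0, 1, 2))
  expect_equal(beats_to_rates(b)$rate_bpm, c(60L, 60L, NA))
  b2 <- tibble::tibble(segment = c(1L, 1L), beat_time_s = c(0, 0.75))
  expect_equal(beats_to_rates(b2)$rate_bpm, c(80L, NA))
  # a steady 5-minute beat sequence has 29 boundary-flagged intervals
  bt <- seq(0.5, 299.5, by = 1)
  b5 <- tibble::tibble(segment = as.integer(bt %/% 10 + 1), beat_time_s = bt)
  r5 <- beats_to_rates(b5)
  expect_equal(sum(r5$boundary_flag, na.rm = TRUE), 29L)
  expect_true(all(is.na(r5$rate_bpm[which(r5$boundary_flag)])))
  expect_true(all(r5$rate_bpm[!r5$boundary_flag & !is.na(r5$boundary_flag)] == 60L))
})

test_that("dendrogram accessors expose a consistent merge history", {
  fv <- random_feature_vectors(7, 3)
  dend <- complete_link(fv, cluster_params(i_min = 0))
  td <- tidy(dend)
  expect_equal(nrow(td), 6L)
  expect_equal(td$height, dend$height)
  hc <- as.hclust(dend)
  expect_s3_class(hc, "hclust")
  expect_equal(sort(hc$order), 1:7)
})
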