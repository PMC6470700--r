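test_that("the same seed reproduces the recording exactly", {
  sp <- bcg_scenario(duration_s = 10, noise_sd_mn = 2, hr_jitter_pct = 3,
                     emi_amp_mn = 5, seed = 9)
  a <- generate_bcg(sp)
  b <- generate_bcg(sp)
  expect_identical(a$recording$force$values, b$recording$force$values)
  expect_identical(a$recording$ecg$values, b$recording$ecg$values)
  expect_identical(a$truth$beats, b$truth$beats)
  c2 <- generate_bcg(bcg_scenario(duration_s = 10, noise_sd_mn = 2,
                                  hr_jitter_pct = 3, emi_amp_mn = 5,
                                  seed = 10))
  expect_false(identical(a$recording$force$values, c2$recording$force$values))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  r1 <- stats::runif(1)
  set.seed(123)
  invisible(generate_bcg(bcg_scenario(duration_s = 5, noise_sd_mn = 1,
                                      seed = 77)))
  expect_identical(stats::runif(1), r1)
})

test_that("the raw force mean is dominated by the preload DC", {
  gen <- generate_bcg(bcg_scenario(duration_s = 60, preload_n = 15, seed = 3))
  expect_equal(mean(gen$recording$force$values), 15000, tolerance = 1e-3)
  gen2 <- generate_bcg(bcg_scenario(duration_s = 60, preload_n = 4.5, seed = 3))
  expect_equal(mean(gen2$recording$force$values), 4500, tolerance = 1e-3)
})

test_that("mains interference aliases to 34.8 Hz on the force channel", {
  gen <- generate_bcg(bcg_scenario(duration_s = 60, emi_amp_mn = 10, seed = 5))
  v <- gen$recording$force$values
  v <- v - mean(v)
  n <- length(v)
  sp <- Mod(stats::fft(v))^2
  f <- (seq_len(n) - 1) * 84.8 / n
  upper <- f > 20 & f < 42.4
  expect_equal(f[upper][which.max(sp[upper])], 34.8, tolerance = 0.05)
})

test_that("spectral peaks sit at the respiration and cardiac fundamentals", {
  gen <- generate_bcg(bcg_scenario(duration_s = 120, hr_bpm = 72,
                                   rr_rpm = 12, seed = 5))
  v <- gen$recording$force$values - mean(gen$recording$force$values)
  n <- length(v)
  sp <- Mod(stats::fft(v))^2
  f <- (seq_len(n) - 1) * 84.8 / n
  resp_band <- f > 0.05 & f < 0.5
  expect_equal(f[resp_band][which.max(sp[resp_band])], 12 / 60,
               tolerance = 0.02)
  # cardiac component has energy at the heart-rate fundamental
  card_band <- f > 0.9 & f < 15
  peak_f <- f[card_band][which.max(sp[card_band])]
  expect_equal(peak_f %% (72 / 60), 0, tolerance = 0.03)
})

test_that("ECG spikes are phase-locked to the true beats at 254.4 Hz", {
  gen <- generate_bcg(bcg_scenario(duration_s = 30, hr_bpm = 80, seed = 4))
  expect_equal(gen$recording$ecg$fs, 3 * 84.8)
  mx <- local_maxima(gen$recording$ecg)
  big <- mx$time_s[mx$value > 0.5]
  expect_equal(length(big), nrow(gen$truth$beats))
  expect_lt(max(abs(big - gen$truth$beats$beat_time_s)), 0.01)
})

test_that("a zero-amplitude BCG yields no detected beats", {
  gen <- generate_bcg(bcg_scenario(duration_s = 30, bcg_amp_mn = 0,
                                   resp_amp_mn = 0, seed = 2))
  card <- cardiac_component(gen$recording$force)
  beats <- suppressWarnings(detect_beats(card))
  expect_equal(nrow(beats), 0L)
})

test_that("arrhythmia generation reduces to the plain generator when disabled", {
  sp <- bcg_scenario(duration_s = 20, seed = 11)
  expect_identical(generate_arrhythmia(sp)$recording$force$values,
                   generate_bcg(sp)$recording$force$values)
  spa <- bcg_scenario(duration_s = 20, premature_every = 7, seed = 11)
  ga <- generate_arrhythmia(spa)
  expect_true(any(ga$truth$beats$premature))
  iv <- diff(ga$truth$beats$beat_time_s)
  prem_iv <- iv[utils::head(ga$truth$beats$premature, -1)]
  expect_equal(unique(round(prem_iv, 6)), 0.8)   # 20% shortened from 1 s
})

test_that("scenario validation rejects out-of-range parameters", {
  expect_error(bcg_scenario(hr_bpm = 200), regexp = "hr_bpm")
  expect_error(bcg_scenario(rr_rpm = 5), regexp = "rr_rpm")
  expect_error(bcg_scenario(preload_n = 60), regexp = "preload")
  expect_error(bcg_scenario(waves_per_cycle = 4), regexp = "waves_per_cycle")
  expect_error(bcg_scenario(bcg_amp_mn = -1), regexp = "amplitudes")
})

test_that("preload-amplitude coupling scales the cardiac waves", {
  lo <- generate_bcg(bcg_scenario(duration_s = 20, preload_n = 5,
                                  resp_amp_mn = 0,
                                  scale_amp_with_preload = TRUE, seed = 6))
  hi <- generate_bcg(bcg_scenario(duration_s = 20, preload_n = 20,
                                  resp_amp_mn = 0,
                                  scale_amp_with_preload = TRUE, seed = 6))
  amp <- function(g) {
    card <- cardiac_component(g$recording$force)
    stats::sd(card$values[round(84.8 * 8):round(84.8 * 12)])
  }
  expect_equal(amp(hi) / amp(lo), 4, tolerance = 0.1)
})
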