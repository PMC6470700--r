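#' Default BCG wave template
#'
#' Gaussian-lobed parameterisation of the commonest normal BCG waveform:
#' the systolic upward tips H, J and L (with J the largest) alternate with
#' the downward I, K troughs to form the characteristic "W" shape, flanked
#' by the smaller G and the diastolic M/N waves. Amplitudes are relative
#' to the J wave; latencies are seconds after the cardiac cycle onset (the
#' R peak of the reference ECG). When the cycle is shorter than
#' `compress_below_s` the latencies and widths are compressed
#' proportionally, mimicking wave superimposition at high rates.
#'
#' The `"two_wave"` variant merges H into J so the cycle presents only two
#' upward waves (J and a similar, slightly smaller L); latencies are given
#' as fractions of the cycle. It exercises the dual `i_min` = 3/2
#' clustering logic.
#'
#' @param type `"normal"` or `"two_wave"`.
#' @return A tibble with columns `wave`, `amp`, `latency`, `width` and the
#'   attribute `latency_unit` (`"s"` or `"cycle_fraction"`).
#' @export
bcg_wave_template <- function(type = c("normal", "two_wave")) {
  type <- match.arg(type)
  if (type == "normal") {
    out <- tibble::tibble(
      wave = c("G", "H", "I", "J", "K", "L", "M", "N"),
      amp = c(0.12, 0.45, -0.55, 1.00, -0.70, 0.40, -0.18, 0.10),
      latency = c(0.02, 0.10, 0.17, 0.25, 0.33, 0.41, 0.49, 0.57),
      width = c(0.030, 0.030, 0.032, 0.030, 0.034, 0.034, 0.036, 0.036))
    attr(out, "latency_unit") <- "s"
  } else {
    out <- tibble::tibble(
      wave = c("J", "K", "L", "M"),
      amp = c(1.00, -0.70, 0.85, -0.55),
      latency = c(0.15, 0.38, 0.62, 0.85),
      width = c(0.045, 0.050, 0.045, 0.050))
    attr(out, "latency_unit") <- "cycle_fraction"
  }
  out
}

#' Synthetic measurement scenario
#'
#' Describes one synthetic bed-sensor recording with known ground truth.
#' The force channel is composed of the static preload (DC), a sinusoidal
#' respiration component, one BCG wave complex per heartbeat, optional
#' white Gaussian sensor noise and optional 50 Hz mains interference
#' (which aliases to 34.8 Hz at the 84.8 Hz force rate). The ECG channel
#' is a spike train phase-locked to the true beat onsets, with optional
#' baseline drift and mains interference of its own.
#'
#' Defaults describe a typical resting measurement: 5 minutes, 60 bpm,
#' 15 breaths/min, 15 N preload (within the two ranges used in practice,
#' 4–5 N and 12–21.5 N), a 30 mN cardiac J-wave amplitude and a 60 mN
#' respiration amplitude — cardiac and respiratory magnitudes of comparable
#' order, as a longitudinally mounted sensor delivers.
#'
#' @param duration_s Recording length in seconds.
#' @param hr_bpm Heart rate: a scalar, or length-2 vector `(start, end)`
#'   for a linear ramp. Must lie within 40–180 bpm.
#' @param rr_rpm Respiration rate in breaths/min, within 8–30.
#' @param preload_n Static preload in N, in (0, 50].
#' @param bcg_amp_mn Peak amplitude of the J wave in mN.
#' @param resp_amp_mn Respiration sinusoid amplitude in mN.
#' @param emi_amp_mn Amplitude of 50 Hz interference on the force channel.
#' @param noise_sd_mn White-noise standard deviation on the force channel.
#' @param waves_per_cycle 3 for the normal morphology, 2 for the
#'   superimposed variant (see [bcg_wave_template()]).
#' @param hr_jitter_pct Uniform beat-interval jitter in percent.
#' @param premature_every Every this-many-th interval is rescaled by
#'   `1 + premature_frac` (0 disables), emulating arrhythmic beats.
#' @param premature_frac Fractional change of the affected intervals
#'   (negative = premature).
#' @param wave_template Optional template overriding [bcg_wave_template()].
#' @param scale_amp_with_preload If `TRUE`, the BCG amplitude is scaled by
#'   `preload_n / 15`, emulating the observed preload-amplitude coupling.
#' @param ecg_amp_v,ecg_drift_amp_v,ecg_drift_freq_hz,ecg_emi_amp_v ECG
#'   spike amplitude, baseline-drift amplitude and frequency, and 50 Hz
#'   interference amplitude (V).
#' @param fs_force Force sampling rate in Hz; the ECG is sampled at three
#'   times this rate.
#' @param seed Integer seed fixing the whole realisation.
#' @return An object of class `bcg_scenario`.
#' @export
bcg_scenario <- function(duration_s = 300, hr_bpm = 60, rr_rpm = 15,
                         preload_n = 15, bcg_amp_mn = 30, resp_amp_mn = 60,
                         emi_amp_mn = 0, noise_sd_mn = 0,
                         waves_per_cycle = 3, hr_jitter_pct = 0,
                         premature_every = 0, premature_frac = -0.2,
                         wave_template = NULL,
                         scale_amp_with_preload = FALSE,
                         ecg_amp_v = 1, ecg_drift_amp_v = 0,
                         ecg_drift_freq_hz = 0.2, ecg_emi_amp_v = 0,
                         fs_force = 84.8, seed = 1L) {
  if (duration_s <= 0) abort("`duration_s` must be positive.")
  if (any(hr_bpm < 40 | hr_bpm > 180)) {
    abort("`hr_bpm` must lie within 40-180 bpm.")
  }
  if (rr_rpm < 8 || rr_rpm > 30) abort("`rr_rpm` must lie within 8-30 rpm.")
  if (preload_n <= 0 || preload_n > 50) {
    abort("`preload_n` must lie in (0, 50] N.")
  }
  if (!waves_per_cycle %in% c(2, 3)) {
    abort("`waves_per_cycle` must be 2 or 3.")
  }
  amps <- c(bcg_amp_mn, resp_amp_mn, emi_amp_mn, noise_sd_mn,
            ecg_amp_v, ecg_drift_amp_v, ecg_emi_amp_v)
  if (any(amps < 0)) abort("amplitudes must be >= 0.")
  structure(list(
    duration_s = duration_s, hr_bpm = hr_bpm, rr_rpm = rr_rpm,
    preload_n = preload_n, bcg_amp_mn = bcg_amp_mn,
    resp_amp_mn = resp_amp_mn, emi_amp_mn = emi_amp_mn,
    noise_sd_mn = noise_sd_mn, waves_per_cycle = waves_per_cycle,
    hr_jitter_pct = hr_jitter_pct, premature_every = premature_every,
    premature_frac = premature_frac, wave_template = wave_template,
    scale_amp_with_preload = scale_amp_with_preload,
    ecg_amp_v = ecg_amp_v, ecg_drift_amp_v = ecg_drift_amp_v,
    ecg_drift_freq_hz = ecg_drift_freq_hz, ecg_emi_amp_v = ecg_emi_amp_v,
    fs_force = fs_force, seed = as.integer(seed)),
    class = "bcg_scenario")
}

with_scenario_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# True beat onset times for a scenario, via sequential interval draws.
scenario_beat_times <- function(spec) {
  hr_at <- function(t) {
    if (length(spec$hr_bpm) == 1L) spec$hr_bpm
    else spec$hr_bpm[1] + (spec$hr_bpm[2] - spec$hr_bpm[1]) *
      pmin(1, t / spec$duration_s)
  }
  times <- numeric(0)
  premature <- logical(0)
  t <- 0.3
  k <- 0L
  while (t < spec$duration_s - 0.3) {
    times <- c(times, t)
    k <- k + 1L
    iv <- 60 / hr_at(t)
    if (spec$hr_jitter_pct > 0) {
      iv <- iv * (1 + stats::runif(1, -1, 1) * spec$hr_jitter_pct / 100)
    }
    is_prem <- spec$premature_every > 0 && k %% spec$premature_every == 0L
    if (is_prem) iv <- iv * (1 + spec$premature_frac)
    premature <- c(premature, is_prem)
    t <- t + iv
  }
  tibble::tibble(beat_time_s = times, premature = premature)
}

# Superimpose one Gaussian lobe per template wave for every beat.
render_bcg_waves <- function(t, beat_times, template, amp_mn, fs) {
  unit <- attr(template, "latency_unit") %||% "s"
  y <- numeric(length(t))
  n_beats <- length(beat_times)
  for (b in seq_len(n_beats)) {
    cyc <- if (b < n_beats) beat_times[b + 1L] - beat_times[b]
           else if (b > 1L) beat_times[b] - beat_times[b - 1L] else 1
    if (unit == "cycle_fraction") {
      lat <- template$latency * cyc
      wid <- template$width * cyc / 0.8
    } else {
      compress <- min(1, cyc / 0.75)
      lat <- template$latency * compress
      wid <- template$width * compress
    }
    for (w in seq_len(nrow(template))) {
      centre <- beat_times[b] + lat[w]
      i0 <- max(1L, floor((centre - 5 * wid[w]) * fs) + 1L)
      i1 <- min(length(t), ceiling((centre + 5 * wid[w]) * fs) + 1L)
      if (i0 > i1) next
      idx <- i0:i1
      y[idx] <- y[idx] + amp_mn * template$amp[w] *
        exp(-(t[idx] - centre)^2 / (2 * wid[w]^2))
    }
  }
  y
}

#' Generate a synthetic bed-sensor recording with ground truth
#'
#' See [bcg_scenario()] for the signal model. The same seed always yields
#' an identical recording; the caller's RNG state is left untouched.
#'
#' @param spec A [bcg_scenario()].
#' @return A list with elements `recording` (a [bcg_recording()]) and
#'   `truth`, itself a list with `beats` (tibble: `beat_time_s`,
#'   `premature`) and `breath_peak_times` (inhalation-peak times of the
#'   respiration component).
#' @export
generate_bcg <- function(spec) {
  stopifnot(inherits(spec, "bcg_scenario"))
  with_scenario_seed(spec$seed, {
    fs <- spec$fs_force
    n <- round(spec$duration_s * fs)
    t <- (seq_len(n) - 1) / fs
    beats <- scenario_beat_times(spec)
    template <- spec$wave_template %||%
      bcg_wave_template(if (spec$waves_per_cycle == 3) "normal" else "two_wave")
    amp <- spec$bcg_amp_mn *
      (if (spec$scale_amp_with_preload) spec$preload_n / 15 else 1)
    f_resp <- spec$rr_rpm / 60
    force <- spec$preload_n * 1000 +
      spec$resp_amp_mn * sin(2 * pi * f_resp * t) +
      render_bcg_waves(t, beats$beat_time_s, template, amp, fs)
    if (spec$emi_amp_mn > 0) {
      force <- force + spec$emi_amp_mn * sin(2 * pi * 50 * t)
    }
    if (spec$noise_sd_mn > 0) {
      force <- force + stats::rnorm(n, 0, spec$noise_sd_mn)
    }
    fs_e <- 3 * fs
    ne <- round(spec$duration_s * fs_e)
    te <- (seq_len(ne) - 1) / fs_e
    ecg <- numeric(ne)
    for (b in beats$beat_time_s) {
      i0 <- max(1L, floor((b - 0.04) * fs_e) + 1L)
      i1 <- min(ne, ceiling((b + 0.04) * fs_e) + 1L)
      idx <- i0:i1
      ecg[idx] <- ecg[idx] + spec$ecg_amp_v *
        exp(-(te[idx] - b)^2 / (2 * 0.008^2))
    }
    if (spec$ecg_drift_amp_v > 0) {
      ecg <- ecg + spec$ecg_drift_amp_v *
        sin(2 * pi * spec$ecg_drift_freq_hz * te)
    }
    if (spec$ecg_emi_amp_v > 0) {
      ecg <- ecg + spec$ecg_emi_amp_v * sin(2 * pi * 50 * te)
    }
    # inhalation peaks of the respiration sinusoid: quarter-period + k/f
    breath_peaks <- seq(1 / (4 * f_resp), spec$duration_s - 1 / fs,
                        by = 1 / f_resp)
    rec <- bcg_recording(
      sampled_signal(force, fs, units = "mN"),
      sampled_signal(ecg, fs_e, units = "V"),
      meta = list(preload_n = spec$preload_n, scenario = spec))
    list(recording = rec,
         truth = list(beats = beats, breath_peak_times = breath_peaks))
  })
}

#' Generate an arrhythmic synthetic recording
#'
#' Identical signal model to [generate_bcg()], emphasising the arrhythmic
#' timing fields: `premature_every` inserts a shortened (premature) or
#' lengthened interval every so many beats, `hr_jitter_pct` adds uniform
#' interval jitter, and the returned truth records which beats were
#' affected. With both fields zero it reduces exactly to
#' [generate_bcg()].
#'
#' @param spec A [bcg_scenario()].
#' @return As [generate_bcg()].
#' @export
generate_arrhythmia <- function(spec) {
  stopifnot(inherits(spec, "bcg_scenario"))
  generate_bcg(spec)
}
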