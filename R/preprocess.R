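#' Cardiac band filter specification
#'
#' The cardiac (BCG) component is isolated by a cascade of two linear-phase
#' FIR filters: a low-pass of `n_lp` taps at `f_lp` and a high-pass of
#' `n_hp` taps at `f_hp`. The defaults — 0.5–15 Hz with lengths 80 and
#' 540 — are the band and lengths found to work best for heart-rate
#' monitoring on this sensor; the earlier, wider 0.5–20 Hz variant remains
#' available by setting `f_lp = 20`. `ripple` and `atten` are the passband
#' deviation and stopband level as linear fractions of unity gain
#' (0.005\% and 0.01\%).
#'
#' @param f_hp High-pass cutoff in Hz.
#' @param f_lp Low-pass cutoff in Hz.
#' @param n_lp,n_hp Filter lengths in taps.
#' @param ripple Passband ripple (linear fraction of unity gain).
#' @param atten Stopband level (linear fraction of unity gain).
#' @return An object of class `cardiac_filter_spec`.
#' @export
cardiac_filter_spec <- function(f_hp = 0.5, f_lp = 15, n_lp = 80, n_hp = 540,
                                ripple = 5e-5, atten = 1e-4) {
  if (!(f_hp > 0 && f_hp < f_lp)) abort("need 0 < f_hp < f_lp.")
  if (n_lp < 2 || n_hp < 2) abort("filter lengths must be >= 2 taps.")
  structure(list(f_hp = f_hp, f_lp = f_lp, n_lp = as.integer(n_lp),
                 n_hp = as.integer(n_hp), ripple = ripple, atten = atten),
            class = "cardiac_filter_spec")
}

#' Respiration band filter specification
#'
#' The respiratory component is extracted with a single 3rd-order band-pass
#' Butterworth filter. Normal adult respiration spans roughly 8–30
#' breaths/min (0.13–0.5 Hz); the default passband is slightly wider at the
#' low end, 0.05–0.5 Hz.
#'
#' @param order Butterworth order.
#' @param f_low,f_high Band edges in Hz.
#' @return An object of class `respiration_filter_spec`.
#' @export
respiration_filter_spec <- function(order = 3, f_low = 0.05, f_high = 0.5) {
  if (!(f_low > 0 && f_low < f_high)) abort("need 0 < f_low < f_high.")
  structure(list(order = as.integer(order), f_low = f_low, f_high = f_high),
            class = "respiration_filter_spec")
}

normalized_sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Kaiser beta for a target ripple/attenuation level (standard empirical
# formula; delta is a linear fraction of unity gain).
kaiser_beta_for <- function(delta) {
  a <- -20 * log10(delta)
  if (a > 50) 0.1102 * (a - 8.7)
  else if (a >= 21) 0.5842 * (a - 21)^0.4 + 0.07886 * (a - 21)
  else 0
}

# Linear-phase low-pass: Kaiser-windowed ideal sinc centred at (n-1)/2.
# The DC gain is normalised to exactly 1.
design_fir_lowpass <- function(n_taps, fc, fs, beta) {
  tau <- (n_taps - 1) / 2
  k <- 0:(n_taps - 1)
  wc <- 2 * fc / fs                      # cutoff as fraction of Nyquist
  h <- wc * normalized_sinc((k - tau) * wc) * signal::kaiser(n_taps, beta)
  h / sum(h)
}

# Linear-phase high-pass: ideal all-pass (full-band sinc at the same,
# possibly fractional, delay) minus the ideal low-pass, Kaiser-windowed.
# Subtracting the tap mean nulls the DC gain exactly while preserving the
# symmetric (hence exactly linear-phase) impulse response. An even tap
# count forces a zero at Nyquist; that region is removed by the cascaded
# low-pass anyway.
design_fir_highpass <- function(n_taps, fc, fs, beta) {
  tau <- (n_taps - 1) / 2
  k <- 0:(n_taps - 1)
  wc <- 2 * fc / fs
  h <- (normalized_sinc(k - tau) - wc * normalized_sinc((k - tau) * wc)) *
    signal::kaiser(n_taps, beta)
  h - mean(h)
}

#' Design the cardiac FIR cascade
#'
#' Returns the two windowed-sinc linear-phase filters and their cascade.
#' Both impulse responses are exactly symmetric, so the cascade delays
#' every in-band component by exactly
#' `(n_lp - 1)/2 + (n_hp - 1)/2` samples (309 at the default lengths,
#' about 3.6 s at 84.8 Hz) without any phase distortion.
#'
#' @param spec A [cardiac_filter_spec()].
#' @param fs Sampling rate in Hz.
#' @return A list with elements `h_lp`, `h_hp`, `h` (cascade impulse
#'   response) and `delay` (group delay of the cascade in samples).
#' @export
design_cardiac_fir <- function(spec = cardiac_filter_spec(), fs = 84.8) {
  if (spec$f_lp >= fs / 2) abort("`f_lp` must be below the Nyquist rate.")
  beta <- kaiser_beta_for(min(spec$ripple, spec$atten))
  h_lp <- design_fir_lowpass(spec$n_lp, spec$f_lp, fs, beta)
  h_hp <- design_fir_highpass(spec$n_hp, spec$f_hp, fs, beta)
  h <- convolve(h_lp, rev(h_hp), type = "open")
  delay <- (spec$n_lp - 1) / 2 + (spec$n_hp - 1) / 2
  stopifnot(delay == round(delay))
  list(h_lp = h_lp, h_hp = h_hp, h = h, delay = as.integer(delay))
}

#' Extract the cardiac (BCG) component
#'
#' Applies the linear-phase FIR band cascade of [design_cardiac_fir()] and
#' shifts the output left by the cascade group delay so the filtered signal
#' is aligned to the raw time base. The input is extended at both ends by
#' replicating the edge samples before convolution, which suppresses the
#' step transient the static preload (a DC offset of thousands of mN)
#' would otherwise cause; samples within one filter length of either end
#' should still be treated as settling.
#'
#' @param raw A [sampled_signal()] with the raw force channel.
#' @param spec A [cardiac_filter_spec()].
#' @return A [sampled_signal()] of the same length, rate and time base.
#' @export
cardiac_component <- function(raw, spec = cardiac_filter_spec()) {
  stopifnot(inherits(raw, "sampled_signal"))
  n <- length(raw)
  if (n <= spec$n_hp) {
    abort(sprintf("signal too short for the cardiac filter (%d <= %d taps).",
                  n, spec$n_hp), class = "bedvitals_length_error")
  }
  des <- design_cardiac_fir(spec, raw$fs)
  h <- des$h
  pad <- length(h) - 1L
  x <- c(rep(raw$values[1], pad), raw$values, rep(raw$values[n], pad))
  y <- convolve(x, rev(h), type = "open")
  aligned <- y[(pad + des$delay + 1):(pad + des$delay + n)]
  bv_log("preprocess", "cardiac filter: %d samples, delay %d removed",
         n, des$delay)
  sampled_signal(aligned, raw$fs, raw$t0, raw$units)
}

#' Extract the respiration component
#'
#' Band-passes the raw force signal with the Butterworth filter of
#' [respiration_filter_spec()]. By default the filter is applied forward
#' and backward ([signal::filtfilt()]) so the net phase is exactly zero;
#' `zero_phase = FALSE` applies it once, as a real-time implementation
#' would, at the cost of the filter's own (mild) phase lag.
#'
#' @param raw A [sampled_signal()].
#' @param spec A [respiration_filter_spec()].
#' @param zero_phase Apply forward-backward filtering (default `TRUE`).
#' @return A [sampled_signal()] on the same grid.
#' @export
respiration_component <- function(raw, spec = respiration_filter_spec(),
                                  zero_phase = TRUE) {
  stopifnot(inherits(raw, "sampled_signal"))
  if (!length(raw)) {
    abort("empty signal.", class = "bedvitals_length_error")
  }
  if (spec$f_high >= raw$fs / 2) abort("`f_high` must be below Nyquist.")
  bf <- signal::butter(spec$order,
                       c(spec$f_low, spec$f_high) / (raw$fs / 2),
                       type = "pass")
  x <- raw$values - mean(raw$values)   # remove DC before the IIR warm-up
  y <- if (zero_phase) signal::filtfilt(bf, x)
       else as.numeric(signal::filter(bf, x))
  sampled_signal(y, raw$fs, raw$t0, raw$units)
}
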