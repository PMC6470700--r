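#' QRS detection parameters
#'
#' The reference ECG is used unfiltered; the QRS complex stays distinct
#' enough that three light-weight detection modes cover the conditions
#' met in practice (see [detect_qrs()]). `abs_threshold` serves the clean
#' mode; `rel_increase_threshold` scales the recording-wide median rise in
#' the baseline-drift mode; `ma_window` and `ma_coeff` parameterise the
#' moving-average comparison of the EMI mode; `refractory_s` is the
#' minimum accepted R-R interval (kept equal to the BCG `t_min`).
#'
#' @param abs_threshold Absolute amplitude threshold in volts.
#' @param rel_increase_threshold Fraction of the median peak rise.
#' @param ma_window Number of surrounding peaks in the moving average.
#' @param ma_coeff Multiplier applied to the moving average.
#' @param refractory_s Minimum R-R interval in seconds.
#' @return An object of class `qrs_params`.
#' @export
qrs_params <- function(abs_threshold = 0.5, rel_increase_threshold = 0.6,
                       ma_window = 8, ma_coeff = 1.2, refractory_s = 0.33) {
  if (abs_threshold <= 0 || rel_increase_threshold <= 0 || ma_coeff <= 0) {
    abort("thresholds must be positive.")
  }
  if (ma_window < 3) abort("`ma_window` must be >= 3.")
  if (refractory_s <= 0) abort("`refractory_s` must be positive.")
  structure(list(abs_threshold = abs_threshold,
                 rel_increase_threshold = rel_increase_threshold,
                 ma_window = as.integer(ma_window), ma_coeff = ma_coeff,
                 refractory_s = refractory_s),
            class = "qrs_params")
}

# Rise of each local maximum above the minimum separating it from the
# previous maximum (or from the signal start).
peak_rises <- function(values, max_idx) {
  prev <- c(1L, max_idx[-length(max_idx)])
  vapply(seq_along(max_idx), function(k) {
    values[max_idx[k]] - min(values[prev[k]:max_idx[k]])
  }, numeric(1))
}

# Greedy refractory pruning: strongest candidates first, a candidate is
# accepted when no already accepted peak lies within the refractory window.
# Returns the accepted positions, sorted by time.
apply_refractory <- function(times, strength, refractory_s) {
  ord <- order(-strength, times)
  accepted <- integer(0)
  for (k in ord) {
    if (!length(accepted) ||
        min(abs(times[accepted] - times[k])) >= refractory_s - 1e-9) {
      accepted <- c(accepted, k)
    }
  }
  sort(accepted)
}

#' Detect R peaks in the reference ECG
#'
#' Three modes match the three signal conditions encountered:
#' \describe{
#'   \item{`clean`}{local maxima above an absolute amplitude threshold —
#'     sufficient for a well-attached electrode.}
#'   \item{`baseline`}{when the baseline drifts, absolute amplitude is
#'     meaningless; instead the immediate rise of each peak above the
#'     preceding local minimum is compared against
#'     `rel_increase_threshold` times the recording-wide median rise.}
#'   \item{`emi`}{under heavy mains interference most local maxima are EMI
#'     crests; a peak is kept when its rise exceeds `ma_coeff` times the
#'     moving average of the rises of the `ma_window` surrounding peaks.}
#' }
#' All modes finish with a refractory pass (strongest peak wins within
#' `refractory_s`). `mode = "auto"` picks a mode from the spectral energy
#' below 1 Hz (drift) and near 50 Hz (EMI); the manual flag mirrors the
#' per-recording choice an operator would make by inspection.
#'
#' @param ecg A [sampled_signal()] with the raw, unfiltered ECG.
#' @param params A [qrs_params()].
#' @param mode One of `"clean"`, `"baseline"`, `"emi"`, `"auto"`.
#' @return A tibble with columns `peak_time_s` and `value`.
#' @export
detect_qrs <- function(ecg, params = qrs_params(),
                       mode = c("clean", "baseline", "emi", "auto")) {
  stopifnot(inherits(ecg, "sampled_signal"))
  mode <- match.arg(mode)
  if (!length(ecg)) {
    return(tibble::tibble(peak_time_s = numeric(), value = numeric()))
  }
  if (mode == "auto") {
    mode <- classify_ecg_mode(ecg)
    bv_log("ecg", "auto mode -> %s", mode)
  }
  mx <- local_maxima(ecg)
  if (!nrow(mx)) {
    return(tibble::tibble(peak_time_s = numeric(), value = numeric()))
  }
  if (mode == "clean") {
    cand <- mx$value >= params$abs_threshold
    strength <- mx$value
  } else {
    rises <- peak_rises(ecg$values, mx$index)
    strength <- rises
    if (mode == "baseline") {
      cand <- rises >= params$rel_increase_threshold * median(rises)
    } else {
      w <- params$ma_window
      n <- nrow(mx)
      ma <- vapply(seq_len(n), function(k) {
        lo <- max(1L, k - w %/% 2L); hi <- min(n, k + w %/% 2L)
        idx <- setdiff(lo:hi, k)
        if (length(idx)) mean(rises[idx]) else rises[k]
      }, numeric(1))
      cand <- rises >= params$ma_coeff * ma
    }
  }
  cand_idx <- which(cand)
  keep <- apply_refractory(mx$time_s[cand_idx], strength[cand_idx],
                           params$refractory_s)
  sel <- cand_idx[keep]
  tibble::tibble(peak_time_s = mx$time_s[sel], value = mx$value[sel])
}

# Heuristic noise-condition classifier: fraction of AC power below 1 Hz
# (baseline drift) and within 2 Hz of the 50 Hz mains line (EMI).
classify_ecg_mode <- function(ecg) {
  v <- ecg$values - mean(ecg$values)
  n <- length(v)
  sp <- Mod(fft(v))[1:(n %/% 2)]^2
  f <- (seq_len(n %/% 2) - 1) * ecg$fs / n
  tot <- sum(sp[f > 0])
  if (tot == 0) return("clean")
  mains <- 50
  if (ecg$fs / 2 < 50) mains <- abs(50 - ecg$fs)   # aliased line frequency
  emi_frac <- sum(sp[abs(f - mains) <= 2]) / tot
  drift_frac <- sum(sp[f > 0 & f < 1]) / tot
  if (emi_frac > 0.2) "emi" else if (drift_frac > 0.2) "baseline" else "clean"
}

#' Beat-to-beat rates from R-peak times
#'
#' @param r_times Numeric vector of R-peak times in seconds, or the tibble
#'   returned by [detect_qrs()].
#' @return A tibble with one row per R-R interval: `t_start`, `t_end` and
#'   the integer `rate_bpm = round(60 / (t_end - t_start))`. Fewer than
#'   two peaks yield an empty tibble.
#' @export
qrs_to_rates <- function(r_times) {
  if (is.data.frame(r_times)) r_times <- r_times$peak_time_s
  r_times <- sort(r_times)
  if (length(r_times) < 2L) {
    return(tibble::tibble(t_start = numeric(), t_end = numeric(),
                          rate_bpm = integer()))
  }
  tibble::tibble(t_start = head(r_times, -1L), t_end = tail(r_times, -1L),
                 rate_bpm = as.integer(round(60 / diff(r_times))))
}
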