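#' Detect respiration cycles
#'
#' Inhalation peaks are the local maxima of the respiration component
#' (see [respiration_component()]); they mark the boundaries of
#' respiration cycles, and the breath-to-breath rate follows as
#' `60 / dt` breaths per minute. The respiration band (below 0.5 Hz) is
#' essentially free of competing noise sources, so no amplitude threshold
#' is applied by default; `min_prominence` adds an optional guard that
#' drops maxima rising less than that amount above the neighbouring
#' minima.
#'
#' @param resp A [sampled_signal()], normally the output of
#'   [respiration_component()].
#' @param min_prominence Minimum rise (signal units) of a retained peak
#'   above the higher of its flanking minima; 0 disables the guard.
#' @return A tibble with columns `peak_time_s` and `rate_rpm`, where
#'   `rate_rpm[k]` is the rate of the cycle ending at peak `k` (`NA` for
#'   the first peak). Fewer than two peaks yield an empty rate column.
#' @export
detect_breaths <- function(resp, min_prominence = 0) {
  stopifnot(inherits(resp, "sampled_signal"))
  mx <- local_maxima(resp)
  if (min_prominence > 0 && nrow(mx) > 0) {
    v <- resp$values
    bounds <- c(1L, mx$index, length(v))
    keep <- vapply(seq_len(nrow(mx)), function(k) {
      left <- min(v[bounds[k]:mx$index[k]])
      right <- min(v[mx$index[k]:bounds[k + 2L]])
      mx$value[k] - max(left, right) >= min_prominence
    }, logical(1))
    mx <- mx[keep, , drop = FALSE]
  }
  rate <- if (nrow(mx) >= 2L) c(NA_real_, 60 / diff(mx$time_s))
          else rep(NA_real_, nrow(mx))
  tibble::tibble(peak_time_s = mx$time_s, rate_rpm = rate)
}
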