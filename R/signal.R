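#' Uniformly sampled signal
#'
#' A light container for one uniformly sampled channel: a numeric vector of
#' sample values, the sampling rate in Hz, the time of the first sample and
#' a unit label. The time of sample `k` (1-based) is `t0 + (k - 1) / fs`;
#' every downstream operation in the package relies on this uniform-grid
#' contract, which [read_recording()] enforces on load.
#'
#' @param values Numeric vector of sample values. Must be finite.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param t0 Time of the first sample in seconds.
#' @param units Unit label, e.g. `"mN"` for force or `"V"` for ECG.
#'
#' @return An object of class `sampled_signal`.
#' @examples
#' s <- sampled_signal(sin(2 * pi * 1 * (0:847) / 84.8), fs = 84.8)
#' signal_duration(s)
#' @export
sampled_signal <- function(values, fs, t0 = 0, units = "mN") {
  values <- as.numeric(values)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a positive finite scalar (Hz).")
  }
  if (length(values) && !all(is.finite(values))) {
    abort("`values` must be finite.")
  }
  structure(
    list(values = values, fs = as.numeric(fs), t0 = as.numeric(t0),
         units = as.character(units)),
    class = "sampled_signal"
  )
}

#' @export
length.sampled_signal <- function(x) length(x$values)

#' Sample times of a signal
#'
#' @param sig A [sampled_signal()].
#' @return Numeric vector of sample times in seconds.
#' @export
signal_time <- function(sig) {
  stopifnot(inherits(sig, "sampled_signal"))
  sig$t0 + (seq_along(sig$values) - 1) / sig$fs
}

#' Duration of a signal in seconds
#'
#' Defined as `n / fs`, i.e. the span covered when each sample owns one
#' sampling interval.
#'
#' @param sig A [sampled_signal()].
#' @return Duration in seconds.
#' @export
signal_duration <- function(sig) length(sig$values) / sig$fs

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal> %d samples @ %.6g Hz (%.4g s), units %s, t0 = %.6g s\n",
              length(x$values), x$fs, signal_duration(x), x$units, x$t0))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @exportS3Method tibble::as_tibble
as_tibble.sampled_signal <- function(x, ...) {
  tibble::tibble(time_s = signal_time(x), value = x$values)
}

#' Extract a sub-signal by time window
#'
#' @param sig A [sampled_signal()].
#' @param from,to Window boundaries in seconds (absolute time). The window
#'   is `[from, to)` on the sample grid.
#' @return A [sampled_signal()] whose `t0` is the time of its first sample.
#' @export
signal_window <- function(sig, from, to) {
  t <- signal_time(sig)
  keep <- which(t >= from - 1e-9 & t < to - 1e-9)
  if (!length(keep)) {
    return(sampled_signal(numeric(0), sig$fs, t0 = from, units = sig$units))
  }
  sampled_signal(sig$values[keep], sig$fs, t0 = t[keep[1]], units = sig$units)
}

#' Line plot of a sampled signal
#'
#' @param object A [sampled_signal()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sampled_signal <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time [s]", y = object$units) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
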