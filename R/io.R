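#' Two-channel bed-sensor recording
#'
#' Bundles the load-cell force channel (nominally 84.8 Hz, millinewton) and
#' the reference ECG channel (sampled at three times the force rate, volt)
#' together with free-form metadata such as the lying position and the
#' static preload. The ECG channel is optional: force-only recordings are
#' valid.
#'
#' @param force A [sampled_signal()] with the force channel.
#' @param ecg A [sampled_signal()] with the ECG channel, or `NULL`.
#' @param meta Named list of annotations. If `preload_n` is present it must
#'   lie in (0, 50] N, the operating range of the load cell.
#'
#' @return An object of class `bcg_recording`.
#' @export
bcg_recording <- function(force, ecg = NULL, meta = list()) {
  stopifnot(inherits(force, "sampled_signal"))
  if (!is.null(ecg)) {
    stopifnot(inherits(ecg, "sampled_signal"))
    if (length(ecg) > 1 && length(force) > 1) {
      ratio <- ecg$fs / force$fs
      if (abs(ratio / 3 - 1) > 0.001) {
        abort(sprintf(
          "ECG rate must be 3x the force rate within 0.1%% (got ratio %.4f).",
          ratio))
      }
    }
  }
  if (!is.null(meta$preload_n)) {
    p <- meta$preload_n
    if (!is.numeric(p) || p <= 0 || p > 50) {
      abort("`meta$preload_n` must lie in (0, 50] N.")
    }
  }
  structure(list(force = force, ecg = ecg, meta = meta),
            class = "bcg_recording")
}

#' @export
print.bcg_recording <- function(x, ...) {
  cat("<bcg_recording>\n  force: ")
  print(x$force)
  cat("  ecg:   ")
  if (is.null(x$ecg) || !length(x$ecg)) cat("(absent)\n") else print(x$ecg)
  scal <- x$meta[vapply(x$meta, function(m) is.atomic(m) && length(m) == 1L,
                        logical(1))]
  if (length(scal)) {
    cat("  meta:  ", paste(names(scal), vapply(scal, format, character(1)),
                           sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

# Snap one channel's rows to a uniform grid at the mean observed rate.
# Raw acquisition timestamps carry transmission jitter; all downstream maths
# assumes uniform sampling, so values are kept in arrival order and indexed
# on the grid t0 + k/fs.
regularize_channel <- function(ts, vals, units, fs_override = NULL,
                               channel = "force") {
  ok <- is.finite(ts) & is.finite(vals)
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    bv_log("io", "channel %s: dropping %d malformed row(s)", channel, n_bad)
  }
  ts <- ts[ok]; vals <- vals[ok]
  n <- length(vals)
  if (n == 0L) {
    return(sampled_signal(numeric(0), fs = fs_override %||% 1, units = units))
  }
  if (n == 1L) {
    return(sampled_signal(vals, fs = fs_override %||% 1, t0 = ts, units = units))
  }
  fs <- fs_override %||% ((n - 1) / (ts[n] - ts[1]))
  if (!is.finite(fs) || fs <= 0) {
    abort(sprintf("channel %s: timestamps span a non-positive duration.",
                  channel), class = "bedvitals_data_error")
  }
  # Jitter beyond half a sampling period means rows are out of order on the
  # nominal grid and cannot be snapped faithfully.
  if (any(diff(ts) < -0.5 / fs)) {
    abort(sprintf("channel %s: non-monotonic timestamps beyond tolerance.",
                  channel), class = "bedvitals_data_error")
  }
  grid_dev <- ts - (ts[1] + (seq_len(n) - 1) / fs)
  if (max(abs(grid_dev)) > 0.5 / fs + 1e-9) {
    abort(sprintf(
      "channel %s: timestamps deviate from a uniform grid by more than half a period.",
      channel), class = "bedvitals_data_error")
  }
  sampled_signal(vals, fs = fs, t0 = ts[1], units = units)
}

#' Read a two-channel recording from CSV
#'
#' The on-disk format is a long CSV with columns `channel` (`force` or
#' `ecg`), `timestamp_s` and `value`; force values are in millinewton, ECG
#' values in volt. Acquisition timestamps may carry small jitter: each
#' channel is regularized onto a uniform grid at its mean observed rate
#' (values are preserved, only timestamps are snapped). Rows with
#' non-finite fields are dropped and the count is logged.
#'
#' @param path Path to the CSV file.
#' @param config Optional named list of format options: `require_ecg`
#'   (logical, default `FALSE`), `fs_force` / `fs_ecg` rate overrides in Hz,
#'   and metadata keys `preload_n` and `position` copied into the recording.
#'   A YAML file with these keys can be loaded with [read_run_config()].
#'
#' @return A [bcg_recording()].
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, config = list()) {
  if (!file.exists(path)) {
    abort(sprintf("recording file not found: %s", path),
          class = "bedvitals_io_error")
  }
  df <- readr::read_csv(path, col_types = readr::cols(
    channel = readr::col_character(),
    timestamp_s = readr::col_double(),
    value = readr::col_double()
  ), progress = FALSE)
  if (!all(c("channel", "timestamp_s", "value") %in% names(df))) {
    abort("recording CSV must have columns channel, timestamp_s, value.",
          class = "bedvitals_format_error")
  }
  fo <- df[df$channel == "force", ]
  ec <- df[df$channel == "ecg", ]
  if (nrow(fo) == 0L) {
    abort("recording has no `force` channel.",
          class = "bedvitals_format_error")
  }
  if (nrow(ec) == 0L && isTRUE(config$require_ecg)) {
    abort("recording has no `ecg` channel but one is required.",
          class = "bedvitals_format_error")
  }
  force <- regularize_channel(fo$timestamp_s, fo$value, "mN",
                              config$fs_force, "force")
  ecg <- NULL
  if (nrow(ec) > 0L) {
    ecg <- regularize_channel(ec$timestamp_s, ec$value, "V",
                              config$fs_ecg, "ecg")
  }
  meta <- config[intersect(names(config), c("preload_n", "position"))]
  bv_log("io", "read %s: %d force + %d ecg samples", path, length(force),
         if (is.null(ecg)) 0L else length(ecg))
  bcg_recording(force, ecg, meta)
}

#' Write a recording to CSV
#'
#' Inverse of [read_recording()]: values round-trip to within the numeric
#' precision of the text format.
#'
#' @param rec A [bcg_recording()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "bcg_recording"))
  chunks <- list(
    tibble::tibble(channel = "force", timestamp_s = signal_time(rec$force),
                   value = rec$force$values)
  )
  if (!is.null(rec$ecg) && length(rec$ecg)) {
    chunks <- c(chunks, list(
      tibble::tibble(channel = "ecg", timestamp_s = signal_time(rec$ecg),
                     value = rec$ecg$values)))
  }
  out <- dplyr::bind_rows(chunks)
  tryCatch(
    readr::write_csv(out, path, progress = FALSE),
    error = function(e) abort(sprintf("cannot write recording to %s: %s",
                                      path, conditionMessage(e)),
                              class = "bedvitals_io_error")
  )
  bv_log("io", "wrote %s: %d rows", path, nrow(out))
  invisible(path)
}

#' Read a YAML run configuration
#'
#' A flat key/value YAML file carrying format options (rate overrides,
#' preload, position label) and parameter overrides for the pipeline.
#' Unknown keys are rejected so that typos do not silently fall back to
#' defaults.
#'
#' @param path Path to a YAML file.
#' @param allowed Character vector of accepted keys.
#' @return A named list.
#' @export
read_run_config <- function(path,
                            allowed = c("require_ecg", "fs_force", "fs_ecg",
                                        "preload_n", "position", "seed",
                                        "band", "theta", "alpha", "t_min",
                                        "zero_phase", "qrs_mode", "out_dir",
                                        "scenario")) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  extra <- setdiff(names(cfg), allowed)
  if (length(extra)) {
    abort(paste0("unknown config key(s): ", paste(extra, collapse = ", ")),
          class = "bedvitals_format_error")
  }
  cfg
}
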