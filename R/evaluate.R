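#' Score BCG beat detection against the ECG reference
#'
#' Every reference cardiac cycle — the interval between two consecutive
#' R peaks — is inspected for BCG detections:
#' \itemize{
#'   \item exactly one BCG beat whose beat-to-beat rate agrees with the
#'     ECG cycle rate within `tol_bpm` (rates rounded to integers) and
#'     whose timing offset from the cycle start matches the segment's
#'     modal offset within `misplaced_tol_s` counts as \emph{correct};
#'   \item more than one beat in a cycle is a \emph{false positive}
#'     (multiplicate detection);
#'   \item no beat is a \emph{false negative};
#'   \item a lone beat that fails the rate or offset test is
#'     \emph{misplaced} — it represents a different wave type than the
#'     segment's majority.
#' }
#' Cycles that straddle a segment boundary are excluded from the
#' theoretically detectable count, because the clustering passes on the
#' two sides may legitimately track different wave types (29 such
#' intermediate cycles in a 5-minute recording). The rate attributed to a
#' lone beat is that of its forward beat-to-beat interval; when that
#' interval is boundary-flagged (or the beat is the last), the preceding
#' interval is used instead. A lone beat with no usable interval leaves
#' its cycle unassessable, and cycles ending after `t_max` are likewise
#' excluded (the pipeline sets `t_max` one feature window before the end
#' of the recording, where the detector can no longer emit a beat).
#'
#' @param beats Tibble from [detect_beats()] (columns `segment`,
#'   `beat_time_s` at least).
#' @param rpeaks Reference R-peak times: numeric vector or the tibble from
#'   [detect_qrs()].
#' @param tol_bpm Maximum rate discrepancy counted as correct.
#' @param plan The [segment_plan()] used for detection; segment boundaries
#'   default to its step times.
#' @param boundary_times Optional explicit boundary times, overriding
#'   `plan`.
#' @param misplaced_tol_s Offset tolerance for the wave-type consistency
#'   check.
#' @param t_max Cycles ending after this time are not assessable;
#'   `NULL` keeps every cycle.
#' @return An object of class `detection_report`; see
#'   [glance.detection_report()] and [tidy.detection_report()].
#' @export
score_recording <- function(beats, rpeaks, tol_bpm = 5,
                            plan = segment_plan(), boundary_times = NULL,
                            misplaced_tol_s = 0.15, t_max = NULL) {
  if (is.data.frame(rpeaks)) rpeaks <- rpeaks$peak_time_s
  rpeaks <- sort(rpeaks)
  if (length(rpeaks) < 2L) {
    abort("reference must contain at least two R peaks.",
          class = "bedvitals_reference_error")
  }
  if (is.null(boundary_times)) {
    boundary_times <- seq(plan$step_s, max(rpeaks), by = plan$step_s)
  }
  if (!all(c("rate_bpm", "boundary_flag") %in% names(beats))) {
    beats <- beats_to_rates(beats[order(beats$beat_time_s), ])
  }
  ord <- order(beats$beat_time_s)
  bt <- beats$beat_time_s[ord]
  seg_of <- beats$segment[ord]
  rate_fwd <- beats$rate_bpm[ord]
  rate_bwd <- c(NA_integer_, head(rate_fwd, -1L))
  nc <- length(rpeaks) - 1L
  cyc <- tibble::tibble(
    t_start = rpeaks[-length(rpeaks)],
    t_end = rpeaks[-1L]
  )
  cyc$ecg_rate_bpm <- as.integer(round(60 / (cyc$t_end - cyc$t_start)))
  cyc$boundary <- vapply(seq_len(nc), function(k) {
    any(boundary_times > cyc$t_start[k] & boundary_times < cyc$t_end[k])
  }, logical(1))
  # locate beats per cycle
  bin <- findInterval(bt, rpeaks)          # 0 before first peak
  cyc$n_beats <- vapply(seq_len(nc), function(k) sum(bin == k), integer(1))
  lone <- function(k) which(bin == k)[1]
  cyc$beat_time_s <- NA_real_
  cyc$bcg_rate_bpm <- NA_integer_
  cyc$segment <- NA_integer_
  for (k in which(cyc$n_beats == 1L)) {
    j <- lone(k)
    cyc$beat_time_s[k] <- bt[j]
    cyc$segment[k] <- seg_of[j]
    cyc$bcg_rate_bpm[k] <- if (!is.na(rate_fwd[j])) rate_fwd[j]
                           else rate_bwd[j]
  }
  cyc$offset_s <- cyc$beat_time_s - cyc$t_start
  # modal (median) offset of lone detections per segment
  modal <- tapply(cyc$offset_s[!is.na(cyc$offset_s)],
                  cyc$segment[!is.na(cyc$offset_s)], median)
  cyc$modal_offset_s <- as.numeric(modal[as.character(cyc$segment)])
  cyc$class <- NA_character_
  for (k in seq_len(nc)) {
    if (!is.null(t_max) && cyc$t_end[k] > t_max) {
      cyc$class[k] <- "unassessable"; next
    }
    if (cyc$boundary[k]) { cyc$class[k] <- "boundary_excluded"; next }
    nb <- cyc$n_beats[k]
    if (nb == 0L) { cyc$class[k] <- "false_negative"; next }
    if (nb > 1L) { cyc$class[k] <- "false_positive"; next }
    if (is.na(cyc$bcg_rate_bpm[k])) { cyc$class[k] <- "unassessable"; next }
    rate_ok <- abs(cyc$bcg_rate_bpm[k] - cyc$ecg_rate_bpm[k]) <= tol_bpm
    off_ok <- is.na(cyc$modal_offset_s[k]) ||
      abs(cyc$offset_s[k] - cyc$modal_offset_s[k]) <= misplaced_tol_s
    cyc$class[k] <- if (rate_ok && off_ok) "correct" else "misplaced"
  }
  counts <- table(factor(cyc$class,
                         levels = c("correct", "false_positive",
                                    "false_negative", "misplaced",
                                    "boundary_excluded", "unassessable")))
  n_detectable <- sum(counts[c("correct", "false_positive",
                               "false_negative", "misplaced")])
  n_not_correct <- sum(counts[c("false_positive", "false_negative",
                                "misplaced")])
  summary <- tibble::tibble(
    n_detectable = as.integer(n_detectable),
    n_not_correct = as.integer(n_not_correct),
    n_false_positive = as.integer(counts[["false_positive"]]),
    n_false_negative = as.integer(counts[["false_negative"]]),
    n_misplaced = as.integer(counts[["misplaced"]]),
    n_boundary_excluded = as.integer(counts[["boundary_excluded"]]),
    pct_correct = detection_percentage(n_detectable, n_not_correct)
  )
  structure(list(summary = summary, cycles = cyc), class = "detection_report")
}

#' Correct-detection percentage
#'
#' `100 * (detectable - not_correct) / detectable`, rounded half away
#' from zero to one decimal.
#'
#' @param n_detectable,n_not_correct Cycle counts.
#' @return Percentage, one decimal.
#' @export
detection_percentage <- function(n_detectable, n_not_correct) {
  round_half_away(100 * (n_detectable - n_not_correct) / n_detectable, 1)
}

#' @export
print.detection_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<detection_report> %d detectable cycles: %.1f%% correct (%d FP, %d FN, %d misplaced; %d boundary-excluded)\n",
    s$n_detectable, s$pct_correct, s$n_false_positive, s$n_false_negative,
    s$n_misplaced, s$n_boundary_excluded))
  invisible(x)
}

#' One-row summary of a detection report
#'
#' @param x A `detection_report`.
#' @param ... Unused.
#' @return A one-row tibble with the counts and `pct_correct`.
#' @exportS3Method generics::glance
glance.detection_report <- function(x, ...) x$summary

#' Per-cycle detail of a detection report
#'
#' @param x A `detection_report`.
#' @param ... Unused.
#' @return A tibble with one row per reference cardiac cycle.
#' @exportS3Method generics::tidy
tidy.detection_report <- function(x, ...) tibble::as_tibble(x$cycles)

#' Bar chart of detection outcome classes
#'
#' @param object A `detection_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.detection_report <- function(object, ...) {
  df <- dplyr::count(tibble::as_tibble(object$cycles), .data$class)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "reference cycles") +
    ggplot2::theme_minimal()
}

#' Aggregate detection rates
#'
#' Unweighted mean of `pct_correct` within groups (all measurements carry
#' the same weight since they have equal duration), rounded half away
#' from zero to one decimal. With no grouping columns the overall mean is
#' returned.
#'
#' @param reports A data frame with a `pct_correct` column, e.g. row-bound
#'   [glance.detection_report()] outputs or [reference_detection_table()].
#' @param ... Grouping columns (tidy-select), e.g. `position` or
#'   `volunteer`.
#' @return A tibble with the grouping columns, `mean_pct_correct` and the
#'   group size `n`.
#' @export
aggregate_reports <- function(reports, ...) {
  grouped <- dplyr::group_by(tibble::as_tibble(reports), ...)
  dplyr::summarise(grouped,
                   mean_pct_correct = round_half_away(
                     mean(.data$pct_correct), 1),
                   n = dplyr::n(), .groups = "drop")
}

#' Bundled reference evaluation table
#'
#' Per-measurement heart-beat detection results of a published
#' seven-volunteer bed-sensor evaluation (four lying positions per
#' volunteer, 5-minute measurements in triplicate): volunteer biometrics,
#' lying position, average heart rate, the number of theoretically
#' detectable beat-to-beat cycles, the cycles not correctly detected, the
#' false-positive count and the resulting correct-detection percentage.
#' Useful as a fixture for [aggregate_reports()] and
#' [detection_percentage()].
#'
#' @return A tibble with 28 rows (7 volunteers x 4 positions).
#' @export
reference_detection_table <- function() {
  path <- system.file("extdata", "reference_detection_table.csv",
                      package = "bedvitals", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    volunteer = readr::col_integer(),
    sex = readr::col_character(),
    age_yr = readr::col_integer(),
    weight_kg = readr::col_integer(),
    height_cm = readr::col_integer(),
    position = readr::col_character(),
    avg_hr_bpm = readr::col_integer(),
    n_detectable = readr::col_integer(),
    n_not_correct = readr::col_integer(),
    n_false_positive = readr::col_integer(),
    pct_correct = readr::col_double()
  ), progress = FALSE)
}
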