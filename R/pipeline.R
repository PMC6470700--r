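#' Pipeline run configuration
#'
#' Bundles everything one end-to-end run needs: where the input comes from
#' (a recording CSV, or a [bcg_scenario()] to synthesise), the parameter
#' objects of every stage, which stages to run and where to write the
#' artifacts. Unknown arguments are rejected.
#'
#' @param input Path to a recording CSV, or `NULL` to synthesise from
#'   `scenario`.
#' @param scenario A [bcg_scenario()] used when `input` is `NULL`.
#' @param out_dir Output directory for artifacts (created if needed);
#'   `NULL` writes nothing.
#' @param cardiac A [cardiac_filter_spec()].
#' @param respiration A [respiration_filter_spec()].
#' @param cluster A [cluster_params()].
#' @param plan A [segment_plan()].
#' @param qrs A [qrs_params()].
#' @param qrs_mode Mode flag for [detect_qrs()].
#' @param stages Character vector of stages to run, a subset of
#'   `c("filter", "detect", "respiration", "ecg", "evaluate")`; stages
#'   with unmet dependencies are skipped with a log line.
#' @param seed Seed applied to the scenario when synthesising.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input = NULL, scenario = bcg_scenario(),
                       out_dir = NULL,
                       cardiac = cardiac_filter_spec(),
                       respiration = respiration_filter_spec(),
                       cluster = cluster_params(), plan = segment_plan(),
                       qrs = qrs_params(), qrs_mode = "auto",
                       stages = c("filter", "detect", "respiration", "ecg",
                                  "evaluate"),
                       seed = NULL) {
  known <- c("filter", "detect", "respiration", "ecg", "evaluate")
  if (length(setdiff(stages, known))) {
    abort(paste0("unknown stage(s): ",
                 paste(setdiff(stages, known), collapse = ", ")))
  }
  structure(list(input = input, scenario = scenario, out_dir = out_dir,
                 cardiac = cardiac, respiration = respiration,
                 cluster = cluster, plan = plan, qrs = qrs,
                 qrs_mode = qrs_mode, stages = stages, seed = seed),
            class = "run_config")
}

#' Run the full vital-signs pipeline
#'
#' Chains synthesis (or loading), band filtering, heartbeat detection,
#' respiration detection, reference QRS detection and evaluation, writing
#' each artifact as CSV/JSON under `config$out_dir`. Identical
#' configuration and seed produce identical artifacts.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the intermediate results: `recording`,
#'   `truth` (when synthesised), `cardiac`, `respiration`, `beats`,
#'   `breaths`, `rpeaks` and `report`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  bv_log("pipeline", "stages: %s", paste(config$stages, collapse = ", "))
  out <- list()
  if (is.null(config$input)) {
    sc <- config$scenario
    if (!is.null(config$seed)) sc$seed <- as.integer(config$seed)
    gen <- generate_bcg(sc)
    out$recording <- gen$recording
    out$truth <- gen$truth
    bv_log("pipeline", "synthesised %g s scenario (seed %d)",
           sc$duration_s, sc$seed)
  } else {
    if (!file.exists(config$input)) {
      abort(sprintf("stage io: input not found: %s", config$input),
            class = "bedvitals_io_error")
    }
    out$recording <- read_recording(config$input)
  }
  dir_out <- config$out_dir
  if (!is.null(dir_out) && !dir.exists(dir_out)) {
    dir.create(dir_out, recursive = TRUE)
  }
  emit <- function(df, name) {
    if (!is.null(dir_out)) {
      readr::write_csv(df, file.path(dir_out, name), progress = FALSE)
    }
  }
  if (!is.null(dir_out)) {
    write_recording(out$recording, file.path(dir_out, "recording.csv"))
  }
  if ("filter" %in% config$stages) {
    out$cardiac <- cardiac_component(out$recording$force, config$cardiac)
    out$respiration_sig <- respiration_component(out$recording$force,
                                                 config$respiration)
    emit(tibble::tibble(time_s = signal_time(out$cardiac),
                        cardiac_mn = out$cardiac$values,
                        respiration_mn = out$respiration_sig$values),
         "filtered.csv")
  }
  if ("detect" %in% config$stages) {
    if (is.null(out$cardiac)) {
      bv_log("pipeline", "detect skipped: no filtered cardiac signal")
    } else {
      out$beats <- detect_beats(out$cardiac, config$cluster, config$plan)
      emit(out$beats, "beats.csv")
    }
  }
  if ("respiration" %in% config$stages && !is.null(out$respiration_sig)) {
    out$breaths <- detect_breaths(out$respiration_sig)
    emit(out$breaths, "breaths.csv")
  }
  if ("ecg" %in% config$stages) {
    if (is.null(out$recording$ecg) || !length(out$recording$ecg)) {
      bv_log("pipeline", "ecg skipped: recording has no ECG channel")
    } else {
      out$rpeaks <- detect_qrs(out$recording$ecg, config$qrs,
                               config$qrs_mode)
      emit(out$rpeaks, "rpeaks.csv")
    }
  }
  if ("evaluate" %in% config$stages) {
    if (is.null(out$beats) || is.null(out$rpeaks)) {
      bv_log("pipeline", "evaluate skipped: needs beats and rpeaks")
    } else {
      out$report <- score_recording(out$beats, out$rpeaks,
                                    plan = config$plan,
                                    t_max = signal_duration(out$cardiac) - 0.66)
      if (!is.null(dir_out)) {
        jsonlite::write_json(as.list(glance(out$report)),
                             file.path(dir_out, "report.json"),
                             auto_unbox = TRUE, digits = NA)
      }
    }
  }
  invisible(out)
}
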