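#' Read and write moment-trace CSV files
#'
#' Traces are stored as two-column CSV with a header: `time_s` plus
#' `moment_nm` (newton-meters) or `value_v` (raw volts). The sampling rate is
#' recovered from the median timestamp spacing.
#'
#' @param trace A [moment_trace()].
#' @param path File path.
#' @return `read_trace_csv()` returns a [moment_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "moment_trace"))
  col <- if (trace$units == "newton_meters") "moment_nm" else "value_v"
  df <- data.frame(time_s = trace_times(trace), v = trace$samples)
  names(df)[2] <- col
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path))
    stop_twitchva("io", sprintf("read_trace_csv: no such file: %s", path))
  df <- utils::read.csv(path)
  if (!"time_s" %in% names(df))
    stop_twitchva("validation", sprintf("read_trace_csv: %s lacks a 'time_s' column", path))
  value_col <- intersect(c("moment_nm", "value_v"), names(df))
  if (length(value_col) != 1L)
    stop_twitchva("validation", sprintf(
      "read_trace_csv: %s needs exactly one of 'moment_nm' or 'value_v'", path))
  if (nrow(df) < 2L)
    stop_twitchva("validation", sprintf("read_trace_csv: %s has < 2 samples", path))
  if (anyNA(df[[value_col]]) || anyNA(df$time_s))
    stop_twitchva("validation", sprintf("read_trace_csv: %s contains missing values", path))
  dt <- stats::median(diff(df$time_s))
  moment_trace(df[[value_col]], sampling_rate = 1 / dt,
               units = if (value_col == "moment_nm") "newton_meters" else "volts",
               start_time = df$time_s[1])
}

#' Write a study dataset to a directory
#'
#' Writes one trace CSV per trial under `<dir>/traces/`, a `manifest.csv`
#' (trial identity, stimulus times, trace path relative to `dir`) and a
#' `ground_truth.csv`.
#'
#' @param study A `study_dataset` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "study_dataset"))
  trace_dir <- file.path(dir, "traces")
  dir.create(trace_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(trace_dir))
    stop_twitchva("io", sprintf("write_study: cannot create %s", trace_dir))
  manifest <- study$manifest
  manifest$trace_path <- file.path("traces", paste0(manifest$trial_id, ".csv"))
  for (i in seq_along(study$trials))
    write_trace_csv(study$trials[[i]]$trace,
                    file.path(dir, manifest$trace_path[i]))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(study$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a study dataset from a directory
#'
#' Validates the manifest schema, reads every referenced trace (an absent
#' file is an error naming the trial), and reconstructs the trial records.
#'
#' @param dir Directory written by [write_study()] (or hand-assembled in the
#'   same layout).
#' @return A `study_dataset`; `ground_truth` is `NULL` when no
#'   `ground_truth.csv` is present (real recordings).
#' @export
read_study <- function(dir) {
  man_path <- file.path(dir, "manifest.csv")
  if (!file.exists(man_path))
    stop_twitchva("io", sprintf("read_study: no manifest.csv in %s", dir))
  manifest <- utils::read.csv(man_path, stringsAsFactors = FALSE)
  required <- c("trial_id", "arm_id", "transfer_group", "posture",
                "trial_type", "target_level", "stim1_time_s", "stim2_time_s",
                "trace_path")
  missing_cols <- setdiff(required, names(manifest))
  if (length(missing_cols))
    stop_twitchva("validation", sprintf(
      "read_study: manifest lacks columns: %s", paste(missing_cols, collapse = ", ")))
  if (nrow(manifest) == 0L)
    stop_twitchva("missing_data", "read_study: no trials in manifest")
  if (!"subject_id" %in% names(manifest)) manifest$subject_id <- manifest$arm_id
  trials <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    tp <- file.path(dir, row$trace_path)
    if (!file.exists(tp))
      stop_twitchva("io", sprintf(
        "read_study: trace file missing for trial '%s': %s", row$trial_id, tp))
    trace <- read_trace_csv(tp)
    stim <- if (row$trial_type == "mvc") numeric(0) else
      c(row$stim1_time_s, row$stim2_time_s)
    trials[[i]] <- trial_record(
      trial_id = row$trial_id, arm_id = row$arm_id,
      subject_id = row$subject_id, transfer_group = row$transfer_group,
      posture = row$posture, trial_type = row$trial_type,
      target_level = row$target_level, trace = trace, stim_times = stim)
  }
  gt_path <- file.path(dir, "ground_truth.csv")
  gt <- if (file.exists(gt_path))
    utils::read.csv(gt_path, stringsAsFactors = FALSE) else NULL
  structure(list(trials = trials, manifest = manifest, ground_truth = gt),
            class = "study_dataset")
}

#' Write analysis result tables
#'
#' @param analysis Output of [analyze_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly; writes `va_results.csv` and
#'   `fit_diagnostics.csv`.
#' @export
write_results <- function(analysis, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(analysis$results, file.path(dir, "va_results.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(analysis$fits, file.path(dir, "fit_diagnostics.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
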