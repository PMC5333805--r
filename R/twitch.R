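#' One experimental trial
#'
#' Bundles a calibrated moment trace with the trial's identity and stimulus
#' event times. Matching trials carry exactly two stimulus times (superimposed
#' then resting); MVC trials carry none. Each stimulus must have at least
#' 250 ms of trace before it and 150 ms after it.
#'
#' @param trial_id,arm_id,subject_id,transfer_group,posture Identity fields.
#' @param trial_type `"mvc"` or `"matched"`.
#' @param target_level Target effort level for matching trials (fraction);
#'   `NA` for MVC trials.
#' @param trace A [moment_trace()] in newton-meters.
#' @param stim_times Stimulus times in seconds (length 0 for MVC, 2 for
#'   matched; second after first).
#' @param achieved_level Optional realized effort level (diagnostics).
#' @return A `trial_record` object.
#' @export
trial_record <- function(trial_id, arm_id, transfer_group, posture, trial_type,
                         target_level, trace, stim_times,
                         subject_id = arm_id, achieved_level = NA_real_) {
  trial_type <- match.arg(trial_type, c("mvc", "matched"))
  if (!inherits(trace, "moment_trace") || trace$units != "newton_meters")
    stop_twitchva("validation", "trial_record: 'trace' must be a moment_trace in newton-meters")
  if (trial_type == "matched") {
    if (length(stim_times) != 2L || stim_times[2] <= stim_times[1])
      stop_twitchva("validation",
                    "trial_record: matched trials need two increasing stimulus times")
    t0 <- trace$start_time
    t_end <- t0 + trace_duration(trace)
    if (any(stim_times - 0.25 < t0 - 1e-9) || any(stim_times + 0.15 > t_end + 1e-9))
      stop_twitchva("validation", paste(
        "trial_record: each stimulus needs >= 250 ms of trace before it",
        "and >= 150 ms after it"))
  } else if (length(stim_times) != 0L) {
    stop_twitchva("validation", "trial_record: MVC trials carry no stimuli")
  }
  structure(list(
    trial_id = as.character(trial_id), arm_id = as.character(arm_id),
    subject_id = as.character(subject_id),
    transfer_group = transfer_group, posture = posture,
    trial_type = trial_type, target_level = target_level,
    trace = trace, stim_times = as.numeric(stim_times),
    achieved_level = achieved_level
  ), class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record> %s [%s/%s, %s] %s%s, %d stimuli\n",
              x$trial_id, x$arm_id, x$posture, x$transfer_group, x$trial_type,
              if (is.na(x$target_level)) "" else sprintf(" @ %g", x$target_level),
              length(x$stim_times)))
  invisible(x)
}

#' Pre-stimulus voluntary moment
#'
#' Mean moment over the 250 ms immediately before the stimulus,
#' `[stim_time - 0.25, stim_time)`; the stimulus sample itself is excluded.
#'
#' @param trace A [moment_trace()].
#' @param stim_time Stimulus time in seconds.
#' @param window Averaging window in seconds (default 0.25).
#' @return Mean pre-stimulus moment (N*m).
#' @export
pre_stimulus_moment <- function(trace, stim_time, window = 0.25) {
  if (stim_time - window < trace$start_time - 1e-9)
    stop_twitchva("bounds", sprintf(
      "pre_stimulus_moment: needs %g ms of trace before the stimulus at %g s",
      window * 1000, stim_time))
  window_mean(trace, stim_time - window, window)
}

#' Twitch amplitude evoked by a stimulus
#'
#' The twitch moment is the difference between the maximum moment within
#' 150 ms after the stimulus (closed window `[stim, stim + 0.15]`) and the
#' pre-stimulus moment. Values can be zero or negative when no evoked response
#' exceeds the voluntary baseline; they are reported as-is.
#'
#' @param trace A [moment_trace()].
#' @param stim_time Stimulus time in seconds.
#' @param window Post-stimulus search window in seconds (default 0.15).
#' @param pre_window Pre-stimulus averaging window (default 0.25).
#' @return Twitch amplitude (N*m).
#' @export
twitch_amplitude <- function(trace, stim_time, window = 0.15, pre_window = 0.25) {
  t_end <- trace$start_time + trace_duration(trace)
  if (stim_time + window > t_end + 1e-9)
    stop_twitchva("bounds", sprintf(
      "twitch_amplitude: needs %g ms of trace after the stimulus at %g s",
      window * 1000, stim_time))
  pre <- pre_stimulus_moment(trace, stim_time, window = pre_window)
  idx <- window_indices(trace, stim_time, window, closed_right = TRUE)
  max(trace$samples[idx]) - pre
}

#' Reduce a stimulated trial to its two twitch measurements
#'
#' Returns one measurement per stimulus: the superimposed stimulus at the
#' trial's target effort and the resting stimulus at 0% effort. A resting
#' baseline that is large relative to the resting twitch triggers a QC
#' warning (class `twitchva_warning_qc`), not an error.
#'
#' @param trial A matched [trial_record()].
#' @param config A [run_config()] supplying window lengths.
#' @return Data frame with columns `trial_id`, `arm_id`, `subject_id`,
#'   `transfer_group`, `posture`, `effort_context` (target level, 0 for the
#'   resting stimulus), `pre_stimulus_moment_nm`, `twitch_amplitude_nm`.
#' @export
extract_trial <- function(trial, config = run_config()) {
  if (!inherits(trial, "trial_record"))
    stop_twitchva("validation", "extract_trial: 'trial' must be a trial_record")
  if (trial$trial_type != "matched")
    stop_twitchva("not_applicable",
                  "extract_trial: MVC trials carry no stimuli to extract")
  pre <- vapply(trial$stim_times, function(s)
    pre_stimulus_moment(trial$trace, s, window = config$pre_stimulus_window_s),
    numeric(1))
  amp <- vapply(trial$stim_times, function(s)
    twitch_amplitude(trial$trace, s, window = config$twitch_window_s,
                     pre_window = config$pre_stimulus_window_s),
    numeric(1))
  if (is.finite(amp[2]) && abs(pre[2]) > 0.5 * abs(amp[2]))
    warning(structure(
      class = c("twitchva_warning_qc", "warning", "condition"),
      list(message = sprintf(
        "trial %s: resting baseline %.3g N*m is large relative to the resting twitch %.3g N*m",
        trial$trial_id, pre[2], amp[2]), call = NULL)))
  data.frame(
    trial_id = trial$trial_id, arm_id = trial$arm_id,
    subject_id = trial$subject_id, transfer_group = trial$transfer_group,
    posture = trial$posture,
    effort_context = c(trial$target_level, 0),
    pre_stimulus_moment_nm = pre, twitch_amplitude_nm = amp,
    stringsAsFactors = FALSE)
}

#' Extract twitch measurements from a set of trials
#'
#' Applies [extract_trial()] to every matched trial; MVC trials are skipped.
#'
#' @param trials List of [trial_record()] objects.
#' @param config A [run_config()].
#' @return Tidy data frame of measurements, two rows per matched trial.
#' @export
extract_measurements <- function(trials, config = run_config()) {
  matched <- Filter(function(x) x$trial_type == "matched", trials)
  if (length(matched) == 0L)
    return(extract_trial_empty())
  do.call(rbind, lapply(matched, extract_trial, config = config))
}

extract_trial_empty <- function() {
  data.frame(trial_id = character(0), arm_id = character(0),
             subject_id = character(0), transfer_group = character(0),
             posture = character(0), effort_context = numeric(0),
             pre_stimulus_moment_nm = numeric(0),
             twitch_amplitude_nm = numeric(0), stringsAsFactors = FALSE)
}

#' Maximum voluntary moment for one arm x posture
#'
#' The greatest 0.5-s sustained mean over all qualifying trials: the dedicated
#' MVC trials (whole trace) and, by default, the 100%-target matching trials
#' (pre-stimulus portion only, so the evoked twitch cannot inflate the
#' voluntary maximum). A short guard interval before the stimulus is also
#' excluded because zero-phase filtering smears the evoked twitch a few tens
#' of milliseconds backward in time.
#'
#' @param trials List of [trial_record()] objects for one arm x posture.
#' @param window Sustained-mean window in seconds (default 0.5).
#' @param include_matched_100 Also scan 100%-target matching trials
#'   (default TRUE); set FALSE to restrict to dedicated MVC trials.
#' @param pre_stim_guard_s Guard interval before the stimulus excluded from
#'   the scan of matching trials (s, default 0.1).
#' @return Maximum voluntary moment (N*m).
#' @export
max_voluntary_moment <- function(trials, window = 0.5, include_matched_100 = TRUE,
                                 pre_stim_guard_s = 0.1) {
  candidates <- list()
  for (tr in trials) {
    if (tr$trial_type == "mvc") {
      candidates[[length(candidates) + 1L]] <- tr$trace
    } else if (include_matched_100 && !is.na(tr$target_level) &&
               abs(tr$target_level - 1) < 1e-12) {
      candidates[[length(candidates) + 1L]] <-
        truncate_trace(tr$trace, tr$stim_times[1] - pre_stim_guard_s)
    }
  }
  if (length(candidates) == 0L)
    stop_twitchva("missing_data",
                  "max_voluntary_moment: no MVC or 100%-target trials available")
  max(vapply(candidates, function(trc) max_sustained_mean(trc, window)$value,
             numeric(1)))
}
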