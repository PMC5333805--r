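#' Analysis configuration
#'
#' Collects every constant of the measurement pipeline in one object. The
#' defaults are the protocol's values: a 4th-order 80 Hz low-pass Butterworth
#' filter, a 250 ms pre-stimulus averaging window, a 150 ms post-stimulus
#' twitch window, a 0.5 s sustained-mean window for maxima, six resting
#' twitches (closest to the median) entering each regression, and exclusion
#' of fits with R-squared below 0.80.
#'
#' @param filter_cutoff_hz Low-pass cutoff (Hz).
#' @param filter_order Butterworth design order.
#' @param filter_traces Apply the filter inside the pipeline (default TRUE).
#' @param pre_stimulus_window_s Pre-stimulus averaging window (s).
#' @param twitch_window_s Post-stimulus twitch search window (s).
#' @param sustained_window_s Sustained-mean window for voluntary maxima (s).
#' @param rest_select_n Number of resting twitches kept per regression.
#' @param r2_threshold Minimum R-squared for a fit to be included, in [0, 1].
#' @param mvc_pool_matched_100 Pool 100%-target matching trials (pre-stimulus
#'   portion) with MVC trials when computing the voluntary maximum.
#' @param heteroscedastic Allow transfer-group-specific residual variances in
#'   the group model.
#' @param random_structure `"arm"` (random intercept per arm, the default:
#'   arms are the independent unit, matching the reported test degrees of
#'   freedom) or `"subject_arm"` (random intercepts for subject with arm
#'   nested, as a sensitivity analysis for subjects contributing both arms).
#' @return A `run_config` object (a named list).
#' @export
run_config <- function(filter_cutoff_hz = 80, filter_order = 4,
                       filter_traces = TRUE,
                       pre_stimulus_window_s = 0.25, twitch_window_s = 0.15,
                       sustained_window_s = 0.5, rest_select_n = 6,
                       r2_threshold = 0.80, mvc_pool_matched_100 = TRUE,
                       heteroscedastic = TRUE,
                       random_structure = c("arm", "subject_arm")) {
  random_structure <- match.arg(random_structure)
  durs <- c(pre_stimulus_window_s, twitch_window_s, sustained_window_s)
  if (any(!is.finite(durs)) || any(durs <= 0))
    stop_twitchva("invalid_parameter", "run_config: all window durations must be > 0")
  if (filter_cutoff_hz <= 0 || filter_order < 1)
    stop_twitchva("invalid_parameter", "run_config: filter settings must be positive")
  if (r2_threshold < 0 || r2_threshold > 1)
    stop_twitchva("invalid_parameter", "run_config: r2_threshold must be in [0, 1]")
  if (rest_select_n < 1)
    stop_twitchva("invalid_parameter", "run_config: rest_select_n must be >= 1")
  structure(list(
    filter_cutoff_hz = filter_cutoff_hz, filter_order = filter_order,
    filter_traces = isTRUE(filter_traces),
    pre_stimulus_window_s = pre_stimulus_window_s,
    twitch_window_s = twitch_window_s,
    sustained_window_s = sustained_window_s,
    rest_select_n = as.integer(rest_select_n), r2_threshold = r2_threshold,
    mvc_pool_matched_100 = isTRUE(mvc_pool_matched_100),
    heteroscedastic = isTRUE(heteroscedastic),
    random_structure = random_structure
  ), class = "run_config")
}

#' Read or write a run configuration as JSON
#'
#' @param path File path.
#' @return `read_run_config()` returns a [run_config()]; unknown fields are
#'   rejected.
#' @export
read_run_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop_twitchva("validation", sprintf(
      "read_run_config: unknown fields: %s (allowed: %s)",
      paste(bad, collapse = ", "), paste(known, collapse = ", ")))
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param config A [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
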