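#' Select the resting twitches closest to the median
#'
#' Each stimulated trial also yields a resting twitch, so rest measurements
#' outnumber each superimposed effort level threefold. For equal
#' representation only the `n_select` resting twitch amplitudes closest to
#' their median enter the regression. Ties are broken in favour of earlier
#' trial order; with `n <= n_select` all values are kept.
#'
#' @param rest_amplitudes Numeric vector of resting twitch amplitudes in
#'   trial order.
#' @param n_select Number to keep (default 6).
#' @return Integer indices of the selected values, in original trial order.
#' @examples
#' x <- c(1.0, 1.1, 1.2, 1.3, 1.4, 1.5, 9.0, 0.1)
#' x[select_rest_twitches(x)]  # outliers 9.0 and 0.1 dropped
#' @export
select_rest_twitches <- function(rest_amplitudes, n_select = 6) {
  n <- length(rest_amplitudes)
  if (n == 0L)
    stop_twitchva("missing_data", "select_rest_twitches: no resting twitches supplied")
  if (n <= n_select) return(seq_len(n))
  med <- stats::median(rest_amplitudes)
  ord <- order(abs(rest_amplitudes - med), seq_len(n))
  sort(ord[seq_len(n_select)])
}

#' Fit the twitch-vs-voluntary-moment extrapolation
#'
#' Ordinary least squares with twitch amplitude as the response and
#' pre-stimulus voluntary moment as the predictor, over the superimposed
#' measurements at all effort levels plus the selected resting measurements
#' (entered at their measured, near-zero pre-stimulus moments). The predicted
#' full-activation moment is the fitted line's x-intercept,
#' `-intercept / slope`; under progressive twitch occlusion the slope is
#' negative and the x-intercept is the voluntary moment at which the evoked
#' twitch would vanish. Fits with non-negative slope are flagged degenerate
#' (predicted moment undefined) and fits with R-squared below the threshold
#' are excluded; both are reported, never dropped silently.
#'
#' @param measurements Measurement data frame as produced by
#'   [extract_measurements()] for one arm x posture.
#' @param rest_indices Optional integer indices (into the rest measurements in
#'   trial order) to use; default: [select_rest_twitches()] with
#'   `config$rest_select_n`.
#' @param config A [run_config()].
#' @return An `extrapolation_fit`: list with `arm_id`, `posture`, `slope`,
#'   `intercept`, `r_squared`, `predicted_moment`, `n_points`, `included`,
#'   `reason` (`"ok"`, `"low_r_squared"` or `"nonnegative_slope"`) and
#'   `points` (the regression data).
#' @export
fit_extrapolation <- function(measurements, rest_indices = NULL,
                              config = run_config()) {
  req <- c("effort_context", "pre_stimulus_moment_nm", "twitch_amplitude_nm")
  if (!all(req %in% names(measurements)))
    stop_twitchva("validation", sprintf(
      "fit_extrapolation: measurements need columns %s", paste(req, collapse = ", ")))
  sup <- measurements[measurements$effort_context > 0, , drop = FALSE]
  rest <- measurements[measurements$effort_context == 0, , drop = FALSE]
  if (is.null(rest_indices) && nrow(rest) > 0L)
    rest_indices <- select_rest_twitches(rest$twitch_amplitude_nm,
                                         n_select = config$rest_select_n)
  rest <- rest[rest_indices, , drop = FALSE]
  pts <- rbind(sup, rest)
  x <- pts$pre_stimulus_moment_nm
  y <- pts$twitch_amplitude_nm
  if (length(unique(round(x, 12))) < 3L)
    stop_twitchva("missing_data", sprintf(
      "fit_extrapolation: need >= 3 distinct voluntary-moment values, have %d",
      length(unique(round(x, 12)))))
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  r2 <- withCallingHandlers(
    summary(fit)$r.squared,
    warning = function(w) {
      # noiseless fixtures fit exactly; summary.lm flags that, harmlessly
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (!is.finite(r2)) r2 <- 0   # degenerate response with zero variance
  if (slope >= 0) {
    predicted <- NA_real_
    included <- FALSE
    reason <- "nonnegative_slope"
  } else {
    predicted <- -intercept / slope
    included <- r2 >= config$r2_threshold
    reason <- if (included) "ok" else "low_r_squared"
  }
  structure(list(
    arm_id = if ("arm_id" %in% names(pts) && nrow(pts)) pts$arm_id[1] else NA_character_,
    posture = if ("posture" %in% names(pts) && nrow(pts)) pts$posture[1] else NA_character_,
    slope = slope, intercept = intercept, r_squared = r2,
    predicted_moment = predicted, n_points = length(x),
    included = included, reason = reason, points = pts
  ), class = "extrapolation_fit")
}

#' @export
print.extrapolation_fit <- function(x, ...) {
  cat(sprintf(
    "<extrapolation_fit> %s/%s: twitch = %.4g %+.4g * moment (R2 = %.3f, n = %d)\n  predicted full-activation moment: %s N*m [%s]\n",
    x$arm_id, x$posture, x$intercept, x$slope, x$r_squared, x$n_points,
    if (is.na(x$predicted_moment)) "NA" else sprintf("%.3f", x$predicted_moment),
    if (x$included) "included" else paste("excluded:", x$reason)))
  invisible(x)
}

#' Compute voluntary activation from a fit and a voluntary maximum
#'
#' Voluntary activation is the maximum voluntary moment divided by the
#' predicted full-activation moment, reported as a dimensionless fraction.
#' Values above 1 (the regression under-predicting the voluntary maximum)
#' are preserved and flagged, not clamped. Excluded fits propagate a missing
#' VA with the exclusion reason.
#'
#' @param max_voluntary_moment Maximum voluntary moment (N*m).
#' @param fit An `extrapolation_fit` from [fit_extrapolation()].
#' @param arm_id,transfer_group,posture,subject_id Identity fields carried
#'   into the result (defaults taken from the fit where available).
#' @return A `va_result`: list with identity fields, `max_voluntary_moment`,
#'   `predicted_moment`, `voluntary_activation`, `r_squared`, `qc_included`,
#'   `over_unity`, `reason`.
#' @examples
#' f <- fit_extrapolation(data.frame(
#'   effort_context = c(0.33, 0.66, 1, 0),
#'   pre_stimulus_moment_nm = c(2, 4, 7, 0),
#'   twitch_amplitude_nm = c(1.6, 1.2, 0.6, 2.0)))
#' compute_va(7, f)$voluntary_activation
#' @export
compute_va <- function(max_voluntary_moment, fit,
                       arm_id = fit$arm_id, transfer_group = NA_character_,
                       posture = fit$posture, subject_id = NA_character_) {
  stopifnot(inherits(fit, "extrapolation_fit"))
  if (!fit$included) {
    va <- NA_real_
    over <- NA
  } else {
    va <- max_voluntary_moment / fit$predicted_moment
    over <- va > 1
  }
  structure(list(
    arm_id = arm_id, subject_id = subject_id, transfer_group = transfer_group,
    posture = posture,
    max_voluntary_moment = max_voluntary_moment,
    predicted_moment = fit$predicted_moment,
    voluntary_activation = va, r_squared = fit$r_squared,
    qc_included = fit$included, over_unity = over, reason = fit$reason
  ), class = "va_result")
}

#' @export
print.va_result <- function(x, ...) {
  cat(sprintf(
    "<va_result> %s/%s [%s]: MVC %.3f N*m / predicted %s N*m -> VA %s%s\n",
    x$arm_id, x$posture, x$transfer_group, x$max_voluntary_moment,
    if (is.na(x$predicted_moment)) "NA" else sprintf("%.3f", x$predicted_moment),
    if (is.na(x$voluntary_activation)) paste0("NA (", x$reason, ")")
    else sprintf("%.3f", x$voluntary_activation),
    if (isTRUE(x$over_unity)) " [over-unity]" else ""))
  invisible(x)
}

#' Full pipeline for one arm x posture
#'
#' Filters every trace, extracts the twitch measurements from the matching
#' trials, selects the resting twitches, fits the extrapolation, computes the
#' maximum voluntary moment and the voluntary-activation ratio. Deterministic
#' given its inputs.
#'
#' @param trials List of [trial_record()] objects sharing one arm and posture.
#' @param config A [run_config()].
#' @return A `va_result` with the `extrapolation_fit` attached as
#'   attribute `"fit"`.
#' @export
run_arm_posture <- function(trials, config = run_config()) {
  if (length(trials) == 0L)
    stop_twitchva("missing_data", "run_arm_posture: no trials supplied")
  arms <- unique(vapply(trials, `[[`, character(1), "arm_id"))
  postures <- unique(vapply(trials, `[[`, character(1), "posture"))
  if (length(arms) != 1L || length(postures) != 1L)
    stop_twitchva("validation", sprintf(
      "run_arm_posture: trials span several arms/postures (%s x %s)",
      paste(arms, collapse = ","), paste(postures, collapse = ",")))
  if (config$filter_traces)
    trials <- lapply(trials, function(tr) {
      tr$trace <- lowpass_filter(tr$trace, cutoff = config$filter_cutoff_hz,
                                 order = config$filter_order)
      tr
    })
  meas <- extract_measurements(trials, config = config)
  if (nrow(meas) == 0L)
    stop_twitchva("missing_data",
                  "run_arm_posture: no matched trials to extract twitches from (stage: extract)")
  fit <- fit_extrapolation(meas, config = config)
  mvm <- max_voluntary_moment(trials, window = config$sustained_window_s,
                              include_matched_100 = config$mvc_pool_matched_100)
  res <- compute_va(mvm, fit,
                    arm_id = trials[[1]]$arm_id,
                    subject_id = trials[[1]]$subject_id,
                    transfer_group = trials[[1]]$transfer_group,
                    posture = trials[[1]]$posture)
  attr(res, "fit") <- fit
  res
}

#' Analyze a whole study
#'
#' Splits trials by arm x posture, runs [run_arm_posture()] on each block and
#' assembles tidy result tables. Every block yields a row: excluded fits
#' carry a missing VA and their exclusion reason, never disappear.
#'
#' @param study A `study_dataset` (from [simulate_study()] or [read_study()])
#'   or a plain list of [trial_record()] objects.
#' @param config A [run_config()].
#' @return List with `results` (one row per arm x posture: identity, maximum
#'   voluntary moment, predicted moment, voluntary activation, R-squared,
#'   `qc_included`, `reason`) and `fits` (per-fit diagnostics: slope,
#'   intercept, R-squared, point count).
#' @export
analyze_study <- function(study, config = run_config()) {
  trials <- if (inherits(study, "study_dataset")) study$trials else study
  if (length(trials) == 0L)
    stop_twitchva("missing_data", "analyze_study: no trials in study")
  key <- vapply(trials, function(x) paste(x$arm_id, x$posture, sep = "|"),
                character(1))
  blocks <- split(trials, factor(key, levels = unique(key)))
  rows <- list(); fit_rows <- list()
  for (b in blocks) {
    res <- run_arm_posture(b, config = config)
    fit <- attr(res, "fit")
    rows[[length(rows) + 1L]] <- data.frame(
      arm_id = res$arm_id, subject_id = res$subject_id,
      transfer_group = res$transfer_group, posture = res$posture,
      max_voluntary_moment_nm = res$max_voluntary_moment,
      predicted_moment_nm = res$predicted_moment,
      voluntary_activation = res$voluntary_activation,
      r_squared = res$r_squared, qc_included = res$qc_included,
      over_unity = res$over_unity, reason = res$reason,
      stringsAsFactors = FALSE)
    fit_rows[[length(fit_rows) + 1L]] <- data.frame(
      arm_id = res$arm_id, posture = res$posture,
      slope = fit$slope, intercept = fit$intercept,
      r_squared = fit$r_squared, n_points = fit$n_points,
      included = fit$included, reason = fit$reason, stringsAsFactors = FALSE)
  }
  list(results = do.call(rbind, rows), fits = do.call(rbind, fit_rows))
}

#' Compare recovered estimates with simulator ground truth
#'
#' @param results Results data frame from [analyze_study()].
#' @param ground_truth Ground-truth table from [simulate_study()].
#' @return The results joined to truth, with `va_error`
#'   (estimate minus truth) and `moment_error_nm` columns.
#' @export
recovery_report <- function(results, ground_truth) {
  merged <- merge(results,
                  ground_truth[, c("arm_id", "posture", "true_va",
                                   "full_activation_moment")],
                  by = c("arm_id", "posture"), sort = FALSE)
  merged$va_error <- merged$voluntary_activation - merged$true_va
  merged$moment_error_nm <- merged$predicted_moment_nm - merged$full_activation_moment
  merged
}
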