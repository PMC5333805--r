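#' Uniformly sampled joint-moment time series
#'
#' A `moment_trace` holds one channel of transducer output sampled at a fixed
#' rate: either raw volts (before calibration) or calibrated newton-meters.
#'
#' @param samples Numeric vector of samples; no missing values allowed.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param units `"newton_meters"` or `"volts"`.
#' @param start_time Time of the first sample, in seconds.
#' @return An object of class `moment_trace` with fields `samples`,
#'   `sampling_rate`, `units`, `start_time`.
#' @examples
#' tr <- moment_trace(sin(seq(0, 1, by = 1e-3)), sampling_rate = 1000)
#' trace_duration(tr)
#' @export
moment_trace <- function(samples, sampling_rate,
                         units = c("newton_meters", "volts"),
                         start_time = 0) {
  units <- match.arg(units)
  samples <- as.numeric(samples)
  if (length(samples) == 0L)
    stop_twitchva("validation", "moment_trace: 'samples' must be non-empty")
  if (anyNA(samples))
    stop_twitchva("validation", "moment_trace: 'samples' contains missing values")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop_twitchva("validation", "moment_trace: 'sampling_rate' must be a single positive number")
  structure(
    list(samples = samples, sampling_rate = as.numeric(sampling_rate),
         units = units, start_time = as.numeric(start_time)),
    class = "moment_trace"
  )
}

#' @export
print.moment_trace <- function(x, ...) {
  cat(sprintf("<moment_trace> %d samples @ %g Hz [%s], t = [%.4g, %.4g) s\n",
              length(x$samples), x$sampling_rate, x$units,
              x$start_time, x$start_time + length(x$samples) / x$sampling_rate))
  invisible(x)
}

#' Sample timestamps of a trace
#'
#' Sample `i` (1-based) is at `start_time + (i - 1) / sampling_rate`.
#'
#' @param trace A [moment_trace()].
#' @return Numeric vector of times in seconds, one per sample.
#' @export
trace_times <- function(trace) {
  trace$start_time + (seq_along(trace$samples) - 1) / trace$sampling_rate
}

#' @rdname trace_times
#' @return `trace_duration()`: trace length in seconds (`n / sampling_rate`).
#' @export
trace_duration <- function(trace) {
  length(trace$samples) / trace$sampling_rate
}

## Index range of the window [start, start + duration) with a small absolute
## tolerance so that windows aligned on sample times are not lost to rounding.
window_indices <- function(trace, start, duration, closed_right = FALSE) {
  tol <- 1e-9
  t <- trace_times(trace)
  end <- start + duration
  if (closed_right) {
    which(t >= start - tol & t <= end + tol)
  } else {
    which(t >= start - tol & t < end - tol)
  }
}

#' Linear transducer calibration
#'
#' Moments are obtained from transducer voltage by an affine map
#' `moment = gain * volts + offset`.
#'
#' @param gain Newton-meters per volt; must be non-zero.
#' @param offset Offset in newton-meters (default 0).
#' @return A `calibration_spec` object.
#' @export
calibration_spec <- function(gain, offset = 0) {
  if (!is.numeric(gain) || length(gain) != 1L || !is.finite(gain) || gain == 0)
    stop_twitchva("invalid_parameter", "calibration_spec: 'gain' must be a single non-zero number")
  structure(list(gain = as.numeric(gain), offset = as.numeric(offset)),
            class = "calibration_spec")
}

#' Apply a linear calibration to a raw voltage trace
#'
#' @param trace A [moment_trace()] in volts.
#' @param cal A [calibration_spec()].
#' @return The trace in newton-meters; length and sampling rate unchanged.
#' @examples
#' tr <- moment_trace(c(0, 0.5, 1), 1000, units = "volts")
#' apply_calibration(tr, calibration_spec(gain = 2, offset = 1))$samples
#' @export
apply_calibration <- function(trace, cal) {
  if (!inherits(trace, "moment_trace"))
    stop_twitchva("validation", "apply_calibration: 'trace' must be a moment_trace")
  if (trace$units != "volts")
    stop_twitchva("units", "apply_calibration: trace is not in volts")
  if (!inherits(cal, "calibration_spec"))
    stop_twitchva("validation", "apply_calibration: 'cal' must be a calibration_spec")
  moment_trace(cal$gain * trace$samples + cal$offset,
               sampling_rate = trace$sampling_rate,
               units = "newton_meters", start_time = trace$start_time)
}

## One pass of an IIR filter with steady-state initial conditions matched to
## the first sample, so a constant input passes through exactly.
filter_steady <- function(x, b, a) {
  dc <- sum(b) / sum(a)
  as.numeric(signal::filter(b, a, x,
                            init.x = rep(x[1L], length(b) - 1L),
                            init.y = rep(x[1L] * dc, length(a) - 1L)))
}

#' Zero-phase low-pass Butterworth filtering
#'
#' Applies a low-pass digital Butterworth filter forward and backward
#' (zero net phase shift), so event latencies such as twitch onsets are not
#' biased by filter delay. The effective magnitude response is the squared
#' single-pass response; DC gain is 1. Edges are handled by odd-reflection
#' padding combined with steady-state initial conditions.
#'
#' @param trace A [moment_trace()].
#' @param cutoff Cutoff frequency in Hz (default 80).
#' @param order Filter design order (default 4); the forward-backward pass
#'   doubles the effective attenuation.
#' @return Filtered trace, same length, units and sampling rate.
#' @examples
#' tr <- moment_trace(rep(3, 1000), 1000)
#' range(lowpass_filter(tr)$samples)  # constant in, constant out
#' @export
lowpass_filter <- function(trace, cutoff = 80, order = 4) {
  if (!inherits(trace, "moment_trace"))
    stop_twitchva("validation", "lowpass_filter: 'trace' must be a moment_trace")
  if (cutoff <= 0 || order < 1)
    stop_twitchva("config", "lowpass_filter: cutoff and order must be positive")
  if (trace$sampling_rate <= 2 * cutoff)
    stop_twitchva("config", sprintf(
      "lowpass_filter: cutoff %g Hz is not below the Nyquist frequency (%g Hz)",
      cutoff, trace$sampling_rate / 2))
  bf <- signal::butter(order, 2 * cutoff / trace$sampling_rate, type = "low")
  b <- bf$b; a <- bf$a
  x <- trace$samples
  n <- length(x)
  pad <- min(3L * max(length(a), length(b)), n - 1L)
  if (pad > 0L) {
    front <- 2 * x[1L] - x[seq(pad + 1L, 2L)]
    back  <- 2 * x[n] - x[seq(n - 1L, n - pad)]
    xp <- c(front, x, back)
  } else {
    xp <- x
  }
  y <- filter_steady(xp, b, a)
  y <- rev(filter_steady(rev(y), b, a))
  if (pad > 0L) y <- y[seq(pad + 1L, pad + n)]
  moment_trace(y, trace$sampling_rate, units = trace$units,
               start_time = trace$start_time)
}

#' Mean moment over a time window
#'
#' Arithmetic mean of the samples whose timestamps fall in the half-open
#' interval `[start, start + duration)`.
#'
#' @param trace A [moment_trace()].
#' @param start Window start in seconds.
#' @param duration Window length in seconds (> 0).
#' @return Mean moment over the window.
#' @export
window_mean <- function(trace, start, duration) {
  if (!inherits(trace, "moment_trace"))
    stop_twitchva("validation", "window_mean: 'trace' must be a moment_trace")
  if (!is.finite(duration) || duration <= 0)
    stop_twitchva("bounds", "window_mean: 'duration' must be positive")
  t0 <- trace$start_time
  t_end <- t0 + trace_duration(trace)
  if (start < t0 - 1e-9 || start + duration > t_end + 1e-9)
    stop_twitchva("bounds", sprintf(
      "window_mean: window [%g, %g) outside trace extent [%g, %g)",
      start, start + duration, t0, t_end))
  idx <- window_indices(trace, start, duration)
  if (length(idx) == 0L)
    stop_twitchva("bounds", "window_mean: window contains no samples")
  mean(trace$samples[idx])
}

#' Greatest average moment sustained over a sliding window
#'
#' Scans every window of the given length (one-sample step) and returns the
#' largest windowed mean, the convention used to score a maximum voluntary
#' contraction as the best 0.5 s of sustained moment. Ties are broken in
#' favour of the earliest window. Each window mean is computed by direct
#' summation so the result matches an exhaustive scan exactly.
#'
#' @param trace A [moment_trace()].
#' @param window Window length in seconds (default 0.5).
#' @return A list with `value` (N*m) and `window_start` (s).
#' @examples
#' tr <- moment_trace(c(rep(1, 400), rep(2, 600), rep(1, 400)), 1000)
#' max_sustained_mean(tr, window = 0.5)
#' @export
max_sustained_mean <- function(trace, window = 0.5) {
  if (!inherits(trace, "moment_trace"))
    stop_twitchva("validation", "max_sustained_mean: 'trace' must be a moment_trace")
  w <- as.integer(round(window * trace$sampling_rate))
  n <- length(trace$samples)
  if (w < 1L || w > n)
    stop_twitchva("bounds", sprintf(
      "max_sustained_mean: window of %g s (%d samples) does not fit a %d-sample trace",
      window, w, n))
  x <- trace$samples
  n_win <- n - w + 1L
  means <- vapply(seq_len(n_win),
                  function(i) sum(x[i:(i + w - 1L)]) / w, numeric(1))
  i_best <- which.max(means)
  list(value = means[i_best],
       window_start = trace$start_time + (i_best - 1L) / trace$sampling_rate)
}

## Truncate a trace to [start_time, end) -- used to score the pre-stimulus
## portion of stimulated trials.
truncate_trace <- function(trace, end) {
  idx <- window_indices(trace, trace$start_time, end - trace$start_time)
  if (length(idx) == 0L)
    stop_twitchva("bounds", "truncate_trace: empty truncation")
  moment_trace(trace$samples[idx], trace$sampling_rate, units = trace$units,
               start_time = trace$start_time)
}
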