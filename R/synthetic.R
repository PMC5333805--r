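#' Ground-truth description of one arm in one posture
#'
#' Parameters of the simulated neuromuscular system. The implied maximum
#' voluntary moment is `true_va * full_activation_moment`: the fraction of the
#' motor pool recruited voluntarily times the moment full recruitment would
#' produce. The superimposed twitch follows the linear occlusion model the
#' interpolated twitch technique assumes: at voluntary drive `v` (fraction of
#' full activation) the evoked twitch amplitude is
#' `rest_twitch_amplitude * (1 - v)`, optionally bent by a curvature term for
#' robustness studies.
#'
#' @param arm_id Identifier for the arm.
#' @param transfer_group `"biceps"` or `"deltoid"` (donor muscle of the
#'   tendon transfer).
#' @param posture `"horizontal"`, `"overhead_reach"` or `"pressure_relief"`.
#'   Posture is a label only; posture-specific mechanics enter through the
#'   ground-truth values supplied here.
#' @param full_activation_moment Moment (N*m, > 0) with the entire motor pool
#'   recruited.
#' @param true_va True voluntary activation, in (0, 1.1].
#' @param rest_twitch_amplitude Twitch amplitude evoked at rest (N*m, > 0).
#' @param twitch_time_constant Time-to-peak of the twitch (s, default 0.07,
#'   so the peak falls well inside a 150 ms detection window).
#' @param noise_sd SD of white Gaussian measurement noise added to every
#'   sample (N*m, default 2% of `full_activation_moment`).
#' @param tremor_amplitude,tremor_frequency Optional sinusoidal tremor
#'   (N*m peak, Hz), scaled by the voluntary-effort envelope; off by default.
#' @param occlusion_curvature Departure from linear occlusion (default 0 =
#'   exactly linear); twitch amplitude becomes
#'   `T0 * (1 - v) * (1 - occlusion_curvature * v)`.
#' @param plateau_drift Linear drift of the voluntary plateau (N*m per s,
#'   default 0).
#' @param subject_id Optional subject identifier (several arms can share one
#'   subject); defaults to the arm id.
#' @return An `arm_ground_truth` object.
#' @export
arm_ground_truth <- function(arm_id, transfer_group, posture,
                             full_activation_moment, true_va,
                             rest_twitch_amplitude,
                             twitch_time_constant = 0.07,
                             noise_sd = 0.02 * full_activation_moment,
                             tremor_amplitude = 0, tremor_frequency = 8,
                             occlusion_curvature = 0, plateau_drift = 0,
                             subject_id = arm_id) {
  transfer_group <- match.arg(transfer_group, c("biceps", "deltoid"))
  posture <- match.arg(posture, c("horizontal", "overhead_reach", "pressure_relief"))
  if (full_activation_moment <= 0)
    stop_twitchva("invalid_parameter", "arm_ground_truth: full_activation_moment must be > 0")
  if (true_va <= 0 || true_va > 1.1)
    stop_twitchva("invalid_parameter", "arm_ground_truth: true_va must be in (0, 1.1]")
  if (rest_twitch_amplitude <= 0)
    stop_twitchva("invalid_parameter", "arm_ground_truth: rest_twitch_amplitude must be > 0")
  if (twitch_time_constant <= 0)
    stop_twitchva("invalid_parameter", "arm_ground_truth: twitch_time_constant must be > 0")
  if (noise_sd < 0 || tremor_amplitude < 0)
    stop_twitchva("invalid_parameter", "arm_ground_truth: noise_sd and tremor_amplitude must be >= 0")
  structure(list(
    arm_id = as.character(arm_id), subject_id = as.character(subject_id),
    transfer_group = transfer_group, posture = posture,
    full_activation_moment = full_activation_moment, true_va = true_va,
    rest_twitch_amplitude = rest_twitch_amplitude,
    twitch_time_constant = twitch_time_constant, noise_sd = noise_sd,
    tremor_amplitude = tremor_amplitude, tremor_frequency = tremor_frequency,
    occlusion_curvature = occlusion_curvature, plateau_drift = plateau_drift
  ), class = "arm_ground_truth")
}

#' Experimental protocol parameters
#'
#' Defaults encode the study protocol the simulator emulates: three maximum
#' voluntary contraction (MVC) trials, then six moment-matching trials at each
#' of 33%, 66% and 100% of the recorded maximum. Each matching trial carries a
#' superimposed stimulus (delivered once the subject has held within +/- 5% of
#' the target for 250 ms) and a resting stimulus 7 s later.
#'
#' @param sampling_rate Hz (default 1000).
#' @param n_mvc_trials Number of dedicated MVC trials (default 3).
#' @param target_levels Target effort levels, strictly increasing fractions in
#'   (0, 1] (default 0.33, 0.66, 1.00).
#' @param trials_per_level Matching trials per level (default 6).
#' @param hold_tolerance Relative tolerance of the effort hold (default 0.05).
#' @param hold_duration Required hold before the first stimulus (s, default 0.25).
#' @param rest_stimulus_delay Delay from the superimposed to the resting
#'   stimulus (s, default 7); must exceed `hold_duration`.
#' @param trial_duration Length of a matching trial (s, default 10).
#' @param mvc_plateau_duration Length of the maximum-effort plateau in an MVC
#'   trial (s, default 5).
#' @return A `protocol_spec` object.
#' @export
protocol_spec <- function(sampling_rate = 1000, n_mvc_trials = 3,
                          target_levels = c(0.33, 0.66, 1.00),
                          trials_per_level = 6, hold_tolerance = 0.05,
                          hold_duration = 0.25, rest_stimulus_delay = 7,
                          trial_duration = 10, mvc_plateau_duration = 5) {
  if (any(diff(target_levels) <= 0) || any(target_levels <= 0) || any(target_levels > 1))
    stop_twitchva("invalid_parameter",
                  "protocol_spec: target_levels must be strictly increasing and in (0, 1]")
  if (rest_stimulus_delay <= hold_duration)
    stop_twitchva("invalid_parameter",
                  "protocol_spec: rest_stimulus_delay must exceed hold_duration")
  if (sampling_rate <= 0 || trial_duration <= 0 || hold_duration <= 0)
    stop_twitchva("invalid_parameter", "protocol_spec: durations and rates must be positive")
  structure(list(
    sampling_rate = sampling_rate, n_mvc_trials = as.integer(n_mvc_trials),
    target_levels = target_levels, trials_per_level = as.integer(trials_per_level),
    hold_tolerance = hold_tolerance, hold_duration = hold_duration,
    rest_stimulus_delay = rest_stimulus_delay, trial_duration = trial_duration,
    mvc_plateau_duration = mvc_plateau_duration
  ), class = "protocol_spec")
}

#' Canonical twitch impulse response
#'
#' A unimodal alpha-function twitch,
#' `amplitude * (t / tau) * exp(1 - t / tau)`, which is zero at onset and
#' peaks at exactly `amplitude` at `t = tau`. Times before the stimulus
#' (`t < 0`) return 0.
#'
#' @param t Time since the stimulus, in seconds (vectorised).
#' @param amplitude Peak twitch moment (N*m).
#' @param time_constant Time-to-peak `tau` (s, > 0).
#' @return Twitch moment at each `t`.
#' @examples
#' twitch_waveform(0.07, amplitude = 1.5, time_constant = 0.07)  # the peak
#' @export
twitch_waveform <- function(t, amplitude, time_constant) {
  if (!is.numeric(time_constant) || length(time_constant) != 1L || time_constant <= 0)
    stop_twitchva("invalid_parameter", "twitch_waveform: time_constant must be > 0")
  out <- numeric(length(t))
  pos <- t > 0
  tt <- t[pos] / time_constant
  out[pos] <- amplitude * tt * exp(1 - tt)
  out
}

## Trial layout (times in seconds from trace start). The subject ramps up to
## the target over 0.5 s, holds, receives the superimposed stimulus 1 s into
## the plateau (comfortably beyond the 250 ms hold criterion), relaxes, and
## receives the resting stimulus rest_stimulus_delay later on a quiet baseline.
trial_layout <- function(protocol, trial_type) {
  ramp_start <- 0.5; ramp_dur <- 0.5
  plateau_start <- ramp_start + ramp_dur
  if (trial_type == "mvc") {
    plateau_end <- plateau_start + protocol$mvc_plateau_duration
    list(ramp_start = ramp_start, ramp_dur = ramp_dur,
         plateau_start = plateau_start, plateau_end = plateau_end,
         relax_dur = 0.5, stim1 = NA_real_, stim2 = NA_real_,
         duration = plateau_end + 1.0)
  } else {
    stim1 <- plateau_start + 1.0
    plateau_end <- stim1 + 0.75   # effort held through the twitch window
    stim2 <- stim1 + protocol$rest_stimulus_delay
    list(ramp_start = ramp_start, ramp_dur = ramp_dur,
         plateau_start = plateau_start, plateau_end = plateau_end,
         relax_dur = 0.5, stim1 = stim1, stim2 = stim2,
         duration = protocol$trial_duration)
  }
}

## Smooth (C2) ramp: voluntary effort rises and falls without slope or
## curvature discontinuities, so low-pass filtering does not ring at the
## plateau corners.
smootherstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  6 * u^5 - 15 * u^4 + 10 * u^3
}

## Voluntary-effort envelope in [0, 1].
effort_envelope <- function(t, layout) {
  up <- smootherstep((t - layout$ramp_start) / layout$ramp_dur)
  down <- 1 - smootherstep((t - layout$plateau_end) / layout$relax_dur)
  up * down
}

#' Simulate one experimental trial
#'
#' Generates the moment trace of a single trial under the linear
#' twitch-occlusion model. For a matching trial the achieved effort is drawn
#' uniformly within the +/- `hold_tolerance` band around the target (capped at
#' the subject's own maximum), the voluntary plateau is
#' `v * full_activation_moment` with drive `v = achieved_level * true_va`, the
#' superimposed twitch has amplitude `rest_twitch_amplitude * (1 - v)`, and
#' the resting twitch (full `rest_twitch_amplitude`) arrives
#' `rest_stimulus_delay` later on a relaxed baseline. MVC trials hold a
#' plateau at `true_va * full_activation_moment` and carry no stimuli.
#' Identical seeds yield bit-identical traces.
#'
#' @param gt An [arm_ground_truth()].
#' @param protocol A [protocol_spec()].
#' @param target_level Target effort level (fraction of maximum); ignored for
#'   MVC trials.
#' @param trial_type `"mvc"` or `"matched"`.
#' @param seed Integer seed for the trial's noise, jitter and tremor phase.
#' @return A `trial_record` (see [trial_record()]).
#' @export
simulate_trial <- function(gt, protocol = protocol_spec(), target_level = NA,
                           trial_type = c("matched", "mvc"), seed = 1L) {
  trial_type <- match.arg(trial_type)
  stopifnot(inherits(gt, "arm_ground_truth"), inherits(protocol, "protocol_spec"))
  layout <- trial_layout(protocol, trial_type)
  if (trial_type == "matched") {
    if (!is.numeric(target_level) || is.na(target_level) ||
        !any(abs(protocol$target_levels - target_level) < 1e-12))
      stop_twitchva("invalid_parameter", sprintf(
        "simulate_trial: target_level must be one of the protocol's levels (%s)",
        paste(protocol$target_levels, collapse = ", ")))
    if (layout$stim2 + 0.2 > layout$duration)
      stop_twitchva("config", sprintf(
        "simulate_trial: trial_duration %g s too short for both stimuli (resting stimulus at %g s)",
        layout$duration, layout$stim2))
  }

  fs <- protocol$sampling_rate
  n <- as.integer(round(layout$duration * fs))
  t <- (seq_len(n) - 1) / fs

  with_seed(seed, {
    if (trial_type == "mvc") {
      achieved_level <- NA_real_
      v <- gt$true_va
      stim_times <- numeric(0)
    } else {
      jitter <- stats::runif(1, -protocol$hold_tolerance, protocol$hold_tolerance)
      # subjects cannot voluntarily exceed their own maximum
      achieved_level <- min(target_level * (1 + jitter), 1)
      v <- achieved_level * gt$true_va
      stim_times <- c(layout$stim1, layout$stim2)
    }
    tremor_phase <- stats::runif(1, 0, 2 * pi)

    env <- effort_envelope(t, layout)
    plateau_m <- v * gt$full_activation_moment
    m <- plateau_m * env
    if (gt$plateau_drift != 0)
      m <- m + gt$plateau_drift * pmax(t - layout$plateau_start, 0) * env
    if (gt$tremor_amplitude > 0)
      m <- m + gt$tremor_amplitude *
        sin(2 * pi * gt$tremor_frequency * t + tremor_phase) * env

    if (trial_type == "matched") {
      v_occ <- min(v, 1)
      amp_sup <- gt$rest_twitch_amplitude * (1 - v_occ) *
        (1 - gt$occlusion_curvature * v_occ)
      m <- m + twitch_waveform(t - layout$stim1, amp_sup, gt$twitch_time_constant)
      m <- m + twitch_waveform(t - layout$stim2, gt$rest_twitch_amplitude,
                               gt$twitch_time_constant)
    }
    if (gt$noise_sd > 0)
      m <- m + stats::rnorm(n, 0, gt$noise_sd)

    trial_record(
      trial_id = NA_character_, arm_id = gt$arm_id, subject_id = gt$subject_id,
      transfer_group = gt$transfer_group, posture = gt$posture,
      trial_type = trial_type,
      target_level = if (trial_type == "mvc") NA_real_ else target_level,
      trace = moment_trace(m, fs, units = "newton_meters"),
      stim_times = stim_times, achieved_level = achieved_level
    )
  })
}

#' Simulate a complete interpolated-twitch study
#'
#' One trial block per ground-truth row (arm x posture): `n_mvc_trials` MVC
#' trials followed by `trials_per_level` matching trials at each target level,
#' presented in randomized order as in the experimental protocol. Per-trial
#' seeds are drawn deterministically from `seed`, so the whole dataset is
#' reproducible bit-for-bit.
#'
#' @param ground_truths A list of [arm_ground_truth()] objects (one per
#'   arm x posture; pairs must be unique). An empty list yields an empty study.
#' @param protocol A [protocol_spec()].
#' @param seed Integer master seed.
#' @return A `study_dataset`: list with `trials` (list of `trial_record`),
#'   `manifest` (one row per trial) and `ground_truth` (one row per
#'   arm x posture, with `true_va` and `full_activation_moment` for recovery
#'   checks).
#' @examples
#' gt <- arm_ground_truth("a1", "biceps", "horizontal", 10, 0.96, 1.5,
#'                        noise_sd = 0)
#' st <- simulate_study(list(gt), seed = 1)
#' nrow(st$manifest)  # 3 MVC + 18 matching trials
#' @export
simulate_study <- function(ground_truths, protocol = protocol_spec(), seed = 1L) {
  stopifnot(inherits(protocol, "protocol_spec"))
  if (length(ground_truths) == 0L) {
    return(structure(list(trials = list(),
                          manifest = empty_manifest(),
                          ground_truth = empty_ground_truth_table()),
                     class = "study_dataset"))
  }
  stopifnot(all(vapply(ground_truths, inherits, logical(1), "arm_ground_truth")))
  keys <- vapply(ground_truths, function(g) paste(g$arm_id, g$posture, sep = "|"),
                 character(1))
  if (anyDuplicated(keys))
    stop_twitchva("validation", sprintf(
      "simulate_study: duplicate arm x posture pairs: %s",
      paste(unique(keys[duplicated(keys)]), collapse = ", ")))

  per_block <- protocol$n_mvc_trials +
    protocol$trials_per_level * length(protocol$target_levels)
  n_total <- per_block * length(ground_truths)

  plan <- with_seed(seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, n_total)
    orders <- lapply(seq_along(ground_truths), function(i)
      sample(rep(protocol$target_levels, protocol$trials_per_level)))
    list(seeds = seeds, orders = orders)
  })

  trials <- vector("list", n_total)
  manifest <- vector("list", n_total)
  k <- 0L
  for (i in seq_along(ground_truths)) {
    gt <- ground_truths[[i]]
    block_targets <- c(rep(NA_real_, protocol$n_mvc_trials), plan$orders[[i]])
    for (j in seq_along(block_targets)) {
      k <- k + 1L
      type <- if (j <= protocol$n_mvc_trials) "mvc" else "matched"
      tr <- simulate_trial(gt, protocol, target_level = block_targets[j],
                           trial_type = type, seed = plan$seeds[k])
      tr$trial_id <- sprintf("%s_%s_t%02d", gt$arm_id, gt$posture, j)
      trials[[k]] <- tr
      manifest[[k]] <- data.frame(
        trial_id = tr$trial_id, arm_id = gt$arm_id, subject_id = gt$subject_id,
        transfer_group = gt$transfer_group, posture = gt$posture,
        trial_type = type, target_level = block_targets[j],
        stim1_time_s = if (type == "mvc") NA_real_ else tr$stim_times[1],
        stim2_time_s = if (type == "mvc") NA_real_ else tr$stim_times[2],
        stringsAsFactors = FALSE)
    }
  }
  gt_table <- do.call(rbind, lapply(ground_truths, function(g)
    data.frame(arm_id = g$arm_id, subject_id = g$subject_id,
               transfer_group = g$transfer_group, posture = g$posture,
               full_activation_moment = g$full_activation_moment,
               true_va = g$true_va,
               rest_twitch_amplitude = g$rest_twitch_amplitude,
               noise_sd = g$noise_sd, stringsAsFactors = FALSE)))
  structure(list(trials = trials,
                 manifest = do.call(rbind, manifest),
                 ground_truth = gt_table),
            class = "study_dataset")
}

empty_manifest <- function() {
  data.frame(trial_id = character(0), arm_id = character(0),
             subject_id = character(0), transfer_group = character(0),
             posture = character(0), trial_type = character(0),
             target_level = numeric(0), stim1_time_s = numeric(0),
             stim2_time_s = numeric(0), stringsAsFactors = FALSE)
}

empty_ground_truth_table <- function() {
  data.frame(arm_id = character(0), subject_id = character(0),
             transfer_group = character(0), posture = character(0),
             full_activation_moment = numeric(0), true_va = numeric(0),
             rest_twitch_amplitude = numeric(0), noise_sd = numeric(0),
             stringsAsFactors = FALSE)
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("<study_dataset> %d trials, %d arm x posture blocks\n",
              length(x$trials), nrow(x$ground_truth)))
  invisible(x)
}

#' Study-cohort ground truths emulating the tendon-transfer cohort
#'
#' Builds ground truths for a cohort shaped like the study the package
#' models: 11 arms (5 biceps transfers across 3 subjects, 6 deltoid transfers
#' across 4 subjects; two subjects per group contribute both arms), each
#' tested in three postures. Group x posture mean voluntary activation is
#' 0.96 for biceps transfers in every posture and 0.80 / 0.69 / 0.70
#' (horizontal / overhead reach / pressure relief) for deltoid transfers;
#' full-activation moments are set so mean maximum voluntary moments match
#' the reported group means. Between-arm variation is drawn around those
#' means.
#'
#' @param seed Integer seed for the between-arm draws.
#' @param noise_frac Measurement-noise SD as a fraction of each arm's
#'   full-activation moment (default 0.02).
#' @return List of [arm_ground_truth()] objects (33 = 11 arms x 3 postures).
#' @export
cohort_ground_truths <- function(seed = 100L, noise_frac = 0.02) {
  arms <- cohort_arm_layout()
  postures <- c("horizontal", "overhead_reach", "pressure_relief")
  va_mean <- list(
    biceps  = c(horizontal = 0.96, overhead_reach = 0.96, pressure_relief = 0.96),
    deltoid = c(horizontal = 0.80, overhead_reach = 0.69, pressure_relief = 0.70))
  # mean maximum voluntary moments per group x posture (N*m)
  mvm_mean <- list(
    biceps  = c(horizontal = 8.78, overhead_reach = 8.26, pressure_relief = 11.09),
    deltoid = c(horizontal = 2.76, overhead_reach = 2.76, pressure_relief = 2.76))
  va_arm_sd <- c(biceps = 0.04, deltoid = 0.10)
  with_seed(seed, {
    out <- list()
    for (i in seq_len(nrow(arms))) {
      grp <- arms$transfer_group[i]
      # one strength scale per arm, shared across postures
      strength_scale <- exp(stats::rnorm(1, 0, 0.25))
      va_shift <- stats::rnorm(1, 0, va_arm_sd[[grp]])
      for (p in postures) {
        va <- min(max(va_mean[[grp]][[p]] + va_shift +
                        stats::rnorm(1, 0, 0.02), 0.2), 1.0)
        m_full <- mvm_mean[[grp]][[p]] / va_mean[[grp]][[p]] * strength_scale
        out[[length(out) + 1L]] <- arm_ground_truth(
          arm_id = arms$arm_id[i], subject_id = arms$subject_id[i],
          transfer_group = grp, posture = p,
          full_activation_moment = m_full, true_va = va,
          rest_twitch_amplitude = 0.15 * m_full,
          noise_sd = noise_frac * m_full)
      }
    }
    out
  })
}

#' Arm-to-subject layout of the emulated cohort
#'
#' @return Data frame with `arm_id`, `subject_id`, `transfer_group`: 5 biceps
#'   arms over 3 subjects and 6 deltoid arms over 4 subjects.
#' @export
cohort_arm_layout <- function() {
  data.frame(
    arm_id = sprintf("arm%02d", 1:11),
    subject_id = c("S1", "S1", "S2", "S2", "S3", "S4", "S5", "S6", "S6", "S7", "S7"),
    transfer_group = c(rep("biceps", 5), rep("deltoid", 6)),
    stringsAsFactors = FALSE)
}
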