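make_twitch_trace <- function(baseline, amp, tau, stim = 1, fs = 1000, dur = 2) {
  t <- (0:(dur * fs - 1)) / fs
  moment_trace(baseline + twitch_waveform(t - stim, amp, tau), fs)
}

test_that("pre-stimulus moment averages the 250 ms before the stimulus", {
  expect_equal(pre_stimulus_moment(moment_trace(rep(6, 1000), 1000), 0.5), 6)
  # ramp crossing the window: direct summation oracle over the 250 samples
  fs <- 1000
  x <- seq(0, 2, length.out = 2 * fs)
  tr <- moment_trace(x, fs)
  idx <- which((0:(2 * fs - 1)) / fs >= 0.75 - 1e-9 &
                 (0:(2 * fs - 1)) / fs < 1.0 - 1e-9)
  expect_length(idx, 250)
  expect_equal(pre_stimulus_moment(tr, 1.0), sum(x[idx]) / 250, tolerance = 1e-12)
  # stimulus at trace start violates the precondition
  expect_error(pre_stimulus_moment(tr, 0.1), class = "twitchva_error_bounds")
})

test_that("twitch amplitude is the post-stimulus peak minus the baseline", {
  tr <- make_twitch_trace(5, 0.8, 0.07)
  expect_equal(twitch_amplitude(tr, 1), 0.8, tolerance = 1e-9)
  # flat trace: no twitch
  expect_equal(twitch_amplitude(moment_trace(rep(5, 2000), 1000), 1), 0)
  # slow twitch peaking near the window edge: exhaustive max-scan oracle
  tr <- make_twitch_trace(2, 1, 0.12)
  t <- trace_times(tr)
  in_win <- t >= 1 - 1e-9 & t <= 1.15 + 1e-9
  pre <- mean(tr$samples[t >= 0.75 - 1e-9 & t < 1 - 1e-9])
  expect_equal(twitch_amplitude(tr, 1), max(tr$samples[in_win]) - pre,
               tolerance = 1e-12)
  expect_error(twitch_amplitude(tr, 1.9), class = "twitchva_error_bounds")
})

test_that("negative twitch amplitudes are retained, not clamped", {
  # declining moment with no evoked response: post-stimulus max sits below
  # the pre-stimulus mean, so the amplitude is legitimately negative
  fs <- 1000
  t <- (0:1999) / fs
  decline <- moment_trace(5 - 0.5 * t, fs)
  expect_lt(twitch_amplitude(decline, 1), 0)
})

test_that("extract_trial yields a superimposed and a resting measurement", {
  gt <- quiet_gt(va = 1.0, m_full = 10, t0 = 1.5)
  pr <- exact_protocol()
  tr <- simulate_trial(gt, pr, target_level = 0.66, trial_type = "matched", seed = 1)
  tr$trial_id <- "t1"
  m <- extract_trial(tr)
  expect_equal(nrow(m), 2)
  expect_equal(m$effort_context, c(0.66, 0))
  expect_equal(m$pre_stimulus_moment_nm[1], 6.6, tolerance = 1e-9)
  expect_equal(m$twitch_amplitude_nm[2], 1.5, tolerance = 1e-9)

  mvc <- simulate_trial(gt, pr, trial_type = "mvc", seed = 1)
  expect_error(extract_trial(mvc), class = "twitchva_error_not_applicable")
})

test_that("a resting baseline that rivals the resting twitch raises a QC warning", {
  fs <- 1000
  t <- (0:9999) / fs
  m <- 2 + twitch_waveform(t - 2, 1, 0.07) + twitch_waveform(t - 9, 1, 0.07)
  tr <- trial_record("t1", "a1", "biceps", "horizontal", "matched", 1,
                     moment_trace(m, fs), c(2, 9))
  expect_warning(extract_trial(tr), class = "twitchva_warning_qc")
})

test_that("measurement count is conserved: two per matched trial", {
  gt <- quiet_gt(va = 0.8)
  st <- simulate_study(list(gt), seed = 9)
  meas <- extract_measurements(st$trials)
  n_matched <- sum(st$manifest$trial_type == "matched")
  expect_equal(nrow(meas), 2 * n_matched)
  expect_equal(nrow(meas), 36)
  expect_equal(sum(meas$effort_context == 0), n_matched)
})

test_that("noiseless superimposed twitches follow T0 * (1 - level * VA)", {
  va <- 0.8; t0 <- 1.2
  gt <- quiet_gt(va = va, m_full = 8, t0 = t0)
  pr <- exact_protocol()
  for (lv in pr$target_levels) {
    tr <- simulate_trial(gt, pr, target_level = lv, seed = 2)
    expect_equal(twitch_amplitude(tr$trace, tr$stim_times[1]),
                 t0 * (1 - lv * va), tolerance = 1e-6)
    # resting twitch never smaller than the superimposed one
    expect_gte(twitch_amplitude(tr$trace, tr$stim_times[2]) + 1e-12,
               twitch_amplitude(tr$trace, tr$stim_times[1]))
  }
})

test_that("maximum voluntary moment takes the best qualifying trial", {
  flat_trial <- function(value, id) {
    trial_record(id, "a1", "biceps", "horizontal", "mvc", NA,
                 moment_trace(rep(value, 3000), 1000), numeric(0))
  }
  trials <- list(flat_trial(6.8, "m1"), flat_trial(7.0, "m2"), flat_trial(6.9, "m3"))
  expect_equal(max_voluntary_moment(trials), 7.0)
  expect_equal(max_voluntary_moment(trials[1:3]), 7.0)

  # noisy simulated set: equals a brute-force scan over every qualifying trial
  gt <- arm_ground_truth("a1", "deltoid", "horizontal", 4, 0.7, 0.6)
  st <- simulate_study(list(gt), seed = 6)
  got <- max_voluntary_moment(st$trials)
  qual <- Filter(function(tr) tr$trial_type == "mvc" ||
                   (!is.na(tr$target_level) && tr$target_level == 1), st$trials)
  want <- max(vapply(qual, function(tr) {
    x <- tr$trace$samples
    if (tr$trial_type == "matched") {
      keep <- trace_times(tr$trace) < tr$stim_times[1] - 0.1 - 1e-9
      x <- x[keep]
    }
    brute_max_sustained(x, 1000, 0.5)$value
  }, numeric(1)))
  expect_identical(got, want)

  # restricting to MVC trials only: a matched-only set then has no candidates
  only_matched <- Filter(function(tr) tr$trial_type == "matched", st$trials)
  expect_error(max_voluntary_moment(only_matched, include_matched_100 = FALSE),
               class = "twitchva_error_missing_data")
  expect_error(max_voluntary_moment(list()), class = "twitchva_error_missing_data")
})

test_that("trial records validate stimulus placement", {
  tr <- moment_trace(rep(1, 1000), 1000)
  expect_error(trial_record("t", "a", "biceps", "horizontal", "matched", 1,
                            tr, c(0.5, 0.95)),   # < 150 ms after second stim
               class = "twitchva_error_validation")
  expect_error(trial_record("t", "a", "biceps", "horizontal", "matched", 1,
                            tr, c(0.9, 0.5)),    # decreasing
               class = "twitchva_error_validation")
  expect_error(trial_record("t", "a", "biceps", "horizontal", "mvc", NA,
                            tr, 0.5),            # MVC with stimuli
               class = "twitchva_error_validation")
})
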