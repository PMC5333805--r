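test_that("rest-twitch selection keeps the six values closest to the median", {
  x <- c(1.0, 1.1, 1.2, 1.3, 1.4, 1.5, 9.0, 0.1)
  idx <- select_rest_twitches(x)
  expect_equal(sort(x[idx]), c(1.0, 1.1, 1.2, 1.3, 1.4, 1.5))
  expect_equal(idx, brute_rest_subset(x))

  # exactly six: all kept, order preserved
  expect_equal(select_rest_twitches(c(3, 1, 2, 5, 4, 6)), 1:6)
  # fewer than six: all kept
  expect_equal(select_rest_twitches(c(2, 1)), 1:2)
  # identical values: earliest six by trial order (the tie-break contract)
  expect_equal(select_rest_twitches(rep(1.7, 10)), 1:6)
  expect_error(select_rest_twitches(numeric(0)),
               class = "twitchva_error_missing_data")
})

test_that("greedy median selection matches brute-force subset search", {
  set.seed(123)
  for (rep in 1:20) {
    n <- sample(7:11, 1)
    x <- round(rnorm(n, 1, 0.4), 2)
    got <- select_rest_twitches(x)
    want <- brute_rest_subset(x)
    expect_equal(sum(abs(x[got] - median(x))),
                 sum(abs(x[want] - median(x))), tolerance = 1e-12)
  }
})

test_that("extrapolation recovers an exact line and its x-intercept", {
  x <- c(0, 1, 2, 3, 3.5)
  meas <- data.frame(effort_context = c(0, 0.33, 0.5, 0.8, 1),
                     pre_stimulus_moment_nm = x,
                     twitch_amplitude_nm = 2 - 0.5 * x)
  fit <- fit_extrapolation(meas)
  expect_equal(fit$slope, -0.5, tolerance = 1e-12)
  expect_equal(fit$intercept, 2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$predicted_moment, 4, tolerance = 1e-10)
  expect_true(fit$included)
})

test_that("OLS slope, intercept and R2 match the normal-equations oracle", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(6:24, 1)
    x <- runif(n, 0, 10)
    y <- 2 - 0.3 * x + rnorm(n, sd = 0.3)
    meas <- data.frame(effort_context = rep(0.5, n),
                       pre_stimulus_moment_nm = x, twitch_amplitude_nm = y)
    fit <- fit_extrapolation(meas)
    o <- ols_oracle(x, y)
    expect_equal(fit$slope, o$slope, tolerance = 1e-10)
    expect_equal(fit$intercept, o$intercept, tolerance = 1e-10)
    expect_equal(fit$r_squared, o$r_squared, tolerance = 1e-10)
    if (o$slope < 0)
      expect_equal(fit$predicted_moment, -o$intercept / o$slope, tolerance = 1e-10)
  }
})

test_that("fits are excluded exactly when oracle R2 falls below 0.80", {
  # scattered points engineered for a mid-range R2, judged by the oracle
  x <- c(0, 0, 1, 2, 3, 4, 5, 6)
  y <- c(2.2, 1.4, 2.4, 0.8, 1.9, 0.3, 1.2, 0.1)
  o <- ols_oracle(x, y)
  expect_lt(o$r_squared, 0.80)
  meas <- data.frame(effort_context = c(0, 0, rep(0.5, 6)),
                     pre_stimulus_moment_nm = x, twitch_amplitude_nm = y)
  fit <- fit_extrapolation(meas)
  expect_false(fit$included)
  expect_equal(fit$reason, "low_r_squared")
  expect_equal(fit$r_squared, o$r_squared, tolerance = 1e-10)

  # a strongly linear set passes the same gate
  y2 <- 2 - 0.3 * x + c(0.01, -0.01, 0.02, 0, -0.02, 0.01, 0, -0.01)
  fit2 <- fit_extrapolation(transform(meas, twitch_amplitude_nm = y2))
  expect_true(fit2$included)
})

test_that("non-negative slopes are flagged degenerate, not fatal", {
  meas <- data.frame(effort_context = c(0, 0.5, 1),
                     pre_stimulus_moment_nm = c(0, 2, 4),
                     twitch_amplitude_nm = c(1, 1.5, 2))
  fit <- fit_extrapolation(meas)
  expect_false(fit$included)
  expect_equal(fit$reason, "nonnegative_slope")
  expect_true(is.na(fit$predicted_moment))

  too_few <- data.frame(effort_context = c(0, 1),
                        pre_stimulus_moment_nm = c(0, 4),
                        twitch_amplitude_nm = c(2, 0))
  expect_error(fit_extrapolation(too_few), class = "twitchva_error_missing_data")
})

test_that("voluntary activation is the moment ratio, preserved above 1", {
  line_fit <- function(pred) {
    x <- c(0, 4, 8)
    fit_extrapolation(data.frame(
      effort_context = c(0, 0.5, 1), pre_stimulus_moment_nm = x,
      twitch_amplitude_nm = 1 - x / pred))
  }
  expect_equal(compute_va(7, line_fit(10))$voluntary_activation, 0.7,
               tolerance = 1e-9)
  expect_equal(compute_va(10, line_fit(10))$voluntary_activation, 1.0,
               tolerance = 1e-9)
  over <- compute_va(10.3, line_fit(10))
  expect_equal(over$voluntary_activation, 1.03, tolerance = 1e-9)
  expect_true(over$over_unity)

  # an excluded fit propagates a missing VA with its reason code
  bad <- fit_extrapolation(data.frame(
    effort_context = c(0, 0.5, 1), pre_stimulus_moment_nm = c(0, 2, 4),
    twitch_amplitude_nm = c(1, 1.5, 2)))
  res <- compute_va(7, bad)
  expect_true(is.na(res$voluntary_activation))
  expect_false(res$qc_included)
  expect_equal(res$reason, "nonnegative_slope")
})

test_that("end-to-end noiseless parameter recovery is exact", {
  gt <- quiet_gt(va = 0.96, m_full = 10, t0 = 1.5)
  st <- simulate_study(list(gt), seed = 1)
  res <- run_arm_posture(st$trials)
  expect_equal(res$voluntary_activation, 0.96, tolerance = 1e-6)
  expect_equal(res$predicted_moment, 10, tolerance = 1e-6)
  expect_true(res$qc_included)
})

test_that("a larger superimposed twitch at full effort strictly lowers VA", {
  base <- data.frame(
    effort_context = c(0, 0, 0.33, 0.66, 1),
    pre_stimulus_moment_nm = c(0.01, -0.01, 2.3, 4.6, 7),
    twitch_amplitude_nm = c(2.0, 1.98, 1.35, 0.67, 0.02))
  va_for <- function(y100) {
    m <- base; m$twitch_amplitude_nm[5] <- y100
    compute_va(7, fit_extrapolation(m))$voluntary_activation
  }
  vas <- vapply(c(0.02, 0.2, 0.4, 0.8), va_for, numeric(1))
  expect_true(all(diff(vas) < 0))
})

test_that("analyze_study keeps one accounted row per arm x posture", {
  gts <- list(quiet_gt(arm = "a1"), quiet_gt(arm = "a2", va = 0.5))
  st <- simulate_study(gts, seed = 3)
  # sabotage arm a2: flatten all its twitches so the fit degenerates
  st$trials <- lapply(st$trials, function(tr) {
    if (tr$arm_id == "a2" && tr$trial_type == "matched") {
      n <- length(tr$trace$samples)
      plateau <- pre_stimulus_moment(tr$trace, tr$stim_times[1])
      tr$trace <- moment_trace(rep(plateau, n), tr$trace$sampling_rate)
    }
    tr
  })
  # flat resting baselines trip the (intended) resting-baseline QC warning
  out <- suppressWarnings(analyze_study(st))
  expect_equal(nrow(out$results), 2)
  expect_equal(sum(out$results$qc_included), 1)
  excl <- out$results[!out$results$qc_included, ]
  expect_equal(excl$arm_id, "a2")
  expect_true(is.na(excl$voluntary_activation))
  expect_false(is.na(excl$max_voluntary_moment_nm))  # moment is retained
})
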