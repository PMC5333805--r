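# Balanced two-group fixture whose deltoid cells are exact shifted copies of
# the biceps cells, so empirical residual structure is identical in both
# groups (homoscedastic by construction).
balanced_fixture <- function(shift = 0) {
  set.seed(202)
  postures <- c("horizontal", "overhead_reach", "pressure_relief")
  arm_vals <- replicate(6, 0.8 + rnorm(1, 0, 0.05) + rnorm(3, 0, 0.04),
                        simplify = FALSE)
  rows <- list()
  for (i in 1:6) {
    for (g in c("biceps", "deltoid")) {
      y <- arm_vals[[i]] + if (g == "deltoid") shift else 0
      rows[[length(rows) + 1L]] <- data.frame(
        arm_id = paste0(g, i), subject_id = paste0(g, i), transfer_group = g,
        posture = postures, voluntary_activation = y,
        max_voluntary_moment_nm = y, qc_included = TRUE)
    }
  }
  do.call(rbind, rows)
}

test_that("group summaries compute cell means and standard errors", {
  tab <- data.frame(transfer_group = c("biceps", "biceps"),
                    posture = c("horizontal", "horizontal"),
                    voluntary_activation = c(0.9, 1.0))
  s <- group_summary(tab)
  cell <- s[s$posture == "horizontal", ]
  expect_equal(cell$mean, 0.95)
  expect_equal(cell$se, 0.05)
  expect_equal(cell$n, 2)

  # identical values everywhere: every mean c, every SE 0
  tab2 <- balanced_fixture()
  tab2$voluntary_activation <- 0.77
  s2 <- group_summary(tab2)
  expect_true(all(s2$mean == 0.77))
  expect_true(all(s2$se == 0))

  # across-posture group mean pools all arm x posture values
  tab3 <- balanced_fixture()
  s3 <- group_summary(tab3)
  all_biceps <- s3[s3$transfer_group == "biceps" & s3$posture == "all", ]
  expect_equal(all_biceps$mean,
               mean(tab3$voluntary_activation[tab3$transfer_group == "biceps"]))
  expect_equal(all_biceps$n, 18)
})

test_that("group summaries ignore row order and report empty cells as n = 0", {
  tab <- balanced_fixture()
  shuffled <- tab[sample(nrow(tab)), ]
  expect_equal(group_summary(tab), group_summary(shuffled))

  tab$voluntary_activation[tab$transfer_group == "deltoid" &
                             tab$posture == "horizontal"] <- NA
  s <- group_summary(tab)
  empty <- s[s$transfer_group == "deltoid" & s$posture == "horizontal", ]
  expect_equal(empty$n, 0)
  expect_true(is.na(empty$mean))
})

test_that("on balanced homoscedastic data the mixed model reproduces the ANOVA F", {
  tab <- balanced_fixture(shift = -0.1)
  # classical two-way repeated-measures oracle: between-arm stratum for the
  # transfer effect, within-arm stratum for posture and the interaction
  tab$arm_f <- factor(tab$arm_id)
  ao <- summary(aov(voluntary_activation ~ transfer_group * posture +
                      Error(arm_f), data = tab))
  f_between <- ao[["Error: arm_f"]][[1]]["transfer_group", "F value"]
  f_within <- ao[["Error: Within"]][[1]][c("posture", "transfer_group:posture"),
                                         "F value"]
  fit <- fit_group_model(tab, "va")
  eff <- fit$effects
  expect_equal(eff$f_statistic[eff$effect == "transfer"], f_between,
               tolerance = 1e-3)
  expect_equal(eff$f_statistic[eff$effect == "posture"], f_within[1],
               tolerance = 1e-3)
  expect_equal(eff$f_statistic[eff$effect == "interaction"], f_within[2],
               tolerance = 1e-3)
  # with a pooled residual variance the equivalence is numerically tight
  fit_eq <- fit_group_model(tab, "va", config = run_config(heteroscedastic = FALSE))
  expect_equal(fit_eq$effects$f_statistic[1], f_between, tolerance = 1e-6)
})

test_that("degenerate designs fail with a diagnostic naming the factor", {
  tab <- balanced_fixture()
  expect_error(fit_group_model(tab[tab$transfer_group == "biceps", ], "va"),
               "transfer_group", class = "twitchva_error_singular_design")
  expect_error(fit_group_model(tab[tab$posture == "horizontal", ], "va"),
               "posture", class = "twitchva_error_singular_design")
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(0.01, 3), 0.03)
  expect_equal(bonferroni_adjust(0.5, 3), 1.0)
  expect_equal(bonferroni_adjust(c(0.2, 0.4), 2), c(0.4, 0.8))
  expect_error(bonferroni_adjust(0.1, 0), class = "twitchva_error_invalid_parameter")
})

test_that("post-hoc contrasts are t-tests with Bonferroni-capped p-values", {
  # identical group distributions: contrast estimates 0, adjusted p = 1
  tab <- balanced_fixture(shift = 0)
  fit <- fit_group_model(tab, "va")
  ph <- bonferroni_posthoc(fit, "transfer_within_posture")
  expect_equal(nrow(ph), 3)
  expect_equal(ph$estimate, rep(0, 3), tolerance = 1e-8)
  expect_equal(ph$p_adjusted, rep(1, 3), tolerance = 1e-8)

  # a real separation is detected and p-values stay within [0, 1]
  tab2 <- balanced_fixture(shift = -0.26)
  fit2 <- fit_group_model(tab2, "va")
  ph2 <- bonferroni_posthoc(fit2, "transfer_within_posture")
  expect_true(all(ph2$p_adjusted >= 0 & ph2$p_adjusted <= 1))
  expect_true(all(ph2$p_adjusted < 0.05))
  ph3 <- bonferroni_posthoc(fit2, "posture_within_transfer")
  expect_equal(nrow(ph3), 6)
})

test_that("the transfer-effect test is calibrated under the null", {
  # identical distributions in two groups of six independent arms
  null_arms <- data.frame(
    arm_id = sprintf("n%02d", 1:12), subject_id = sprintf("n%02d", 1:12),
    transfer_group = rep(c("biceps", "deltoid"), each = 6))
  rej <- vapply(1:120, function(s) {
    tab <- simulate_va_table(arms = null_arms, sd_subject = 0, seed = s)
    f <- fit_group_model(tab, "va")
    f$effects$p_value[f$effects$effect == "transfer"] < 0.05
  }, logical(1))
  # 95% binomial band around 0.05 for 120 replicates
  expect_gte(sum(rej), qbinom(0.025, 120, 0.05))
  expect_lte(sum(rej), qbinom(0.975, 120, 0.05))
})

test_that("a cohort-sized activation deficit is reliably detected", {
  rej <- vapply(1:60, function(s) {
    tab <- simulate_va_table(
      cell_means = list(biceps = 0.96, deltoid = 0.70),
      sd_resid = c(biceps = 0.03, deltoid = 0.08), seed = 1000 + s)
    f <- fit_group_model(tab, "va")
    f$effects$p_value[f$effects$effect == "transfer"] < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.8)
})

test_that("deterioration back-correction inverts a fractional strength loss", {
  expect_equal(round(deterioration_backcorrect(2.74, 0.16), 2), 3.26)
  expect_equal(deterioration_backcorrect(5.5, 0), 5.5)
  expect_equal(deterioration_backcorrect(8.4, 0.5), 16.8)
  expect_error(deterioration_backcorrect(2, 1),
               class = "twitchva_error_invalid_parameter")
  expect_error(deterioration_backcorrect(2, -0.1),
               class = "twitchva_error_invalid_parameter")
})

test_that("the table-level simulator is seed-deterministic with the cohort layout", {
  a <- simulate_va_table(seed = 5)
  b <- simulate_va_table(seed = 5)
  expect_identical(a, b)
  expect_equal(nrow(a), 33)
  expect_equal(length(unique(a$subject_id)), 7)
  expect_equal(sum(a$transfer_group == "biceps") / 3, 5)
})
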