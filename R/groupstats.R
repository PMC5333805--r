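#' Cell means and standard errors per transfer group x posture
#'
#' Mean and standard error (sd / sqrt(n)) of a response per
#' transfer group x posture cell, plus each group's across-posture summary
#' computed over all qualifying arm x posture values. Missing responses
#' (QC-excluded voluntary activations) are dropped per cell; empty cells are
#' reported with `n = 0` and missing summaries.
#'
#' @param table Data frame with columns `transfer_group`, `posture` and the
#'   response column.
#' @param response Name of the response column
#'   (default `"voluntary_activation"`).
#' @return Data frame with `transfer_group`, `posture` (including an `"all"`
#'   row per group), `n`, `mean`, `se`. Row order is independent of the input
#'   row order.
#' @export
group_summary <- function(table, response = "voluntary_activation") {
  if (!response %in% names(table))
    stop_twitchva("validation", sprintf("group_summary: no column '%s'", response))
  groups <- sort(unique(table$transfer_group))
  postures <- sort(unique(table$posture))
  cell <- function(g, p) {
    vals <- table[[response]][table$transfer_group == g &
                                (p == "all" | table$posture == p)]
    vals <- vals[!is.na(vals)]
    n <- length(vals)
    data.frame(transfer_group = g, posture = p, n = n,
               mean = if (n) mean(vals) else NA_real_,
               se = if (n > 1) stats::sd(vals) / sqrt(n) else if (n == 1) 0 else NA_real_,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(groups, function(g)
    do.call(rbind, lapply(c(postures, "all"), function(p) cell(g, p)))))
  rownames(out) <- NULL
  out
}

#' Heteroscedastic linear mixed model for group comparisons
#'
#' Fits the study's group model to one response (voluntary activation or
#' maximum voluntary moment): fixed effects for transfer group, posture and
#' their interaction; a random intercept per arm (the independent unit of the
#' reported tests; a nested subject/arm structure is available as a
#' sensitivity option); and, by default, residual variances allowed to differ
#' between transfer groups. Fitting is by
#' restricted maximum likelihood via [nlme::lme()]; main effects and the
#' interaction are tested with marginal (type III) F-tests under sum-to-zero
#' contrasts. Rows with missing response (QC-excluded) are dropped.
#'
#' @param table Data frame with one row per arm x posture: `arm_id`,
#'   `subject_id`, `transfer_group`, `posture` and the response column
#'   (`voluntary_activation` or `max_voluntary_moment_nm`).
#' @param response `"va"` or `"moment"`.
#' @param config A [run_config()]; `heteroscedastic` and `random_structure`
#'   are honoured.
#' @return A `va_group_fit`: list with `model` (the `lme` fit), `effects`
#'   (data frame: effect, `f_statistic`, `df_num`, `df_den`, `p_value`),
#'   `response`, `data`.
#' @export
fit_group_model <- function(table, response = c("va", "moment"),
                            config = run_config()) {
  response <- match.arg(response)
  col <- switch(response, va = "voluntary_activation",
                moment = "max_voluntary_moment_nm")
  if (!col %in% names(table))
    stop_twitchva("validation", sprintf("fit_group_model: no column '%s'", col))
  d <- table[!is.na(table[[col]]), , drop = FALSE]
  if (length(unique(d$transfer_group)) < 2L)
    stop_twitchva("singular_design",
                  "fit_group_model: factor 'transfer_group' needs both levels present")
  if (length(unique(d$posture)) < 2L)
    stop_twitchva("singular_design",
                  "fit_group_model: factor 'posture' needs >= 2 levels present")
  if (!"subject_id" %in% names(d)) d$subject_id <- d$arm_id
  d <- data.frame(
    y = d[[col]],
    transfer_group = factor(d$transfer_group),
    posture = factor(d$posture),
    subject_id = factor(d$subject_id), arm_id = factor(d$arm_id))
  # sum-to-zero contrasts so marginal F-tests are the usual type III tests
  stats::contrasts(d$transfer_group) <- stats::contr.sum(nlevels(d$transfer_group))
  stats::contrasts(d$posture) <- stats::contr.sum(nlevels(d$posture))
  random <- switch(config$random_structure,
                   subject_arm = ~ 1 | subject_id / arm_id,
                   arm = ~ 1 | arm_id)
  args <- list(fixed = y ~ transfer_group * posture, random = random,
               data = d, method = "REML", na.action = stats::na.omit,
               control = nlme::lmeControl(opt = "optim", maxIter = 200,
                                          msMaxIter = 200, niterEM = 50,
                                          returnObject = TRUE))
  if (config$heteroscedastic)
    args$weights <- nlme::varIdent(form = ~ 1 | transfer_group)
  model <- do.call(nlme::lme, args)
  an <- stats::anova(model, type = "marginal")
  pick <- function(term) {
    i <- match(term, rownames(an))
    data.frame(response = response,
               effect = c(transfer_group = "transfer",
                          posture = "posture",
                          `transfer_group:posture` = "interaction")[[term]],
               f_statistic = an$`F-value`[i], df_num = an$numDF[i],
               df_den = an$denDF[i], p_value = an$`p-value`[i],
               stringsAsFactors = FALSE)
  }
  effects <- do.call(rbind, lapply(
    c("transfer_group", "posture", "transfer_group:posture"), pick))
  rownames(effects) <- NULL
  structure(list(model = model, effects = effects, response = response,
                 data = d),
            class = "va_group_fit")
}

#' @export
print.va_group_fit <- function(x, ...) {
  cat(sprintf("<va_group_fit> response: %s\n", x$response))
  print(x$effects, row.names = FALSE)
  invisible(x)
}

#' Bonferroni-adjusted pairwise comparisons
#'
#' Pairwise t-tests on the fitted cell means via \pkg{emmeans}, with p-values
#' multiplied by the number of comparisons in the family and capped at 1.
#'
#' @param fit A `va_group_fit` from [fit_group_model()].
#' @param which Family of contrasts: transfer groups compared within each
#'   posture, postures within each transfer group, or the marginal
#'   transfer/posture comparisons.
#' @return Data frame with `family`, `contrast`, `estimate`, `se`, `df`,
#'   `t_ratio`, `p_adjusted`.
#' @export
bonferroni_posthoc <- function(fit,
                               which = c("transfer_within_posture",
                                         "posture_within_transfer",
                                         "transfer", "posture")) {
  stopifnot(inherits(fit, "va_group_fit"))
  which <- match.arg(which)
  contrast_spec <- switch(which,
                 transfer_within_posture = ~ transfer_group | posture,
                 posture_within_transfer = ~ posture | transfer_group,
                 transfer = ~ transfer_group,
                 posture = ~ posture)
  em <- withCallingHandlers(
    emmeans::emmeans(fit$model, contrast_spec, data = fit$data),
    warning = function(w) {
      # emmeans notes that it drops the sum-to-zero contrast attributes when
      # rebuilding the reference grid; that is expected here
      if (grepl("contrasts dropped", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  pr <- as.data.frame(emmeans::test(graphics::pairs(em), adjust = "bonferroni"))
  by_col <- intersect(c("posture", "transfer_group"), names(pr))
  lab <- if (length(by_col)) paste0(pr$contrast, " | ", pr[[by_col[1]]]) else pr$contrast
  data.frame(family = which, contrast = lab, estimate = pr$estimate,
             se = pr$SE, df = pr$df, t_ratio = pr$t.ratio,
             p_adjusted = pmin(pr$p.value, 1), stringsAsFactors = FALSE)
}

#' Bonferroni adjustment of raw p-values
#'
#' @param p Raw p-values.
#' @param n_comparisons Number of comparisons in the family.
#' @return `min(1, p * n_comparisons)`, elementwise.
#' @examples
#' bonferroni_adjust(c(0.01, 0.5), 3)
#' @export
bonferroni_adjust <- function(p, n_comparisons) {
  if (n_comparisons < 1)
    stop_twitchva("invalid_parameter", "bonferroni_adjust: n_comparisons must be >= 1")
  pmin(1, p * n_comparisons)
}

#' Back-correct an observed mean for strength deterioration
#'
#' If strength is assumed to have deteriorated by a given fraction since an
#' earlier time point, the earlier mean is the observed mean divided by
#' (1 - fraction).
#'
#' @param observed_mean Observed mean moment (N*m).
#' @param deterioration_fraction Fraction lost, in [0, 1).
#' @return The back-corrected moment (N*m).
#' @examples
#' deterioration_backcorrect(2.74, 0.16)  # 3.26 N*m
#' @export
deterioration_backcorrect <- function(observed_mean, deterioration_fraction) {
  if (!is.numeric(deterioration_fraction) ||
      any(deterioration_fraction < 0) || any(deterioration_fraction >= 1))
    stop_twitchva("invalid_parameter",
                  "deterioration_backcorrect: fraction must be in [0, 1)")
  observed_mean / (1 - deterioration_fraction)
}

#' Simulate an arm x posture response table directly
#'
#' Draws a study table at the response level (no traces): cell mean plus a
#' subject random intercept, an arm random intercept and residual noise whose
#' SD may differ by transfer group. Used for calibration and power studies of
#' the group model. Under the null (`effects` all equal across groups and a
#' common residual SD) the transfer main-effect p-value should be uniform.
#'
#' @param arms Data frame with `arm_id`, `subject_id`, `transfer_group`
#'   (default [cohort_arm_layout()], the emulated cohort: 5 biceps and 6
#'   deltoid arms over 7 subjects).
#' @param postures Character vector of postures.
#' @param cell_means Named list mapping each transfer group to a vector of
#'   per-posture means (recycled if length 1).
#' @param sd_subject,sd_arm SDs of the subject and arm random intercepts.
#' @param sd_resid Residual SD; single value or named per transfer group.
#' @param seed Integer seed.
#' @return Data frame with `arm_id`, `subject_id`, `transfer_group`,
#'   `posture`, `voluntary_activation`, `max_voluntary_moment_nm` (a copy of
#'   the response, so either model interface can be exercised), `qc_included`.
#' @export
simulate_va_table <- function(arms = cohort_arm_layout(),
                              postures = c("horizontal", "overhead_reach",
                                           "pressure_relief"),
                              cell_means = list(biceps = 0.8, deltoid = 0.8),
                              sd_subject = 0.03, sd_arm = 0.03,
                              sd_resid = c(biceps = 0.05, deltoid = 0.05),
                              seed = 1L) {
  with_seed(seed, {
    subj_eff <- stats::rnorm(length(unique(arms$subject_id)), 0, sd_subject)
    names(subj_eff) <- unique(arms$subject_id)
    arm_eff <- stats::rnorm(nrow(arms), 0, sd_arm)
    rows <- list()
    for (i in seq_len(nrow(arms))) {
      g <- arms$transfer_group[i]
      mu <- rep_len(cell_means[[g]], length(postures))
      sdr <- if (length(sd_resid) > 1L) sd_resid[[g]] else sd_resid
      y <- mu + subj_eff[[arms$subject_id[i]]] + arm_eff[i] +
        stats::rnorm(length(postures), 0, sdr)
      rows[[i]] <- data.frame(
        arm_id = arms$arm_id[i], subject_id = arms$subject_id[i],
        transfer_group = g, posture = postures,
        voluntary_activation = y, max_voluntary_moment_nm = y,
        qc_included = TRUE, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}
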