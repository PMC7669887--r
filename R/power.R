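# Monte-Carlo power analysis for the 2x2 mixed design: simulate from a
# specified generative model, refit with and without the tested term,
# count likelihood-ratio rejections.

#' Convert meta-analysis effect ratios to additive model effects
#'
#' An effect ratio `r` (treatment mean over control mean) enters the
#' additive model as `(r - 1) * intercept`.
#'
#' @param ratios named list/vector with `temperature`, `pco2`,
#'   `interaction` ratios (see [effect_ratio_set()]).
#' @param intercept control-cell mean (> 0).
#' @return named numeric vector of additive effects.
#' @export
ratios_to_effects <- function(ratios, intercept) {
  stopifnot(intercept > 0)
  r <- unlist(ratios)[c("temperature", "pco2", "interaction")]
  stopifnot(all(r > 0))
  (r - 1) * intercept
}

#' Meta-analysis effect-ratio set for minimum oxygen uptake
#'
#' Default ratios follow cross-taxon meta-analytic estimates of climate
#' stressor effects on minimum oxygen uptake in marine ectotherms: 1.67
#' for temperature, 1.06 for pCO2, and 1.60 for their interaction.
#'
#' @param temperature,pco2,interaction effect ratios (> 0).
#' @return named list.
#' @export
effect_ratio_set <- function(temperature = 1.67, pco2 = 1.06,
                             interaction = 1.60) {
  stopifnot(temperature > 0, pco2 > 0, interaction > 0)
  list(temperature = temperature, pco2 = pco2, interaction = interaction)
}

#' Specify a Monte-Carlo power analysis
#'
#' The generative model is the study's linear mixed model: cell mean =
#' intercept + additive effects, replicate-group random intercepts, and
#' Gaussian residuals. Significance inside the power loop is judged by the
#' rule in `test` (an exact F test of nested linear models when
#' `group_sd = 0`, where the model degenerates to a fixed-effects linear
#' model).
#'
#' @param intercept control-cell mean.
#' @param effect_temperature,effect_pco2,effect_interaction additive
#'   effects (same units as the trait; see [ratios_to_effects()]).
#' @param group_sd replicate-group random-intercept sd.
#' @param resid_sd residual sd.
#' @param groups_per_cell,sharks_per_group design.
#' @param effect which term's power is being estimated.
#' @param alpha test size.
#' @param n_sim Monte-Carlo replicates (>= 100).
#' @param seed integer seed; each replicate uses a child seed so power
#'   curves over designs share random numbers.
#' @param test test rule for the tested (single-df) term:
#'   `"satterthwaite"` (default) uses the t statistic with
#'   Satterthwaite denominator degrees of freedom, which holds its nominal
#'   size at this design's small sample; `"lr"` uses the likelihood-ratio
#'   chi-square of nested maximum-likelihood fits, which is anticonservative
#'   here (null rejection ~6% at 36 observations). With `group_sd = 0`
#'   both reduce to the exact F test of nested linear models.
#' @return object of class `power_spec`.
#' @export
power_spec <- function(intercept, effect_temperature = 0, effect_pco2 = 0,
                       effect_interaction = 0, group_sd = 0, resid_sd = 1,
                       groups_per_cell = 3, sharks_per_group = 3,
                       effect = c("interaction", "temperature", "pco2"),
                       alpha = 0.05, n_sim = 1000, seed = 1,
                       test = c("satterthwaite", "lr")) {
  effect <- match.arg(effect)
  test <- match.arg(test)
  stopifnot(resid_sd > 0, group_sd >= 0, groups_per_cell >= 1,
            sharks_per_group >= 1, alpha > 0, alpha < 1, n_sim >= 100)
  structure(list(intercept = intercept,
                 effect_temperature = effect_temperature,
                 effect_pco2 = effect_pco2,
                 effect_interaction = effect_interaction,
                 group_sd = group_sd, resid_sd = resid_sd,
                 groups_per_cell = as.integer(groups_per_cell),
                 sharks_per_group = as.integer(sharks_per_group),
                 effect = effect, alpha = alpha,
                 n_sim = as.integer(n_sim), seed = as.integer(seed),
                 test = test),
            class = "power_spec")
}

# Simulate one dataset from the spec's generative model.
simulate_power_data <- function(spec, groups_per_cell, sim_seed) {
  g <- groups_per_cell
  m <- spec$sharks_per_group
  cells <- expand.grid(temp = c(0, 1), pco2 = c(0, 1))
  d <- cells[rep(seq_len(4), each = g * m), ]
  d$group <- factor(rep(seq_len(4 * g), each = m))
  mu <- spec$intercept + spec$effect_temperature * d$temp +
    spec$effect_pco2 * d$pco2 + spec$effect_interaction * d$temp * d$pco2
  with_seed(sim_seed, {
    b <- if (spec$group_sd > 0) rnorm(4 * g, 0, spec$group_sd) else rep(0, 4 * g)
    d$y <- mu + b[as.integer(d$group)] + rnorm(nrow(d), 0, spec$resid_sd)
  })
  d$temp_f <- factor(d$temp); d$pco2_f <- factor(d$pco2)
  d
}

# p-value for the tested term on one dataset. Returns NA on
# non-convergence.
power_test_once <- function(spec, d) {
  forms <- switch(spec$effect,
    interaction = list(full = y ~ temp_f * pco2_f,
                       reduced = y ~ temp_f + pco2_f),
    temperature = list(full = y ~ temp_f + pco2_f, reduced = y ~ pco2_f),
    pco2 = list(full = y ~ temp_f + pco2_f, reduced = y ~ temp_f))
  if (spec$group_sd <= 0) {
    return(tryCatch({
      full <- lm(forms$full, data = d)
      red <- lm(forms$reduced, data = d)
      anova(red, full)[2, "Pr(>F)"]
    }, error = function(e) NA_real_))
  }
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  re <- ~ . + (1 | group)
  if (spec$test == "satterthwaite") {
    term <- switch(spec$effect, interaction = "temp_f1:pco2_f1",
                   temperature = "temp_f1", pco2 = "pco2_f1")
    tryCatch({
      full <- suppressMessages(suppressWarnings(
        lmerTest::lmer(update(forms$full, re), data = d, REML = TRUE,
                       control = ctrl)))
      coef(summary(full))[term, "Pr(>|t|)"]
    }, error = function(e) NA_real_)
  } else {
    tryCatch({
      full <- suppressMessages(suppressWarnings(
        lme4::lmer(update(forms$full, re), data = d, REML = FALSE,
                   control = ctrl)))
      red <- suppressMessages(suppressWarnings(
        lme4::lmer(update(forms$reduced, re), data = d, REML = FALSE,
                   control = ctrl)))
      anova(red, full)[2, "Pr(>Chisq)"]
    }, error = function(e) NA_real_)
  }
}

#' Estimate power by Monte-Carlo simulation
#'
#' Repeats `n_sim` times: simulate a dataset from the spec's generative
#' model, refit nested models with and without the tested term, and test
#' at level `alpha`. Power is the fraction of rejections, with a Wilson
#' binomial interval. Aborts if more than 5% of refits fail.
#'
#' @param spec a [power_spec()].
#' @param groups_per_cell optionally override the spec's design size (used
#'   by [required_groups()]).
#' @return object of class `power_result`: list with `power`, `ci_low`,
#'   `ci_high`, `n_significant`, `n_sim`, `n_failed`, `groups_per_cell`,
#'   `effect`.
#' @export
simulate_power <- function(spec, groups_per_cell = spec$groups_per_cell) {
  stopifnot(inherits(spec, "power_spec"))
  ps <- vapply(seq_len(spec$n_sim), function(i) {
    d <- simulate_power_data(spec, groups_per_cell,
                             child_seed(spec$seed, "powersim", i))
    power_test_once(spec, d)
  }, numeric(1))
  n_fail <- sum(is.na(ps))
  if (n_fail > 0.05 * spec$n_sim) {
    stop(sprintf("%d of %d refits failed to converge", n_fail, spec$n_sim))
  }
  ok <- !is.na(ps)
  k <- sum(ps[ok] < spec$alpha)
  n <- sum(ok)
  ci <- wilson_ci(k, n)
  structure(list(power = k / n, ci_low = unname(ci["lower"]),
                 ci_high = unname(ci["upper"]), n_significant = k,
                 n_sim = n, n_failed = n_fail,
                 groups_per_cell = groups_per_cell, effect = spec$effect),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("Power for %s effect: %.3f (95%% CI %.3f-%.3f; %d/%d; %d groups/cell)\n",
              x$effect, x$power, x$ci_low, x$ci_high,
              x$n_significant, x$n_sim, x$groups_per_cell))
  invisible(x)
}

#' Interaction retention rule
#'
#' The interaction term is only interpreted when the design has power
#' above 80% to detect it; otherwise the main-effects model is reported.
#'
#' @param spec a [power_spec()] (its `effect` is forced to "interaction").
#' @param threshold retention threshold (strict inequality).
#' @return list with `keep` (logical) and the underlying `power_result`.
#' @export
interaction_retention <- function(spec, threshold = 0.80) {
  spec$effect <- "interaction"
  res <- simulate_power(spec)
  list(keep = res$power > threshold, power = res)
}

#' Replicate groups needed to reach a target power
#'
#' Evaluates the power curve on an increasing grid of replicate-group
#' counts, with common random numbers across grid points (each simulation
#' index reuses its seed) so the curve is monotone up to Monte-Carlo
#' error. Reports both the strict answer (smallest count whose power
#' exceeds the target) and the plateau answer (smallest count whose power
#' exceeds the target and whose successor improves by less than
#' `plateau_gain`).
#'
#' @param spec a [power_spec()].
#' @param target target power.
#' @param max_groups largest group count searched.
#' @param plateau_gain maximum successor gain for the plateau rule.
#' @return list with `curve` (`data.frame` `groups_per_cell`, `power`,
#'   `ci_low`, `ci_high`), `required_strict`, `required_plateau`
#'   (`NA` when unattained within `max_groups`), and `attained`.
#' @export
required_groups <- function(spec, target = 0.80,
                            max_groups = 12, plateau_gain = 0.02) {
  stopifnot(inherits(spec, "power_spec"), max_groups >= spec$groups_per_cell)
  grid <- seq(spec$groups_per_cell, max_groups)
  res <- lapply(grid, function(g) simulate_power(spec, groups_per_cell = g))
  curve <- data.frame(
    groups_per_cell = grid,
    power = vapply(res, `[[`, numeric(1), "power"),
    ci_low = vapply(res, `[[`, numeric(1), "ci_low"),
    ci_high = vapply(res, `[[`, numeric(1), "ci_high"))
  above <- which(curve$power > target)
  required_strict <- if (length(above)) grid[above[1]] else NA_integer_
  required_plateau <- NA_integer_
  for (i in above) {
    gain <- if (i < nrow(curve)) curve$power[i + 1] - curve$power[i] else 0
    if (gain < plateau_gain) { required_plateau <- grid[i]; break }
  }
  list(curve = curve, required_strict = required_strict,
       required_plateau = required_plateau,
       attained = !is.na(required_strict))
}

#' Observed (post-hoc) power of a fitted trait model
#'
#' Builds a [power_spec()] from a fitted model's own estimates (effects,
#' group and residual standard deviations) and estimates the probability
#' that the realised design declares the tested effect significant.
#'
#' @param fit a [fit_trait_model()] result.
#' @param effect which term to test.
#' @param groups_per_cell,sharks_per_group design; defaults to the
#'   fitted data's replicate structure.
#' @param n_sim,alpha,seed passed to [power_spec()].
#' @return a `power_result`.
#' @export
observed_power <- function(fit, effect = c("interaction", "temperature", "pco2"),
                           groups_per_cell = NULL, sharks_per_group = NULL,
                           n_sim = 1000, alpha = 0.05, seed = 1) {
  stopifnot(inherits(fit, "trait_fit"))
  effect <- match.arg(effect)
  beta <- fit$coefficients
  d <- fit$data
  if (is.null(groups_per_cell)) {
    groups_per_cell <- round(length(unique(d$group_id)) / 4)
  }
  if (is.null(sharks_per_group)) {
    sharks_per_group <- round(nrow(d) / length(unique(d$group_id)))
  }
  spec <- power_spec(
    intercept = beta[["intercept"]],
    effect_temperature = if ("high_temperature" %in% names(beta))
      beta[["high_temperature"]] else 0,
    effect_pco2 = if ("high_pco2" %in% names(beta)) beta[["high_pco2"]] else 0,
    effect_interaction = if ("interaction" %in% names(beta))
      beta[["interaction"]] else 0,
    group_sd = max(fit$group_sd, 0), resid_sd = fit$resid_sd,
    groups_per_cell = max(groups_per_cell, 1),
    sharks_per_group = max(sharks_per_group, 1),
    effect = effect, alpha = alpha, n_sim = n_sim, seed = seed)
  simulate_power(spec)
}
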