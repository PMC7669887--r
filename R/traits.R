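#' Ground truth for one simulated trait
#'
#' A trait is generated on the additive scale of the linear mixed model used
#' downstream: `value = intercept + effects + group intercept + residual`.
#' Treatment effects enter as multiplicative ratios relative to the control
#' mean: a ratio `r` on a factor contributes `(r - 1) * intercept` when that
#' factor is at its high level; the interaction ratio contributes
#' `(r - 1) * intercept` when both factors are high. This is how effect-size
#' ratios from the marine-ectotherm meta-analysis enter an additive model.
#'
#' @param intercept control-cell mean (low temperature, low pCO2).
#' @param ratio_temperature,ratio_pco2,ratio_interaction effect ratios (> 0);
#'   1 means no effect.
#' @param group_sd standard deviation of the replicate-group random
#'   intercept.
#' @param resid_sd residual (within-group, between-shark) standard deviation.
#' @return an object of class `trait_truth`.
#' @export
trait_truth <- function(intercept,
                        ratio_temperature = 1,
                        ratio_pco2 = 1,
                        ratio_interaction = 1,
                        group_sd = 0,
                        resid_sd = 0) {
  stopifnot(ratio_temperature > 0, ratio_pco2 > 0, ratio_interaction > 0,
            group_sd >= 0, resid_sd >= 0)
  structure(list(intercept = intercept,
                 ratio_temperature = ratio_temperature,
                 ratio_pco2 = ratio_pco2,
                 ratio_interaction = ratio_interaction,
                 group_sd = group_sd,
                 resid_sd = resid_sd),
            class = "trait_truth")
}

#' Expected trait mean for a treatment cell under a ground truth
#'
#' Deterministic part of the generative model: intercept plus the additive
#' shifts implied by the effect ratios.
#'
#' @param truth a [trait_truth()].
#' @param high_temperature,high_pco2 logical, is the factor at its high level?
#' @return expected value (no random components).
#' @export
trait_cell_mean <- function(truth, high_temperature, high_pco2) {
  truth$intercept +
    (truth$ratio_temperature - 1) * truth$intercept * high_temperature +
    (truth$ratio_pco2 - 1) * truth$intercept * high_pco2 +
    (truth$ratio_interaction - 1) * truth$intercept *
      (high_temperature & high_pco2)
}

#' Generate a single trait value for one shark
#'
#' @param truth a [trait_truth()].
#' @param high_temperature,high_pco2 treatment cell of the shark.
#' @param group_id replicate-group label (sharks sharing a group share the
#'   same random intercept).
#' @param shark_id shark label (residuals are independent across sharks).
#' @param seed experiment-level seed; group and residual draws use child
#'   seeds so results are invariant to generation order.
#' @return numeric trait value.
#' @export
generate_trait <- function(truth, high_temperature, high_pco2,
                           group_id, shark_id, seed) {
  stopifnot(inherits(truth, "trait_truth"))
  g <- if (truth$group_sd > 0) {
    with_seed(child_seed(seed, "traitgroup", group_id),
              rnorm(1, 0, truth$group_sd))
  } else 0
  e <- if (truth$resid_sd > 0) {
    with_seed(child_seed(seed, "traitresid", group_id, shark_id),
              rnorm(1, 0, truth$resid_sd))
  } else 0
  trait_cell_mean(truth, high_temperature, high_pco2) + g + e
}

#' Default ground truths for the 15 study traits
#'
#' Control means are set to values representative of neonatal blacktip reef
#' sharks (e.g. minimum oxygen uptake 133.69 mg O2 kg^-0.89 h^-1, haematocrit
#' 0.21); residual standard deviations are derived from the within-group
#' coefficients of variation reported for this species (e.g. 15.3% for
#' minimum uptake, 8.4% for haematocrit), and replicate-group standard
#' deviations are set to roughly 40% of the residual ones. All effect ratios
#' default to 1 (no treatment effect); override per trait to simulate
#' effects.
#'
#' @return named list of [trait_truth()] objects for the 12 directly
#'   generated traits. The remaining three study traits (absolute and
#'   factorial aerobic scope and MCHC) are derived arithmetically by
#'   [generate_trait_table()].
#' @export
default_trait_truths <- function() {
  tt <- function(mean, resid_sd, group_sd = 0.4 * resid_sd) {
    trait_truth(intercept = mean, group_sd = group_sd, resid_sd = resid_sd)
  }
  list(
    lr                = tt(-17.16, 55, 10),
    la                = tt(56.93, 25.6, 8),
    odba              = tt(0.089, 0.011, 0.004),
    hypoxia_tolerance = tt(24.52, 2.5, 0.8),
    mo2_min           = tt(133.69, 20.5, 8),
    mo2_max           = tt(360.15, 63.7, 20),
    epoc              = tt(369.14, 129, 40),
    recovery_time     = tt(11.75, 4.1, 1.2),
    blood_ph          = tt(8.09, 0.12, 0.03),
    lactate           = tt(3.58, 1.64, 0.4),
    hct               = tt(0.21, 0.0176, 0.005),
    hb                = tt(0.45, 0.158, 0.04)
  )
}

#' Generate the shark x trait table for a roster
#'
#' Directly generated traits come from [generate_trait()]; absolute aerobic
#' scope (`aas = mo2_max - mo2_min`), factorial aerobic scope
#' (`fas = mo2_max / mo2_min`) and `mchc = hb / hct` are derived
#' arithmetically so the algebraic identities linking them hold exactly,
#' as they do in real data.
#'
#' @param roster a roster from [generate_design()].
#' @param truths named list of [trait_truth()] objects; defaults to
#'   [default_trait_truths()].
#' @param seed experiment-level seed.
#' @return a `data.frame` with design columns and the 15 trait columns.
#' @export
generate_trait_table <- function(roster, truths = default_trait_truths(),
                                 seed = 1) {
  design <- attr(roster, "design")
  hi_t <- max(roster$temperature); hi_c <- max(roster$pco2)
  out <- roster[, c("id", "mass_kg", "temperature", "pco2", "group_id")]
  for (trait in names(truths)) {
    out[[trait]] <- vapply(seq_len(nrow(roster)), function(i) {
      generate_trait(truths[[trait]],
                     high_temperature = roster$temperature[i] == hi_t,
                     high_pco2 = roster$pco2[i] == hi_c,
                     group_id = roster$group_id[i],
                     shark_id = roster$id[i],
                     seed = child_seed(seed, "trait", trait))
    }, numeric(1))
  }
  out$aas <- out$mo2_max - out$mo2_min
  out$fas <- out$mo2_max / out$mo2_min
  out$mchc <- out$hb / out$hct
  attr(out, "design") <- design
  attr(out, "truths") <- truths
  out
}

#' Names of the 15 study traits
#' @return character vector of trait column names in a trait table.
#' @export
trait_names <- function() {
  c("lr", "la", "odba", "hypoxia_tolerance", "mo2_min", "mo2_max",
    "aas", "fas", "epoc", "recovery_time", "blood_ph", "lactate",
    "hct", "hb", "mchc")
}
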