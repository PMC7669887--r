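# Per-trait linear mixed models (temperature x pCO2 fixed, replicate group
# random), effect estimates with simulated confidence intervals, and the
# inter-individual variability screens.

# Prepare the model frame for one trait: high/low treatment factors with
# the low level as reference, complete cases only.
trait_model_frame <- function(table, trait) {
  if (!trait %in% names(table)) stop(sprintf("unknown trait '%s'", trait))
  d <- data.frame(
    y = table[[trait]],
    temp_f = factor(ifelse(table$temperature == max(table$temperature),
                           "high", "low"), levels = c("low", "high")),
    pco2_f = factor(ifelse(table$pco2 == max(table$pco2),
                           "high", "low"), levels = c("low", "high")),
    group_id = factor(table$group_id))
  d <- d[complete.cases(d), , drop = FALSE]
  if (nrow(d) == 0) stop(sprintf("trait '%s' has no non-missing values", trait))
  d
}

# Human-readable fixed-effect term names in Table 1/2 order.
rename_terms <- function(terms) {
  map <- c("(Intercept)" = "intercept",
           "pco2_fhigh" = "high_pco2",
           "temp_fhigh" = "high_temperature",
           "temp_fhigh:pco2_fhigh" = "interaction",
           "pco2_fhigh:temp_fhigh" = "interaction")
  out <- map[terms]
  ifelse(is.na(out), terms, out)
}

#' Fit the per-trait linear mixed model
#'
#' Gaussian linear mixed model with temperature and pCO2 as interacting
#' nominal fixed effects (high/low, low as reference) and replicate group
#' as a random intercept, fitted by REML for reporting. A singular fit
#' (group variance estimated at zero) is flagged, not an error.
#'
#' @param table a trait table (see [generate_trait_table()] or
#'   [read_trait_table_csv()]).
#' @param trait trait column name.
#' @param include_interaction include the temperature x pCO2 interaction?
#' @param reml fit by REML (TRUE, default, for reporting) or ML (for
#'   nested model comparisons).
#' @return object of class `trait_fit`: list with the `lme4` model,
#'   `coefficients`, their covariance `vcov`, `group_sd`, `resid_sd`,
#'   `singular` flag, `trait`, `n`.
#' @export
fit_trait_model <- function(table, trait, include_interaction = TRUE,
                            reml = TRUE) {
  d <- trait_model_frame(table, trait)
  form <- if (include_interaction) {
    y ~ pco2_f * temp_f + (1 | group_id)
  } else {
    y ~ pco2_f + temp_f + (1 | group_id)
  }
  model <- suppressMessages(lme4::lmer(form, data = d, REML = reml,
    control = lme4::lmerControl(check.conv.singular = "ignore")))
  vc <- as.data.frame(lme4::VarCorr(model))
  group_sd <- vc$sdcor[vc$grp == "group_id"][1]
  beta <- lme4::fixef(model)
  names(beta) <- rename_terms(names(beta))
  V <- as.matrix(vcov(model))
  dimnames(V) <- list(names(beta), names(beta))
  structure(list(model = model, coefficients = beta, vcov = V,
                 group_sd = group_sd,
                 resid_sd = stats::sigma(model),
                 singular = lme4::isSingular(model),
                 trait = trait, n = nrow(d), data = d),
            class = "trait_fit")
}

#' @export
print.trait_fit <- function(x, ...) {
  cat(sprintf("Mixed model for '%s' (n = %d%s)\n", x$trait, x$n,
              if (x$singular) ", singular random effect" else ""))
  print(round(x$coefficients, 4))
  cat(sprintf("  group sd %.4g, residual sd %.4g\n", x$group_sd, x$resid_sd))
  invisible(x)
}

# Clip non-positive eigenvalues to restore positive definiteness.
nearest_pd <- function(V) {
  e <- eigen(V, symmetric = TRUE)
  if (all(e$values > 0)) return(V)
  warning("coefficient covariance not positive definite; repaired by eigenvalue clipping")
  vals <- pmax(e$values, max(e$values) * 1e-10)
  e$vectors %*% diag(vals, nrow = length(vals)) %*% t(e$vectors)
}

#' Simulated confidence intervals for fixed effects
#'
#' Draws `n_sim` coefficient vectors from a multivariate normal centred at
#' the estimates with the estimated coefficient covariance (variance
#' components held at their point estimates) and reports percentile
#' intervals; an effect is called significant when its interval excludes
#' zero.
#'
#' @param fit a [fit_trait_model()] result.
#' @param n_sim number of posterior simulations.
#' @param level interval coverage level.
#' @param seed integer seed for the draws.
#' @return `data.frame` with `term`, `mean`, `ci_low`, `ci_high`,
#'   `significant` (intercept rows are never flagged).
#' @export
effect_ci <- function(fit, n_sim = 1000, level = 0.95, seed = 1) {
  stopifnot(inherits(fit, "trait_fit"), n_sim >= 2)
  V <- nearest_pd(fit$vcov)
  draws <- with_seed(child_seed(seed, "effectci", fit$trait),
                     MASS::mvrnorm(n_sim, fit$coefficients, V))
  alpha <- (1 - level) / 2
  qs <- apply(draws, 2, quantile, probs = c(alpha, 1 - alpha))
  out <- data.frame(term = names(fit$coefficients),
                    mean = unname(fit$coefficients),
                    ci_low = qs[1, ], ci_high = qs[2, ],
                    row.names = NULL)
  out$significant <- out$ci_low > 0 | out$ci_high < 0
  out$significant[out$term == "intercept"] <- NA
  out
}

#' Fit and summarise all traits of a table
#'
#' Runs [fit_trait_model()] and [effect_ci()] for each trait and stacks
#' the tidy rows, mirroring the layout of a per-trait effects table.
#'
#' @inheritParams fit_trait_model
#' @inheritParams effect_ci
#' @param traits trait columns to fit; defaults to all 15 study traits.
#' @return `data.frame` with `trait`, `term`, `mean`, `ci_low`, `ci_high`,
#'   `significant`, `singular`.
#' @export
fit_all_traits <- function(table, traits = trait_names(),
                           include_interaction = FALSE, n_sim = 1000,
                           level = 0.95, seed = 1) {
  rows <- lapply(traits, function(tr) {
    fit <- fit_trait_model(table, tr, include_interaction)
    ci <- effect_ci(fit, n_sim = n_sim, level = level, seed = seed)
    ci$trait <- tr
    ci$singular <- fit$singular
    ci
  })
  out <- do.call(rbind, rows)
  out[, c("trait", "term", "mean", "ci_low", "ci_high", "significant",
          "singular")]
}

#' Coefficient-of-variation screen
#'
#' `CV = sd / mean * 100` computed within each treatment cell; the pooled
#' per-trait CV is the mean of the cell CVs (within-group variability,
#' uninflated by treatment differences).
#'
#' @param table a trait table.
#' @param traits trait columns to screen.
#' @return list with `by_cell` (`data.frame` `trait`, `temperature`,
#'   `pco2`, `n`, `cv`) and `pooled` (`data.frame` `trait`, `cv`).
#' @export
cv_screen <- function(table, traits = trait_names()) {
  cells <- unique(table[, c("temperature", "pco2")])
  by_cell <- do.call(rbind, lapply(traits, function(tr) {
    do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      v <- table[[tr]][table$temperature == cells$temperature[i] &
                         table$pco2 == cells$pco2[i]]
      v <- v[!is.na(v)]
      cv <- if (length(v) >= 2 && mean(v) != 0) {
        sd(v) / abs(mean(v)) * 100
      } else NA_real_
      data.frame(trait = tr, temperature = cells$temperature[i],
                 pco2 = cells$pco2[i], n = length(v), cv = cv)
    }))
  }))
  pooled <- aggregate(cv ~ trait, data = by_cell, FUN = mean,
                      na.action = stats::na.omit)
  list(by_cell = by_cell, pooled = pooled[match(traits, pooled$trait), ])
}

#' Pairwise Pearson correlation screen across traits
#'
#' All `n(n-1)/2` trait pairs (105 for the 15 study traits) are tested
#' with Pearson's correlation on pairwise-complete observations.
#' Significance uses a Bonferroni-corrected threshold (default
#' `alpha = 0.0005`, i.e. 0.05/105 rounded to the conventional reporting
#' value); pairs with `r > strong_r` and `p < strong_p` are additionally
#' flagged as strong.
#'
#' @param table a trait table.
#' @param traits trait columns to screen.
#' @param alpha Bonferroni-corrected significance threshold.
#' @param strong_r,strong_p thresholds for the "strong correlation" flag.
#' @param min_pairs minimum paired observations per test.
#' @return `data.frame` with `trait1`, `trait2`, `n`, `r`, `p`,
#'   `significant`, `strong`; the number of pairs is `nrow()`.
#' @export
correlation_screen <- function(table, traits = trait_names(),
                               alpha = 0.0005, strong_r = 0.80,
                               strong_p = 0.001, min_pairs = 3) {
  pairs <- utils::combn(traits, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- table[[pairs[1, j]]]; b <- table[[pairs[2, j]]]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < min_pairs) {
      return(data.frame(trait1 = pairs[1, j], trait2 = pairs[2, j],
                        n = sum(ok), r = NA_real_, p = NA_real_))
    }
    ct <- cor.test(a[ok], b[ok], method = "pearson")
    data.frame(trait1 = pairs[1, j], trait2 = pairs[2, j], n = sum(ok),
               r = unname(ct$estimate), p = ct$p.value)
  })
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p) & out$p < alpha
  out$strong <- !is.na(out$r) & out$r > strong_r & out$p < strong_p
  attr(out, "alpha") <- alpha
  out
}

#' Distribution and variance tests for the lateralisation indices
#'
#' Two-sample Kolmogorov-Smirnov tests compare the distribution of the
#' relative lateralisation index between treatment cells (all pairs, or
#' each treatment against the ambient cell), and Bartlett tests compare
#' the variances of both indices across the four cells.
#'
#' @param table a trait table with `lr` and `la` columns.
#' @param mode `"all_pairs"` (6 comparisons) or `"vs_ambient"` (3,
#'   against the low-temperature low-pCO2 cell).
#' @return list with `ks` (`data.frame` `cell1`, `cell2`, `d`, `p`) and
#'   `bartlett` (`data.frame` `index`, `k_squared`, `df`, `p`).
#' @export
lateralisation_tests <- function(table, mode = c("all_pairs", "vs_ambient")) {
  mode <- match.arg(mode)
  cell <- interaction(table$temperature, table$pco2, drop = TRUE, sep = "C/")
  cells <- levels(cell)
  ambient <- sprintf("%sC/%s", min(table$temperature), min(table$pco2))
  pairs <- utils::combn(cells, 2)
  if (mode == "vs_ambient") {
    keep <- pairs[1, ] == ambient | pairs[2, ] == ambient
    pairs <- pairs[, keep, drop = FALSE]
  }
  ks <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    x <- table$lr[cell == pairs[1, j]]
    y <- table$lr[cell == pairs[2, j]]
    kt <- suppressWarnings(ks.test(x, y))
    data.frame(cell1 = pairs[1, j], cell2 = pairs[2, j],
               d = unname(kt$statistic), p = kt$p.value)
  }))
  bartlett <- do.call(rbind, lapply(c("lr", "la"), function(ix) {
    bt <- bartlett.test(table[[ix]], cell)
    data.frame(index = ix, k_squared = unname(bt$statistic),
               df = unname(bt$parameter), p = bt$p.value)
  }))
  list(ks = ks, bartlett = bartlett)
}
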