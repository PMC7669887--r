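test_that("noise-free balanced data give exact cell-mean contrasts", {
  truths <- noiseless_truths()
  truths$mo2_min <- trait_truth(133.69, ratio_temperature = 1.1,
                                ratio_pco2 = 1.167, ratio_interaction = 1.2)
  roster <- generate_design(study_design(seed = 31))
  tab <- generate_trait_table(roster, truths, seed = 31)
  fit <- fit_trait_model(tab, "mo2_min", include_interaction = TRUE)
  b <- fit$coefficients
  expect_equal(unname(b["intercept"]), 133.69, tolerance = 1e-8)
  expect_equal(unname(b["high_pco2"]), 0.167 * 133.69, tolerance = 1e-6)
  expect_equal(unname(b["high_temperature"]), 0.1 * 133.69, tolerance = 1e-6)
  expect_equal(unname(b["interaction"]), 0.2 * 133.69, tolerance = 1e-6)
})

test_that("zero generative group variance is recovered as a singular-fit flag", {
  tab <- make_table(mo2_min = list(group_sd = 0, resid_sd = 15), seed = 41)
  fit <- fit_trait_model(tab, "mo2_min")
  expect_lt(fit$group_sd, 2)
})

test_that("adding a constant shifts only the intercept", {
  tab <- make_table(seed = 51)
  f1 <- fit_trait_model(tab, "mo2_min", include_interaction = FALSE)
  tab2 <- tab
  tab2$mo2_min <- tab$mo2_min + 100
  f2 <- fit_trait_model(tab2, "mo2_min", include_interaction = FALSE)
  expect_equal(unname(f2$coefficients["intercept"] -
                        f1$coefficients["intercept"]), 100, tolerance = 1e-6)
  expect_equal(f2$coefficients[c("high_pco2", "high_temperature")],
               f1$coefficients[c("high_pco2", "high_temperature")],
               tolerance = 1e-6)
})

test_that("simulated CIs collapse onto exact estimates when noise vanishes", {
  truths <- noiseless_truths()
  truths$hct <- trait_truth(0.21, ratio_temperature = 1.1)
  roster <- generate_design(study_design(seed = 61))
  tab <- generate_trait_table(roster, truths, seed = 61)
  # a zero-variance response makes the optimizer grumble; exactness is the point
  fit <- suppressWarnings(fit_trait_model(tab, "hct", include_interaction = FALSE))
  ci <- effect_ci(fit, n_sim = 500, seed = 6)
  expect_true(all(ci$ci_low <= ci$mean + 1e-8))
  expect_true(all(ci$mean <= ci$ci_high + 1e-8))
  expect_lt(max(ci$ci_high - ci$ci_low), 1e-6)
  expect_true(ci$significant[ci$term == "high_temperature"])
})

test_that("a generated pCO2 shift is recovered inside its simulation CI", {
  tab <- make_table(mo2_min = list(ratio_pco2 = 1.167), seed = 71,
                    design = study_design(groups_per_cell = 6,
                                          sharks_per_group = 4, seed = 71))
  fit <- fit_trait_model(tab, "mo2_min", include_interaction = FALSE)
  ci <- effect_ci(fit, n_sim = 1000, seed = 7)
  row <- ci[ci$term == "high_pco2", ]
  true_eff <- 0.167 * 133.69
  expect_gte(true_eff, row$ci_low)
  expect_lte(true_eff, row$ci_high)
})

test_that("missing trait values are dropped, never imputed", {
  tab <- make_table(seed = 81)
  tab$epoc[c(2, 5, 9)] <- NA
  fit <- fit_trait_model(tab, "epoc")
  expect_equal(fit$n, nrow(tab) - 3)
  tab$epoc <- NA_real_
  expect_error(fit_trait_model(tab, "epoc"), "non-missing")
  expect_error(fit_trait_model(tab, "nonesuch"), "unknown trait")
})

test_that("the CV screen matches hand arithmetic and is scale invariant", {
  mini <- data.frame(temperature = 28, pco2 = 650, group_id = "g",
                     x = c(10, 20, 30), y = 7)
  sc <- cv_screen(mini, traits = c("x", "y"))
  expect_equal(sc$pooled$cv[sc$pooled$trait == "x"], 50)
  expect_equal(sc$pooled$cv[sc$pooled$trait == "y"], 0)
  mini$x <- mini$x * 3.7
  expect_equal(cv_screen(mini, "x")$pooled$cv, 50)
})

test_that("the correlation screen enumerates 105 pairs over 15 traits", {
  tab <- make_table(seed = 91)
  scr <- correlation_screen(tab)
  expect_equal(nrow(scr), 15 * 14 / 2)
  expect_true(all(abs(scr$r) <= 1, na.rm = TRUE))
  # an exact linear pair is maximally correlated
  tab$shadow <- 2 * tab$odba
  scr2 <- correlation_screen(tab, traits = c("odba", "shadow", "lr"))
  expect_equal(scr2$r[scr2$trait1 == "odba" & scr2$trait2 == "shadow"], 1,
               tolerance = 1e-12)
})

test_that("KS and Bartlett screens behave at their boundary cases", {
  tab <- make_table(seed = 95)
  # identical distributions across cells: D = 0 against itself
  x <- tab$lr[tab$temperature == 28 & tab$pco2 == 650]
  expect_equal(unname(suppressWarnings(ks.test(x, x))$statistic), 0)
  res <- lateralisation_tests(tab)
  expect_equal(nrow(res$ks), 6)
  expect_true(all(res$ks$d >= 0 & res$ks$d <= 1))
  expect_equal(nrow(res$bartlett), 2)
  expect_true(all(res$bartlett$k_squared >= 0))
  amb <- lateralisation_tests(tab, mode = "vs_ambient")
  expect_equal(nrow(amb$ks), 3)
  # disjoint supports: D = 1
  tab2 <- tab
  sel <- tab2$temperature == 31 & tab2$pco2 == 1050
  tab2$lr[sel] <- tab2$lr[sel] + 1000
  res2 <- lateralisation_tests(tab2)
  expect_equal(max(res2$ks$d), 1)
})
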