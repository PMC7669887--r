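test_that("default design yields 4 crossed cells, 3 groups each, 3-4 sharks per group", {
  roster <- generate_design(study_design(seed = 3))
  cells <- unique(roster[, c("temperature", "pco2")])
  expect_equal(nrow(cells), 4)
  expect_setequal(cells$temperature, c(28, 31))
  expect_setequal(cells$pco2, c(650, 1050))
  expect_equal(length(unique(roster$group_id)), 12)
  sizes <- table(roster$group_id)
  expect_true(all(sizes %in% 3:4))
  expect_gte(nrow(roster), 36)
  expect_lte(nrow(roster), 48)
  # each shark in exactly one group, masses inside the truncation bounds
  expect_equal(anyDuplicated(roster$id), 0)
  expect_true(all(roster$mass_kg >= 0.7 & roster$mass_kg <= 1.4))
})

test_that("roster generation is deterministic in the seed and stable under growth", {
  a <- generate_design(study_design(seed = 11))
  b <- generate_design(study_design(seed = 11))
  expect_identical(a, b)
  c <- generate_design(study_design(seed = 12))
  expect_false(identical(a$mass_kg, c$mass_kg))
  # adding groups leaves existing sharks' draws untouched (child seeds)
  big <- generate_design(study_design(groups_per_cell = 4, seed = 11))
  shared <- intersect(a$id, big$id)
  expect_true(length(shared) > 0)
  expect_equal(a$mass_kg[match(shared, a$id)],
               big$mass_kg[match(shared, big$id)])
})

test_that("degenerate and non-crossable designs are handled", {
  one <- generate_design(study_design(temperature_levels = 28,
                                      pco2_levels = 650,
                                      groups_per_cell = 1,
                                      sharks_per_group = 1, seed = 1))
  expect_equal(nrow(one), 1)
  expect_error(study_design(temperature_levels = numeric(0)), "crossable")
  expect_error(study_design(groups_per_cell = 0), ">= 1")
})

test_that("trait generation follows the additive ratio model exactly when noise-free", {
  null_truth <- trait_truth(intercept = 133.69)
  expect_identical(
    generate_trait(null_truth, FALSE, FALSE, "g1", "s1", seed = 5), 133.69)
  warm <- trait_truth(intercept = 133.69, ratio_temperature = 1.67)
  expect_equal(generate_trait(warm, TRUE, FALSE, "g1", "s1", seed = 5),
               223.2623, tolerance = 1e-10)
  # interaction only contributes when both factors are high
  both <- trait_truth(133.69, 1.67, 1.06, 1.60)
  expect_equal(trait_cell_mean(both, TRUE, TRUE),
               133.69 + 0.67 * 133.69 + 0.06 * 133.69 + 0.60 * 133.69)
  expect_equal(trait_cell_mean(both, FALSE, TRUE), 133.69 * 1.06)
})

test_that("effects are additive on the trait scale: doubling (r-1) doubles the shift", {
  base <- trait_truth(100, ratio_pco2 = 1.3)
  doubled <- trait_truth(100, ratio_pco2 = 1.6)
  shift1 <- trait_cell_mean(base, FALSE, TRUE) - 100
  shift2 <- trait_cell_mean(doubled, FALSE, TRUE) - 100
  expect_equal(shift2, 2 * shift1)
})

test_that("empirical group and residual sds match the generative truth within 5%", {
  truth <- trait_truth(intercept = 0, group_sd = 1, resid_sd = 2)
  n_g <- 100; n_s <- 100
  vals <- matrix(NA_real_, n_g, n_s)
  for (g in seq_len(n_g)) {
    for (s in seq_len(n_s)) {
      vals[g, s] <- generate_trait(truth, FALSE, FALSE,
                                   paste0("g", g), paste0("s", s), seed = 77)
    }
  }
  group_means <- rowMeans(vals)
  resid_sd_hat <- sqrt(mean(apply(vals, 1, var)))
  group_sd_hat <- sqrt(max(var(group_means) - resid_sd_hat^2 / n_s, 0))
  expect_equal(resid_sd_hat, 2, tolerance = 0.05)
  expect_equal(group_sd_hat, 1, tolerance = 0.05)
})

test_that("trait table carries all 15 traits with exact derived identities", {
  tab <- make_table(seed = 21)
  expect_true(all(trait_names() %in% names(tab)))
  expect_equal(tab$aas, tab$mo2_max - tab$mo2_min)
  expect_equal(tab$fas, tab$mo2_max / tab$mo2_min)
  expect_equal(tab$mchc, tab$hb / tab$hct)
})

test_that("turn generator honours the bias probability and the maze-side split", {
  all_right <- generate_turns(1, 20, seed = 1)
  expect_equal(lateralisation(all_right)$lr, 100)
  expect_equal(table(all_right$trial_side)[["A"]], 10)
  expect_identical(generate_turns(0.7, 20, seed = 4),
                   generate_turns(0.7, 20, seed = 4))
  # binomial expectation: E[L_R] = (2p - 1) * 100 = 50 at p = 0.75
  lrs <- vapply(1:2000, function(i) {
    lateralisation(generate_turns(0.75, 20, seed = i))$lr
  }, numeric(1))
  expect_equal(mean(lrs), 50, tolerance = 0.04)
  # symmetry at p = 0.5
  lr0 <- vapply(1:2000, function(i) {
    lateralisation(generate_turns(0.5, 20, seed = i + 5000))$lr
  }, numeric(1))
  expect_lt(abs(mean(lr0)), 2)
  expect_error(generate_turns(0.5, n_turns = 15), "n_turns")
})

test_that("noise-free blood panels are self-consistent with their truth", {
  panel <- generate_blood_panel(true_hct = 0.21, true_mchc = 2.07, seed = 9)
  traits <- blood_panel_traits(panel)
  expect_equal(traits$mchc, 2.07, tolerance = 1e-12)
  expect_equal(traits$hct, 0.21, tolerance = 1e-12)
  expect_equal(traits$hb, 2.07 * 0.21, tolerance = 1e-12)
})
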