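test_that("noiseless pipeline recovers all six metrics within 1% of truth", {
  trace <- generate_o2_trace(mass_kg = 1.1, mo2_max = 360.15,
                             mo2_min = 133.69, recovery_k = 0.5)
  truth <- attr(trace, "truth")
  m <- respirometry_metrics(trace)
  for (metric in c("mo2_min", "mo2_max", "aas", "fas", "epoc",
                   "recovery_time")) {
    expect_equal(m[[metric]], truth[[metric]], tolerance = 0.01,
                 label = metric)
  }
  expect_equal(m$n_retained, 96)
})

test_that("a constant-rate animal yields 96 identical determinations equal to truth", {
  trace <- generate_o2_trace(mass_kg = 1, mo2_max = 150, mo2_min = 150)
  dets <- extract_determinations(trace)
  expect_equal(nrow(dets), 96)
  expect_lt(diff(range(dets$mo2)) / mean(dets$mo2), 1e-6)
  expect_equal(mean(dets$mo2), 150, tolerance = 1e-6)
  expect_true(all(dets$r_squared > 0.95))
})

test_that("flat phases give zero uptake and the mass correction is exact", {
  flat <- generate_o2_trace(mass_kg = 1, mo2_max = 0, mo2_min = 0)
  dets <- extract_determinations(flat)
  expect_equal(max(abs(dets$mo2)), 0, tolerance = 1e-9)
  # MO2 = |slope| * V_eff * 3600 / mass^0.89 on a hand-built phase
  tr <- data.frame(time_s = 0:599, o2_mg_l = 7 - 0.001 * (0:599),
                   phase = "measure")
  attr(tr, "volume_l") <- 25
  attr(tr, "animal_mass_kg") <- 1.2
  attr(tr, "animal_volume_l") <- 1.2
  d <- extract_determinations(tr)
  expect_equal(d$mo2, 0.001 * (25 - 1.2) * 3600 / 1.2^0.89,
               tolerance = 1e-12)
  # 1 kg animal: correction is the identity
  attr(tr, "animal_mass_kg") <- 1
  attr(tr, "animal_volume_l") <- 1
  expect_equal(extract_determinations(tr)$mo2, 0.001 * 24 * 3600,
               tolerance = 1e-12)
})

test_that("mass-corrected uptake scales as m^(1-0.89) for uptake linear in mass", {
  # whole-animal uptake proportional to mass => corrected MO2 ~ m^0.11
  m1 <- 1.0; m2 <- 1.3
  slope1 <- 0.001
  slope2 <- slope1 * m2 / m1
  mk <- function(slope, mass) {
    tr <- data.frame(time_s = 0:599, o2_mg_l = 7 - slope * (0:599),
                     phase = "measure")
    attr(tr, "volume_l") <- 30
    attr(tr, "animal_mass_kg") <- mass
    attr(tr, "animal_volume_l") <- 0   # fix V_eff so only mass varies
    extract_determinations(tr)$mo2
  }
  expect_equal(mk(slope2, m2) / mk(slope1, m1), (m2 / m1)^(1 - 0.89),
               tolerance = 1e-10)
})

test_that("linear background drift biases raw uptake and is removed exactly by correction", {
  trace <- generate_o2_trace(mo2_max = 300, mo2_min = 140, recovery_k = 0.6,
                             background_start = 2, background_end = 6)
  raw <- extract_determinations(trace)
  corr <- background_correct(raw, trace)
  # late determinations: truth ~ mo2_min; raw is inflated, corrected is not
  late_raw <- raw$mo2[raw$animal_h > 12]
  late_corr <- corr$mo2[corr$animal_h > 12]
  expect_gt(mean(late_raw) - 140, 1)
  expect_lt(abs(mean(late_corr) - 140) / 140, 0.005)
  expect_true(all(corr$background_corrected))
})

test_that("zero background correction is the identity", {
  trace <- generate_o2_trace(mo2_max = 200, mo2_min = 150)
  raw <- extract_determinations(trace)
  corr <- background_correct(raw, trace)
  expect_equal(corr$mo2, raw$mo2, tolerance = 1e-12)
})

test_that("MLND recovers the lower mode of a bimodal determination set", {
  x <- with_seed(42, c(rnorm(67, 140, 10), rnorm(29, 260, 20)))
  fit <- mo2_min_mlnd(x)
  expect_lt(abs(fit$mo2_min - 140), 5)
  expect_gte(fit$n_components, 2)
})

test_that("MLND degenerates gracefully and respects its bounds", {
  expect_equal(mo2_min_mlnd(rep(120, 30))$mo2_min, 120)
  expect_error(mo2_min_mlnd(rnorm(10, 100, 5)), "too few")
  # lowest-component mean never exceeds the overall mean
  for (s in 1:5) {
    x <- with_seed(s, rnorm(96, 150, 25) + rbinom(96, 1, 0.3) * 80)
    expect_lte(mo2_min_mlnd(x)$mo2_min, mean(x))
  }
})

test_that("maximum uptake comes from the earliest window of a monotone decay", {
  trace <- generate_o2_trace(mo2_max = 360, mo2_min = 130, recovery_k = 0.5)
  mx <- mo2_max(trace)
  # first measure phase starts when the animal enters (t = 1800 s here)
  expect_equal(mx$window_start_s, attr(trace, "animal_start_s"))
  expect_equal(mx$mo2_max, 360, tolerance = 0.01)
})

test_that("a metabolically inert trace yields near-zero maximum uptake", {
  flat <- generate_o2_trace(mo2_max = 0, mo2_min = 0)
  expect_lt(abs(mo2_max(flat)$mo2_max), 1e-6)
})

test_that("EPOC closed form matches numerical integration of the fitted curve", {
  # y(t) = 200 exp(-0.5 t) + 100, MO2Min = 150 -> t* = ln(4)/0.5
  tt <- seq(0, 20, by = 0.25)
  dets <- data.frame(animal_h = tt, mo2 = 200 * exp(-0.5 * tt) + 100,
                     retained = TRUE)
  res <- epoc_and_recovery(dets, mo2_min = 150)
  t_star <- log(4) / 0.5
  oracle <- integrate(function(t) 200 * exp(-0.5 * t) - 50, 0, t_star)$value
  expect_equal(res$recovery_h, t_star, tolerance = 1e-6)
  expect_equal(res$epoc, oracle, tolerance = 1e-3)
  expect_false(res$approximate)
  # trapezoidal cross-check of the analytic area
  grid <- seq(0, res$recovery_h, length.out = 4001)
  yfit <- res$a * exp(-res$k * grid) + res$c
  trap <- sum(diff(grid) * (head(yfit - 150, -1) + tail(yfit - 150, -1)) / 2)
  expect_equal(res$epoc, trap, tolerance = 1e-3)
})

test_that("an animal starting at MO2Min has zero EPOC and instant recovery", {
  tt <- seq(0, 20, by = 0.25)
  dets <- data.frame(animal_h = tt, mo2 = 10 * exp(-0.4 * tt) + 140,
                     retained = TRUE)
  res <- epoc_and_recovery(dets, mo2_min = 151)
  expect_equal(res$epoc, 0)
  expect_equal(res$recovery_h, 0)
})

test_that("non-intersecting fits fall back to the proximity rule and are flagged", {
  tt <- seq(0, 20, by = 0.25)
  dets <- data.frame(animal_h = tt, mo2 = 100 * exp(-0.2 * tt) + 150,
                     retained = TRUE)
  res <- epoc_and_recovery(dets, mo2_min = 150)
  expect_true(res$approximate)
  expect_equal(res$recovery_h, log(100 / 15) / 0.2, tolerance = 1e-3)
})

test_that("geometry violations are rejected", {
  expect_error(generate_o2_trace(mass_kg = 30, animal_volume_l = 30,
                                 config = respirometer_config(volume_l = 25)),
               "exceed")
})
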