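test_that("lateralisation indices match the worked turn records", {
  expect_equal(lateralisation(rep("R", 20))$lr, 100)
  expect_equal(lateralisation(rep("R", 20))$la, 100)
  expect_equal(lateralisation(c(rep("R", 10), rep("L", 10)))$lr, 0)
  res <- lateralisation(c(rep("R", 6), rep("L", 14)))
  expect_equal(res$lr, -40)
  expect_equal(res$la, 40)
  expect_error(lateralisation(character(0)), "no turns")
})

test_that("swapping left/right labels negates L_R and preserves L_A", {
  for (s in 1:10) {
    rec <- generate_turns(0.3 + 0.05 * s, 20, seed = s)
    swapped <- rec
    swapped$turn_direction <- ifelse(rec$turn_direction == "R", "L", "R")
    a <- lateralisation(rec); b <- lateralisation(swapped)
    expect_equal(b$lr, -a$lr)
    expect_equal(b$la, a$la)
    expect_equal(a$la, abs(a$lr))
    expect_true(a$lr %% 10 == 0)   # 20 turns => multiples of 10
  }
})

test_that("ODBA of a constant trace is zero and of a pure sine is 2A/pi", {
  const <- data.frame(time_s = seq(0, 60, by = 0.04),
                      x_g = 0.3, y_g = -0.1, z_g = 0.95)
  expect_equal(max(odba_series(const)$odba), 0, tolerance = 1e-12)
  sine <- generate_accel_trace(duration_s = 600, amplitudes = c(0.1, 0, 0),
                               sway_period_s = Inf, noise_sd = 0)
  expect_equal(mean(odba_series(sine)$odba), 2 * 0.1 / pi, tolerance = 0.02)
})

test_that("ODBA is invariant to axis permutation and to constant offsets", {
  tr <- generate_accel_trace(duration_s = 120, amplitudes = c(0.08, 0.04, 0.02),
                             noise_sd = 0.01, seed = 2)
  od <- odba_series(tr)
  perm <- tr
  names(perm)[2:4] <- c("y_g", "z_g", "x_g")
  expect_equal(odba_series(perm)$odba, od$odba, tolerance = 1e-12)
  shifted <- tr
  shifted$x_g <- tr$x_g + 0.5
  shifted$z_g <- tr$z_g - 1
  expect_equal(mean(odba_series(shifted)$odba), mean(od$odba),
               tolerance = 0.01)
})

test_that("ODBA requires uniform sampling and adequate rates", {
  bad <- data.frame(time_s = cumsum(runif(100, 0.02, 0.06)),
                    x_g = 0, y_g = 0, z_g = 1)
  expect_error(odba_series(bad), "non-uniform")
  expect_error(generate_accel_trace(hz = 3, tailbeat_hz = 2), "aliasing")
})

test_that("activity level averages the half-open clock window only", {
  od <- data.frame(time_s = seq(0, 7200 - 1, by = 1),
                   odba = rep(c(1, 9), each = 3600))
  attr(od, "clock_start_s") <- 14 * 3600
  # window [14:00, 15:00): only the first hour's value
  expect_equal(activity_level(od, "14:00", "15:00"), 1)
  # sample at exactly 15:00 belongs to the next window
  expect_equal(activity_level(od, "15:00", "16:00"), 9)
  expect_error(activity_level(od, "18:00", "19:00"), "clock window")
  expect_equal(activity_level(od, "14:00", "16:00"), 5)
})

test_that("windowed activity recovers the generator's programmed level", {
  tr <- generate_accel_trace(duration_s = 5 * 3600, clock_start = "10:30",
                             noise_sd = 0.005, seed = 8)
  od <- odba_series(tr)
  lvl <- activity_level(od, "11:00", "15:00")
  # noise inflates |dynamic| slightly; truth must be recovered within 2%
  expect_equal(lvl, attr(tr, "true_odba"), tolerance = 0.02)
  expect_gte(lvl, min(od$odba))
  expect_lte(lvl, max(od$odba))
})

test_that("hypoxia tolerance interpolates the saturation at the event time", {
  trial <- list(saturation = data.frame(time_s = 0:10,
                                        sat_pct = seq(30, 20, by = -1)),
                os_time_s = 5)
  expect_equal(hypoxia_tolerance(trial), 25)
  trial$os_time_s <- 5.5
  expect_equal(hypoxia_tolerance(trial), 24.5)
  trial$os_time_s <- 99
  expect_error(hypoxia_tolerance(trial), "outside")
  gen <- generate_hypoxia_trial(os_threshold = 24.52, seed = 3)
  expect_equal(hypoxia_tolerance(gen), 24.52, tolerance = 1e-9)
})
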