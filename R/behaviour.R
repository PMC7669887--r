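# Behavioural traits: detour-maze lateralisation indices, overall dynamic
# body acceleration (ODBA) and windowed activity level, and the
# hypoxia-tolerance endpoint.

#' Lateralisation indices from a turn record
#'
#' The relative lateralisation index is
#' `L_R = (right - left) / (right + left) * 100` (positive = right-turning
#' bias) and the absolute index is `L_A = |L_R|` (strength of
#' lateralisation regardless of direction).
#'
#' @param turns a `data.frame` with a `turn_direction` column of "L"/"R"
#'   values (e.g. from [generate_turns()] or [read_turns_csv()]), or a
#'   character vector of "L"/"R".
#' @return list with `lr`, `la`, `n_right`, `n_left`.
#' @export
lateralisation <- function(turns) {
  dirs <- if (is.data.frame(turns)) turns$turn_direction else turns
  dirs <- toupper(as.character(dirs))
  if (length(dirs) == 0) stop("turn record contains no turns")
  if (!all(dirs %in% c("L", "R"))) stop("turn directions must be 'L' or 'R'")
  r <- sum(dirs == "R"); l <- sum(dirs == "L")
  lr <- (r - l) / (r + l) * 100
  list(lr = lr, la = abs(lr), n_right = r, n_left = l)
}

#' Simulate a detour-maze turn record
#'
#' Bernoulli turning decisions with right-turn probability `right_bias_p`,
#' half initiated from each side of the maze (to account for maze
#' asymmetry).
#'
#' @param right_bias_p probability of a right turn, in `[0, 1]`.
#' @param n_turns total turns (even; half per maze side).
#' @param seed integer seed.
#' @param shark_id optional label attached to the record.
#' @return `data.frame` with `shark_id`, `trial_side` ("A"/"B"),
#'   `turn_direction` ("L"/"R").
#' @export
generate_turns <- function(right_bias_p = 0.5, n_turns = 20, seed = 1,
                           shark_id = "shark") {
  stopifnot(right_bias_p >= 0, right_bias_p <= 1, n_turns >= 2,
            n_turns %% 2 == 0)
  dirs <- with_seed(child_seed(seed, "turns", shark_id),
                    rbinom(n_turns, 1, right_bias_p))
  data.frame(shark_id = shark_id,
             trial_side = rep(c("A", "B"), each = n_turns / 2),
             turn_direction = ifelse(dirs == 1, "R", "L"),
             stringsAsFactors = FALSE)
}

#' Overall dynamic body acceleration per sample
#'
#' For each axis the static (postural/gravity) component is estimated by a
#' centred running mean over `window_s` seconds (shrinking window at the
#' trace edges) and subtracted from the raw signal; ODBA at each sample is
#' the sum over axes of the absolute dynamic components.
#'
#' @param trace acceleration `data.frame` with `time_s`, `x_g`, `y_g`,
#'   `z_g` sampled uniformly (e.g. [generate_accel_trace()] or
#'   [read_accel_csv()]).
#' @param window_s running-mean window, s.
#' @return `data.frame` with `time_s` and `odba` (g); carries over the
#'   `clock_start_s` attribute if present.
#' @export
odba_series <- function(trace, window_s = 2) {
  stopifnot(all(c("time_s", "x_g", "y_g", "z_g") %in% names(trace)))
  dts <- diff(trace$time_s)
  if (length(dts) == 0) stop("trace shorter than the running-mean window")
  if (max(dts) - min(dts) > 1e-6 * median(dts)) {
    stop("non-uniform sampling; resample the trace first")
  }
  hz <- 1 / median(dts)
  k <- max(3L, 2L * floor(window_s * hz / 2) + 1L)   # odd window
  if (nrow(trace) < k) stop("trace shorter than the running-mean window")
  dyn <- vapply(c("x_g", "y_g", "z_g"), function(ax) {
    abs(trace[[ax]] - running_mean_centred(trace[[ax]], k))
  }, numeric(nrow(trace)))
  out <- data.frame(time_s = trace$time_s, odba = rowSums(dyn))
  attr(out, "clock_start_s") <- attr(trace, "clock_start_s")
  out
}

# "HH:MM" -> seconds since midnight
clock_to_s <- function(x) {
  if (is.numeric(x)) return(x)
  parts <- as.numeric(strsplit(x, ":", fixed = TRUE)[[1]])
  parts[1] * 3600 + parts[2] * 60 + if (length(parts) > 2) parts[3] else 0
}

#' Mean activity level over a clock window
#'
#' Arithmetic mean of ODBA samples whose wall-clock timestamps fall in the
#' half-open window `[start, end)`; the default 1100-1500 window gives
#' animals two hours to resume routine activity after tagging before
#' scoring begins.
#'
#' @param odba an ODBA series from [odba_series()]; its `clock_start_s`
#'   attribute (seconds since midnight at the first sample) anchors the
#'   wall clock.
#' @param start,end window bounds, "HH:MM" strings or seconds since
#'   midnight.
#' @return mean ODBA (g) in the window.
#' @export
activity_level <- function(odba, start = "11:00", end = "15:00") {
  clock0 <- attr(odba, "clock_start_s")
  if (is.null(clock0)) stop("ODBA series lacks a clock_start_s attribute")
  clock <- clock0 + odba$time_s - odba$time_s[1]
  lo <- clock_to_s(start); hi <- clock_to_s(end)
  sel <- clock >= lo & clock < hi
  if (!any(sel)) stop("no ODBA samples fall inside the clock window")
  mean(odba$odba[sel])
}

#' Simulate a tri-axial acceleration trace with known true ODBA
#'
#' The signal is a slowly reorienting gravity component plus a sinusoidal
#' tail-beat dynamic component plus Gaussian sensor noise. For a rectified
#' sine of amplitude `A` the mean absolute value is `2A/pi`, so the true
#' mean ODBA is `(2/pi) * sum(amplitudes)`.
#'
#' @param duration_s trace length, s.
#' @param hz sampling rate (must exceed twice the tail-beat frequency).
#' @param amplitudes length-3 dynamic amplitudes per axis (g).
#' @param tailbeat_hz tail-beat frequency, Hz. The default (~1.96 Hz, a
#'   routine-swimming tail-beat) is chosen to complete an integer number
#'   of cycles per 2-s averaging window at 25 Hz, so the running-mean
#'   static estimate has zero spectral leakage and the `2A/pi` identity
#'   holds exactly; off-grid frequencies bias ODBA by up to the window's
#'   Dirichlet factor (~2% at 1.5 Hz).
#' @param gravity length-3 unit-norm gravity orientation at the start.
#' @param sway_period_s period of the slow gravity reorientation, s
#'   (`Inf` for a fixed posture).
#' @param noise_sd sensor noise, g.
#' @param clock_start wall-clock time of the first sample ("HH:MM" or
#'   seconds since midnight).
#' @param seed integer seed.
#' @return `data.frame` `time_s`, `x_g`, `y_g`, `z_g` with attributes
#'   `clock_start_s` and `true_odba`.
#' @export
generate_accel_trace <- function(duration_s = 3600, hz = 25,
                                 amplitudes = c(0.08, 0.04, 0.02),
                                 tailbeat_hz = 25 * 4 / 51,
                                 gravity = c(0, 0, 1),
                                 sway_period_s = 600,
                                 noise_sd = 0,
                                 clock_start = "10:00", seed = 1) {
  if (hz < 2 * tailbeat_hz) {
    stop("sampling rate below twice the tail-beat frequency (aliasing)")
  }
  stopifnot(length(amplitudes) == 3, all(amplitudes >= 0))
  tt <- seq(0, duration_s - 1 / hz, by = 1 / hz)
  n <- length(tt)
  gravity <- gravity / sqrt(sum(gravity^2))
  # slow rotation of the gravity vector about the x axis
  ang <- if (is.finite(sway_period_s)) {
    0.2 * sin(2 * pi * tt / sway_period_s)
  } else rep(0, n)
  gx <- rep(gravity[1], n)
  gy <- gravity[2] * cos(ang) - gravity[3] * sin(ang)
  gz <- gravity[2] * sin(ang) + gravity[3] * cos(ang)
  phase <- 2 * pi * tailbeat_hz * tt
  dyn <- cbind(amplitudes[1] * sin(phase),
               amplitudes[2] * sin(phase + pi / 3),
               amplitudes[3] * sin(phase + 2 * pi / 3))
  noise <- if (noise_sd > 0) {
    with_seed(child_seed(seed, "accel"),
              matrix(rnorm(3 * n, 0, noise_sd), ncol = 3))
  } else 0
  sig <- cbind(gx, gy, gz) + dyn + noise
  out <- data.frame(time_s = tt, x_g = sig[, 1], y_g = sig[, 2],
                    z_g = sig[, 3])
  attr(out, "clock_start_s") <- clock_to_s(clock_start)
  attr(out, "true_odba") <- 2 / pi * sum(amplitudes)
  out
}

#' Hypoxia tolerance: air saturation at the onset of muscle spasms
#'
#' Linear interpolation of the trial's saturation series at the recorded
#' event time.
#'
#' @param trial a hypoxia trial: list with `saturation` (`data.frame`
#'   `time_s`, `sat_pct`) and `os_time_s` (event time), e.g. from
#'   [generate_hypoxia_trial()].
#' @return percent air saturation at the onset of muscle spasms.
#' @export
hypoxia_tolerance <- function(trial) {
  s <- trial$saturation
  t_os <- trial$os_time_s
  stopifnot(!is.null(s), !is.null(t_os))
  if (t_os < min(s$time_s) || t_os > max(s$time_s)) {
    stop("onset-of-spasms time falls outside the recorded trace")
  }
  approx(s$time_s, s$sat_pct, xout = t_os)$y
}

#' Simulate a hypoxia-tolerance trial with a programmed endpoint
#'
#' Air saturation is drawn down linearly from 100% by nitrogen bubbling at
#' `drawdown_pct_min` percent per minute; the onset of muscle spasms is
#' programmed at `os_threshold` percent saturation and the event time is
#' recorded from the true (noise-free) drawdown.
#'
#' @param os_threshold true saturation at the onset of spasms, %.
#' @param drawdown_pct_min drawdown rate, % air saturation per minute.
#' @param hz sampling rate of the oxygen meter.
#' @param noise_sd measurement noise on recorded saturation, %.
#' @param floor_pct run the trace down to this saturation.
#' @param seed integer seed.
#' @return list with `saturation` (`data.frame` `time_s`, `sat_pct`),
#'   `os_time_s`, and `true_os_saturation`.
#' @export
generate_hypoxia_trial <- function(os_threshold = 24.5,
                                   drawdown_pct_min = 8.9, hz = 1,
                                   noise_sd = 0, floor_pct = 5, seed = 1) {
  stopifnot(os_threshold > floor_pct, os_threshold < 100,
            drawdown_pct_min > 0)
  dur <- (100 - floor_pct) / drawdown_pct_min * 60
  tt <- seq(0, dur, by = 1 / hz)
  sat <- 100 - drawdown_pct_min * tt / 60
  if (noise_sd > 0) {
    sat <- sat + with_seed(child_seed(seed, "hypoxia"),
                           rnorm(length(tt), 0, noise_sd))
  }
  os_time <- (100 - os_threshold) / drawdown_pct_min * 60
  list(saturation = data.frame(time_s = tt, sat_pct = sat),
       os_time_s = os_time, true_os_saturation = os_threshold)
}
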