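# Synthetic intermittent-flow respirometry traces with known ground truth.

#' Configure a simulated intermittent-flow respirometer
#'
#' Defaults follow a 24-h protocol of 96 oxygen-uptake determinations:
#' 10 min measure / 5 min flush cycles (96 x 15 min = 24 h), bracketed by
#' empty-chamber background recordings.
#'
#' @param volume_l respirometer volume, L.
#' @param sample_hz oxygen-probe sampling rate, Hz.
#' @param n_cycles number of measure/flush cycles.
#' @param measure_s,flush_s phase durations, s.
#' @param background_s duration of each empty-chamber background recording.
#' @param o2_saturation dissolved oxygen at full saturation, mg/L.
#' @return list of class `respirometer_config`.
#' @export
respirometer_config <- function(volume_l = 25, sample_hz = 1,
                                n_cycles = 96, measure_s = 600,
                                flush_s = 300, background_s = 1800,
                                o2_saturation = 6.8) {
  stopifnot(volume_l > 0, sample_hz > 0, n_cycles >= 1)
  structure(list(volume_l = volume_l, sample_hz = sample_hz,
                 n_cycles = n_cycles, measure_s = measure_s,
                 flush_s = flush_s, background_s = background_s,
                 o2_saturation = o2_saturation),
            class = "respirometer_config")
}

#' Simulate a post-exercise oxygen trace with known metabolic truth
#'
#' The animal's true mass-corrected uptake follows an exponential recovery
#' from `mo2_max` toward `mo2_min`:
#' `MO2(t) = mo2_min + (mo2_max - mo2_min) * exp(-k t)` (t in hours since
#' entering the chamber, immediately post-exercise). Within each measure
#' phase the dissolved-oxygen decline is the exact integral of animal
#' uptake (scaled by `mass^0.89` and the effective water volume) plus
#' background respiration, which drifts linearly over the session between
#' `background_start` and `background_end` (chamber-wide mg O2/h). Flush
#' phases restore saturation; empty-chamber background phases bracket the
#' trial.
#'
#' Because the recovery asymptote equals `mo2_min`, the fitted decay curve
#' never strictly crosses it; the stored ground truth for EPOC and recovery
#' time therefore uses the same proximity rule as [epoc_and_recovery()]:
#' recovery is when excess uptake falls to `recovery_threshold * mo2_min`.
#'
#' @param mass_kg animal mass, kg.
#' @param mo2_max,mo2_min true maximum/minimum uptake, mg O2 kg^-0.89 h^-1.
#' @param recovery_k exponential recovery rate, h^-1.
#' @param background_start,background_end chamber background respiration at
#'   session start/end, mg O2 h^-1 (linear drift between).
#' @param config a [respirometer_config()].
#' @param animal_volume_l body volume displaced, L; defaults to
#'   `mass_kg` (1 kg/L).
#' @param noise_sd Gaussian probe noise, mg/L.
#' @param recovery_threshold proximity rule for the stored EPOC/recovery
#'   truth (fraction of `mo2_min`).
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @return a `data.frame` `time_s`, `o2_mg_l`, `phase` with attributes
#'   `volume_l`, `animal_mass_kg`, `animal_volume_l`, `sample_hz`, `truth`
#'   (list of the six true metrics plus generator parameters) and
#'   `animal_start_s` (trace time at which the animal entered).
#' @export
generate_o2_trace <- function(mass_kg = 1.0, mo2_max = 360.15,
                              mo2_min = 133.69, recovery_k = 0.5,
                              background_start = 0, background_end = 0,
                              config = respirometer_config(),
                              animal_volume_l = mass_kg,
                              noise_sd = 0, recovery_threshold = 0.1,
                              seed = 1) {
  stopifnot(inherits(config, "respirometer_config"))
  if (animal_volume_l >= config$volume_l) {
    stop("respirometer volume must exceed animal volume")
  }
  stopifnot(mass_kg > 0, mo2_max >= mo2_min, mo2_min >= 0, recovery_k > 0)
  v_eff <- config$volume_l - animal_volume_l
  hz <- config$sample_hz
  dt <- 1 / hz
  amp <- mo2_max - mo2_min

  # cumulative animal uptake (mg, per kg^0.89) over t hours in the chamber
  uptake_int <- function(t_h) {
    mo2_min * t_h + amp * (1 - exp(-recovery_k * t_h)) / recovery_k
  }
  session_h <- (2 * config$background_s +
                config$n_cycles * (config$measure_s + config$flush_s)) / 3600
  # cumulative background consumption (mg) over session time s_h hours
  bg_int <- function(s_h) {
    background_start * s_h +
      (background_end - background_start) * s_h^2 / (2 * session_h)
  }

  segments <- list()
  t0 <- 0
  add_segment <- function(label, dur_s) {
    tt <- seq(t0, t0 + dur_s - dt, by = dt)
    segments[[length(segments) + 1]] <<- list(label = label, time = tt)
    t0 <<- t0 + dur_s
  }
  add_segment("background_pre", config$background_s)
  for (i in seq_len(config$n_cycles)) {
    add_segment("measure", config$measure_s)
    add_segment("flush", config$flush_s)
  }
  add_segment("background_post", config$background_s)

  animal_start <- config$background_s
  sat <- config$o2_saturation
  out <- lapply(segments, function(seg) {
    tt <- seg$time
    o2 <- if (seg$label %in% c("background_pre", "background_post")) {
      s_h <- tt / 3600
      sat - (bg_int(s_h) - bg_int(tt[1] / 3600)) / config$volume_l
    } else if (seg$label == "measure") {
      a_h <- (tt - animal_start) / 3600
      s_h <- tt / 3600
      drop <- mass_kg^0.89 * (uptake_int(a_h) - uptake_int(a_h[1])) +
        (bg_int(s_h) - bg_int(tt[1] / 3600))
      sat - drop / v_eff
    } else {
      rep(sat, length(tt))
    }
    data.frame(time_s = tt, o2_mg_l = o2, phase = seg$label,
               stringsAsFactors = FALSE)
  })
  trace <- do.call(rbind, out)
  rownames(trace) <- NULL
  if (noise_sd > 0) {
    trace$o2_mg_l <- trace$o2_mg_l +
      with_seed(child_seed(seed, "o2noise"),
                rnorm(nrow(trace), 0, noise_sd))
  }

  # stored ground truth, proximity rule for the EPOC/recovery pair
  thr <- recovery_threshold * mo2_min
  recovery_true <- if (amp <= thr) 0 else log(amp / thr) / recovery_k
  epoc_true <- if (amp <= thr) 0 else (amp - thr) / recovery_k

  attr(trace, "volume_l") <- config$volume_l
  attr(trace, "animal_mass_kg") <- mass_kg
  attr(trace, "animal_volume_l") <- animal_volume_l
  attr(trace, "sample_hz") <- hz
  attr(trace, "animal_start_s") <- animal_start
  attr(trace, "truth") <- list(
    mo2_min = mo2_min, mo2_max = mo2_max,
    aas = mo2_max - mo2_min, fas = mo2_max / mo2_min,
    epoc = epoc_true, recovery_time = recovery_true,
    recovery_k = recovery_k, recovery_threshold = recovery_threshold,
    background_start = background_start, background_end = background_end)
  trace
}
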