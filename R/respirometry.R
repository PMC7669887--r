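# Oxygen-uptake metrics from intermittent-flow respirometry traces:
# per-phase slope extraction, background correction, minimum uptake by the
# mean of the lowest normal distribution (MLND), maximum uptake from rolling
# 30-s slopes, aerobic scope, EPOC and recovery time.

MASS_SCALING_EXPONENT <- 0.89

trace_attr <- function(trace, name) {
  val <- attr(trace, name)
  if (is.null(val)) stop(sprintf("trace lacks attribute '%s'", name))
  val
}

#' Extract per-phase oxygen-uptake determinations from a trace
#'
#' One least-squares slope of dissolved oxygen against time is fitted per
#' measure phase. Uptake is the absolute slope times the effective water
#' volume (respirometer minus animal), converted to hourly rate and
#' allometrically mass-corrected to 1 kg with exponent 0.89:
#' `MO2 = |slope| * V_eff * 3600 / mass^0.89`. Determinations whose
#' coefficient of determination is 0.95 or less are flagged as not
#' retained; phases with fewer than `min_samples` points are skipped with
#' a warning.
#'
#' @param trace an oxygen trace from [generate_o2_trace()] or
#'   [read_trace_csv()].
#' @param r2_min retention threshold on R^2 (strictly greater than).
#' @param min_samples minimum samples per phase.
#' @return a `data.frame` of class `mo2_determinations`: `start_s`,
#'   `end_s`, `mid_s` (trace time), `animal_h` (hours since the animal
#'   entered), `slope`, `r_squared`, `mo2` (mg O2 kg^-0.89 h^-1, not yet
#'   background-corrected), `retained`, `background_corrected`.
#' @export
extract_determinations <- function(trace, r2_min = 0.95, min_samples = 5) {
  stopifnot(is.data.frame(trace), all(c("time_s", "o2_mg_l", "phase") %in%
                                        names(trace)))
  mass <- trace_attr(trace, "animal_mass_kg")
  v_eff <- trace_attr(trace, "volume_l") - trace_attr(trace, "animal_volume_l")
  stopifnot(v_eff > 0)
  animal_start <- attr(trace, "animal_start_s")
  if (is.null(animal_start)) {
    animal_start <- min(trace$time_s[trace$phase == "measure"])
  }
  meas <- trace[trace$phase == "measure", , drop = FALSE]
  if (nrow(meas) == 0) stop("no measure phases labelled in trace")
  # contiguous phases: break where time jumps by more than one median step
  step <- median(diff(meas$time_s))
  phase_id <- cumsum(c(1, diff(meas$time_s) > 1.5 * step))
  skipped <- 0L
  rows <- lapply(split(meas, phase_id), function(ph) {
    if (nrow(ph) < min_samples) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    fit <- fast_slope(ph$time_s, ph$o2_mg_l)
    mo2 <- abs(fit$slope) * v_eff * 3600 / mass^MASS_SCALING_EXPONENT
    data.frame(start_s = ph$time_s[1], end_s = ph$time_s[nrow(ph)],
               mid_s = mean(range(ph$time_s)),
               slope = fit$slope, r_squared = fit$r_squared, mo2 = mo2)
  })
  if (skipped > 0) {
    warning(sprintf("%d measure phase(s) skipped: fewer than %d samples",
                    skipped, min_samples))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$animal_h <- (out$mid_s - animal_start) / 3600
  out$retained <- out$r_squared > r2_min
  out$background_corrected <- FALSE
  attr(out, "animal_mass_kg") <- mass
  attr(out, "volume_l") <- trace_attr(trace, "volume_l")
  attr(out, "effective_volume_l") <- v_eff
  class(out) <- c("mo2_determinations", "data.frame")
  out
}

# Background chamber respiration rates (mg O2/h) measured in the empty
# chamber before/after the trial. Uses the full chamber volume (no animal).
background_rates <- function(trace, min_samples = 5) {
  vol <- trace_attr(trace, "volume_l")
  out <- lapply(c(pre = "background_pre", post = "background_post"),
                function(lab) {
    ph <- trace[trace$phase == lab, , drop = FALSE]
    if (nrow(ph) < min_samples) return(NULL)
    fit <- fast_slope(ph$time_s, ph$o2_mg_l)
    list(rate = abs(fit$slope) * vol * 3600, mid_s = mean(range(ph$time_s)))
  })
  out[!vapply(out, is.null, logical(1))]
}

#' Correct uptake determinations for background respiration
#'
#' Fits a line through the two empty-chamber background measurements
#' (pre/post) and subtracts the interpolated background rate at each
#' determination's midpoint from its whole-chamber uptake before mass
#' correction. With a single background measurement a constant correction
#' is applied with a warning. Corrected determinations that go negative are
#' flagged as not retained (sensor drift, excluded rather than clipped).
#'
#' @param determinations output of [extract_determinations()].
#' @param trace the trace the determinations came from (supplies the
#'   background phases and volumes).
#' @return the determinations with `mo2` corrected and
#'   `background_corrected` set.
#' @export
background_correct <- function(determinations, trace) {
  stopifnot(inherits(determinations, "mo2_determinations"))
  bg <- background_rates(trace)
  if (length(bg) == 0) {
    warning("no background phases found; determinations left uncorrected")
    return(determinations)
  }
  mass <- attr(determinations, "animal_mass_kg")
  v_eff <- attr(determinations, "effective_volume_l")
  total_rate <- abs(determinations$slope) * v_eff * 3600
  bg_at <- if (length(bg) == 2) {
    approx(x = c(bg$pre$mid_s, bg$post$mid_s),
           y = c(bg$pre$rate, bg$post$rate),
           xout = determinations$mid_s, rule = 2)$y
  } else {
    warning("only one background measurement; applying constant correction")
    rep(bg[[1]]$rate, nrow(determinations))
  }
  corrected <- (total_rate - bg_at) / mass^MASS_SCALING_EXPONENT
  determinations$mo2 <- corrected
  negative <- corrected < 0
  determinations$retained <- determinations$retained & !negative
  determinations$background_corrected <- TRUE
  determinations
}

#' Minimum oxygen uptake by the Mean of the Lowest Normal Distribution
#'
#' Fits univariate Gaussian mixtures with 1 to `max_components` components
#' to the retained determinations, selects the component count by BIC, and
#' returns the mean of the component with the lowest mean. With one
#' component this degenerates to the overall mean.
#'
#' @param determinations an `mo2_determinations` object or a numeric vector
#'   of uptake values.
#' @param max_components maximum number of mixture components tried.
#' @param min_n minimum number of determinations required.
#' @return list with `mo2_min`, `n_components`, `component_means`,
#'   `component_weights`.
#' @export
mo2_min_mlnd <- function(determinations, max_components = 4, min_n = 20) {
  x <- if (inherits(determinations, "mo2_determinations")) {
    determinations$mo2[determinations$retained]
  } else as.numeric(determinations)
  if (length(x) < min_n) {
    stop(sprintf(paste0("only %d retained determinations (< %d); too few ",
                        "for a mixture fit - consider a low-quantile ",
                        "estimate instead"), length(x), min_n))
  }
  if (sd(x) < .Machine$double.eps^0.5 * max(1, abs(mean(x)))) {
    return(list(mo2_min = mean(x), n_components = 1L,
                component_means = mean(x), component_weights = 1))
  }
  fit <- mclust::Mclust(x, G = seq_len(max_components), verbose = FALSE)
  if (is.null(fit)) stop("mixture fit failed")
  means <- as.numeric(fit$parameters$mean)
  weights <- as.numeric(fit$parameters$pro)
  lo <- which.min(means)
  list(mo2_min = means[lo], n_components = fit$G,
       component_means = means, component_weights = weights)
}

#' Maximum oxygen uptake from rolling 30-s slopes in the first hour
#'
#' Rolling regressions over windows of `window_s` seconds advance sample by
#' sample within each measure phase (windows never span a flush) of the
#' first `search_h` hours after the animal entered the chamber. The
#' steepest absolute slope is converted to uptake with the same volume and
#' mass corrections as full determinations and corrected for interpolated
#' background respiration. Ties go to the first occurrence.
#'
#' @param trace an oxygen trace.
#' @param window_s rolling window length, s.
#' @param search_h search horizon, hours after animal entry.
#' @return list with `mo2_max` (mg O2 kg^-0.89 h^-1), `window_start_s`,
#'   `slope`.
#' @export
mo2_max <- function(trace, window_s = 30, search_h = 1) {
  mass <- trace_attr(trace, "animal_mass_kg")
  vol <- trace_attr(trace, "volume_l")
  v_eff <- vol - trace_attr(trace, "animal_volume_l")
  hz <- trace_attr(trace, "sample_hz")
  animal_start <- attr(trace, "animal_start_s")
  if (is.null(animal_start)) {
    animal_start <- min(trace$time_s[trace$phase == "measure"])
  }
  width <- as.integer(round(window_s * hz))
  meas <- trace[trace$phase == "measure" &
                  trace$time_s >= animal_start &
                  trace$time_s < animal_start + search_h * 3600, ,
                drop = FALSE]
  if (nrow(meas) == 0) stop("no measure-phase data in the search window")
  step <- median(diff(meas$time_s))
  phase_id <- cumsum(c(1, diff(meas$time_s) > 1.5 * step))
  best <- NULL
  for (ph in split(meas, phase_id)) {
    if (nrow(ph) < width) next
    sl <- rolling_slopes(ph$time_s, ph$o2_mg_l, width)
    j <- which.max(abs(sl))
    if (is.null(best) || abs(sl[j]) > abs(best$slope)) {
      best <- list(slope = sl[j], start_s = ph$time_s[j],
                   mid_s = ph$time_s[j] + window_s / 2)
    }
  }
  if (is.null(best)) {
    stop(sprintf("no complete %g-s window inside a measure phase", window_s))
  }
  bg <- background_rates(trace)
  bg_rate <- if (length(bg) == 2) {
    approx(x = c(bg$pre$mid_s, bg$post$mid_s),
           y = c(bg$pre$rate, bg$post$rate),
           xout = best$mid_s, rule = 2)$y
  } else if (length(bg) == 1) bg[[1]]$rate else 0
  rate <- abs(best$slope) * v_eff * 3600 - bg_rate
  list(mo2_max = rate / mass^MASS_SCALING_EXPONENT,
       window_start_s = best$start_s, slope = best$slope)
}

#' EPOC and recovery time from the post-exercise uptake series
#'
#' Fits `y(t) = a exp(-k t) + c` to the retained determinations by
#' nonlinear least squares. Recovery time is the earliest `t` with
#' `y(t) <= mo2_min` (closed form `t* = log(a / (mo2_min - c)) / k` when
#' the asymptote `c` lies well below `mo2_min`); EPOC is the area between
#' the fitted curve and `mo2_min` up to `t*`, evaluated analytically. The
#' intersection time diverges as `c` approaches `mo2_min` and does not
#' exist above it, so the curve is never required to approach its own
#' asymptote closer than `threshold * mo2_min`: past that point a proximity
#' rule takes over continuously (recovery when excess uptake falls to
#' `threshold * mo2_min`) and the result is flagged approximate.
#'
#' @param determinations an `mo2_determinations` object (background
#'   corrected) or data.frame with `animal_h`, `mo2`, `retained`.
#' @param mo2_min minimum uptake, e.g. from [mo2_min_mlnd()].
#' @param threshold proximity rule fraction for non-intersecting fits.
#' @return list with `epoc` (mg O2 kg^-0.89), `recovery_h`, the fitted
#'   parameters `a`, `k`, `c`, and `approximate` (TRUE when the proximity
#'   rule was used).
#' @export
epoc_and_recovery <- function(determinations, mo2_min, threshold = 0.1) {
  d <- determinations[determinations$retained, , drop = FALSE]
  stopifnot(nrow(d) >= 4, mo2_min >= 0)
  t_h <- d$animal_h
  y <- d$mo2
  c0 <- min(y)
  a0 <- max(max(y) - c0, .Machine$double.eps)
  fit <- minpack.lm::nlsLM(
    y ~ a * exp(-k * t_h) + cc,
    start = list(a = a0, k = 0.5, cc = c0),
    lower = c(a = 0, k = 1e-6, cc = -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- coef(fit)
  a <- p[["a"]]; k <- p[["k"]]; cc <- p[["cc"]]
  y0 <- a + cc
  if (y0 <= mo2_min) {
    return(list(epoc = 0, recovery_h = 0, a = a, k = k, c = cc,
                approximate = FALSE))
  }
  # Recovery is when the fitted curve reaches mo2_min, but the curve is
  # never required to approach its own asymptote closer than
  # threshold * mo2_min: the intersection time diverges logarithmically as
  # c -> mo2_min, so the strict rule is ill-conditioned there and the
  # proximity rule takes over continuously.
  excess_target <- max(mo2_min - cc, threshold * mo2_min)
  approximate <- (mo2_min - cc) < threshold * mo2_min
  t_star <- if (a <= excess_target) 0 else log(a / excess_target) / k
  epoc <- a / k * (1 - exp(-k * t_star)) + (cc - mo2_min) * t_star
  list(epoc = max(epoc, 0), recovery_h = max(t_star, 0),
       a = a, k = k, c = cc, approximate = approximate)
}

#' Run the full respirometry pipeline on a trace
#'
#' Convenience wrapper: extract determinations, background-correct,
#' estimate minimum uptake by MLND, maximum uptake from rolling 30-s
#' windows, then aerobic scope, EPOC and recovery time.
#'
#' @param trace an oxygen trace.
#' @param ... passed to [epoc_and_recovery()].
#' @return list of class `respirometry_metrics`: `mo2_min`, `mo2_max`,
#'   `aas`, `fas`, `epoc`, `recovery_time`, `n_retained`, `n_dropped`,
#'   plus the determination table.
#' @export
respirometry_metrics <- function(trace, ...) {
  dets <- extract_determinations(trace)
  dets <- background_correct(dets, trace)
  mlnd <- mo2_min_mlnd(dets)
  mx <- mo2_max(trace)
  ep <- epoc_and_recovery(dets, mlnd$mo2_min, ...)
  structure(list(
    mo2_min = mlnd$mo2_min, mo2_max = mx$mo2_max,
    aas = mx$mo2_max - mlnd$mo2_min,
    fas = mx$mo2_max / mlnd$mo2_min,
    epoc = ep$epoc, recovery_time = ep$recovery_h,
    n_retained = sum(dets$retained),
    n_dropped = sum(!dets$retained),
    determinations = dets, mlnd = mlnd, epoc_fit = ep),
    class = "respirometry_metrics")
}

#' @export
print.respirometry_metrics <- function(x, ...) {
  cat("Respirometry metrics (mg O2 kg^-0.89 h^-1 unless noted)\n")
  cat(sprintf("  MO2Min (MLND):  %.2f\n", x$mo2_min))
  cat(sprintf("  MO2Max (30 s):  %.2f\n", x$mo2_max))
  cat(sprintf("  AAS:            %.2f\n", x$aas))
  cat(sprintf("  FAS:            %.3f\n", x$fas))
  cat(sprintf("  EPOC:           %.1f mg O2 kg^-0.89\n", x$epoc))
  cat(sprintf("  recovery:       %.2f h\n", x$recovery_time))
  cat(sprintf("  determinations: %d retained, %d dropped\n",
              x$n_retained, x$n_dropped))
  invisible(x)
}
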