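#' Define a fully factorial temperature x pCO2 study design
#'
#' The default design mirrors a 2x2 acclimation experiment on neonatal
#' blacktip reef sharks: two temperatures (28 and 31 degrees C), two pCO2
#' levels (650 and 1050 uatm), three replicate holding tanks ("groups") of
#' 3-4 sharks per treatment cell. Replicate groups are the random-intercept
#' unit of all downstream mixed models.
#'
#' @param temperature_levels numeric vector of treatment temperatures (deg C).
#' @param pco2_levels numeric vector of treatment pCO2 levels (uatm).
#' @param groups_per_cell replicate groups per treatment cell.
#' @param sharks_per_group integer vector of admissible group sizes; each
#'   group's size is drawn uniformly from this set.
#' @param seed integer seed controlling roster randomness.
#' @return an object of class `study_design`.
#' @export
study_design <- function(temperature_levels = c(28, 31),
                         pco2_levels = c(650, 1050),
                         groups_per_cell = 3,
                         sharks_per_group = c(3, 4),
                         seed = 1) {
  if (length(temperature_levels) < 1 || length(pco2_levels) < 1) {
    stop("design is not crossable: empty factor level list")
  }
  if (groups_per_cell < 1 || any(sharks_per_group < 1)) {
    stop("counts must be >= 1")
  }
  structure(
    list(temperature_levels = sort(temperature_levels),
         pco2_levels = sort(pco2_levels),
         groups_per_cell = as.integer(groups_per_cell),
         sharks_per_group = as.integer(sharks_per_group),
         seed = as.integer(seed)),
    class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Fully factorial study design\n")
  cat("  temperature levels:", paste(x$temperature_levels, collapse = ", "), "deg C\n")
  cat("  pCO2 levels:      ", paste(x$pco2_levels, collapse = ", "), "uatm\n")
  cat("  replicate groups: ", x$groups_per_cell, "per cell,",
      paste(range(x$sharks_per_group), collapse = "-"), "sharks per group\n")
  invisible(x)
}

#' Generate the shark roster for a study design
#'
#' Every treatment cell receives `groups_per_cell` replicate groups; each
#' group's size is drawn from `sharks_per_group`. Body masses are drawn from
#' a truncated normal (mean 1.0 kg, sd 0.2 kg, bounds 0.7-1.4 kg, the
#' observed neonate range) and total lengths from N(569.2, 31.9) mm. Each
#' shark carries a child seed derived from the design seed, so enlarging the
#' roster never perturbs sharks already generated.
#'
#' @param design a [study_design()].
#' @param mass_mean,mass_sd,mass_bounds body-mass distribution (kg).
#' @return a `data.frame` with one row per shark: `id`, `mass_kg`,
#'   `total_length_mm`, `temperature`, `pco2`, `group_id`, `seed`.
#' @export
generate_design <- function(design = study_design(),
                            mass_mean = 1.0, mass_sd = 0.2,
                            mass_bounds = c(0.7, 1.4)) {
  stopifnot(inherits(design, "study_design"))
  cells <- expand.grid(temperature = design$temperature_levels,
                       pco2 = design$pco2_levels,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- list()
  for (ci in seq_len(nrow(cells))) {
    tt <- cells$temperature[ci]; pp <- cells$pco2[ci]
    for (g in seq_len(design$groups_per_cell)) {
      gid <- sprintf("T%g_C%g_G%d", tt, pp, g)
      n_g <- with_seed(child_seed(design$seed, "groupsize", gid), {
        if (length(design$sharks_per_group) == 1) design$sharks_per_group
        else sample(design$sharks_per_group, 1)
      })
      for (k in seq_len(n_g)) {
        id <- sprintf("%s_S%d", gid, k)
        sseed <- child_seed(design$seed, "shark", id)
        body <- with_seed(sseed, {
          m <- rtrunc_norm(1, mass_mean, mass_sd, mass_bounds[1], mass_bounds[2])
          l <- rnorm(1, 569.2, 31.9)
          c(m, l)
        })
        rows[[length(rows) + 1]] <- data.frame(
          id = id, mass_kg = body[1], total_length_mm = body[2],
          temperature = tt, pco2 = pp, group_id = gid, seed = sseed,
          stringsAsFactors = FALSE)
      }
    }
  }
  roster <- do.call(rbind, rows)
  rownames(roster) <- NULL
  attr(roster, "design") <- design
  roster
}

# Truncated-normal draws by rejection (bounds are a few sd from the mean,
# so acceptance is high).
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * n, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}
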