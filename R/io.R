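# Plain-CSV readers and writers for every record the pipeline consumes or
# produces. Columns are documented here and in the function docs; metadata
# that CSV cannot carry (volumes, masses, rates) is passed explicitly on
# read.

#' Write / read a shark roster CSV
#'
#' Columns: `id`, `mass_kg`, `total_length_mm`, `temperature`, `pco2`,
#' `group_id`.
#'
#' @param roster a roster from [generate_design()].
#' @param path file path.
#' @return `read_roster_csv()` returns the roster `data.frame`.
#' @export
write_roster_csv <- function(roster, path) {
  write.csv(roster[, c("id", "mass_kg", "total_length_mm", "temperature",
                       "pco2", "group_id")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roster_csv
#' @export
read_roster_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read an oxygen trace CSV
#'
#' Long format, columns `time_s`, `o2_mg_l`, `phase` (one of
#' `background_pre`, `measure`, `flush`, `background_post`). Respirometer
#' geometry travels as explicit arguments on read.
#'
#' @param trace an oxygen trace.
#' @param path file path.
#' @param volume_l respirometer volume, L.
#' @param animal_mass_kg animal mass, kg.
#' @param animal_volume_l displaced volume, L (defaults to mass at
#'   1 kg/L).
#' @param sample_hz probe sampling rate.
#' @return `read_trace_csv()` returns a trace `data.frame` with the
#'   attributes the pipeline needs.
#' @export
write_trace_csv <- function(trace, path) {
  write.csv(trace[, c("time_s", "o2_mg_l", "phase")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path, volume_l, animal_mass_kg,
                           animal_volume_l = animal_mass_kg,
                           sample_hz = NULL) {
  trace <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("time_s", "o2_mg_l", "phase") %in% names(trace)))
  attr(trace, "volume_l") <- volume_l
  attr(trace, "animal_mass_kg") <- animal_mass_kg
  attr(trace, "animal_volume_l") <- animal_volume_l
  attr(trace, "sample_hz") <- if (is.null(sample_hz)) {
    1 / median(diff(trace$time_s[trace$phase == trace$phase[1]]))
  } else sample_hz
  trace
}

#' Write / read a turn-record CSV
#'
#' Columns: `shark_id`, `trial_side`, `turn_direction` ("L"/"R").
#'
#' @param turns a turn record (possibly several sharks stacked).
#' @param path file path.
#' @return `read_turns_csv()` returns the stacked records.
#' @export
write_turns_csv <- function(turns, path) {
  write.csv(turns[, c("shark_id", "trial_side", "turn_direction")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_turns_csv
#' @export
read_turns_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Read an acceleration trace CSV
#'
#' Columns: `time_s`, `x_g`, `y_g`, `z_g`, uniformly sampled.
#'
#' @param path file path.
#' @param clock_start wall-clock time of the first sample ("HH:MM" or
#'   seconds since midnight), needed by [activity_level()].
#' @return acceleration `data.frame` with a `clock_start_s` attribute.
#' @export
read_accel_csv <- function(path, clock_start = "10:00") {
  trace <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("time_s", "x_g", "y_g", "z_g") %in% names(trace)))
  attr(trace, "clock_start_s") <- clock_to_s(clock_start)
  trace
}

#' Read a titration CSV
#'
#' Columns: `acid_ml` (cumulative acid volume), `ph`. Sample geometry and
#' conditions travel as explicit arguments.
#'
#' @param path file path.
#' @param sample_ml sample volume, mL.
#' @param acid_mol_l titrant concentration, mol/L.
#' @param temperature,salinity titration conditions.
#' @return titration `data.frame` with the attributes
#'   [gran_alkalinity()] needs.
#' @export
read_titration_csv <- function(path, sample_ml = 50, acid_mol_l = 0.1,
                               temperature = 25, salinity = 35) {
  curve <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("acid_ml", "ph") %in% names(curve)))
  attr(curve, "sample_ml") <- sample_ml
  attr(curve, "acid_mol_l") <- acid_mol_l
  attr(curve, "temperature") <- temperature
  attr(curve, "salinity") <- salinity
  curve
}

#' Write / read a trait table CSV
#'
#' One row per shark: `id`, `mass_kg`, `temperature`, `pco2`, `group_id`
#' and the 15 trait columns (see [trait_names()]); missing measurements
#' are empty cells.
#'
#' @param table a trait table.
#' @param path file path.
#' @return `read_trait_table_csv()` returns the table.
#' @export
write_trait_table_csv <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trait_table_csv
#' @export
read_trait_table_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write a tidy effects table CSV
#'
#' Columns: `trait`, `term`, `mean`, `ci_low`, `ci_high`, `significant`,
#' mirroring a per-trait effects table.
#'
#' @param effects output of [fit_all_traits()].
#' @param path file path.
#' @export
write_effects_csv <- function(effects, path) {
  write.csv(effects, path, row.names = FALSE)
  invisible(path)
}
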