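# Blood-panel traits: Drabkin's haemoglobin, haematocrit aggregation,
# mean corpuscular haemoglobin concentration, and pluggable temperature
# correction of measured blood pH.

#' Haemoglobin concentration from Drabkin's assay absorbance
#'
#' Beer-Lambert with the cyanmethemoglobin convention:
#' `[Hb] = mean(A540) / (extinction * path) * dilution`, in mmol/L. The
#' default dilution of 201 corresponds to 5 uL of whole blood added to
#' 1 mL of Drabkin's reagent; the default path length of 0.56 cm to a
#' 200 uL aliquot in a flat-bottom 96-well plate.
#'
#' @param a540 absorbance replicates at 540 nm (typically a triplicate).
#' @param dilution dilution factor of blood in reagent.
#' @param path_cm optical path length, cm.
#' @param extinction millimolar extinction coefficient, mmol^-1 L cm^-1.
#' @return list with `hb` (mmol/L) and `replicate_cv` (%, `NA` for a
#'   single replicate).
#' @export
hb_from_absorbance <- function(a540, dilution = 201, path_cm = 0.56,
                               extinction = 11) {
  stopifnot(length(a540) >= 1, path_cm > 0, dilution > 0, extinction > 0)
  if (any(a540 < 0)) stop("negative absorbance reading")
  m <- mean(a540)
  cv <- if (length(a540) > 1 && m > 0) sd(a540) / m * 100 else NA_real_
  list(hb = m / (extinction * path_cm) * dilution, replicate_cv = cv)
}

#' Mean corpuscular haemoglobin concentration
#'
#' `MCHC = [Hb] / Hct` (mmol/L), with haematocrit as a fraction.
#'
#' @param hb haemoglobin concentration, mmol/L.
#' @param hct haematocrit fraction in (0, 1).
#' @return MCHC, mmol/L.
#' @export
mchc <- function(hb, hct) {
  stopifnot(hb >= 0)
  if (any(hct <= 0)) stop("haematocrit must be positive")
  if (any(hct >= 1)) stop("haematocrit must be a fraction below 1")
  hb / hct
}

#' Define an affine temperature correction for measured blood pH
#'
#' Species-specific corrections map meter pH at the measurement
#' temperature to pH at the animal's acclimation temperature; they are
#' supplied as an affine map `pH + intercept + slope * (temperature -
#' ref_temperature)`. The default is the identity (no correction
#' configured).
#'
#' @param slope pH units per deg C.
#' @param intercept constant offset, pH units.
#' @param ref_temperature reference temperature, deg C.
#' @return function of `(ph, temperature)`.
#' @export
ph_correction <- function(slope = 0, intercept = 0, ref_temperature = 25) {
  force(slope); force(intercept); force(ref_temperature)
  function(ph, temperature) {
    ph + intercept + slope * (temperature - ref_temperature)
  }
}

#' Apply a temperature correction to measured blood pH
#'
#' @param ph_measured meter reading.
#' @param temperature measurement temperature, deg C.
#' @param correction a correction function from [ph_correction()];
#'   identity by default.
#' @return corrected pH.
#' @export
correct_ph <- function(ph_measured, temperature,
                       correction = ph_correction()) {
  correction(ph_measured, temperature)
}

#' Simulate a blood panel with known true haematology
#'
#' Generates duplicate haematocrit readings, triplicate Drabkin's
#' absorbances consistent with the true haemoglobin concentration
#' (`hb = mchc * hct`), measured pH and lactate, with optional replicate
#' noise.
#'
#' @param true_hct true haematocrit fraction.
#' @param true_mchc true MCHC, mmol/L.
#' @param true_ph,true_lactate true blood pH and lactate (mmol/L).
#' @param dilution,path_cm,extinction Drabkin's assay configuration.
#' @param hct_noise_sd,a540_noise_sd replicate noise.
#' @param seed integer seed.
#' @param shark_id label.
#' @return list of class `blood_panel` with replicate vectors, assay
#'   configuration and the truth.
#' @export
generate_blood_panel <- function(true_hct = 0.21, true_mchc = 2.07,
                                 true_ph = 7.9, true_lactate = 3.58,
                                 dilution = 201, path_cm = 0.56,
                                 extinction = 11,
                                 hct_noise_sd = 0, a540_noise_sd = 0,
                                 seed = 1, shark_id = "shark") {
  stopifnot(true_hct > 0, true_hct < 1, true_mchc > 0)
  true_hb <- true_mchc * true_hct
  a540_true <- true_hb * extinction * path_cm / dilution
  noise <- with_seed(child_seed(seed, "blood", shark_id), {
    list(hct = rnorm(2, 0, hct_noise_sd), a540 = rnorm(3, 0, a540_noise_sd))
  })
  structure(list(
    shark_id = shark_id,
    ph_measured = true_ph,
    lactate = true_lactate,
    hct_replicates = pmin(pmax(true_hct + noise$hct, 1e-6), 1 - 1e-6),
    a540_replicates = pmax(a540_true + noise$a540, 0),
    dilution = dilution, path_cm = path_cm, extinction = extinction,
    truth = list(hct = true_hct, hb = true_hb, mchc = true_mchc,
                 ph = true_ph, lactate = true_lactate)),
    class = "blood_panel")
}

#' Derive the haematological traits from a blood panel
#'
#' Replicates are aggregated by arithmetic mean; haemoglobin comes from
#' [hb_from_absorbance()], MCHC from [mchc()], and pH through the supplied
#' correction.
#'
#' @param panel a `blood_panel`.
#' @param temperature measurement temperature for the pH correction.
#' @param correction pH correction function; identity by default.
#' @return `data.frame` row: `blood_ph`, `lactate`, `hct`, `hb`, `mchc`,
#'   `hb_replicate_cv`.
#' @export
blood_panel_traits <- function(panel, temperature = 25,
                               correction = ph_correction()) {
  stopifnot(inherits(panel, "blood_panel"))
  hct <- mean(panel$hct_replicates)
  hb <- hb_from_absorbance(panel$a540_replicates, panel$dilution,
                           panel$path_cm, panel$extinction)
  data.frame(
    blood_ph = correct_ph(panel$ph_measured, temperature, correction),
    lactate = panel$lactate,
    hct = hct, hb = hb$hb, mchc = mchc(hb$hb, hct),
    hb_replicate_cv = hb$replicate_cv)
}
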