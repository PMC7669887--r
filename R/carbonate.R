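# Seawater CO2-system chemistry: equilibrium constants, a pCO2 solver for
# (pH_NBS, A_T, T, S) inputs, open-cell Gran titration alkalinity, and the
# EOS-80 surface density needed to express alkalinity per kg of seawater.

#' Carbonic-acid system equilibrium constants
#'
#' Constants follow the conventional CO2-system recipe for the "Mehrbach
#' refit" choice: K1 and K2 from Mehrbach et al. as refit by Dickson &
#' Millero (1987) on the seawater pH scale; K0 from Weiss (1974); KB from
#' Dickson (1990b); KW from Millero (1995); KS (bisulfate) from Dickson
#' (1990a) on the free scale; total boron proportional to salinity
#' (Uppstrom 1974). Hydrogen fluoride is excluded by default, so the
#' seawater and total pH scales coincide. The NBS activity factor `fH`
#' (Takahashi et al. 1982) converts NBS-scale pH readings to
#' seawater-scale hydrogen-ion concentration, and `fugacity_factor`
#' converts CO2 fugacity to partial pressure.
#'
#' @param temperature deg C; fit range roughly 0-45.
#' @param salinity practical salinity; fit range roughly 19-43.
#' @param warn warn when (temperature, salinity) falls outside the fit
#'   ranges (the constants are then extrapolated).
#' @return an object of class `co2_constants`: list with `K0` (mol kg^-1
#'   atm^-1), `K1`, `K2`, `KB`, `KW`, `KS`, total boron `BT`, total sulfate
#'   `ST` (mol kg^-1), `fH`, `fugacity_factor`, and the inputs.
#' @export
equilibrium_constants <- function(temperature, salinity, warn = TRUE) {
  if (warn && (temperature < 0 || temperature > 45 ||
               salinity < 19 || salinity > 43)) {
    warning("temperature/salinity outside constant fit ranges; extrapolating")
  }
  TK <- temperature + 273.15
  lTK <- log(TK)
  s <- salinity
  sqS <- sqrt(s)

  # ionic strength and major-ion totals
  ion_s <- 19.924 * s / (1000 - 1.005 * s)
  BT <- 0.0004157 * s / 35
  ST <- (0.14 / 96.062) * (s / 1.80655)

  # bisulfate, free scale (Dickson 1990a)
  lnKS <- -4276.1 / TK + 141.328 - 23.093 * lTK +
    (-13856 / TK + 324.57 - 47.986 * lTK) * sqrt(ion_s) +
    (35474 / TK - 771.54 + 114.723 * lTK) * ion_s -
    2698 / TK * ion_s^1.5 + 1776 / TK * ion_s^2
  KS <- exp(lnKS) * (1 - 0.001005 * s)

  # borate, total scale == seawater scale with fluoride excluded
  lnKB <- (-8966.9 - 2890.53 * sqS - 77.942 * s +
           1.728 * s^1.5 - 0.0996 * s^2) / TK +
    148.0248 + 137.1942 * sqS + 1.62142 * s +
    (-24.4344 - 25.085 * sqS - 0.2474 * s) * lTK +
    0.053105 * sqS * TK
  KB <- exp(lnKB)

  # water, seawater scale (Millero 1995)
  lnKW <- 148.9802 - 13847.26 / TK - 23.6521 * lTK +
    (118.67 / TK - 5.977 + 1.0495 * lTK) * sqS - 0.01615 * s
  KW <- exp(lnKW)

  # carbonic acid, Mehrbach refit by Dickson & Millero (1987), seawater scale
  pK1 <- 3670.7 / TK - 62.008 + 9.7944 * lTK - 0.0118 * s + 0.000116 * s^2
  pK2 <- 1394.7 / TK + 4.777 - 0.0184 * s + 0.000118 * s^2

  # CO2 solubility (Weiss 1974)
  lnK0 <- -60.2409 + 93.4517 * (100 / TK) + 23.3585 * log(TK / 100) +
    s * (0.023517 - 0.023656 * (TK / 100) + 0.0047036 * (TK / 100)^2)

  # NBS activity factor (Takahashi et al. 1982)
  fH <- 1.2948 - 0.002036 * TK + (0.0004607 - 0.000001475 * TK) * s^2

  # fugacity-to-partial-pressure factor at 1 atm
  delta <- 57.7 - 0.118 * TK
  bvir <- -1636.75 + 12.0408 * TK - 0.0327957 * TK^2 + 3.16528e-5 * TK^3
  fug <- exp((bvir + 2 * delta) * 1.01325 / (83.14462618 * TK))

  structure(list(K0 = exp(lnK0), K1 = 10^(-pK1), K2 = 10^(-pK2),
                 KB = KB, KW = KW, KS = KS, BT = BT, ST = ST,
                 fH = fH, fugacity_factor = fug,
                 temperature = temperature, salinity = salinity),
            class = "co2_constants")
}

# Hydrogen-ion concentration on the seawater scale from an NBS pH reading.
h_from_ph_nbs <- function(ph_nbs, k) 10^(-ph_nbs) / k$fH

# Alkalinity components other than carbonate at a given [H+] (seawater
# scale, mol/kg). Free H+ and bisulfate follow the conventional linearised
# free/total relation.
noncarb_alkalinity <- function(h, k) {
  free_to_tot <- 1 + k$ST / k$KS
  hfree <- h / free_to_tot
  hso4 <- k$ST / (1 + k$KS / hfree)
  list(borate = k$BT * k$KB / (k$KB + h),
       oh = k$KW / h,
       hfree = hfree, hso4 = hso4)
}

#' Solve the seawater CO2 system for pCO2 from pH, alkalinity, T and S
#'
#' Converts the NBS-scale pH reading to a seawater-scale hydrogen-ion
#' concentration via the activity factor `fH`, partitions total alkalinity
#' into carbonate alkalinity by subtracting borate and hydroxide and adding
#' free H+ and bisulfate, speciates dissolved inorganic carbon with K1/K2,
#' and converts dissolved CO2 to partial pressure via K0 and the fugacity
#' factor.
#'
#' @param temperature deg C.
#' @param salinity practical salinity.
#' @param ph_nbs pH on the NBS scale.
#' @param alkalinity total alkalinity, umol per kg seawater.
#' @return list with `pco2` (uatm), `fco2` (uatm), `dic` (umol/kg),
#'   `hco3`, `co3`, `co2` (umol/kg), and `carb_alkalinity` (umol/kg).
#' @examples
#' solve_pco2(28.1, 37, 8.01, 2354)$pco2
#' @export
solve_pco2 <- function(temperature, salinity, ph_nbs, alkalinity) {
  stopifnot(alkalinity > 0, salinity > 0, salinity < 50)
  k <- equilibrium_constants(temperature, salinity)
  ta <- alkalinity * 1e-6
  h <- h_from_ph_nbs(ph_nbs, k)
  nc <- noncarb_alkalinity(h, k)
  ca <- ta - nc$borate - nc$oh + nc$hfree + nc$hso4
  if (ca <= 0) {
    stop(sprintf(paste0("non-physical negative carbonate alkalinity for ",
                        "(T=%g, S=%g, pH_NBS=%g, A_T=%g)"),
                 temperature, salinity, ph_nbs, alkalinity))
  }
  hco3 <- ca / (1 + 2 * k$K2 / h)
  co3 <- hco3 * k$K2 / h
  co2 <- hco3 * h / k$K1
  fco2 <- co2 / k$K0
  list(pco2 = fco2 / k$fugacity_factor * 1e6,
       fco2 = fco2 * 1e6,
       dic = (co2 + hco3 + co3) * 1e6,
       hco3 = hco3 * 1e6, co3 = co3 * 1e6, co2 = co2 * 1e6,
       carb_alkalinity = ca * 1e6)
}

#' Solve for the NBS pH giving a target pCO2 at fixed alkalinity, T and S
#'
#' Inverse of [solve_pco2()], found by root bisection; used for
#' round-tripping and for simulating treatment water dosed to a target
#' pCO2.
#'
#' @inheritParams solve_pco2
#' @param pco2 target partial pressure, uatm.
#' @param interval pH search interval.
#' @return pH on the NBS scale.
#' @export
solve_ph_nbs <- function(temperature, salinity, pco2, alkalinity,
                         interval = c(4, 10)) {
  f <- function(ph) {
    solve_pco2(temperature, salinity, ph, alkalinity)$pco2 - pco2
  }
  uniroot(f, interval, tol = 1e-12)$root
}

#' Seawater density at atmospheric pressure (EOS-80)
#'
#' One-atmosphere International Equation of State of Seawater (1980),
#' used to convert per-volume titration quantities to per-kg alkalinity.
#'
#' @param temperature deg C.
#' @param salinity practical salinity.
#' @return density, kg per litre.
#' @export
seawater_density <- function(temperature, salinity) {
  t <- temperature; s <- salinity
  rho_w <- 999.842594 + 6.793952e-2 * t - 9.095290e-3 * t^2 +
    1.001685e-4 * t^3 - 1.120083e-6 * t^4 + 6.536332e-9 * t^5
  A <- 0.824493 - 4.0899e-3 * t + 7.6438e-5 * t^2 -
    8.2467e-7 * t^3 + 5.3875e-9 * t^4
  B <- -5.72466e-3 + 1.0227e-4 * t - 1.6546e-6 * t^2
  C <- 4.8314e-4
  (rho_w + A * s + B * s^1.5 + C * s^2) / 1000
}

#' Total alkalinity from an open-cell Gran titration
#'
#' Computes the Gran function `F = (V0 + V) * 10^(-pH)` over the readings
#' whose pH falls in the linear strong-acid window (default 3.0-3.5, where
#' CO2 has been protonated/degassed), fits a straight line in acid volume,
#' and takes the equivalence volume `Ve` from the x-intercept. Total
#' alkalinity is `Ve * C_acid / (V0 * rho_sw)` expressed in umol per kg of
#' seawater. The x-intercept is invariant to the constant activity factor
#' between pH scales, so NBS-scale meter readings are used as-is.
#'
#' @param curve a titration record: list or data.frame with `acid_ml`
#'   (cumulative acid volume, mL) and `ph` columns, plus `sample_ml`,
#'   `acid_mol_l`, `temperature`, `salinity` (attributes or list fields;
#'   see [generate_titration()] and [read_titration_csv()]).
#' @param gran_window pH window (inclusive) defining the linear region.
#' @return list with `alkalinity` (umol/kg-SW), `ve_ml`, `n_points`, and
#'   the fitted Gran line.
#' @export
gran_alkalinity <- function(curve, gran_window = c(3.0, 3.5)) {
  acid <- curve$acid_ml
  ph <- curve$ph
  stopifnot(length(acid) == length(ph), all(diff(acid) > 0))
  v0 <- titration_field(curve, "sample_ml")
  c_acid <- titration_field(curve, "acid_mol_l")
  temp <- titration_field(curve, "temperature")
  sal <- titration_field(curve, "salinity")
  in_win <- ph >= gran_window[1] & ph <= gran_window[2]
  if (sum(in_win) < 3) {
    stop(sprintf("only %d titration points in the Gran pH window [%g, %g]; need >= 3",
                 sum(in_win), gran_window[1], gran_window[2]))
  }
  Fg <- (v0 + acid[in_win]) * 10^(-ph[in_win])
  fit <- fast_slope(acid[in_win], Fg)
  ve <- -fit$intercept / fit$slope
  if (ve <= 0) stop("Gran fit produced a non-positive equivalence volume")
  rho <- seawater_density(temp, sal)
  ta <- ve / 1000 * c_acid / (v0 / 1000 * rho) * 1e6
  list(alkalinity = ta, ve_ml = ve, n_points = sum(in_win),
       slope = fit$slope, intercept = fit$intercept)
}

titration_field <- function(curve, name) {
  val <- curve[[name]]
  if (is.null(val)) val <- attr(curve, name)
  if (is.null(val)) stop(sprintf("titration curve lacks '%s'", name))
  val[1]
}
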