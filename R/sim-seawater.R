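# Synthetic seawater: treatment-water chemistry and Gran titration curves
# with known true alkalinity.

# Total alkalinity implied by the carbonate model at a given seawater-scale
# [H+], DIC in mol/kg. Shares its speciation conventions with solve_pco2().
ta_from_h <- function(h, dic, k) {
  denom <- h^2 + k$K1 * h + k$K1 * k$K2
  hco3 <- dic * k$K1 * h / denom
  co3 <- dic * k$K1 * k$K2 / denom
  nc <- noncarb_alkalinity(h, k)
  hco3 + 2 * co3 + nc$borate + nc$oh - nc$hfree - nc$hso4
}

# pH_NBS of a sample with known TA and DIC (mol/kg) at T, S.
ph_from_ta_dic <- function(ta, dic, k) {
  f <- function(ph_sws) ta_from_h(10^(-ph_sws), dic, k) - ta
  ph_sws <- uniroot(f, c(1.5, 10), tol = 1e-12)$root
  -log10(10^(-ph_sws) * k$fH)
}

#' Simulate an open-cell Gran titration of seawater with known alkalinity
#'
#' A 50 mL seawater sample of known total alkalinity is dosed with 0.1 M
#' HCl in 0.1 mL increments. After each addition the remaining alkalinity
#' and diluted DIC are updated by mass balance and the pH (NBS scale) is
#' solved from the same carbonate-system model used by [solve_pco2()],
#' optionally with Gaussian meter noise. The returned curve carries the
#' true alkalinity so recovery by [gran_alkalinity()] can be scored.
#'
#' @param true_alkalinity true total alkalinity, umol per kg seawater.
#' @param dic initial dissolved inorganic carbon, umol/kg; by default set
#'   so the undosed sample sits at pH_NBS 8.0.
#' @param sample_ml sample volume, mL.
#' @param acid_mol_l titrant concentration, mol/L.
#' @param increment_ml acid increment, mL.
#' @param n_steps number of increments (curve must pass pH ~3).
#' @param temperature,salinity titration conditions.
#' @param ph_noise_sd meter noise standard deviation (pH units).
#' @param seed integer seed (used only when `ph_noise_sd > 0`).
#' @return a `data.frame` with `acid_ml` and `ph`, carrying attributes
#'   `sample_ml`, `acid_mol_l`, `temperature`, `salinity`,
#'   `true_alkalinity`.
#' @export
generate_titration <- function(true_alkalinity, dic = NULL,
                               sample_ml = 50, acid_mol_l = 0.1,
                               increment_ml = 0.1, n_steps = 25,
                               temperature = 25, salinity = 37,
                               ph_noise_sd = 0, seed = 1) {
  stopifnot(true_alkalinity > 0)
  k <- equilibrium_constants(temperature, salinity)
  rho <- seawater_density(temperature, salinity)
  m0 <- sample_ml / 1000 * rho                      # kg of seawater
  ta0 <- true_alkalinity * 1e-6
  if (is.null(dic)) {
    # choose DIC so the undosed sample reads pH_NBS 8.0
    f <- function(d) ph_from_ta_dic(ta0, d, k) - 8.0
    dic <- uniroot(f, c(0.5, 1.2) * ta0, tol = 1e-12)$root * 1e6
  }
  dic0 <- dic * 1e-6
  acid <- seq_len(n_steps) * increment_ml
  ph <- vapply(acid, function(v) {
    m_acid <- v / 1000                              # ~1 kg/L titrant
    m <- m0 + m_acid
    ta_v <- (ta0 * m0 - acid_mol_l * v / 1000) / m
    dic_v <- dic0 * m0 / m
    ph_from_ta_dic(ta_v, dic_v, k)
  }, numeric(1))
  if (ph_noise_sd > 0) {
    ph <- ph + with_seed(child_seed(seed, "titration"),
                         rnorm(length(ph), 0, ph_noise_sd))
  }
  out <- data.frame(acid_ml = acid, ph = ph)
  attr(out, "sample_ml") <- sample_ml
  attr(out, "acid_mol_l") <- acid_mol_l
  attr(out, "temperature") <- temperature
  attr(out, "salinity") <- salinity
  attr(out, "true_alkalinity") <- true_alkalinity
  out
}
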