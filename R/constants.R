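# Physical constants used across the package.
# Tweezers arm works in pN / nm / s, energies in kBT.
# Coarse-grained arm works in kcal/mol / Angstrom, per the CG literature.

#' Boltzmann constant in pN nm / K
#' @noRd
.KB_PN_NM <- 0.01380649

#' Boltzmann constant in kcal mol^-1 K^-1
#' @noRd
.KB_KCAL <- 0.0019872

#' Coulomb constant e^2 * N_A / (4 pi eps0), in kcal mol^-1 Angstrom
#' (energy of two unit charges 1 Angstrom apart in vacuum)
#' @noRd
.COULOMB_KCAL_A <- 332.0637

#' Thermal energy in pN nm
#'
#' @param temperature temperature in Kelvin
#' @return k_B T in pN nm
#' @export
kBT_pN_nm <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  .KB_PN_NM * temperature
}

#' Thermal energy in kcal/mol
#'
#' @param temperature temperature in Kelvin
#' @return k_B T in kcal/mol
#' @export
kBT_kcal <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  .KB_KCAL * temperature
}
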