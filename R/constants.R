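#' Physical constants and unit helpers
#'
#' The package works in the unit system conventional for protein
#' biophysics: concentrations in micromolar (subunit units unless stated
#' otherwise), energies in kcal/mol, temperatures in Kelvin internally
#' (Celsius accepted at I/O boundaries), rates in s^-1.
#'
#' @name constants
#' @keywords internal
NULL

# Gas constant, kcal mol^-1 K^-1
R_KCAL <- 1.987e-3

# Boltzmann constant (J K^-1) and Planck constant (J s), SI exact values
K_BOLTZMANN <- 1.380649e-23
H_PLANCK <- 6.62607015e-34

#' Convert Celsius to Kelvin
#'
#' @param x temperature in degrees Celsius.
#' @return temperature in Kelvin.
#' @export
celsius_to_kelvin <- function(x) x + 273.15

#' Convert Kelvin to Celsius
#'
#' @param x temperature in Kelvin.
#' @return temperature in degrees Celsius.
#' @export
kelvin_to_celsius <- function(x) x - 273.15

#' Dynamic viscosity of water
#'
#' Interpolates tabulated water viscosities at common experimental
#' temperatures (20, 25, 37 degrees C). Used as the default solvent
#' viscosity in Stokes-Einstein conversions; override for buffers.
#'
#' @param temperature_K temperature in Kelvin.
#' @return viscosity in Pa s.
#' @export
water_viscosity <- function(temperature_K) {
  stopifnot(temperature_K > 0)
  tab_T <- celsius_to_kelvin(c(20, 25, 37))
  tab_eta <- c(1.002e-3, 0.890e-3, 0.6913e-3)
  # log-linear interpolation is accurate to <1% over 15-45 C
  exp(stats::approx(tab_T, log(tab_eta), xout = temperature_K, rule = 2)$y)
}

# internal: stop with a classed condition so callers can test error classes
stop_dimerscape <- function(msg, class) {
  stop(structure(
    class = c(class, "dimerscape_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
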