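#' Fit a pulsed-field-gradient (DOSY) attenuation decay
#'
#' Stejskal-Tanner fit of signal intensity against gradient strength for
#' square gradient pulses:
#' `I(g) = I0 exp(-D gamma^2 g^2 delta^2 (Delta - delta/3))`, with
#' `g = gradient_fraction * g_max`. The fit is invariant to rescaling of
#' the intensities (I0 is free).
#'
#' @param gradient_fraction gradient amplitudes as fractions of `g_max`
#'   (>= 8 steps).
#' @param intensity peak intensities (positive).
#' @param gamma gyromagnetic ratio, rad s^-1 T^-1 (default 1H).
#' @param g_max maximum gradient strength, T m^-1.
#' @param delta gradient pulse length, s.
#' @param Delta diffusion time, s.
#' @param temperature sample temperature, K (carried to the result).
#' @param viscosity solvent viscosity, Pa s; defaults to water at
#'   `temperature` via [water_viscosity()].
#' @return object of class `diffusion_fit`: `D` (m^2 s^-1), `logD`
#'   (log10), `D_se`, `hydrodynamic_diameter` (Angstrom, via
#'   [stokes_einstein_diameter()] when temperature is supplied),
#'   `temperature`, `viscosity`.
#' @export
fit_stejskal_tanner <- function(gradient_fraction, intensity,
                                gamma = 2.6752218744e8, g_max = 0.535,
                                delta = 3e-3, Delta = 0.2,
                                temperature = NA_real_, viscosity = NULL) {
  if (length(gradient_fraction) < 8) {
    stop_dimerscape("need >= 8 gradient steps", "invalid_input")
  }
  if (any(intensity <= 0)) {
    stop_dimerscape("intensities must be positive", "invalid_input")
  }
  g <- gradient_fraction * g_max
  b <- gamma^2 * g^2 * delta^2 * (Delta - delta / 3)  # s m^-2
  # log-linear solution; exact for noiseless single-exponential decays
  fit <- stats::lm(log(intensity) ~ b)
  sfit <- suppressWarnings(summary(fit))
  D <- -unname(stats::coef(fit)[2])
  if (!is.finite(D) || D <= 0 ||
      abs(D) * diff(range(b)) < 3 * sfit$sigma) {
    stop_dimerscape("intensities do not decay with gradient", "no_decay")
  }
  # refine on the natural intensity scale (log-fit overweights weak points)
  resid_fn <- function(p) intensity - exp(p[1]) * exp(-exp(p[2]) * b)
  best <- multistart_lm(resid_fn,
                        c(unname(stats::coef(fit)[1]), log(D)),
                        n_starts = 3, seed = 1L)
  if (!is.null(best)) {
    D <- exp(best$par[2])
    D_se <- param_se(best)[2] * D
  } else {
    D_se <- sfit$coefficients[2, 2]
  }
  eta <- NULL; diam <- NA_real_
  if (is.finite(temperature)) {
    eta <- if (is.null(viscosity)) water_viscosity(temperature) else viscosity
    diam <- stokes_einstein_diameter(D, temperature, eta)
  }
  structure(list(D = D, logD = log10(D), D_se = D_se,
                 hydrodynamic_diameter = diam,
                 temperature = temperature,
                 viscosity = if (is.null(eta)) NA_real_ else eta),
            class = "diffusion_fit")
}

#' Hydrodynamic diameter from a diffusion coefficient
#'
#' Stokes-Einstein relation for a sphere:
#' `d = k_B T / (3 pi eta D)`, reported in Angstrom.
#'
#' @param D translational diffusion coefficient, m^2 s^-1.
#' @param temperature temperature, K.
#' @param viscosity solvent viscosity, Pa s.
#' @return hydrodynamic diameter, Angstrom.
#' @examples
#' stokes_einstein_diameter(4.55e-11, 293.15, 1.002e-3)  # ~ 94 Angstrom
#' @export
stokes_einstein_diameter <- function(D, temperature, viscosity) {
  if (any(D <= 0) || any(temperature <= 0) || any(viscosity <= 0)) {
    stop_dimerscape("D, temperature and viscosity must be positive",
                    "invalid_parameter")
  }
  K_BOLTZMANN * temperature / (3 * pi * viscosity * D) * 1e10
}

#' Diffusion coefficient from a hydrodynamic diameter
#'
#' Inverse of [stokes_einstein_diameter()].
#'
#' @param diameter hydrodynamic diameter, Angstrom.
#' @param temperature temperature, K.
#' @param viscosity solvent viscosity, Pa s.
#' @return diffusion coefficient, m^2 s^-1.
#' @export
diameter_to_D <- function(diameter, temperature, viscosity) {
  if (any(diameter <= 0) || any(temperature <= 0) || any(viscosity <= 0)) {
    stop_dimerscape("diameter, temperature and viscosity must be positive",
                    "invalid_parameter")
  }
  K_BOLTZMANN * temperature / (3 * pi * viscosity * diameter * 1e-10)
}

#' Dimer population from an observed diffusion coefficient
#'
#' Under fast monomer-dimer exchange on the diffusion timescale the
#' observed coefficient is the population-weighted average
#' `D_obs = f_M D_monomer + (1 - f_M) D_dimer`; inverting gives the
#' subunit fraction in dimers, `1 - f_M`. Observations outside the
#' `[D_dimer, D_monomer]` interval are clipped with a warning.
#'
#' @param D_obs observed diffusion coefficient.
#' @param D_monomer,D_dimer reference coefficients of the pure species
#'   (`D_monomer > D_dimer > 0`); any consistent units.
#' @return dimer subunit fraction in \[0, 1\].
#' @export
two_species_population <- function(D_obs, D_monomer, D_dimer) {
  if (D_dimer <= 0 || D_monomer <= D_dimer) {
    stop_dimerscape("require D_monomer > D_dimer > 0", "invalid_input")
  }
  if (any(D_obs > D_monomer) || any(D_obs < D_dimer)) {
    warning("D_obs outside [D_dimer, D_monomer]: clipped to the interval")
    D_obs <- pmin(pmax(D_obs, D_dimer), D_monomer)
  }
  f_M <- (D_obs - D_dimer) / (D_monomer - D_dimer)
  1 - f_M
}
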