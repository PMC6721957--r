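#' Fit a single-exponential aggregation decay
#'
#' Isothermal CD traces of an aggregating monomer lose signal as a
#' first-order process: `theta(t) = theta_inf + (theta_0 - theta_inf)
#' exp(-k_Ag t)`. The estimate of `k_Ag` is invariant to affine
#' transformations of the signal (amplitude and offset are free).
#'
#' @param time times, s (increasing; >= 10 points).
#' @param ellipticity CD signal at each time.
#' @param temperature trace temperature, Kelvin (carried through to the
#'   result for downstream Arrhenius analysis).
#' @param n_starts,seed multi-start controls.
#' @return object of class `decay_fit`: `k_Ag` (s^-1), `amplitude`,
#'   `offset`, standard errors, `flags` (short-trace warning when the
#'   trace covers < 3/k_Ag).
#' @export
fit_decay <- function(time, ellipticity, temperature = NA_real_,
                      n_starts = 5, seed = 1L) {
  if (length(time) < 10) {
    stop_dimerscape("decay trace needs >= 10 points", "invalid_input")
  }
  if (is.unsorted(time, strictly = FALSE)) {
    ord <- order(time); time <- time[ord]; ellipticity <- ellipticity[ord]
  }
  y <- ellipticity
  span <- diff(range(y))
  # noise scale from second differences (trend-insensitive)
  noise <- stats::sd(diff(diff(y))) / sqrt(6)
  if (!is.finite(noise)) noise <- 0
  if (span < 3 * noise || span == 0) {
    stop_dimerscape("no decay: amplitude below 3x noise", "no_decay")
  }
  # log-linear initialization on the baseline-subtracted signal
  y_inf0 <- y[length(y)]
  amp0 <- y[1] - y_inf0
  z <- (y - y_inf0) / amp0
  okz <- z > 0.05
  k0 <- if (sum(okz) >= 3) {
    max(-stats::coef(stats::lm(log(z[okz]) ~ time[okz]))[2], 1e-9)
  } else 1 / max(time)
  resid_fn <- function(p) y - (p[2] + p[3] * exp(-exp(p[1]) * time))
  start <- c(log(k0), y_inf0, amp0)
  best <- multistart_lm(resid_fn, start, n_starts = n_starts, seed = seed,
                        jitter_sd = c(0.4, 0.1 * abs(span), 0.1 * abs(span)))
  if (is.null(best)) stop_dimerscape("decay fit did not converge",
                                     "fit_failure")
  p <- best$par
  k <- exp(p[1])
  se <- param_se(best)
  sigma <- sqrt(best$deviance / max(length(y) - 3, 1))
  if (abs(p[3]) < 3 * sigma) {
    stop_dimerscape("no decay: fitted amplitude below 3x residual noise",
                    "no_decay")
  }
  flags <- character()
  if (max(time) - min(time) < 3 / k) {
    flags <- c(flags, "short trace: duration < 3/k_Ag, rate poorly bounded")
  }
  structure(list(k_Ag = k, amplitude = p[3], offset = p[2],
                 k_Ag_se = se[1] * k, amplitude_se = se[3],
                 offset_se = se[2], sigma = sigma,
                 temperature = temperature, flags = flags,
                 converged = TRUE),
            class = "decay_fit")
}

#' Arrhenius analysis of temperature-dependent rates
#'
#' Linear regression of `ln k` on `1/T`: slope `= -Ea/R`, intercept
#' `= ln A` (rates referenced to 1 s^-1). Optionally weighted by
#' `1/se^2` of the log-rates.
#'
#' @param temperature temperatures, K (>= 3, duplicates allowed).
#' @param k_Ag rates at each temperature, s^-1 (all > 0).
#' @param k_se optional standard errors of the rates; when supplied the
#'   regression is weighted by the propagated log-rate variances.
#' @return object of class `arrhenius_fit`: `Ea` (kcal/mol), `lnA`,
#'   standard errors, `residuals`, and the fitted `lm` object.
#' @export
fit_arrhenius <- function(temperature, k_Ag, k_se = NULL) {
  if (length(temperature) < 3) {
    stop_dimerscape("Arrhenius fit needs >= 3 temperatures", "invalid_input")
  }
  if (any(k_Ag <= 0)) {
    stop_dimerscape("all rates must be positive", "invalid_input")
  }
  x <- 1 / temperature
  yl <- log(k_Ag)
  w <- NULL
  if (!is.null(k_se)) w <- (k_Ag / k_se)^2  # var(log k) = (se/k)^2
  fit <- if (is.null(w)) stats::lm(yl ~ x) else stats::lm(yl ~ x, weights = w)
  # noiseless rate sets fit exactly; the perfect-fit warning is expected
  co <- suppressWarnings(summary(fit)$coefficients)
  Ea <- -co[2, 1] * R_KCAL
  structure(list(Ea = Ea, lnA = co[1, 1],
                 Ea_se = co[2, 2] * R_KCAL, lnA_se = co[1, 2],
                 residuals = stats::residuals(fit), lm = fit),
            class = "arrhenius_fit")
}

#' Transition-state-theory pre-exponential factor
#'
#' Natural log of the Eyring frequency factor `k_B T / h` relative to a
#' 1 s^-1 reference (transmission coefficient taken as 1).
#'
#' @param temperature temperature, K.
#' @return `ln(k_B T / h)`, dimensionless (s^-1 reference).
#' @examples
#' eyring_prefactor(310.15)  # ~ 29.5
#' @export
eyring_prefactor <- function(temperature) {
  if (any(temperature <= 0)) {
    stop_dimerscape("temperature must be positive", "invalid_parameter")
  }
  log(K_BOLTZMANN * temperature / H_PLANCK)
}

#' Free-energy barrier from a rate constant (Eyring)
#'
#' `dG_barrier = R T [ln(k_B T / h) - ln k]`, the transition-state free
#' energy corresponding to a first-order rate at the given temperature.
#'
#' @param k rate constant, s^-1 (> 0).
#' @param temperature temperature, K.
#' @return barrier free energy, kcal/mol.
#' @examples
#' barrier_free_energy(4.5e-4, 310.15)  # ~ 22.9 kcal/mol
#' @export
barrier_free_energy <- function(k, temperature = 310.15) {
  if (any(k <= 0)) stop_dimerscape("rate must be positive", "invalid_input")
  R_KCAL * temperature * (eyring_prefactor(temperature) - log(k))
}

#' Rate constant from an Eyring barrier
#'
#' Inverse of [barrier_free_energy()]:
#' `k = (k_B T / h) exp(-dG / (R T))`.
#'
#' @param dG_barrier barrier free energy, kcal/mol.
#' @param temperature temperature, K.
#' @return rate constant, s^-1.
#' @export
eyring_rate <- function(dG_barrier, temperature = 310.15) {
  exp(eyring_prefactor(temperature) - dG_barrier / (R_KCAL * temperature))
}
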