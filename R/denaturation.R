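#' A circular-dichroism thermal melt curve
#'
#' Container for a single-wavelength (222 nm) thermal denaturation scan.
#' Temperatures are stored in Kelvin; Celsius input is converted.
#'
#' @param temperature scan temperatures (strictly increasing after
#'   sorting), in the unit given by `unit`.
#' @param ellipticity CD signal at each temperature (millidegrees or
#'   molar ellipticity; fits are scale-invariant through the baselines).
#' @param C_T total protein concentration, uM (subunit units).
#' @param label free-text label for the sample.
#' @param unit `"K"` or `"C"`.
#' @return object of class `melt_curve`.
#' @export
melt_curve <- function(temperature, ellipticity, C_T = NA_real_,
                       label = "", unit = c("K", "C")) {
  unit <- match.arg(unit)
  if (unit == "C") temperature <- celsius_to_kelvin(temperature)
  if (anyNA(temperature) || anyNA(ellipticity)) {
    stop_dimerscape("melt curve contains missing values", "invalid_input")
  }
  if (length(temperature) != length(ellipticity)) {
    stop_dimerscape("temperature and ellipticity lengths differ",
                    "invalid_input")
  }
  ord <- order(temperature)
  temperature <- temperature[ord]; ellipticity <- ellipticity[ord]
  if (length(temperature) < 20) {
    stop_dimerscape("melt curve needs >= 20 points", "invalid_input")
  }
  if (diff(range(temperature)) < 30) {
    stop_dimerscape("melt curve must span >= 30 K", "invalid_input")
  }
  structure(list(temperature = temperature, ellipticity = ellipticity,
                 C_T = C_T, label = label),
            class = "melt_curve")
}

# two-state LEM forward model pieces ----------------------------------------

# unfolded population of a van't Hoff transition (dCp = 0):
# dG(T) = dH (1 - T/Tm); p_U = K/(1+K), K = exp(-dG/RT)
lem_pu <- function(temp, Tm, dH) {
  dG <- dH * (1 - temp / Tm)
  1 / (1 + exp(dG / (R_KCAL * temp)))
}

# observed signal: linear baselines mixed by the unfolded population
lem_signal <- function(temp, Tref, bf, bu, pu) {
  thetaF <- bf[1] + bf[2] * (temp - Tref)
  thetaU <- bu[1] + bu[2] * (temp - Tref)
  thetaF * (1 - pu) + thetaU * pu
}

#' Unfolding free energy from two-state melt parameters
#'
#' Pure van't Hoff extrapolation `dG(T) = dH (1 - T/Tm)` (zero heat
#' capacity change), exactly zero at `T = Tm`.
#'
#' @param params a `two_state_fit` from [fit_two_state_melt()], or a list
#'   with `Tm` (K) and `dH_vH` (kcal/mol).
#' @param temperature temperature(s), Kelvin.
#' @return dG_MU in kcal/mol.
#' @export
two_state_dG <- function(params, temperature) {
  params$dH_vH * (1 - temperature / params$Tm)
}

#' Fit a two-state thermal melt (linear extrapolation model)
#'
#' Least-squares fit of
#' `theta(T) = [theta_F(T) + theta_U(T) K(T)] / [1 + K(T)]` with
#' `K(T) = exp(-dG(T)/RT)` and `dG(T) = dH (1 - T/Tm)`: two linear
#' baselines plus a van't Hoff transition. Multi-start
#' Levenberg-Marquardt with data-driven initialization.
#'
#' @param curve a [melt_curve()].
#' @param n_starts,seed multi-start controls.
#' @return object of class `two_state_fit`: `Tm` (K), `dH_vH` (kcal/mol),
#'   `baseline_folded`, `baseline_unfolded` (intercept/slope at the
#'   reference temperature `Tref`), standard errors `Tm_se`, `dH_se`,
#'   residual sd `sigma`, and `flags`.
#' @export
fit_two_state_melt <- function(curve, n_starts = 5, seed = 1L) {
  stopifnot(inherits(curve, "melt_curve"))
  temp <- curve$temperature; y <- curve$ellipticity
  Tref <- mean(temp)
  span <- diff(range(y))
  lin <- stats::lm(y ~ temp)
  lin_sigma <- suppressWarnings(summary(lin)$sigma)  # warns on exact fits
  if (span == 0 || lin_sigma < 1e-10 * max(span, 1e-10)) {
    stop_dimerscape("no unfolding transition detected (flat/linear curve)",
                    "fit_failure")
  }
  init <- melt_init(temp, y, Tref)
  resid_fn <- function(p) {
    pu <- lem_pu(temp, p[5], exp(p[6]))
    y - lem_signal(temp, Tref, p[1:2], p[3:4], pu)
  }
  start <- c(init$bf, init$bu, init$Tm, log(init$dH))
  best <- multistart_lm(resid_fn, start, n_starts = n_starts, seed = seed,
                        jitter_sd = c(abs(span) * 0.05, 0.01 * abs(span),
                                      abs(span) * 0.05, 0.01 * abs(span),
                                      3, 0.2))
  if (is.null(best)) stop_dimerscape("melt fit did not converge", "fit_failure")
  p <- best$par
  Tm <- p[5]; dH <- exp(p[6])
  if (Tm < min(temp) || Tm > max(temp)) {
    stop_dimerscape(sprintf(
      "fitted midpoint %.1f K lies outside the scanned range [%.1f, %.1f] K",
      Tm, min(temp), max(temp)), "fit_failure")
  }
  sigma <- sqrt(best$deviance / max(length(y) - 6, 1))
  amp <- abs(lem_signal(Tm, Tref, p[3:4], p[3:4], 1) -
             lem_signal(Tm, Tref, p[1:2], p[1:2], 0))
  if (amp < 3 * sigma) {
    stop_dimerscape("transition amplitude below 3x residual noise",
                    "fit_failure")
  }
  flags <- character()
  if (Tm - min(temp) < 10 || max(temp) - Tm < 10) {
    flags <- c(flags, "baseline span < 10 K on one side of the transition")
  }
  se <- param_se(best)
  structure(list(Tm = Tm, dH_vH = dH,
                 baseline_folded = p[1:2], baseline_unfolded = p[3:4],
                 Tref = Tref,
                 Tm_se = se[5], dH_se = se[6] * dH, sigma = sigma,
                 flags = flags, converged = TRUE),
            class = "two_state_fit")
}

# data-driven starting values for a melt: baselines from the scan ends,
# Tm from the steepest point of a smoothed curve
melt_init <- function(temp, y, Tref) {
  n <- length(temp)
  lo <- seq_len(max(3, floor(n * 0.15)))
  hi <- seq(n - max(3, floor(n * 0.15)) + 1, n)
  bf <- stats::coef(stats::lm(y[lo] ~ I(temp[lo] - Tref)))
  bu <- stats::coef(stats::lm(y[hi] ~ I(temp[hi] - Tref)))
  sm <- stats::smooth.spline(temp, y, spar = 0.6)
  d1 <- stats::predict(sm, temp, deriv = 1)$y
  interior <- temp > stats::quantile(temp, 0.05) &
              temp < stats::quantile(temp, 0.95)
  Tm <- temp[interior][which.max(abs(d1[interior]))]
  list(bf = unname(bf), bu = unname(bu), Tm = Tm, dH = 60)
}

#' Global bimodal fit of a concentration series of melts
#'
#' Concentration-dependent melts of an aggregation-prone dimer show two
#' apparent transitions: an aggregation-coupled event at `Tm1` whose
#' weight is the aggregate molar fraction `chi_A` of that sample, and the
#' monomer unfolding at `Tm2`. The observed signal is modelled as a
#' convex combination of two van't Hoff transitions sharing the folded
#' and unfolded baselines:
#' `p_U(T) = chi_A p1(T) + (1 - chi_A) p2(T)`, signal
#' `theta = theta_F (1 - p_U) + theta_U p_U`. `Tm1`, `Tm2`, both
#' enthalpies and the baselines are shared across curves; `chi_A` is one
#' free parameter per curve, kept in \[0, 1\] by a logistic transform.
#' With `chi_A = 0` the model collapses to the single two-state melt.
#'
#' @param curves list of [melt_curve()] at distinct concentrations.
#' @param chiA_fixed optional numeric vector: fix `chi_A` per curve
#'   instead of fitting (used for the single-curve fallback and for the
#'   reduction check).
#' @param n_starts,seed multi-start controls.
#' @return object of class `bimodal_fit`: `Tm1`, `Tm2` (K), `dH1`, `dH2`
#'   (kcal/mol), shared baselines, data.frame `chiA` (`C_T`, `label`,
#'   `chiA`, `chiA_se`), standard errors, `sigma`, `flags`.
#' @export
fit_bimodal_melts <- function(curves, chiA_fixed = NULL,
                              n_starts = 8, seed = 1L) {
  if (inherits(curves, "melt_curve")) curves <- list(curves)
  stopifnot(all(vapply(curves, inherits, TRUE, "melt_curve")))
  nc <- length(curves)
  if (nc < 2 && is.null(chiA_fixed)) {
    warning("single curve supplied: chi_A fixed at 0.5 (not identifiable)")
    chiA_fixed <- 0.5
  }
  if (!is.null(chiA_fixed)) chiA_fixed <- rep_len(chiA_fixed, nc)
  temp_all <- unlist(lapply(curves, `[[`, "temperature"))
  y_all <- unlist(lapply(curves, `[[`, "ellipticity"))
  idx <- rep(seq_len(nc), vapply(curves, function(cv) length(cv$temperature),
                                 1L))
  Tref <- mean(temp_all)
  free_chi <- is.null(chiA_fixed)

  model <- function(p) {
    bf <- p[1:2]; bu <- p[3:4]
    Tm1 <- p[5]; Tm2 <- p[5] + exp(p[6])  # enforces Tm1 < Tm2
    dH1 <- exp(p[7]); dH2 <- exp(p[8])
    chi <- if (free_chi) stats::plogis(p[8 + seq_len(nc)]) else chiA_fixed
    pu1 <- lem_pu(temp_all, Tm1, dH1)
    pu2 <- lem_pu(temp_all, Tm2, dH2)
    pu <- chi[idx] * pu1 + (1 - chi[idx]) * pu2
    lem_signal(temp_all, Tref, bf, bu, pu)
  }
  resid_fn <- function(p) y_all - model(p)

  # initialize from the steepest curve's derivative structure
  ref <- curves[[which.max(vapply(curves, function(cv) cv$C_T, 1))]]
  if (is.na(ref$C_T[1])) ref <- curves[[nc]]
  init <- melt_init(ref$temperature, ref$ellipticity, Tref)
  guess <- two_transition_guess(ref$temperature, ref$ellipticity)
  start <- c(init$bf, init$bu, guess[1], log(max(guess[2] - guess[1], 5)),
             log(60), log(60))
  if (free_chi) start <- c(start, rep(0, nc))
  best <- multistart_lm(resid_fn, start, n_starts = n_starts, seed = seed,
                        jitter_sd = 0.25)
  if (is.null(best)) {
    stop_dimerscape("bimodal global fit did not converge", "fit_failure")
  }
  p <- best$par
  se <- param_se(best)
  chi <- if (free_chi) stats::plogis(p[8 + seq_len(nc)]) else chiA_fixed
  chi_se <- if (free_chi) {
    se[8 + seq_len(nc)] * chi * (1 - chi)  # delta method through plogis
  } else rep(NA_real_, nc)
  structure(list(
    Tm1 = p[5], Tm2 = p[5] + exp(p[6]),
    dH1 = exp(p[7]), dH2 = exp(p[8]),
    baseline_folded = p[1:2], baseline_unfolded = p[3:4], Tref = Tref,
    Tm1_se = se[5],
    Tm2_se = sqrt(sum(c(se[5], se[6] * exp(p[6]))^2, na.rm = TRUE)),
    chiA = data.frame(
      C_T = vapply(curves, function(cv) cv$C_T, 1),
      label = vapply(curves, function(cv) cv$label, ""),
      chiA = chi, chiA_se = chi_se),
    sigma = sqrt(best$deviance / max(length(y_all) - length(p), 1)),
    flags = character(), converged = TRUE),
    class = "bimodal_fit")
}

# locate two candidate transition midpoints from derivative peaks;
# falls back to the 35%/65% quantiles of the scan
two_transition_guess <- function(temp, y) {
  sm <- stats::smooth.spline(temp, y, spar = 0.6)
  d1 <- abs(stats::predict(sm, temp, deriv = 1)$y)
  cand <- which(diff(sign(diff(d1))) < 0) + 1L
  cand <- cand[temp[cand] > stats::quantile(temp, 0.05) &
               temp[cand] < stats::quantile(temp, 0.95)]
  cand <- cand[order(d1[cand], decreasing = TRUE)]
  picks <- numeric()
  for (i in cand) {
    if (all(abs(temp[i] - picks) > 8)) picks <- c(picks, temp[i])
    if (length(picks) == 2) break
  }
  if (length(picks) < 2) {
    picks <- stats::quantile(temp, c(0.35, 0.65))
  }
  sort(unname(picks))
}

#' Fit an isothermal chemical denaturation curve
#'
#' Two-state linear extrapolation model in denaturant concentration:
#' `dG(c) = dG0 - m c`, signal mixed between linear baselines as in the
#' thermal case. Sign-agnostic in the ellipticity direction.
#'
#' @param denaturant denaturant concentrations, M (>= 15 points).
#' @param ellipticity CD signal.
#' @param temperature experiment temperature, Kelvin (enters dG via RT).
#' @param n_starts,seed multi-start controls.
#' @return object of class `chem_denat_fit`: `dG0` (kcal/mol), `m_value`
#'   (kcal/mol/M), `Cm = dG0/m` (M), baselines, standard errors, `sigma`.
#' @export
fit_chemical_denaturation <- function(denaturant, ellipticity,
                                      temperature = 310.15,
                                      n_starts = 5, seed = 1L) {
  if (length(denaturant) < 15) {
    stop_dimerscape("need >= 15 denaturant points", "invalid_input")
  }
  if (anyNA(denaturant) || anyNA(ellipticity)) {
    stop_dimerscape("missing values in denaturation data", "invalid_input")
  }
  ord <- order(denaturant)
  x <- denaturant[ord]; y <- ellipticity[ord]
  RT <- R_KCAL * temperature
  xref <- mean(x)
  span <- diff(range(y))
  if (span == 0) stop_dimerscape("flat curve: no transition", "fit_failure")
  n <- length(x)
  lo <- seq_len(max(3, floor(n * 0.15)))
  hi <- seq(n - max(3, floor(n * 0.15)) + 1, n)
  bf0 <- stats::coef(stats::lm(y[lo] ~ I(x[lo] - xref)))
  bu0 <- stats::coef(stats::lm(y[hi] ~ I(x[hi] - xref)))
  sm <- stats::smooth.spline(x, y, spar = 0.6)
  d1 <- stats::predict(sm, x, deriv = 1)$y
  Cm0 <- x[which.max(abs(d1))]
  m0 <- 2
  resid_fn <- function(p) {
    dG <- p[5] - exp(p[6]) * x
    pu <- 1 / (1 + exp(dG / RT))
    thetaF <- p[1] + p[2] * (x - xref)
    thetaU <- p[3] + p[4] * (x - xref)
    y - (thetaF * (1 - pu) + thetaU * pu)
  }
  start <- c(unname(bf0), unname(bu0), m0 * Cm0, log(m0))
  best <- multistart_lm(resid_fn, start, n_starts = n_starts, seed = seed,
                        jitter_sd = c(rep(0.05 * abs(span), 4), 1, 0.3))
  if (is.null(best)) {
    stop_dimerscape("chemical denaturation fit did not converge",
                    "fit_failure")
  }
  p <- best$par
  dG0 <- p[5]; m <- exp(p[6])
  Cm <- dG0 / m
  if (Cm < min(x) || Cm > max(x)) {
    stop_dimerscape("denaturation midpoint outside the sampled range",
                    "fit_failure")
  }
  se <- param_se(best)
  structure(list(dG0 = dG0, m_value = m, Cm = Cm,
                 baseline_folded = p[1:2], baseline_unfolded = p[3:4],
                 xref = xref, dG0_se = se[5], m_se = se[6] * m,
                 sigma = sqrt(best$deviance / max(length(y) - 6, 1)),
                 converged = TRUE),
            class = "chem_denat_fit")
}

#' Destabilization free energy from a melting-temperature shift
#'
#' First-order estimate of the change in unfolding free energy between a
#' reference (wild-type) protein and a variant from the shift in melting
#' temperature: `ddG = dH (Tm_wt - Tm_mut) / Tm_wt`, with the van't Hoff
#' enthalpy at the reference Tm. Positive when the variant is
#' destabilized.
#'
#' @param dH_Tm van't Hoff enthalpy at the reference Tm, kcal/mol.
#' @param Tm_wt,Tm_mut reference and variant melting temperatures, K.
#' @return ddG in kcal/mol.
#' @examples
#' ddg_from_tm_shift(75, 341.45, 341.45 - 4.553)  # ~ 1 kcal/mol
#' @export
ddg_from_tm_shift <- function(dH_Tm, Tm_wt, Tm_mut) {
  if (Tm_wt <= 0 || Tm_mut <= 0) {
    stop_dimerscape("Tm values must be positive (Kelvin)", "invalid_parameter")
  }
  dH_Tm * (Tm_wt - Tm_mut) / Tm_wt
}

#' Aggregation phase diagram from aggregate fractions
#'
#' The soluble-monomer fraction `1 - chi_A` inferred from the bimodal
#' melt analysis decays with total concentration; a phenomenological
#' exponential `1 - chi_A = exp(-C_T / C_star)` captures the trend. The
#' resulting monomer line `[M] = (1 - chi_A) C_T` against the diagonal
#' `[M] = C_T` (a hypothetical aggregation-free species) is the phase
#' diagram: deviation below the diagonal measures aggregation propensity.
#'
#' @param C_T total concentrations, uM (>= 3 values).
#' @param chiA aggregate molar fractions in \[0, 1\], same length.
#' @return object of class `phase_diagram_fit`: `C_star` (uM; `Inf` with
#'   a flag when all `chiA = 0`), `C_star_se`, and data.frame `table`
#'   with `C_T`, `chiA`, `M`, `diagonal`, `deviation` (= 1 - M/C_T).
#' @export
phase_diagram <- function(C_T, chiA) {
  if (length(C_T) < 3 || length(C_T) != length(chiA)) {
    stop_dimerscape("need >= 3 (C_T, chiA) pairs of equal length",
                    "invalid_input")
  }
  if (any(chiA < 0 | chiA > 1)) {
    stop_dimerscape("chiA must lie in [0, 1]", "invalid_input")
  }
  if (any(C_T < 0)) stop_dimerscape("C_T must be >= 0", "invalid_input")
  tab <- data.frame(C_T = C_T, chiA = chiA, M = (1 - chiA) * C_T,
                    diagonal = C_T,
                    deviation = chiA)
  flags <- character()
  if (all(chiA == 0)) {
    return(structure(list(C_star = Inf, C_star_se = NA_real_, table = tab,
                          flags = "all chiA = 0: monomer line on the diagonal, C_star unbounded"),
                     class = "phase_diagram_fit"))
  }
  # exact on noiseless data: regression through the origin on logs,
  # then Levenberg-Marquardt refinement on the natural scale
  ok <- chiA < 1 & C_T > 0
  slope <- if (any(ok)) {
    sum(C_T[ok] * log(1 - chiA[ok])) / sum(C_T[ok]^2)
  } else -1 / stats::median(C_T[C_T > 0])
  C_star0 <- max(-1 / slope, 1e-6)
  resid_fn <- function(p) (1 - chiA) - exp(-C_T / exp(p))
  best <- multistart_lm(resid_fn, log(C_star0), n_starts = 3, seed = 1L)
  C_star <- exp(best$par[1])
  se <- param_se(best) * C_star
  structure(list(C_star = C_star, C_star_se = se, table = tab,
                 flags = flags),
            class = "phase_diagram_fit")
}
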