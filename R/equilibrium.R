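#' Monomer-dimer equilibrium specification
#'
#' A homodimeric protein at total subunit concentration `C_T` dissociates
#' with constant `K_D = [M]^2 / [D]` ([M] free monomer in subunit units,
#' [D] dimer in dimer units; mass balance `C_T = [M] + 2 [D]`).
#'
#' @param C_T total protein concentration in subunit units, uM.
#' @param K_D dimer dissociation constant, uM.
#' @param temperature temperature in Kelvin (default 310.15 K, 37 C).
#' @return an object of class `equilibrium_spec`.
#' @examples
#' equilibrium_spec(C_T = 1, K_D = 0.5)
#' @export
equilibrium_spec <- function(C_T, K_D, temperature = 310.15) {
  if (!is.numeric(K_D) || any(K_D <= 0)) {
    stop_dimerscape("K_D must be positive", "invalid_parameter")
  }
  if (!is.numeric(C_T) || any(C_T < 0)) {
    stop_dimerscape("C_T must be non-negative", "invalid_parameter")
  }
  if (any(temperature <= 0)) {
    stop_dimerscape("temperature must be positive (Kelvin)", "invalid_parameter")
  }
  structure(list(C_T = C_T, K_D = K_D, temperature = temperature),
            class = "equilibrium_spec")
}

#' Partition total protein between monomer and dimer
#'
#' Solves the mass balance `C_T = [M] + 2 [M]^2 / K_D` in closed form:
#' the unique non-negative root is
#' `[M] = (K_D / 4) * (-1 + sqrt(1 + 8 C_T / K_D))`.
#' Also reports the standard-state dimer dissociation free energy
#' `dG_DM = -R T log(K_D / C0)` with reference concentration C0 = 1 M,
#' positive for a sub-molar K_D (dissociation is unfavourable).
#'
#' @param spec an [equilibrium_spec()].
#' @return list of class `equilibrium_state` with elements `M` (uM,
#'   subunit units), `D` (uM, dimer units), `fraction_dimer` (fraction of
#'   subunits in dimers; 0 for an empty system) and `dG_DM` (kcal/mol).
#' @examples
#' monomer_dimer_partition(equilibrium_spec(C_T = 1, K_D = 0.5))
#' @export
monomer_dimer_partition <- function(spec) {
  stopifnot(inherits(spec, "equilibrium_spec"))
  C_T <- spec$C_T
  K_D <- spec$K_D
  M <- (K_D / 4) * (-1 + sqrt(1 + 8 * C_T / K_D))
  M <- pmin(M, C_T)  # guard rounding at C_T ~ 0
  D <- (C_T - M) / 2
  fraction_dimer <- ifelse(C_T > 0, 2 * D / C_T, 0)
  dG_DM <- -R_KCAL * spec$temperature * log(K_D * 1e-6)  # uM -> M, C0 = 1 M
  structure(list(M = M, D = D, fraction_dimer = fraction_dimer,
                 dG_DM = dG_DM, C_T = C_T, K_D = K_D,
                 temperature = spec$temperature),
            class = "equilibrium_state")
}

#' Two-state folded population
#'
#' Boltzmann population of the folded state for a two-state monomer
#' folding equilibrium with unfolding free energy `dG_MU`:
#' `f = 1 / (1 + exp(-dG_MU / (R T)))`.
#'
#' @param dG_MU unfolding free energy, kcal/mol (positive = folded
#'   favoured).
#' @param temperature temperature, Kelvin.
#' @return folded fraction in \[0, 1\].
#' @examples
#' folded_fraction(9.5, 310.15)  # > 0.99
#' @export
folded_fraction <- function(dG_MU, temperature = 310.15) {
  if (any(temperature <= 0)) {
    stop_dimerscape("temperature must be positive", "invalid_parameter")
  }
  1 / (1 + exp(-dG_MU / (R_KCAL * temperature)))
}

#' Michaelis-Menten parameters for the dimer-only-active model
#'
#' @param Km Michaelis constant, uM.
#' @param kcat turnover number per subunit within the dimer, s^-1.
#' @param Km_se,kcat_se optional standard errors.
#' @return object of class `enzyme_kinetics`.
#' @export
enzyme_kinetics <- function(Km, kcat, Km_se = NA_real_, kcat_se = NA_real_) {
  if (Km <= 0 || kcat <= 0) {
    stop_dimerscape("Km and kcat must be positive", "invalid_parameter")
  }
  structure(list(Km = Km, kcat = kcat, Km_se = Km_se, kcat_se = kcat_se),
            class = "enzyme_kinetics")
}

#' Initial rate under dimer-only Michaelis-Menten enzymology
#'
#' Only subunits engaged in dimers carry active sites, so the velocity is
#' `v = kcat * 2 [D] * S / (Km + S)` with `[D]` from
#' [monomer_dimer_partition()]. This is the model behind activity versus
#' total-concentration titrations of obligate-dimer enzymes.
#'
#' @param spec an [equilibrium_spec()] giving `C_T` and `K_D`.
#' @param kinetics an [enzyme_kinetics()].
#' @param S substrate concentration, uM (scalar or vector).
#' @return initial rate, uM s^-1.
#' @export
dimer_activity_rate <- function(spec, kinetics, S) {
  stopifnot(inherits(kinetics, "enzyme_kinetics"))
  if (any(S < 0)) stop_dimerscape("substrate concentration must be >= 0",
                                  "invalid_parameter")
  st <- monomer_dimer_partition(spec)
  kinetics$kcat * 2 * st$D * S / (kinetics$Km + S)
}

#' Fit a Michaelis-Menten titration
#'
#' Nonlinear least-squares fit of `v = Vmax S / (Km + S)` to initial
#' rates, with multi-start Levenberg-Marquardt refinement. When the total
#' enzyme concentration and dimer dissociation constant are supplied, the
#' turnover number is normalized to active sites in dimers,
#' `kcat = Vmax / (2 [D])`; otherwise `kcat` uses all subunits
#' (`Vmax / C_T`), the uncorrected convention.
#'
#' @param S substrate concentrations, uM (>= 4 distinct values).
#' @param v initial rates, uM s^-1.
#' @param enzyme_C_T total enzyme concentration, uM (subunit units).
#' @param K_D dimer dissociation constant used for the active-site
#'   correction, uM; `NULL` disables the correction.
#' @param n_starts number of jittered starts.
#' @param seed integer seed for the start jitter.
#' @param relative minimize relative residuals (default), the maximum-
#'   likelihood choice when measurement error is proportional to the
#'   rate, as is typical of initial-rate assays; `FALSE` for absolute
#'   residuals.
#' @return list of class `mm_fit`: `Km`, `kcat`, `Vmax`, standard errors,
#'   `converged`, `flags` (character vector of warnings such as
#'   `"degenerate"`).
#' @export
fit_michaelis_menten <- function(S, v, enzyme_C_T = NULL, K_D = NULL,
                                 n_starts = 5, seed = 1L, relative = TRUE) {
  if (length(S) != length(v)) {
    stop_dimerscape("S and v must have equal length", "invalid_input")
  }
  if (length(unique(S)) < 4) {
    stop_dimerscape("need >= 4 distinct substrate concentrations",
                    "fit_failure")
  }
  flags <- character()
  if (stats::sd(v) < 1e-12 * max(abs(v), 1e-300)) {
    stop_dimerscape("rates show no substrate dependence", "fit_failure")
  }
  resid_fn <- function(p) {
    pred <- exp(p[2]) * S / (exp(p[1]) + S)
    if (relative) (v - pred) / pmax(pred, 1e-12) else v - pred
  }
  # Hanes-Woolf linearization for the starting point
  ok <- v > 0
  hw <- stats::lm(I(S[ok] / v[ok]) ~ S[ok])
  Km0 <- max(stats::coef(hw)[1] / stats::coef(hw)[2], min(S[S > 0]) / 10)
  Vmax0 <- max(1 / stats::coef(hw)[2], max(v))
  start <- log(c(Km0, Vmax0))
  best <- multistart_lm(resid_fn, start, n_starts = n_starts, seed = seed)
  if (is.null(best)) {
    stop_dimerscape("Michaelis-Menten fit did not converge", "fit_failure")
  }
  Km <- exp(best$par[1]); Vmax <- exp(best$par[2])
  se <- param_se(best) * c(Km, Vmax)  # delta method on log scale
  if (Km < min(S[S > 0]) / 50 || Km > max(S) * 50) {
    flags <- c(flags, "Km outside the sampled substrate range")
  }
  kcat <- NA_real_; kcat_se <- NA_real_; active_sites <- NA_real_
  if (!is.null(enzyme_C_T)) {
    active_sites <- if (!is.null(K_D)) {
      2 * monomer_dimer_partition(equilibrium_spec(enzyme_C_T, K_D))$D
    } else enzyme_C_T
    kcat <- Vmax / active_sites
    kcat_se <- se[2] / active_sites
  }
  structure(list(Km = Km, Vmax = Vmax, kcat = kcat,
                 Km_se = se[1], Vmax_se = se[2], kcat_se = kcat_se,
                 active_sites = active_sites,
                 converged = TRUE, flags = flags),
            class = "mm_fit")
}

#' Fit the dimer dissociation constant from an activity-vs-C_T scan
#'
#' Fits `v(C_T) = kcat * 2 [D](C_T; K_D) * S / (Km + S)` for `K_D`
#' (optionally also `kcat`) by Levenberg-Marquardt least squares.
#' When every sampled `C_T` sits far above the recovered `K_D` the dimer
#' fraction is saturated and `K_D` is unidentifiable; the result then
#' carries a warning flag.
#'
#' @param C_T total enzyme concentrations, uM (>= 5 values).
#' @param v initial rates, uM s^-1.
#' @param S_fixed the fixed substrate concentration, uM.
#' @param kinetics an [enzyme_kinetics()]; when `fit_kcat = TRUE` its
#'   `kcat` is used only as the starting value.
#' @param fit_kcat also estimate kcat (default FALSE).
#' @param n_starts,seed multi-start controls.
#' @param relative minimize relative residuals (default; matched to
#'   proportional rate noise) or absolute residuals.
#' @return list of class `kd_fit`: `K_D`, `K_D_se`, optional `kcat`,
#'   `flags`.
#' @export
fit_activity_vs_concentration <- function(C_T, v, S_fixed, kinetics,
                                          fit_kcat = FALSE,
                                          n_starts = 5, seed = 1L,
                                          relative = TRUE) {
  stopifnot(inherits(kinetics, "enzyme_kinetics"))
  if (length(C_T) < 5) {
    stop_dimerscape("need >= 5 total-concentration points", "fit_failure")
  }
  sat <- S_fixed / (kinetics$Km + S_fixed)
  model_v <- function(K_D, kcat) {
    st <- monomer_dimer_partition(equilibrium_spec(C_T, K_D))
    kcat * 2 * st$D * sat
  }
  wrap <- function(pred) {
    if (relative) (v - pred) / pmax(pred, 1e-12) else v - pred
  }
  if (fit_kcat) {
    resid_fn <- function(p) wrap(model_v(exp(p[1]), exp(p[2])))
    start <- log(c(stats::median(C_T), kinetics$kcat))
  } else {
    resid_fn <- function(p) wrap(model_v(exp(p[1]), kinetics$kcat))
    start <- log(stats::median(C_T))
  }
  best <- multistart_lm(resid_fn, start, n_starts = n_starts, seed = seed)
  if (is.null(best)) {
    stop_dimerscape("K_D fit did not converge", "fit_failure")
  }
  K_D <- exp(best$par[1])
  se <- param_se(best)
  flags <- character()
  if (min(C_T) > 10 * K_D) {
    flags <- c(flags,
      "all C_T >> K_D: dimer fraction saturated, K_D poorly identified")
  }
  if (max(C_T) < K_D / 10) {
    flags <- c(flags,
      "all C_T << K_D: dimer barely populated, K_D poorly identified")
  }
  out <- list(K_D = K_D, K_D_se = se[1] * K_D, flags = flags,
              converged = TRUE)
  if (fit_kcat) {
    out$kcat <- exp(best$par[2])
    out$kcat_se <- se[2] * out$kcat
  }
  structure(out, class = "kd_fit")
}

#' Simulate the dimer/monomer/aggregate scheme over time
#'
#' Integrates irreversible first-order monomer aggregation under the
#' rapid pre-equilibrium assumption: the dimer-monomer equilibrium
#' re-partitions instantaneously relative to aggregation, so the only
#' dynamical variable is the aggregated pool,
#' `d[Ag]/dt = k_Ag [M](C_T(0) - [Ag])`.
#'
#' @param spec an [equilibrium_spec()] giving the initial `C_T` and `K_D`.
#' @param k_Ag first-order aggregation rate of the monomer, s^-1.
#' @param t_grid times at which to report the state, s.
#' @return data.frame with columns `time`, `M`, `D`, `Ag` (uM; `Ag` and
#'   `M` in subunit units, `D` in dimer units).
#' @export
simulate_scheme1_timecourse <- function(spec, k_Ag, t_grid) {
  stopifnot(inherits(spec, "equilibrium_spec"))
  if (k_Ag < 0) stop_dimerscape("k_Ag must be >= 0", "invalid_parameter")
  C0 <- spec$C_T
  rhs <- function(t, y, parms) {
    sol <- max(C0 - y[1], 0)
    M <- monomer_dimer_partition(equilibrium_spec(sol, spec$K_D))$M
    list(k_Ag * M)
  }
  t_grid <- sort(unique(c(0, t_grid)))
  sol <- deSolve::lsoda(c(Ag = 0), t_grid, rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  Ag <- pmin(sol[, "Ag"], C0)
  st <- monomer_dimer_partition(equilibrium_spec(C0 - Ag, spec$K_D))
  data.frame(time = sol[, "time"], M = st$M, D = st$D, Ag = Ag)
}

# --- shared nonlinear least-squares machinery -------------------------------

# Levenberg-Marquardt with jittered restarts; returns the best nls.lm fit
# (by residual sum of squares) or NULL if every start failed.
multistart_lm <- function(resid_fn, start, n_starts = 5, seed = 1L,
                          jitter_sd = 0.3, lower = NULL, upper = NULL) {
  starts <- list(start)
  if (n_starts > 1) {
    jit <- withr_seed(seed, {
      lapply(seq_len(n_starts - 1), function(i) {
        start + stats::rnorm(length(start), sd = jitter_sd)
      })
    })
    starts <- c(starts, jit)
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = s, fn = resid_fn, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(
          ptol = 1e-12, ftol = 1e-12, maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$deviance)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  best
}

# 1-sigma standard errors from the nls.lm fit covariance
param_se <- function(fit) {
  tryCatch(
    unname(summary(fit)$coefficients[, "Std. Error"]),
    error = function(e) rep(NA_real_, length(fit$par)))
}

# evaluate expr under a local RNG seed without disturbing the caller's RNG
withr_seed <- function(seed, expr) {
  force(seed)  # before snapshotting: evaluating `seed` may draw from the RNG
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
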