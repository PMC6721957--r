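#' Wild-type generating parameters for synthetic datasets
#'
#' The default parameter set used by every simulation scenario: the
#' monomer melting temperature and van't Hoff enthalpy, the two apparent
#' transition temperatures of the dimer-regime melts, the chemical
#' unfolding free energy and m-value at 37 C, the Arrhenius parameters
#' of monomer aggregation, the Michaelis-Menten constants of the dimer,
#' and the dimer dissociation constant. `k_Ag` is the 37 C aggregation
#' rate implied by the Arrhenius parameters.
#'
#' @return named list of generating parameters.
#' @export
wt_defaults <- function() {
  Ea <- 20.9; lnA <- 26
  list(
    Tm = celsius_to_kelvin(68.3),   # monomer-regime melting temperature, K
    dH = 75,                        # van't Hoff enthalpy, kcal/mol
    Tm1 = celsius_to_kelvin(48),    # aggregation-coupled apparent melt, K
    Tm2 = celsius_to_kelvin(70),    # monomer unfolding in the dimer regime, K
    dH1 = 60, dH2 = 75,             # transition enthalpies, kcal/mol
    dG0 = 9.5,                      # unfolding free energy at 37 C, kcal/mol
    m_value = 3,                    # kcal/mol/M
    Ea = Ea, lnA = lnA,             # Arrhenius parameters of k_Ag
    k_Ag = exp(lnA - Ea / (R_KCAL * 310.15)),  # s^-1 at 37 C
    Km = 25.2,                      # uM
    kcat = 0.10,                    # s^-1 per subunit in the dimer
    K_D = 0.5,                      # uM
    C_star = 5,                     # uM, phase-diagram exponential scale
    baseline_folded = c(-20, -0.01),   # mdeg intercept/slope (at Tref)
    baseline_unfolded = c(-4, 0.01)
  )
}

# add Gaussian noise scaled to a fraction of the clean signal's span
add_span_noise <- function(y, frac, seed) {
  if (frac <= 0) return(y)
  sigma <- frac * diff(range(y))
  withr_seed(seed, y + stats::rnorm(length(y), sd = sigma))
}

#' Simulate a monomer-regime thermal melt
#'
#' Two-state LEM forward model with linear baselines and Gaussian noise
#' scaled to the signal span.
#'
#' @param Tm,dH transition midpoint (K) and van't Hoff enthalpy
#'   (kcal/mol).
#' @param temperature_C scan grid, degrees Celsius.
#' @param baseline_folded,baseline_unfolded intercept/slope pairs
#'   (slopes per K, intercepts at the grid mean).
#' @param C_T protein concentration recorded with the curve, uM.
#' @param noise_frac Gaussian noise sd as a fraction of the signal span.
#' @param seed RNG seed.
#' @param label curve label.
#' @return a [melt_curve()].
#' @export
simulate_melt_curve <- function(Tm = wt_defaults()$Tm, dH = wt_defaults()$dH,
                                temperature_C = seq(25, 90, by = 0.5),
                                baseline_folded = wt_defaults()$baseline_folded,
                                baseline_unfolded = wt_defaults()$baseline_unfolded,
                                C_T = 0.5, noise_frac = 0.02, seed = 1L,
                                label = "synthetic melt") {
  temp <- celsius_to_kelvin(temperature_C)
  Tref <- mean(temp)
  y <- lem_signal(temp, Tref, baseline_folded, baseline_unfolded,
                  lem_pu(temp, Tm, dH))
  melt_curve(temp, add_span_noise(y, noise_frac, seed), C_T = C_T,
             label = label)
}

#' Simulate a dimer-regime melt family (bimodal model)
#'
#' One melt per concentration, each a convex combination of the
#' aggregation-coupled transition (`Tm1`) and the monomer unfolding
#' (`Tm2`) weighted by `chi_A(C_T) = 1 - exp(-C_T / C_star)`.
#'
#' @param C_T concentrations of the family, uM.
#' @param Tm1,Tm2,dH1,dH2 shared transition parameters.
#' @param C_star exponential scale of the aggregate fraction, uM.
#' @param temperature_C scan grid, Celsius.
#' @param baseline_folded,baseline_unfolded shared baselines.
#' @param noise_frac,seed noise controls (one independent realization
#'   per curve, offset from `seed`).
#' @return list with `curves` (list of [melt_curve()]) and `truth`
#'   (generating parameters including the per-curve `chiA`).
#' @export
simulate_melt_family <- function(C_T = c(2.5, 5, 10, 25),
                                 Tm1 = wt_defaults()$Tm1,
                                 Tm2 = wt_defaults()$Tm2,
                                 dH1 = wt_defaults()$dH1,
                                 dH2 = wt_defaults()$dH2,
                                 C_star = wt_defaults()$C_star,
                                 temperature_C = seq(25, 90, by = 0.5),
                                 baseline_folded = wt_defaults()$baseline_folded,
                                 baseline_unfolded = wt_defaults()$baseline_unfolded,
                                 noise_frac = 0.02, seed = 1L) {
  temp <- celsius_to_kelvin(temperature_C)
  Tref <- mean(temp)
  chiA <- 1 - exp(-C_T / C_star)
  curves <- lapply(seq_along(C_T), function(i) {
    pu <- chiA[i] * lem_pu(temp, Tm1, dH1) +
          (1 - chiA[i]) * lem_pu(temp, Tm2, dH2)
    y <- lem_signal(temp, Tref, baseline_folded, baseline_unfolded, pu)
    melt_curve(temp, add_span_noise(y, noise_frac, seed + i - 1L),
               C_T = C_T[i], label = sprintf("C_T = %g uM", C_T[i]))
  })
  list(curves = curves,
       truth = list(Tm1 = Tm1, Tm2 = Tm2, dH1 = dH1, dH2 = dH2,
                    C_star = C_star, chiA = chiA, C_T = C_T))
}

#' Simulate an isothermal chemical denaturation curve
#'
#' @param dG0,m_value LEM parameters (kcal/mol, kcal/mol/M).
#' @param denaturant_M denaturant grid, M.
#' @param temperature experiment temperature, K.
#' @param baseline_folded,baseline_unfolded intercept/slope pairs
#'   (slopes per M).
#' @param noise_frac,seed noise controls.
#' @return data.frame `denaturant_M`, `ellipticity`.
#' @export
simulate_chem_denat <- function(dG0 = wt_defaults()$dG0,
                                m_value = wt_defaults()$m_value,
                                denaturant_M = seq(0, 7, by = 0.1),
                                temperature = 310.15,
                                baseline_folded = wt_defaults()$baseline_folded,
                                baseline_unfolded = wt_defaults()$baseline_unfolded,
                                noise_frac = 0.02, seed = 1L) {
  RT <- R_KCAL * temperature
  xref <- mean(denaturant_M)
  pu <- 1 / (1 + exp((dG0 - m_value * denaturant_M) / RT))
  thetaF <- baseline_folded[1] + baseline_folded[2] * (denaturant_M - xref)
  thetaU <- baseline_unfolded[1] + baseline_unfolded[2] * (denaturant_M - xref)
  y <- thetaF * (1 - pu) + thetaU * pu
  data.frame(denaturant_M = denaturant_M,
             ellipticity = add_span_noise(y, noise_frac, seed))
}

#' Simulate an isothermal aggregation decay trace
#'
#' @param k_Ag first-order rate, s^-1.
#' @param t_max,n_points trace duration (s; default 4/k_Ag) and length.
#' @param theta0,theta_inf initial and final signal.
#' @param noise_frac,seed noise controls.
#' @param temperature trace temperature, K (metadata).
#' @return data.frame `time_s`, `ellipticity` with attribute
#'   `temperature`.
#' @export
simulate_decay_trace <- function(k_Ag = wt_defaults()$k_Ag,
                                 t_max = 4 / k_Ag, n_points = 100,
                                 theta0 = -20, theta_inf = -2,
                                 noise_frac = 0.02, seed = 1L,
                                 temperature = 310.15) {
  t <- seq(0, t_max, length.out = n_points)
  y <- theta_inf + (theta0 - theta_inf) * exp(-k_Ag * t)
  out <- data.frame(time_s = t,
                    ellipticity = add_span_noise(y, noise_frac, seed))
  attr(out, "temperature") <- temperature
  out
}

#' Simulate a temperature series of aggregation rates
#'
#' Rates from the Arrhenius law with multiplicative lognormal noise
#' (keeps rates positive).
#'
#' @param Ea,lnA Arrhenius parameters (kcal/mol; s^-1 reference).
#' @param temperature_K temperatures, K.
#' @param noise_cv coefficient of variation of the lognormal noise.
#' @param seed RNG seed.
#' @return data.frame `temperature_K`, `k_Ag`.
#' @export
simulate_arrhenius_series <- function(Ea = wt_defaults()$Ea,
                                      lnA = wt_defaults()$lnA,
                                      temperature_K = seq(302, 318,
                                                          length.out = 5),
                                      noise_cv = 0.10, seed = 1L) {
  k <- exp(lnA - Ea / (R_KCAL * temperature_K))
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    k <- withr_seed(seed, k * stats::rlnorm(length(k), meanlog = -sdlog^2 / 2,
                                            sdlog = sdlog))
  }
  data.frame(temperature_K = temperature_K, k_Ag = k)
}

#' Simulate a Michaelis-Menten substrate titration
#'
#' Initial rates from the dimer-only-active model with proportional
#' Gaussian noise.
#'
#' @param Km,kcat kinetic parameters (uM, s^-1 per dimer subunit).
#' @param enzyme_C_T total enzyme, uM; `K_D` partitions it into active
#'   dimer subunits.
#' @param K_D dimer dissociation constant, uM.
#' @param S substrate grid, uM (default 10 log-spaced points, 5-500 uM).
#' @param noise_cv proportional noise coefficient of variation.
#' @param seed RNG seed.
#' @return data.frame `substrate_uM`, `rate_uM_per_s`.
#' @export
simulate_mm_titration <- function(Km = wt_defaults()$Km,
                                  kcat = wt_defaults()$kcat,
                                  enzyme_C_T = 5, K_D = wt_defaults()$K_D,
                                  S = exp(seq(log(5), log(500),
                                              length.out = 10)),
                                  noise_cv = 0.05, seed = 1L) {
  v <- dimer_activity_rate(equilibrium_spec(enzyme_C_T, K_D),
                           enzyme_kinetics(Km, kcat), S)
  if (noise_cv > 0) {
    v <- withr_seed(seed, v * (1 + stats::rnorm(length(v), sd = noise_cv)))
  }
  data.frame(substrate_uM = S, rate_uM_per_s = v)
}

#' Simulate an activity-versus-total-concentration scan
#'
#' @param K_D dimer dissociation constant, uM.
#' @param Km,kcat kinetic parameters.
#' @param C_T total-enzyme grid, uM.
#' @param S_fixed fixed substrate concentration, uM.
#' @param noise_cv proportional noise coefficient of variation.
#' @param seed RNG seed.
#' @return data.frame `ctotal_uM`, `rate_uM_per_s`.
#' @export
simulate_ctotal_scan <- function(K_D = wt_defaults()$K_D,
                                 Km = wt_defaults()$Km,
                                 kcat = wt_defaults()$kcat,
                                 C_T = c(0.1, 0.25, 0.5, 1, 2.5, 5, 10),
                                 S_fixed = 2000, noise_cv = 0.10,
                                 seed = 1L) {
  v <- dimer_activity_rate(equilibrium_spec(C_T, K_D),
                           enzyme_kinetics(Km, kcat), S_fixed)
  if (noise_cv > 0) {
    v <- withr_seed(seed, v * (1 + stats::rnorm(length(v), sd = noise_cv)))
  }
  data.frame(ctotal_uM = C_T, rate_uM_per_s = v)
}

#' Simulate a DOSY gradient-attenuation decay
#'
#' @param D diffusion coefficient, m^2 s^-1.
#' @param gradient_fraction gradient grid as fractions of `g_max`.
#' @param gamma,g_max,delta,Delta Stejskal-Tanner calibration.
#' @param noise_frac Gaussian noise sd as a fraction of I0.
#' @param seed RNG seed.
#' @return data.frame `gradient_fraction`, `intensity`.
#' @export
simulate_dosy_decay <- function(D = 5e-11,
                                gradient_fraction = seq(0.02, 0.95,
                                                        length.out = 32),
                                gamma = 2.6752218744e8, g_max = 0.535,
                                delta = 3e-3, Delta = 0.2,
                                noise_frac = 0.01, seed = 1L) {
  g <- gradient_fraction * g_max
  b <- gamma^2 * g^2 * delta^2 * (Delta - delta / 3)
  I <- exp(-D * b)
  if (noise_frac > 0) {
    I <- withr_seed(seed, I + stats::rnorm(length(I), sd = noise_frac))
    I <- pmax(I, 1e-6)
  }
  data.frame(gradient_fraction = gradient_fraction, intensity = I)
}

#' Simulation design for [generate()]
#'
#' @param scenario one of `"monomer_melt"`, `"dimer_melt_family"`,
#'   `"chem_denat"`, `"decay_series"`, `"arrhenius_series"`,
#'   `"mm_titration"`, `"ctotal_scan"`, `"dosy_decay"`.
#' @param params named list overriding [wt_defaults()] entries and
#'   scenario arguments.
#' @param seed integer RNG seed (recorded in the truth record).
#' @return object of class `simulation_design`.
#' @export
simulation_design <- function(scenario, params = list(), seed = 1L) {
  scenarios <- c("monomer_melt", "dimer_melt_family", "chem_denat",
                 "decay_series", "arrhenius_series", "mm_titration",
                 "ctotal_scan", "dosy_decay")
  if (!scenario %in% scenarios) {
    stop_dimerscape(sprintf("unknown scenario '%s'", scenario),
                    "invalid_input")
  }
  structure(list(scenario = scenario, params = params, seed = as.integer(seed)),
            class = "simulation_design")
}

#' Generate a synthetic dataset with its truth record
#'
#' Runs the forward model of the requested scenario and, when `dir` is
#' given, writes the dataset in the CSV dialect the paired fitting
#' operation reads plus a `truth.json` with the generating parameters
#' and seed. Deterministic for a fixed (design, seed).
#'
#' @param design a [simulation_design()].
#' @param dir optional output directory.
#' @return list with `data` (scenario-dependent), `truth` (named list,
#'   always including `scenario` and `seed`), and `files` (paths written,
#'   or `NULL`).
#' @export
generate <- function(design, dir = NULL) {
  stopifnot(inherits(design, "simulation_design"))
  p <- utils::modifyList(wt_defaults(), design$params)
  seed <- design$seed
  sc <- design$scenario
  out <- switch(sc,
    monomer_melt = {
      cv <- simulate_melt_curve(Tm = p$Tm, dH = p$dH,
                                baseline_folded = p$baseline_folded,
                                baseline_unfolded = p$baseline_unfolded,
                                noise_frac = p$noise_frac %||% 0.02,
                                seed = seed)
      list(data = cv, truth = list(Tm = p$Tm, dH = p$dH))
    },
    dimer_melt_family = {
      fam <- simulate_melt_family(Tm1 = p$Tm1, Tm2 = p$Tm2, dH1 = p$dH1,
                                  dH2 = p$dH2, C_star = p$C_star,
                                  baseline_folded = p$baseline_folded,
                                  baseline_unfolded = p$baseline_unfolded,
                                  noise_frac = p$noise_frac %||% 0.02,
                                  seed = seed)
      list(data = fam$curves, truth = fam$truth)
    },
    chem_denat = {
      d <- simulate_chem_denat(dG0 = p$dG0, m_value = p$m_value,
                               baseline_folded = p$baseline_folded,
                               baseline_unfolded = p$baseline_unfolded,
                               noise_frac = p$noise_frac %||% 0.02,
                               seed = seed)
      list(data = d, truth = list(dG0 = p$dG0, m_value = p$m_value))
    },
    decay_series = {
      d <- simulate_decay_trace(k_Ag = p$k_Ag,
                                noise_frac = p$noise_frac %||% 0.02,
                                seed = seed)
      list(data = d, truth = list(k_Ag = p$k_Ag))
    },
    arrhenius_series = {
      d <- simulate_arrhenius_series(Ea = p$Ea, lnA = p$lnA,
                                     noise_cv = p$noise_cv %||% 0.10,
                                     seed = seed)
      list(data = d, truth = list(Ea = p$Ea, lnA = p$lnA))
    },
    mm_titration = {
      d <- simulate_mm_titration(Km = p$Km, kcat = p$kcat, K_D = p$K_D,
                                 noise_cv = p$noise_cv %||% 0.05,
                                 seed = seed)
      list(data = d, truth = list(Km = p$Km, kcat = p$kcat, K_D = p$K_D))
    },
    ctotal_scan = {
      d <- simulate_ctotal_scan(K_D = p$K_D, Km = p$Km, kcat = p$kcat,
                                noise_cv = p$noise_cv %||% 0.10,
                                seed = seed)
      list(data = d, truth = list(K_D = p$K_D, Km = p$Km, kcat = p$kcat))
    },
    dosy_decay = {
      d <- simulate_dosy_decay(D = p$D %||% 5e-11,
                               noise_frac = p$noise_frac %||% 0.01,
                               seed = seed)
      list(data = d, truth = list(D = p$D %||% 5e-11))
    })
  out$truth$scenario <- sc
  out$truth$seed <- seed
  out$files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    out$files <- write_scenario(sc, out$data, dir)
    truth_path <- file.path(dir, "truth.json")
    jsonlite::write_json(out$truth, truth_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    out$files <- c(out$files, truth_path)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write a scenario's dataset in the CSV dialect its fit operation reads
write_scenario <- function(scenario, data, dir) {
  paths <- character()
  put <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    paths <<- c(paths, path)
  }
  if (scenario %in% c("monomer_melt")) {
    put(data.frame(temperature_C = kelvin_to_celsius(data$temperature),
                   ellipticity = data$ellipticity), "melt.csv")
  } else if (scenario == "dimer_melt_family") {
    for (i in seq_along(data)) {
      cv <- data[[i]]
      put(data.frame(temperature_C = kelvin_to_celsius(cv$temperature),
                     ellipticity = cv$ellipticity),
          sprintf("melt_ct%g.csv", cv$C_T))
    }
  } else if (scenario == "chem_denat") {
    put(data, "chem_denat.csv")
  } else if (scenario == "decay_series") {
    put(data, "decay.csv")
  } else if (scenario == "arrhenius_series") {
    put(data.frame(temperature_C = kelvin_to_celsius(data$temperature_K),
                   k_ag_per_s = data$k_Ag), "rates.csv")
  } else if (scenario == "mm_titration") {
    put(data, "mm_titration.csv")
  } else if (scenario == "ctotal_scan") {
    put(data, "ctotal_scan.csv")
  } else if (scenario == "dosy_decay") {
    put(data, "dosy.csv")
  }
  paths
}

#' Generate a panel of synthetic variants
#'
#' Builds per-variant datasets emulating the two destabilization
#' mechanisms of pathogenic variants of an aggregating dimeric enzyme:
#' dimer-interface destabilizers (elevated K_D, Gr1-like) and monomer
#' kinetic destabilizers (elevated k_Ag, Gr2-like), plus melting-point
#' shifts feeding the Tm-shift free-energy estimate. The wild type is
#' always included as the reference.
#'
#' @param specs named list; each element a list with multipliers
#'   `kd_mult`, `kag_mult` (> 0) and `dTm` (K, positive = destabilized).
#' @param noise_cv proportional/lognormal noise level applied to rate
#'   data; melt noise is 2% of span.
#' @param seed integer seed.
#' @return named list (one element per variant incl. `"WT"`), each with
#'   `datasets` (ctotal_scan, decay, melt) and `truth` (the generating
#'   parameters after applying the multipliers).
#' @export
mutant_panel <- function(specs, noise_cv = 0.05, seed = 1L) {
  stopifnot(is.list(specs))
  wt <- wt_defaults()
  all_specs <- c(list(WT = list(kd_mult = 1, kag_mult = 1, dTm = 0)), specs)
  out <- vector("list", length(all_specs))
  names(out) <- names(all_specs)
  for (i in seq_along(all_specs)) {
    sp <- all_specs[[i]]
    if (sp$kd_mult <= 0 || sp$kag_mult <= 0) {
      stop_dimerscape("multipliers must be positive", "invalid_parameter")
    }
    K_D <- wt$K_D * sp$kd_mult
    k_Ag <- wt$k_Ag * sp$kag_mult
    Tm <- wt$Tm - sp$dTm
    s <- seed + 100L * i
    out[[i]] <- list(
      datasets = list(
        ctotal_scan = simulate_ctotal_scan(K_D = K_D, Km = wt$Km,
                                           kcat = wt$kcat,
                                           noise_cv = noise_cv, seed = s),
        decay = simulate_decay_trace(k_Ag = k_Ag, noise_frac = 0.02,
                                     seed = s + 1L),
        melt = simulate_melt_curve(Tm = Tm, dH = wt$dH, noise_frac = 0.02,
                                   seed = s + 2L)),
      truth = list(label = names(all_specs)[i], K_D = K_D, k_Ag = k_Ag,
                   Tm = Tm, kd_mult = sp$kd_mult, kag_mult = sp$kag_mult,
                   dTm = sp$dTm, seed = s))
  }
  out
}
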