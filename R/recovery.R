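#' Monte-Carlo parameter-recovery study
#'
#' Repeatedly generates a synthetic dataset of one scenario at the
#' stated noise level and refits it with the paired fitting operation,
#' returning the recovered parameters per replicate. This is the
#' package's validation workhorse: with the generating parameters set to
#' the literature values of the system under study, the medians of the
#' recovered parameters measure the bias of the whole
#' generate-plus-fit chain.
#'
#' Replicate seeds are derived deterministically from `seed` so the
#' study is reproducible and replicates are independent.
#'
#' @param scenario one of `"monomer_melt"`, `"chem_denat"`,
#'   `"mm_titration"`, `"arrhenius_series"`, `"ctotal_scan"`,
#'   `"dimer_melt_family"`, `"decay_series"`, `"dosy_decay"`.
#' @param n_rep number of replicates.
#' @param seed base integer seed.
#' @param params named list of generating-parameter overrides (see
#'   [wt_defaults()] and the scenario simulators).
#' @param n_starts multi-start count passed to the fitters (the
#'   data-driven initializations make a small value sufficient for
#'   well-formed synthetic data).
#' @return data.frame with one row per successful replicate; columns are
#'   the scenario's recovered parameters plus `rep`. Failed fits are
#'   dropped (column `n_failed` is reported as an attribute).
#' @export
recovery_study <- function(scenario, n_rep = 200, seed = 1L,
                           params = list(), n_starts = 2) {
  p <- utils::modifyList(wt_defaults(), params)
  rows <- vector("list", n_rep)
  n_failed <- 0L
  for (r in seq_len(n_rep)) {
    s <- seed + 1009L * r  # fixed stride keeps replicate streams apart
    res <- tryCatch(switch(scenario,
      monomer_melt = {
        cv <- simulate_melt_curve(Tm = p$Tm, dH = p$dH,
                                  noise_frac = p$noise_frac %||% 0.02,
                                  seed = s)
        f <- fit_two_state_melt(cv, n_starts = n_starts, seed = s)
        data.frame(Tm = f$Tm, dH = f$dH_vH)
      },
      chem_denat = {
        d <- simulate_chem_denat(dG0 = p$dG0, m_value = p$m_value,
                                 noise_frac = p$noise_frac %||% 0.02,
                                 seed = s)
        f <- fit_chemical_denaturation(d$denaturant_M, d$ellipticity,
                                       n_starts = n_starts, seed = s)
        data.frame(dG0 = f$dG0, m_value = f$m_value)
      },
      mm_titration = {
        d <- simulate_mm_titration(Km = p$Km, kcat = p$kcat, K_D = p$K_D,
                                   enzyme_C_T = p$enzyme_C_T %||% 5,
                                   noise_cv = p$noise_cv %||% 0.05,
                                   seed = s)
        f <- fit_michaelis_menten(d$substrate_uM, d$rate_uM_per_s,
                                  enzyme_C_T = p$enzyme_C_T %||% 5,
                                  K_D = p$K_D, n_starts = n_starts,
                                  seed = s)
        data.frame(Km = f$Km, kcat = f$kcat)
      },
      arrhenius_series = {
        d <- simulate_arrhenius_series(Ea = p$Ea, lnA = p$lnA,
                                       noise_cv = p$noise_cv %||% 0.10,
                                       seed = s)
        f <- fit_arrhenius(d$temperature_K, d$k_Ag)
        data.frame(Ea = f$Ea, lnA = f$lnA)
      },
      ctotal_scan = {
        d <- simulate_ctotal_scan(K_D = p$K_D, Km = p$Km, kcat = p$kcat,
                                  noise_cv = p$noise_cv %||% 0.10,
                                  seed = s)
        f <- fit_activity_vs_concentration(
          d$ctotal_uM, d$rate_uM_per_s, S_fixed = 2000,
          kinetics = enzyme_kinetics(p$Km, p$kcat),
          n_starts = n_starts, seed = s)
        data.frame(K_D = f$K_D)
      },
      dimer_melt_family = {
        fam <- simulate_melt_family(Tm1 = p$Tm1, Tm2 = p$Tm2, dH1 = p$dH1,
                                    dH2 = p$dH2, C_star = p$C_star,
                                    noise_frac = p$noise_frac %||% 0.02,
                                    seed = s)
        f <- fit_bimodal_melts(fam$curves, n_starts = n_starts, seed = s)
        data.frame(Tm1 = f$Tm1, Tm2 = f$Tm2,
                   chiA_monotone = !is.unsorted(f$chiA$chiA))
      },
      decay_series = {
        d <- simulate_decay_trace(k_Ag = p$k_Ag,
                                  noise_frac = p$noise_frac %||% 0.02,
                                  seed = s)
        f <- fit_decay(d$time_s, d$ellipticity, n_starts = n_starts,
                       seed = s)
        data.frame(k_Ag = f$k_Ag)
      },
      dosy_decay = {
        d <- simulate_dosy_decay(D = p$D %||% 5e-11,
                                 noise_frac = p$noise_frac %||% 0.01,
                                 seed = s)
        f <- fit_stejskal_tanner(d$gradient_fraction, d$intensity)
        data.frame(D = f$D)
      },
      stop_dimerscape(sprintf("unknown scenario '%s'", scenario),
                      "invalid_input")),
      dimerscape_error = function(e) {
        if (inherits(e, "invalid_input")) stop(e)
        NULL
      })
    if (is.null(res)) { n_failed <- n_failed + 1L; next }
    res$rep <- r
    rows[[r]] <- res
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  attr(out, "n_failed") <- n_failed
  out
}
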