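#' @export
print.equilibrium_state <- function(x, ...) {
  cat(sprintf(
    "monomer-dimer partition (K_D = %g uM, %.2f K)\n", x$K_D[1],
    x$temperature[1]))
  print(data.frame(C_T = x$C_T, M = x$M, D = x$D,
                   fraction_dimer = x$fraction_dimer), ...)
  cat(sprintf("dG_DM = %.2f kcal/mol (C0 = 1 M)\n", x$dG_DM[1]))
  invisible(x)
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat(sprintf(
    "two-state melt: Tm = %.2f K (%.2f C) +/- %.2g, dH = %.1f +/- %.2g kcal/mol\n",
    x$Tm, kelvin_to_celsius(x$Tm), x$Tm_se, x$dH_vH, x$dH_se))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
print.bimodal_fit <- function(x, ...) {
  cat(sprintf(
    "bimodal melt family: Tm1 = %.2f K (%.2f C), Tm2 = %.2f K (%.2f C)\n",
    x$Tm1, kelvin_to_celsius(x$Tm1), x$Tm2, kelvin_to_celsius(x$Tm2)))
  print(x$chiA, ...)
  invisible(x)
}

#' @export
print.chem_denat_fit <- function(x, ...) {
  cat(sprintf(
    "chemical denaturation: dG0 = %.2f +/- %.2g kcal/mol, m = %.2f kcal/mol/M, Cm = %.2f M\n",
    x$dG0, x$dG0_se, x$m_value, x$Cm))
  invisible(x)
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten: Km = %.2f +/- %.2g uM", x$Km, x$Km_se))
  if (!is.na(x$kcat)) {
    cat(sprintf(", kcat = %.3g +/- %.2g /s (per %g uM active sites)",
                x$kcat, x$kcat_se, x$active_sites))
  }
  cat("\n")
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
print.kd_fit <- function(x, ...) {
  cat(sprintf("dimer dissociation: K_D = %.3g +/- %.2g uM\n",
              x$K_D, x$K_D_se))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("aggregation decay: k_Ag = %.4g +/- %.2g /s\n",
              x$k_Ag, x$k_Ag_se))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("Arrhenius: Ea = %.2f +/- %.2g kcal/mol, lnA = %.2f +/- %.2g\n",
              x$Ea, x$Ea_se, x$lnA, x$lnA_se))
  invisible(x)
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("diffusion: D = %.3g m^2/s (logD = %.2f)", x$D, x$logD))
  if (!is.na(x$hydrodynamic_diameter)) {
    cat(sprintf(", hydrodynamic diameter = %.1f Angstrom",
                x$hydrodynamic_diameter))
  }
  cat("\n")
  invisible(x)
}

#' @export
print.variant_landscape <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat(sprintf(
    "variant landscape (%d variants; thresholds: dimer < %.2g -> Gr1, k_Ag > %.2gx -> Gr2, dG_MU < %.2g -> unfolding-destabilized)\n",
    nrow(x), th$dimer_cut, th$kag_cut, th$dg_cut))
  NextMethod()
}
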