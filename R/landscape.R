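#' Default mechanistic-classification thresholds
#'
#' The cutoffs separating the mechanism groups. The biophysical
#' separations the classes reflect are qualitative; these defaults put
#' the boundaries in the gaps between the observed clusters and every
#' report prints the thresholds used.
#'
#' @return list with `dimer_cut` (relative dimer fraction below which a
#'   variant is an interface destabilizer, Gr1), `kag_cut` (fold-increase
#'   in aggregation rate above which a dimer-competent variant is a
#'   kinetic destabilizer, Gr2), `dg_cut` (kcal/mol; unfolding free
#'   energy below which the folded state itself is compromised).
#' @export
default_thresholds <- function() {
  list(dimer_cut = 0.7, kag_cut = 2, dg_cut = 3)
}

#' Classify a variant's destabilization mechanism
#'
#' Rule, applied in order: an unfolding free energy below `dg_cut`
#' marks the variant `unfolding-destabilized` (overrides everything
#' else); a relative dimer fraction below `dimer_cut` together with a
#' relative aggregation rate above `kag_cut` is flagged `indeterminate`
#' (both mechanisms operating); relative dimer fraction below
#' `dimer_cut` alone gives `Gr1`; dimer fraction retained but
#' aggregation accelerated beyond `kag_cut` gives `Gr2`; otherwise
#' `WT-like`. Missing required fields give `indeterminate` with a
#' diagnostic flag. Classification is a pure function of its inputs.
#'
#' @param rel_dimer_fraction dimer fraction relative to wild type.
#' @param rel_kAg aggregation rate relative to wild type.
#' @param dG_MU unfolding free energy, kcal/mol (optional, `NA` to skip
#'   the stability override).
#' @param thresholds list as from [default_thresholds()].
#' @return list with `group` (character) and `flags`.
#' @export
classify_mechanism <- function(rel_dimer_fraction, rel_kAg,
                               dG_MU = NA_real_,
                               thresholds = default_thresholds()) {
  th <- utils::modifyList(default_thresholds(), thresholds)
  flags <- character()
  if (is.na(rel_dimer_fraction) || is.na(rel_kAg)) {
    return(list(group = "indeterminate",
                flags = "missing relative dimer fraction or k_Ag"))
  }
  if (rel_dimer_fraction < 0 || rel_kAg < 0) {
    stop_dimerscape("relative quantities must be >= 0", "invalid_input")
  }
  if (!is.na(dG_MU) && dG_MU < th$dg_cut) {
    return(list(group = "unfolding-destabilized", flags = flags))
  }
  low_dimer <- rel_dimer_fraction < th$dimer_cut
  fast_agg <- rel_kAg > th$kag_cut
  group <- if (low_dimer && fast_agg) {
    flags <- c("dimer fraction reduced", "aggregation accelerated")
    "indeterminate"
  } else if (low_dimer) "Gr1"
  else if (fast_agg) "Gr2"
  else "WT-like"
  list(group = group, flags = flags)
}

#' Assemble a per-variant energy landscape
#'
#' Combines the fitted observables of each variant with the wild-type
#' reference into the energy-landscape summary of the
#' dimer = monomer = unfolded scheme with irreversible monomer
#' aggregation: the dimer dissociation free energy from `K_D`, the
#' unfolding free energy, and the Eyring aggregation barrier from
#' `k_Ag`, plus the relative (to wild type) activity, dimer fraction and
#' aggregation rate that drive the mechanistic classification.
#'
#' @param variants named list; each element a list with any of `K_D`
#'   (uM), `k_Ag` (s^-1), `dG_MU` (kcal/mol), `activity` (rate in any
#'   consistent unit). Must contain an element named `WT` (or set
#'   `wt_label`).
#' @param wt_label name of the reference variant.
#' @param C_ref reference total concentration (uM) at which dimer
#'   fractions are compared (default 5 uM, a typical assay
#'   concentration).
#' @param temperature temperature for the energy conversions, K.
#' @param thresholds classification thresholds.
#' @return data.frame of class `variant_landscape`: one row per variant
#'   with `label`, `rel_activity`, `rel_dimer_fraction`, `rel_kAg`,
#'   `dG_MU`, `dG_DM`, `barrier_dG`, `group`, `flags`.
#' @export
assemble_landscape <- function(variants, wt_label = "WT", C_ref = 5,
                               temperature = 310.15,
                               thresholds = default_thresholds()) {
  if (!wt_label %in% names(variants)) {
    stop_dimerscape("no wild-type reference in the variant list",
                    "missing_reference")
  }
  wt <- variants[[wt_label]]
  dimer_frac <- function(v) {
    if (is.null(v$K_D)) return(NA_real_)
    monomer_dimer_partition(
      equilibrium_spec(C_ref, v$K_D, temperature))$fraction_dimer
  }
  wt_dimer <- dimer_frac(wt)
  rows <- lapply(names(variants), function(nm) {
    v <- variants[[nm]]
    if (is.null(v$dG_MU) && is.null(v$K_D) && is.null(v$k_Ag)) {
      stop_dimerscape(sprintf("variant '%s' carries no usable observable",
                              nm), "invalid_input")
    }
    rel_dimer <- dimer_frac(v) / wt_dimer
    rel_kAg <- if (is.null(v$k_Ag) || is.null(wt$k_Ag)) NA_real_ else
      v$k_Ag / wt$k_Ag
    rel_act <- if (is.null(v$activity) || is.null(wt$activity)) NA_real_ else
      v$activity / wt$activity
    dG_MU <- v$dG_MU %||% NA_real_
    dG_DM <- if (is.null(v$K_D)) NA_real_ else
      -R_KCAL * temperature * log(v$K_D * 1e-6)
    barrier <- if (is.null(v$k_Ag)) NA_real_ else
      barrier_free_energy(v$k_Ag, temperature)
    cl <- classify_mechanism(rel_dimer, rel_kAg, dG_MU, thresholds)
    data.frame(label = nm, rel_activity = rel_act,
               rel_dimer_fraction = rel_dimer, rel_kAg = rel_kAg,
               dG_MU = dG_MU, dG_DM = dG_DM, barrier_dG = barrier,
               group = cl$group,
               flags = paste(cl$flags, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "thresholds") <- utils::modifyList(default_thresholds(),
                                               thresholds)
  attr(out, "temperature") <- temperature
  attr(out, "C_ref") <- C_ref
  class(out) <- c("variant_landscape", "data.frame")
  out
}

#' Serialize a variant landscape to JSON (and optionally CSV)
#'
#' @param landscape a `variant_landscape` from [assemble_landscape()].
#' @param json_path output JSON path.
#' @param csv_path optional CSV summary path (one row per variant).
#' @return `json_path`, invisibly.
#' @export
write_landscape <- function(landscape, json_path, csv_path = NULL) {
  stopifnot(inherits(landscape, "variant_landscape"))
  payload <- list(
    thresholds = attr(landscape, "thresholds"),
    temperature = attr(landscape, "temperature"),
    C_ref = attr(landscape, "C_ref"),
    variants = landscape)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(landscape), csv_path, row.names = FALSE)
  }
  invisible(json_path)
}

#' Read a serialized variant landscape
#'
#' Inverse of [write_landscape()]: `read_landscape(write_landscape(x))`
#' reproduces `x`.
#'
#' @param json_path path written by [write_landscape()].
#' @return a `variant_landscape` data.frame.
#' @export
read_landscape <- function(json_path) {
  payload <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  out <- payload$variants
  # JSON drops NA -> NULL; restore missing numeric columns
  num_cols <- c("rel_activity", "rel_dimer_fraction", "rel_kAg", "dG_MU",
                "dG_DM", "barrier_dG")
  for (cc in num_cols) {
    if (is.null(out[[cc]])) out[[cc]] <- NA_real_
    out[[cc]] <- as.numeric(out[[cc]])
  }
  if (is.null(out$flags)) out$flags <- ""
  out$flags[is.na(out$flags)] <- ""
  attr(out, "thresholds") <- payload$thresholds
  attr(out, "temperature") <- payload$temperature
  attr(out, "C_ref") <- payload$C_ref
  class(out) <- c("variant_landscape", "data.frame")
  out
}
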