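#' Read a two-column data CSV
#'
#' All package CSV dialects are plain comma-separated files with a
#' header and optional `#` comment lines:
#' \itemize{
#'   \item melt: `temperature_C, ellipticity`
#'   \item chemical denaturation: `denaturant_M, ellipticity`
#'   \item decay trace: `time_s, ellipticity`
#'   \item rate table: `substrate_uM, rate_uM_per_s` or
#'     `ctotal_uM, rate_uM_per_s`
#'   \item Arrhenius table: `temperature_C, k_ag_per_s`
#'   \item DOSY: `gradient_fraction, intensity`
#' }
#'
#' @param path file path.
#' @param expected optional character vector of required column names;
#'   mismatch is an error.
#' @return data.frame.
#' @export
read_data_csv <- function(path, expected = NULL) {
  if (!file.exists(path)) {
    stop_dimerscape(sprintf("file not found: %s", path), "io_error")
  }
  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  if (!is.null(expected) && !all(expected %in% names(df))) {
    stop_dimerscape(sprintf("%s: expected columns %s, found %s", path,
                            paste(expected, collapse = ", "),
                            paste(names(df), collapse = ", ")),
                    "io_error")
  }
  df
}

#' Read a melt CSV as a [melt_curve()]
#'
#' @param path CSV with columns `temperature_C, ellipticity`.
#' @param C_T concentration metadata, uM (usually from the manifest).
#' @param label sample label.
#' @return a [melt_curve()].
#' @export
read_melt_csv <- function(path, C_T = NA_real_, label = basename(path)) {
  df <- read_data_csv(path, c("temperature_C", "ellipticity"))
  melt_curve(df$temperature_C, df$ellipticity, C_T = C_T, label = label,
             unit = "C")
}

#' Read a dataset manifest
#'
#' The manifest is a Debian-control-format (DCF) key-value file: one
#' block per dataset separated by blank lines, with fields `file`,
#' `type` (`melt`, `chem`, `decay`, `mm`, `ctotal`, `dosy`, `rates`)
#' and optional metadata (`C_T_uM`, `temperature_C`, `label`, plus the
#' DOSY calibration `gamma`, `g_max`, `delta_s`, `Delta_s`).
#'
#' @param path manifest file.
#' @return data.frame, one row per dataset, numeric metadata converted.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    stop_dimerscape(sprintf("manifest not found: %s", path), "io_error")
  }
  m <- as.data.frame(read.dcf(path), stringsAsFactors = FALSE)
  if (!all(c("file", "type") %in% names(m))) {
    stop_dimerscape("manifest blocks need at least 'file' and 'type'",
                    "io_error")
  }
  for (cc in intersect(c("C_T_uM", "temperature_C", "gamma", "g_max",
                         "delta_s", "Delta_s"), names(m))) {
    m[[cc]] <- as.numeric(m[[cc]])
  }
  m
}
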