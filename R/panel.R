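#' Marker panel: the ion signals the assay quantifies
#'
#' The assay quantifies five apolipoprotein ion signals in linear-mode serum
#' profile spectra: apolipoprotein C-II (m/z 8205), apolipoprotein C-III_0
#' (m/z 8766), pro-apolipoprotein C-II (m/z 8916), apolipoprotein C-III_1
#' (m/z 9422) and apolipoprotein C-III_2 (m/z 9713). Every spectrum is first
#' recalibrated internally on two calibrant signals, apolipoprotein C-I
#' (m/z 6631.6) and transthyretin (m/z 13,762.4). Two quality-control
#' positions, m/z 11,527.0 and 11,683.5 (des-Arg and full-length serum
#' amyloid A1), flag acute-phase contaminated sera for exclusion.
#'
#' @param marker_mzs Numeric vector of marker positions (Da).
#' @param calibrant_mzs Numeric vector of exactly two calibrant positions (Da).
#' @param qc_mzs Numeric vector of contamination (serum amyloid A1) positions (Da).
#' @param match_tolerance_da Half-window (Da) within which an observed apex is
#'   matched to a target position. Default 10 Da (~0.12% at m/z 8000,
#'   consistent with external-calibration accuracy of a linear ToF).
#'
#' @return An object of class `marker_panel`.
#' @examples
#' marker_panel()
#' @export
marker_panel <- function(marker_mzs = c(8205, 8766, 8916, 9422, 9713),
                         calibrant_mzs = c(6631.6, 13762.4),
                         qc_mzs = c(11527.0, 11683.5),
                         match_tolerance_da = 10) {
  if (length(calibrant_mzs) != 2L || any(!is.finite(calibrant_mzs))) {
    stop_validation("`calibrant_mzs` must be exactly two finite m/z values.")
  }
  if (length(marker_mzs) < 1L || any(!is.finite(marker_mzs)) || any(marker_mzs <= 0)) {
    stop_validation("`marker_mzs` must be positive finite m/z values.")
  }
  if (!is.numeric(match_tolerance_da) || length(match_tolerance_da) != 1L ||
      match_tolerance_da <= 0) {
    stop_validation("`match_tolerance_da` must be a single positive number.")
  }
  structure(
    list(
      marker_mzs = sort(as.numeric(marker_mzs)),
      calibrant_mzs = sort(as.numeric(calibrant_mzs)),
      qc_mzs = sort(as.numeric(qc_mzs)),
      match_tolerance_da = as.numeric(match_tolerance_da)
    ),
    class = "marker_panel"
  )
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("<marker_panel>\n")
  cat("  markers (m/z):   ", paste(x$marker_mzs, collapse = ", "), "\n")
  cat("  calibrants (m/z):", paste(x$calibrant_mzs, collapse = ", "), "\n")
  cat("  QC/SAA (m/z):    ", paste(x$qc_mzs, collapse = ", "), "\n")
  cat("  match tolerance: ±", x$match_tolerance_da, " Da\n", sep = "")
  invisible(x)
}

# Column name used for a marker area in wide tables, e.g. mz_8205.
marker_col <- function(mz) paste0("mz_", format(mz, trim = TRUE, scientific = FALSE))
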