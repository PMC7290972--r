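#' Construct a profile mass spectrum
#'
#' A spectrum is a tibble with columns `mz` (Da, strictly increasing) and
#' `intensity` (arbitrary units, non-negative), carrying the annotations
#' `patient_id`, `series_id` and `cohort` as attributes.
#'
#' @param mz Numeric vector of m/z values (Da), strictly increasing.
#' @param intensity Numeric vector of non-negative intensities, same length.
#' @param patient_id,series_id,cohort Optional annotations.
#' @return A tibble of class `fgr_spectrum`.
#' @examples
#' new_spectrum(mz = c(4000, 4001, 4002), intensity = c(0, 1, 0))
#' @export
new_spectrum <- function(mz, intensity, patient_id = NA_character_,
                         series_id = NA_character_, cohort = NA_character_) {
  if (length(mz) != length(intensity) || length(mz) < 2L) {
    stop_validation("`mz` and `intensity` must have equal length >= 2.")
  }
  if (any(!is.finite(mz)) || any(diff(mz) <= 0)) {
    stop_format("`mz` must be finite and strictly increasing.")
  }
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop_validation("`intensity` must be finite and non-negative.")
  }
  out <- tibble::tibble(mz = as.numeric(mz), intensity = as.numeric(intensity))
  attr(out, "patient_id") <- as.character(patient_id)
  attr(out, "series_id") <- as.character(series_id)
  attr(out, "cohort") <- as.character(cohort)
  class(out) <- c("fgr_spectrum", class(out))
  out
}

spectrum_annotation <- function(spectrum, which) {
  a <- attr(spectrum, which, exact = TRUE)
  if (is.null(a)) NA_character_ else a
}

#' @export
print.fgr_spectrum <- function(x, ...) {
  cat(sprintf(
    "<fgr_spectrum> %d points, m/z %.1f-%.1f  [patient %s, series %s, cohort %s]\n",
    nrow(x), min(x$mz), max(x$mz),
    spectrum_annotation(x, "patient_id"), spectrum_annotation(x, "series_id"),
    spectrum_annotation(x, "cohort")
  ))
  NextMethod()
}

#' Read a profile spectrum from disk
#'
#' Supports two formats: plain two-column whitespace-delimited text
#' (m/z, intensity; no header) and mzML (first spectrum of the file, via the
#' `mzR` package). With `format = "auto"`, files ending in `.mzml` (any case)
#' are read as mzML, everything else as xy text.
#'
#' Annotations are recovered from the file name convention
#' `<patient>_<series>_<cohort>.<ext>` (e.g. `F001_MS1_FGR.txt`); fewer
#' underscore-separated fields simply leave the remaining annotations `NA`.
#'
#' @param path File path.
#' @param format One of `"auto"`, `"xy_text"`, `"mzml"`.
#' @return An [new_spectrum()] object.
#' @seealso [write_spectrum()]
#' @export
read_spectrum <- function(path, format = c("auto", "xy_text", "mzml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_format(paste0("File not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml" else "xy_text"
  }
  if (format == "mzml") {
    if (!requireNamespace("mzR", quietly = TRUE)) {
      stop_format("Reading mzML requires the `mzR` package.")
    }
    fh <- mzR::openMSfile(path)
    on.exit(mzR::close(fh), add = TRUE)
    pk <- mzR::peaks(fh, 1L)
    mz <- pk[, 1]
    intensity <- pk[, 2]
  } else {
    tab <- tryCatch(
      utils::read.table(path, header = FALSE, col.names = c("mz", "intensity"),
                        colClasses = "numeric"),
      error = function(e) stop_format(paste0("Cannot parse xy text file: ", path))
    )
    mz <- tab$mz
    intensity <- tab$intensity
  }
  if (any(diff(mz) <= 0)) {
    stop_format(paste0("Non-monotone m/z axis in ", path))
  }
  ann <- strsplit(sub("\\.[^.]*$", "", basename(path)), "_", fixed = TRUE)[[1]]
  new_spectrum(
    mz, intensity,
    patient_id = if (length(ann) >= 1) ann[[1]] else NA_character_,
    series_id = if (length(ann) >= 2) ann[[2]] else NA_character_,
    cohort = if (length(ann) >= 3) ann[[3]] else NA_character_
  )
}

#' Write a profile spectrum to disk
#'
#' @param spectrum An [new_spectrum()] object.
#' @param path Output file path.
#' @param format `"xy_text"` (two-column whitespace-delimited, no header) or
#'   `"mzml"` (via `mzR`).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path, format = c("xy_text", "mzml")) {
  format <- match.arg(format)
  if (format == "xy_text") {
    readr::write_delim(
      tibble::tibble(mz = spectrum$mz, intensity = spectrum$intensity),
      path, delim = " ", col_names = FALSE
    )
  } else {
    if (!requireNamespace("mzR", quietly = TRUE)) {
      stop_format("Writing mzML requires the `mzR` package.")
    }
    pk <- cbind(mz = spectrum$mz, intensity = spectrum$intensity)
    hdr <- mzml_header(spectrum)
    mzR::writeMSData(list(pk), file = path, header = hdr)
  }
  invisible(path)
}

# Minimal single-scan MS1 header accepted by mzR::writeMSData.
mzml_header <- function(spectrum) {
  data.frame(
    seqNum = 1L, acquisitionNum = 1L, msLevel = 1L, polarity = 1L,
    peaksCount = nrow(spectrum), totIonCurrent = sum(spectrum$intensity),
    retentionTime = 0,
    basePeakMZ = spectrum$mz[which.max(spectrum$intensity)],
    basePeakIntensity = max(spectrum$intensity),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = min(spectrum$mz), highMZ = max(spectrum$mz),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_, spectrumId = "scan=1",
    centroided = FALSE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = min(spectrum$mz),
    scanWindowUpperLimit = max(spectrum$mz),
    stringsAsFactors = FALSE
  )
}

#' Plot a profile spectrum
#'
#' Intensity against m/z, with the marker panel positions marked.
#'
#' @param object An `fgr_spectrum`.
#' @param panel A [marker_panel()]; `NULL` suppresses the position guides.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fgr_spectrum <- function(object, panel = marker_panel(), ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$mz, y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "m/z (Da)", y = "Intensity (a.u.)") +
    ggplot2::theme_minimal()
  if (!is.null(panel)) {
    guides <- tibble::tibble(
      mz = c(panel$marker_mzs, panel$calibrant_mzs),
      role = rep(c("marker", "calibrant"),
                 c(length(panel$marker_mzs), length(panel$calibrant_mzs)))
    )
    p <- p + ggplot2::geom_vline(
      data = guides,
      ggplot2::aes(xintercept = .data$mz, colour = .data$role),
      linetype = "dashed", alpha = 0.6
    ) + ggplot2::labs(colour = NULL)
  }
  p
}
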