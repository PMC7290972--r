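#' Internally recalibrate a spectrum on two calibrant signals
#'
#' Locates the apex nearest each calibrant position (apolipoprotein C-I at
#' m/z 6631.6 and transthyretin at m/z 13,762.4 in the default panel) within
#' `match_tolerance_da`, then fits the two-point affine map sending the
#' observed apexes to the reference masses and applies it to the whole m/z
#' axis. After transformation both calibrant apexes sit at their reference
#' masses exactly (a two-point fit passes through both points).
#'
#' A spectrum fails calibration - and is to be excluded - when either
#' calibrant peak is missing (apex intensity below `min_rel_intensity` of the
#' spectrum's maximum, a scale-invariant peak-presence check) or the fitted
#' slope deviates from 1 by more than 0.01.
#'
#' @param spectrum An [new_spectrum()] object.
#' @param panel A [marker_panel()].
#' @param min_rel_intensity Minimum calibrant apex intensity as a fraction of
#'   the spectrum's maximum intensity (default 0.05).
#' @return A list with elements `spectrum` (recalibrated) and `model`
#'   (list with `slope`, `intercept`, and the observed apex positions).
#' @examples
#' mz <- seq(4000, 20000, 1)
#' ints <- 100 * dnorm(mz, 6631.6, 4) + 100 * dnorm(mz, 13762.4, 4)
#' out <- recalibrate(new_spectrum(mz, ints))
#' out$model$slope
#' @export
recalibrate <- function(spectrum, panel = marker_panel(),
                        min_rel_intensity = 0.05) {
  tol <- panel$match_tolerance_da
  global_max <- max(spectrum$intensity)
  observed <- vapply(panel$calibrant_mzs, function(target) {
    win <- spectrum$mz >= target - tol & spectrum$mz <= target + tol
    if (!any(win)) {
      stop_calibration(sprintf(
        "Calibrant m/z %.1f outside the spectrum range.", target))
    }
    idx <- which(win)
    apex <- idx[which.max(spectrum$intensity[idx])]
    if (spectrum$intensity[apex] < min_rel_intensity * global_max) {
      stop_calibration(sprintf(
        "Calibrant peak at m/z %.1f not found within ±%g Da (apex %.3g below %g%% of the spectrum maximum).",
        target, tol, spectrum$intensity[apex], 100 * min_rel_intensity))
    }
    spectrum$mz[apex]
  }, numeric(1))

  slope <- diff(panel$calibrant_mzs) / diff(observed)
  intercept <- panel$calibrant_mzs[1] - slope * observed[1]
  if (abs(slope - 1) > 0.01) {
    stop_calibration(sprintf(
      "Calibration slope %.5f deviates from 1 by more than 0.01.", slope))
  }

  recal <- new_spectrum(
    spectrum$mz * slope + intercept, spectrum$intensity,
    patient_id = spectrum_annotation(spectrum, "patient_id"),
    series_id = spectrum_annotation(spectrum, "series_id"),
    cohort = spectrum_annotation(spectrum, "cohort")
  )
  list(
    spectrum = recal,
    model = list(slope = unname(slope), intercept = unname(intercept),
                 observed_apexes = unname(observed),
                 reference_mzs = panel$calibrant_mzs)
  )
}

#' Integrate one ion signal
#'
#' The apex is the intensity maximum within `target_mz` ± `window_da` (grid
#' maximum, no sub-grid interpolation). With `baseline = "linear_endpoints"`
#' the chord between the window-edge intensities is subtracted, clipped so the
#' corrected signal stays non-negative; the area is the trapezoidal integral
#' of the corrected intensity over the window.
#'
#' @param spectrum A recalibrated [new_spectrum()] object.
#' @param target_mz Target position (Da).
#' @param window_da Integration half-window (Da, default 25).
#' @param baseline `"linear_endpoints"` (default) or `"none"`.
#' @return A one-row tibble with columns `target_mz`, `apex_mz`,
#'   `apex_intensity`, `area` and `flag` (`NA` or `"zero_window"`).
#' @examples
#' mz <- seq(4000, 20000, 1)
#' sp <- new_spectrum(mz, 100 * dnorm(mz, 8205, 4))
#' integrate_peak(sp, 8205)
#' @export
integrate_peak <- function(spectrum, target_mz, window_da = 25,
                           baseline = c("linear_endpoints", "none")) {
  baseline <- match.arg(baseline)
  lo <- target_mz - window_da
  hi <- target_mz + window_da
  if (lo < min(spectrum$mz) || hi > max(spectrum$mz)) {
    stop_validation(sprintf(
      "Integration window [%.1f, %.1f] outside the spectrum range.", lo, hi))
  }
  idx <- which(spectrum$mz >= lo & spectrum$mz <= hi)
  if (length(idx) < 3L) {
    stop_validation("Integration window covers fewer than 3 grid points.")
  }
  mz <- spectrum$mz[idx]
  y <- spectrum$intensity[idx]
  if (all(y == 0)) {
    return(tibble::tibble(target_mz = target_mz, apex_mz = mz[which.max(y)],
                          apex_intensity = 0, area = 0, flag = "zero_window"))
  }
  apex <- which.max(y)
  if (baseline == "linear_endpoints") {
    chord <- y[1] + (y[length(y)] - y[1]) * (mz - mz[1]) / (mz[length(mz)] - mz[1])
    y <- pmax(0, y - chord)
  }
  tibble::tibble(
    target_mz = target_mz,
    apex_mz = mz[apex],
    apex_intensity = spectrum$intensity[idx][apex],
    area = pracma::trapz(mz, y),
    flag = NA_character_
  )
}

#' Quantify the five marker ion signals of a spectrum
#'
#' Integrates each panel marker with [integrate_peak()] and checks that each
#' apex falls within the matching tolerance of its target and that each area
#' is positive; a violated check raises a marker-missing error naming the
#' marker.
#'
#' @param spectrum A recalibrated [new_spectrum()] object.
#' @param panel A [marker_panel()].
#' @param window_da,baseline Passed to [integrate_peak()].
#' @return A tibble with one row per marker: `marker` (e.g. `"mz_8205"`),
#'   `target_mz`, `apex_mz`, `apex_intensity`, `area`.
#' @export
extract_marker_areas <- function(spectrum, panel = marker_panel(),
                                 window_da = 25,
                                 baseline = c("linear_endpoints", "none")) {
  baseline <- match.arg(baseline)
  rows <- lapply(panel$marker_mzs, function(target) {
    pk <- integrate_peak(spectrum, target, window_da = window_da,
                         baseline = baseline)
    if (abs(pk$apex_mz - target) > panel$match_tolerance_da || pk$area <= 0) {
      stop_marker(sprintf(
        "Marker m/z %s missing: apex at %.1f Da (tolerance ±%g), area %.3g.",
        format(target), pk$apex_mz, panel$match_tolerance_da, pk$area
      ), marker = target)
    }
    pk
  })
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out, marker = marker_col(.data$target_mz), .before = 1)
}

#' Quality-control check for a spectrum
#'
#' Classifies a spectrum as `pass`, `exclude_saa` (serum amyloid A1
#' contamination: dominant ion signals at m/z 11,527.0 and 11,683.5, a serum
#' composition unlike the rest of the cohort) or `exclude_calibration`
#' (internal recalibration failed). The SAA rule fires when the apexes at
#' both QC positions exceed `qc_factor` times the median marker apex
#' intensity; being a ratio of intensities it is invariant to uniform
#' intensity scaling.
#'
#' @param spectrum An [new_spectrum()] object.
#' @param panel A [marker_panel()].
#' @param marker_areas Marker table from [extract_marker_areas()], or `NULL`
#'   when calibration already failed.
#' @param qc_factor Multiple of the median marker apex intensity above which
#'   the SAA signals are called dominant (default 2).
#' @param calibration_failed Set `TRUE` when [recalibrate()] raised an error.
#' @param detail Free-text reason, required for exclusions (auto-filled).
#' @return A one-row tibble with columns `qc_status` and `qc_detail`.
#' @export
qc_check <- function(spectrum, panel = marker_panel(), marker_areas = NULL,
                     qc_factor = 2, calibration_failed = FALSE, detail = NULL) {
  if (isTRUE(calibration_failed)) {
    return(tibble::tibble(
      qc_status = "exclude_calibration",
      qc_detail = detail %||% "internal recalibration failed"
    ))
  }
  if (is.null(marker_areas) || nrow(marker_areas) == 0L) {
    stop_validation("`marker_areas` required unless `calibration_failed`.")
  }
  tol <- panel$match_tolerance_da
  qc_apex <- vapply(panel$qc_mzs, function(target) {
    idx <- which(spectrum$mz >= target - tol & spectrum$mz <= target + tol)
    if (length(idx) == 0L) return(0)
    max(spectrum$intensity[idx])
  }, numeric(1))
  med <- stats::median(marker_areas$apex_intensity)
  if (length(qc_apex) > 0 && all(qc_apex > qc_factor * med)) {
    return(tibble::tibble(
      qc_status = "exclude_saa",
      qc_detail = sprintf(
        "serum amyloid A1 signals at m/z %s dominate (> %g x median marker apex %.3g)",
        paste(format(panel$qc_mzs), collapse = "/"), qc_factor, med
      )
    ))
  }
  tibble::tibble(qc_status = "pass", qc_detail = NA_character_)
}

#' Preprocess a cohort of spectra into a marker-area table
#'
#' For each spectrum: internal recalibration, marker integration and QC.
#' Spectra failing recalibration are kept in the table with status
#' `exclude_calibration` and `NA` areas; SAA-contaminated spectra keep their
#' areas but carry status `exclude_saa`. Downstream stages use only rows with
#' `qc_status == "pass"`.
#'
#' @param cohort Either the tibble returned by [simulate_cohort()] (with a
#'   `spectrum` list-column) or a bare list of `fgr_spectrum` objects.
#' @param panel A [marker_panel()].
#' @param window_da,baseline Passed to [integrate_peak()].
#' @param qc_factor Passed to [qc_check()].
#' @param min_rel_intensity Passed to [recalibrate()].
#' @return A tibble with one row per spectrum: `patient_id`, `series_id`,
#'   `cohort`, one `mz_<target>` area column per marker, `cal_slope`,
#'   `cal_intercept`, `qc_status`, `qc_detail`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_ctrl = 1, n_sga = 0, n_fgr = 1,
#'                                      seed = 1))
#' preprocess_spectra(cohort)
#' @export
preprocess_spectra <- function(cohort, panel = marker_panel(), window_da = 25,
                               baseline = c("linear_endpoints", "none"),
                               qc_factor = 2, min_rel_intensity = 0.05) {
  baseline <- match.arg(baseline)
  spectra <- if (is.data.frame(cohort)) cohort$spectrum else cohort
  if (is.null(spectra)) stop_validation("No spectra found in `cohort`.")

  rows <- lapply(spectra, function(sp) {
    base <- tibble::tibble(
      patient_id = spectrum_annotation(sp, "patient_id"),
      series_id = spectrum_annotation(sp, "series_id"),
      cohort = spectrum_annotation(sp, "cohort")
    )
    recal <- tryCatch(
      recalibrate(sp, panel, min_rel_intensity = min_rel_intensity),
      fgrms_error_calibration = function(e) e
    )
    if (inherits(recal, "error")) {
      qc <- qc_check(sp, panel, calibration_failed = TRUE,
                     detail = conditionMessage(recal))
      areas <- stats::setNames(
        rep(list(NA_real_), length(panel$marker_mzs)),
        marker_col(panel$marker_mzs)
      )
      return(dplyr::bind_cols(base, tibble::as_tibble(areas),
                              tibble::tibble(cal_slope = NA_real_,
                                             cal_intercept = NA_real_),
                              qc))
    }
    marker_tab <- withCallingHandlers(
      extract_marker_areas(recal$spectrum, panel, window_da = window_da,
                           baseline = baseline),
      fgrms_error_marker = function(e) {
        stop_marker(paste0(
          "Spectrum ", base$patient_id, "/", base$series_id, ": ",
          conditionMessage(e)
        ), marker = e$marker)
      }
    )
    qc <- qc_check(recal$spectrum, panel, marker_tab, qc_factor = qc_factor)
    areas <- stats::setNames(as.list(marker_tab$area), marker_tab$marker)
    dplyr::bind_cols(base, tibble::as_tibble(areas),
                     tibble::tibble(cal_slope = recal$model$slope,
                                    cal_intercept = recal$model$intercept),
                     qc)
  })
  dplyr::bind_rows(rows)
}
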