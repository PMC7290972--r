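#' Simulation configuration for synthetic serum profile cohorts
#'
#' Defines the statistical structure of a synthetic affinity-MS cohort:
#' cohort sizes, per-marker log-area means for the control and FGR groups,
#' biological and technical variability, background peak count, noise and
#' calibration-drift levels, and the rates of the two quality-control
#' artifacts (serum amyloid A1 contamination; calibration failure).
#'
#' Areas are drawn log-normally: a patient-level log-area per marker
#' (`marker_area_sd`) plus an independent series-level technical jitter
#' (`replicate_sd`) for each measurement series of the same serum. SGA
#' patients are drawn from the control distribution: constitutionally small
#' but healthy fetuses carry the control serum profile. The FGR effect is
#' applied to the log-means of the m/z 8916 and 8766 signals, which raises
#' the expected assessment quotients A, B and C jointly.
#'
#' @param n_ctrl,n_sga,n_fgr Patients per cohort.
#' @param series_per_patient Measurement series per patient (2 or 4,
#'   labelled MS1...MS4).
#' @param marker_area_means_ctrl,marker_area_means_fgr Named numeric vectors:
#'   mean log-area per marker m/z (names `"8205"`, `"8766"`, `"8916"`,
#'   `"9422"`, `"9713"`).
#' @param marker_area_sd Log-scale between-patient standard deviation of
#'   marker areas (default 0.2, ~20% CV).
#' @param replicate_sd Log-scale technical jitter between measurement series
#'   of the same serum (default 0.05).
#' @param calibrant_area_meanlog,calibrant_area_sd Log-area mean and SD of the
#'   two calibrant signals (identical in all cohorts).
#' @param n_background_peaks Number of non-panel protein signals per spectrum
#'   (default 53, so markers + calibrants total ~60 signals).
#' @param background_area_meanlog,background_area_sd Log-area distribution of
#'   background signals.
#' @param noise_sd Additive Gaussian intensity noise per grid point.
#' @param baseline_intensity Chemical-baseline amplitude at m/z 4000; the
#'   baseline decays exponentially with length constant 5000 Da.
#' @param calibration_drift_max Bound on the per-spectrum affine m/z drift:
#'   slope `1 + U(-d/2, d/2)` and intercept `U(-d/2, d/2) * 4000` Da, so the
#'   worst-case calibrant displacement stays inside the default 10 Da match
#'   tolerance at the default `d = 0.001`.
#' @param peak_width_sigma Gaussian peak width sigma in Da (default 4).
#' @param mz_step m/z grid step in Da (default 1, linear-mode resolution scale).
#' @param mz_range Simulated m/z range (default 4000--20000 Da).
#' @param p_saa_contamination,p_calibration_failure Per-patient probabilities
#'   of the two QC artifacts (all series of an affected patient carry the
#'   artifact, mirroring how these arise from the serum itself or its
#'   preparation).
#' @param seed Integer RNG seed; `NULL` uses the current RNG state.
#'
#' @return A validated object of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_ctrl = 2, n_sga = 0, n_fgr = 2, seed = 1)
#' @export
sim_config <- function(n_ctrl = 30,
                       n_sga = 15,
                       n_fgr = 30,
                       series_per_patient = 2,
                       marker_area_means_ctrl = c(
                         "8205" = log(1400), "8766" = log(1200),
                         "8916" = log(3520), "9422" = log(250),
                         "9713" = log(150)
                       ),
                       marker_area_means_fgr = c(
                         "8205" = log(1400), "8766" = log(1200) + 0.7,
                         "8916" = log(3520) + 1.0, "9422" = log(250),
                         "9713" = log(150)
                       ),
                       marker_area_sd = 0.2,
                       replicate_sd = 0.05,
                       calibrant_area_meanlog = log(4000),
                       calibrant_area_sd = 0.1,
                       n_background_peaks = 53,
                       background_area_meanlog = 6,
                       background_area_sd = 0.7,
                       noise_sd = 2,
                       baseline_intensity = 2,
                       calibration_drift_max = 0.001,
                       peak_width_sigma = 4,
                       mz_step = 1,
                       mz_range = c(4000, 20000),
                       p_saa_contamination = 1 / 75,
                       p_calibration_failure = 1 / 75,
                       seed = NULL) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  chk_count <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != floor(x)) {
      stop_validation(paste0("`", nm, "` must be a single non-negative integer."))
    }
  }
  chk_count(cfg$n_ctrl, "n_ctrl")
  chk_count(cfg$n_sga, "n_sga")
  chk_count(cfg$n_fgr, "n_fgr")
  chk_count(cfg$n_background_peaks, "n_background_peaks")
  if (!cfg$series_per_patient %in% c(1, 2, 3, 4)) {
    stop_validation("`series_per_patient` must be between 1 and 4.")
  }
  for (nm in c("marker_area_sd", "replicate_sd", "calibrant_area_sd",
               "background_area_sd", "noise_sd", "baseline_intensity",
               "calibration_drift_max")) {
    x <- cfg[[nm]]
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
      stop_validation(paste0("`", nm, "` must be a single non-negative number."))
    }
  }
  for (nm in c("p_saa_contamination", "p_calibration_failure")) {
    x <- cfg[[nm]]
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
      stop_validation(paste0("`", nm, "` must be a probability in [0, 1]."))
    }
  }
  if (cfg$peak_width_sigma <= 0) stop_validation("`peak_width_sigma` must be > 0.")
  if (cfg$mz_step <= 0) stop_validation("`mz_step` must be > 0.")
  if (length(cfg$mz_range) != 2L || diff(cfg$mz_range) <= 0) {
    stop_validation("`mz_range` must be an increasing pair.")
  }
  marker_names <- c("8205", "8766", "8916", "9422", "9713")
  for (nm in c("marker_area_means_ctrl", "marker_area_means_fgr")) {
    x <- cfg[[nm]]
    if (!all(marker_names %in% names(x)) || any(!is.finite(x))) {
      stop_validation(paste0(
        "`", nm, "` must be finite and named for all five markers (",
        paste(marker_names, collapse = ", "), ")."
      ))
    }
  }
  # The configured group means must imply higher expected quotients in FGR
  # than CTRL; otherwise the simulated study has no signal to recover.
  q_ctrl <- quotients_from_areas(exp(cfg$marker_area_means_ctrl))
  q_fgr <- quotients_from_areas(exp(cfg$marker_area_means_fgr))
  if (!all(unlist(q_fgr[c("A", "B", "C")]) > unlist(q_ctrl[c("A", "B", "C")]))) {
    stop_validation(paste0(
      "`marker_area_means_fgr` must imply higher expected quotients A, B and C ",
      "than `marker_area_means_ctrl`."
    ))
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  patients: %d CTRL, %d SGA, %d FGR; %d series each\n",
              x$n_ctrl, x$n_sga, x$n_fgr, x$series_per_patient))
  cat(sprintf("  grid: m/z %g-%g step %g Da; peak sigma %g Da\n",
              x$mz_range[1], x$mz_range[2], x$mz_step, x$peak_width_sigma))
  cat(sprintf("  noise sd %g; drift max %g; P(SAA) %.3f; P(cal. failure) %.3f\n",
              x$noise_sd, x$calibration_drift_max,
              x$p_saa_contamination, x$p_calibration_failure))
  cat(sprintf("  seed: %s\n", if (is.null(x$seed)) "<none>" else x$seed))
  invisible(x)
}

#' Simulate a synthetic serum-profiling cohort
#'
#' Generates one profile spectrum per (patient, measurement series) together
#' with the ground truth used to create it. Marker and calibrant areas are
#' drawn log-normally per patient with series-level technical jitter;
#' background signals sit at randomized positions avoiding a ±50 Da zone
#' around panel positions; each spectrum's m/z axis is warped by a bounded
#' affine drift; QC artifacts (serum amyloid A1 contamination, calibration
#' failure) are injected per patient at the configured rates.
#'
#' @param config A [sim_config()].
#' @param panel A [marker_panel()].
#' @return A tibble with one row per spectrum and columns `patient_id`,
#'   `cohort`, `series_id`, `artifact`, `true_areas` (list of named numeric:
#'   marker and calibrant areas) and `spectrum` (list of `fgr_spectrum`).
#'   The configuration is attached as attribute `config`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_ctrl = 1, n_sga = 0, n_fgr = 1,
#'                                      seed = 1))
#' cohort$spectrum[[1]]
#' @export
simulate_cohort <- function(config = sim_config(), panel = marker_panel()) {
  config <- validate_sim_config(config)
  run <- function() simulate_cohort_impl(config, panel)
  if (!is.null(config$seed)) withr::with_seed(config$seed, run()) else run()
}

simulate_cohort_impl <- function(config, panel) {
  truth <- cohort_ground_truth(config)
  spectra <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    spectra[[i]] <- simulate_spectrum(truth[i, ], config, panel)
  }
  truth$spectrum <- spectra
  attr(truth, "config") <- config
  truth
}

# Patient table, artifact assignment and per-series true areas.
cohort_ground_truth <- function(config) {
  patients <- tibble::tibble(
    patient_id = c(
      sprintf("C%03d", seq_len(config$n_ctrl)),
      sprintf("S%03d", seq_len(config$n_sga)),
      sprintf("F%03d", seq_len(config$n_fgr))
    ),
    cohort = rep(c("CTRL", "SGA", "FGR"),
                 c(config$n_ctrl, config$n_sga, config$n_fgr))
  )
  if (nrow(patients) == 0L) {
    return(tibble::tibble(
      patient_id = character(), cohort = character(), series_id = character(),
      artifact = character(), true_areas = list()
    ))
  }
  u <- runif(nrow(patients))
  p1 <- config$p_saa_contamination
  p2 <- config$p_calibration_failure
  patients$artifact <- dplyr::case_when(
    u < p1 ~ "saa",
    u < p1 + p2 ~ "calibration_failure",
    TRUE ~ "none"
  )

  marker_names <- c("8205", "8766", "8916", "9422", "9713")
  rows <- vector("list", nrow(patients))
  for (i in seq_len(nrow(patients))) {
    pat <- patients[i, ]
    means <- if (pat$cohort == "FGR") config$marker_area_means_fgr else
      config$marker_area_means_ctrl
    patient_log <- rnorm(5, means[marker_names], config$marker_area_sd)
    calib_log <- rnorm(2, config$calibrant_area_meanlog, config$calibrant_area_sd)
    series <- paste0("MS", seq_len(config$series_per_patient))
    areas <- lapply(series, function(s) {
      a <- exp(c(patient_log, calib_log) +
                 rnorm(7, 0, config$replicate_sd))
      names(a) <- c(marker_names, "6631.6", "13762.4")
      a
    })
    rows[[i]] <- tibble::tibble(
      patient_id = pat$patient_id, cohort = pat$cohort, series_id = series,
      artifact = pat$artifact, true_areas = areas
    )
  }
  dplyr::bind_rows(rows)
}

#' Simulate a single profile spectrum from ground truth
#'
#' The intensity is a sum of Gaussian peaks (one per configured marker,
#' calibrant and background signal; peak area equals the true area) on a
#' decaying baseline, plus additive Gaussian noise clipped at zero, sampled
#' on a regular m/z grid. The axis is then warped by a per-spectrum affine
#' drift bounded by `calibration_drift_max`. The artifact `"saa"` adds two
#' dominant serum amyloid A1 peaks at m/z 11,527.0 and 11,683.5; the artifact
#' `"calibration_failure"` suppresses both calibrant peaks so internal
#' recalibration cannot anchor the axis.
#'
#' Draws from the current RNG stream: seed at the cohort level (see
#' [simulate_cohort()]) for reproducibility.
#'
#' @param record One row of the ground-truth tibble (fields `patient_id`,
#'   `cohort`, `series_id`, `artifact`, `true_areas`), or an equivalent list.
#' @param config A [sim_config()].
#' @param panel A [marker_panel()].
#' @return An [new_spectrum()] object.
#' @export
simulate_spectrum <- function(record, config = sim_config(), panel = marker_panel()) {
  areas <- record$true_areas
  if (is.list(areas) && !is.numeric(areas)) areas <- areas[[1]]
  marker_names <- c("8205", "8766", "8916", "9422", "9713")
  calib_names <- format(panel$calibrant_mzs, trim = TRUE)
  need <- c(marker_names, calib_names)
  if (is.null(areas) || !all(need %in% names(areas))) {
    stop_validation(paste0(
      "`record$true_areas` must name areas for all five markers and both ",
      "calibrants (", paste(need, collapse = ", "), ")."
    ))
  }
  artifact <- as.character(record$artifact %||% "none")

  grid <- seq(config$mz_range[1], config$mz_range[2], by = config$mz_step)
  centers <- c(panel$marker_mzs, panel$calibrant_mzs)
  peak_areas <- as.numeric(areas[c(marker_names, calib_names)])

  if (artifact == "calibration_failure") {
    peak_areas[length(marker_names) + seq_along(calib_names)] <- 0
  }
  if (artifact == "saa") {
    saa_area <- 4 * max(peak_areas[seq_along(marker_names)])
    centers <- c(centers, panel$qc_mzs)
    peak_areas <- c(peak_areas, rep(saa_area, length(panel$qc_mzs)))
  }

  # Background signals: uniform positions with a ±50 Da exclusion zone around
  # every panel position so integration windows stay free of interference.
  protected <- c(panel$marker_mzs, panel$calibrant_mzs, panel$qc_mzs)
  bg_pos <- numeric(0)
  if (config$n_background_peaks > 0) {
    lo <- config$mz_range[1] + 50
    hi <- config$mz_range[2] - 50
    while (length(bg_pos) < config$n_background_peaks) {
      cand <- runif(config$n_background_peaks - length(bg_pos), lo, hi)
      ok <- vapply(cand, function(m) all(abs(m - protected) > 50), logical(1))
      bg_pos <- c(bg_pos, cand[ok])
    }
    bg_area <- rlnorm(length(bg_pos), config$background_area_meanlog,
                      config$background_area_sd)
    centers <- c(centers, bg_pos)
    peak_areas <- c(peak_areas, bg_area)
  }

  intensity <- gaussian_mixture(grid, centers, peak_areas, config$peak_width_sigma)
  baseline <- config$baseline_intensity * exp(-(grid - config$mz_range[1]) / 5000)
  noise <- if (config$noise_sd > 0) rnorm(length(grid), 0, config$noise_sd) else 0
  intensity <- pmax(0, intensity + baseline + noise)

  d <- config$calibration_drift_max
  slope <- 1 + runif(1, -d / 2, d / 2)
  intercept <- runif(1, -d / 2, d / 2) * 4000
  mz_observed <- grid * slope + intercept

  new_spectrum(
    mz_observed, intensity,
    patient_id = record$patient_id %||% NA_character_,
    series_id = record$series_id %||% NA_character_,
    cohort = record$cohort %||% NA_character_
  )
}

# Sum of Gaussian peaks with unit-area parameterization, each evaluated only
# within ±8 sigma of its center.
gaussian_mixture <- function(grid, centers, areas, sigma) {
  y <- numeric(length(grid))
  step <- grid[2] - grid[1]
  half <- ceiling(8 * sigma / step)
  for (k in seq_along(centers)) {
    if (areas[k] <= 0) next
    i0 <- findInterval(centers[k], grid)
    idx <- max(1L, i0 - half):min(length(grid), i0 + half + 1L)
    y[idx] <- y[idx] + areas[k] * dnorm(grid[idx], centers[k], sigma)
  }
  y
}

#' Write / read a cohort ground-truth table as CSV
#'
#' Flattens the `true_areas` list-column into one `area_<mz>` column per
#' marker/calibrant. The round trip `read_ground_truth(write_ground_truth(x))`
#' is lossless up to numeric printing precision.
#'
#' @param records Ground-truth tibble as returned by [simulate_cohort()]
#'   (the `spectrum` column, if present, is not written).
#' @param path CSV file path.
#' @return `write_ground_truth()`: `path`, invisibly. `read_ground_truth()`:
#'   the ground-truth tibble with a `true_areas` list-column.
#' @export
write_ground_truth <- function(records, path) {
  flat <- ground_truth_flat(records)
  readr::write_csv(flat, path)
  invisible(path)
}

ground_truth_flat <- function(records) {
  base <- tibble::as_tibble(records)[
    , intersect(c("patient_id", "cohort", "series_id", "artifact"), names(records)),
    drop = FALSE
  ]
  if (nrow(base) == 0L) {
    nm <- c("8205", "8766", "8916", "9422", "9713", "6631.6", "13762.4")
    area_cols <- stats::setNames(
      rep(list(numeric(0)), length(nm)), paste0("area_", nm)
    )
    return(tibble::as_tibble(c(as.list(base), area_cols)))
  }
  areas <- purrr::map(records$true_areas, function(a) {
    tibble::as_tibble(as.list(stats::setNames(as.numeric(a),
                                              paste0("area_", names(a)))))
  })
  dplyr::bind_cols(base, dplyr::bind_rows(areas))
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  flat <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            patient_id = "c", cohort = "c",
                            series_id = "c", artifact = "c",
                            .default = "d"
                          ))
  area_cols <- grep("^area_", names(flat), value = TRUE)
  out <- flat[, setdiff(names(flat), area_cols), drop = FALSE]
  out$true_areas <- purrr::map(seq_len(nrow(flat)), function(i) {
    stats::setNames(as.numeric(flat[i, area_cols]),
                    sub("^area_", "", area_cols))
  })
  out
}
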