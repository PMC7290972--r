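#' Run the serum-profiling pipeline end to end
#'
#' Simulates a cohort, preprocesses every spectrum (recalibration, marker
#' integration, QC), forms quotients, trains cut-offs by Youden-index scan on
#' the first measurement series (MS1) of the CTRL and FGR patients (the
#' training set), scores the remaining spectra plus all SGA spectra (the test
#' set), consolidates replicate spectra into patient calls, and evaluates
#' diagnostic performance at patient and spectrum level. SGA patients count
#' as negatives in the evaluation: constitutionally small but healthy fetuses
#' should classify with the controls.
#'
#' @param config A [sim_config()]; `seed`, if supplied here, overrides
#'   `config$seed`.
#' @param panel A [marker_panel()].
#' @param mode `"single"` (0/1 scores against the trained cut-offs) or
#'   `"dual"` (0.0/0.5/1.0 scores against combined lower/upper cut-offs).
#' @param cutoffs Optional. `NULL` trains from the simulated training set; in
#'   dual mode the trained set is combined with `second_set`. Supplying a
#'   `cutoff_set` or `dual_cutoffs` (e.g. [cutoffs_paper_ow()]) skips
#'   training.
#' @param second_set `cutoff_set` combined with the trained one in dual mode
#'   (default: the previous study's training set "W", A 3.4, B 7.0, C 5.1).
#' @param discriminator Cumulative-score discriminator (default 1.0).
#' @param qc_factor,window_da Preprocessing settings, see
#'   [preprocess_spectra()].
#' @param seed Integer seed for the whole run; all stochastic steps draw from
#'   this one seeded stream.
#' @param out_dir Optional directory: all intermediate tables plus a manifest
#'   are written there as CSV/JSON (see Details).
#'
#' @details With `out_dir` set, the run writes `ground_truth.csv`,
#' `marker_areas.csv`, `quotients.csv`, `cutoffs.json`, `scores.csv`,
#' `patient_calls.csv`, `metrics.json`, `roc_points.csv` and `manifest.json`.
#' Rerunning with identical configuration and seed reproduces identical
#' files.
#'
#' @return An object of class `fgr_run`: list with elements `config`, `seed`,
#'   `counts` (spectra simulated / excluded by reason / indeterminate
#'   patients), `cutoffs`, `areas`, `quotients`, `scores`, `patient_calls`,
#'   `metrics_patient`, `metrics_spectrum`, `roc`, `min_n_per_group` and
#'   `excluded` (machine-readable exclusion reasons).
#' @examples
#' \donttest{
#' run <- run_pipeline(sim_config(n_ctrl = 8, n_sga = 4, n_fgr = 8), seed = 1)
#' run$metrics_patient
#' }
#' @export
run_pipeline <- function(config = sim_config(), panel = marker_panel(),
                         mode = c("dual", "single"), cutoffs = NULL,
                         second_set = cutoff_set(A = 3.4, B = 7.0, C = 5.1,
                                                 training_label = "W"),
                         discriminator = 1.0, qc_factor = 2, window_da = 25,
                         seed = NULL, out_dir = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) config$seed <- seed
  config <- validate_sim_config(config)

  cohort <- with_stage("simulate", simulate_cohort(config, panel))
  areas <- with_stage("preprocess",
                      preprocess_spectra(cohort, panel, window_da = window_da,
                                         qc_factor = qc_factor))
  excluded <- dplyr::filter(areas, .data$qc_status != "pass")
  passed <- dplyr::filter(areas, .data$qc_status == "pass")
  quotients <- with_stage("quotients", compute_quotients(passed))

  is_training <- quotients$series_id == "MS1" & quotients$cohort %in% c("CTRL", "FGR")
  training <- quotients[is_training, ]
  test <- quotients[!is_training, ]

  used_cutoffs <- cutoffs
  trained <- NULL
  if (is.null(used_cutoffs)) {
    trained <- with_stage(
      "train-cutoffs",
      train_cutoff_set(training, label_col = "cohort", training_label = "O"))
    used_cutoffs <- if (mode == "dual") {
      with_stage("train-cutoffs", combine_cutoffs(trained, second_set))
    } else {
      trained
    }
  } else {
    want_dual <- mode == "dual"
    if (want_dual != inherits(used_cutoffs, "dual_cutoffs")) {
      stop_validation("`cutoffs` class does not match `mode`.")
    }
  }

  scores <- with_stage("score",
                       score_spectra(test, used_cutoffs,
                                     discriminator = discriminator))
  calls <- with_stage("aggregate", aggregate_patients(scores))
  determinate <- dplyr::filter(calls, .data$final != "indeterminate")

  truth_patient <- ifelse(determinate$cohort == "FGR", "FGR", "CTRL")
  metrics_patient <- with_stage(
    "evaluate", confusion_metrics(determinate$final, truth_patient))
  truth_spectrum <- ifelse(scores$cohort == "FGR", "FGR", "CTRL")
  metrics_spectrum <- with_stage(
    "evaluate", confusion_metrics(scores$call, truth_spectrum))
  roc <- with_stage("evaluate", roc_auc(scores$cumulative, truth_spectrum))
  d <- tryCatch(
    cohens_d(scores$cumulative[truth_spectrum == "FGR"],
             scores$cumulative[truth_spectrum == "CTRL"]),
    fgrms_error = function(e) NA_real_
  )
  min_n <- if (is.na(d)) NA_integer_ else min_sample_size(d)

  run <- structure(
    list(
      config = config, seed = config$seed, mode = mode,
      counts = list(
        n_spectra = nrow(cohort),
        n_excluded_saa = sum(excluded$qc_status == "exclude_saa"),
        n_excluded_calibration = sum(excluded$qc_status == "exclude_calibration"),
        n_training = nrow(training),
        n_test = nrow(test),
        n_indeterminate_patients = sum(calls$final == "indeterminate")
      ),
      cutoffs = used_cutoffs, trained = trained,
      truth = ground_truth_flat(cohort), areas = areas,
      quotients = quotients, scores = scores, patient_calls = calls,
      metrics_patient = metrics_patient, metrics_spectrum = metrics_spectrum,
      roc = roc, effect_size = d, min_n_per_group = min_n,
      excluded = dplyr::select(excluded, dplyr::all_of(
        c("patient_id", "series_id", "qc_status", "qc_detail")))
    ),
    class = "fgr_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# Re-raise any stage failure with the stage name so end-to-end runs report
# where and on which record they stopped.
with_stage <- function(stage, expr) {
  withCallingHandlers(
    expr,
    fgrms_error = function(e) {
      rlang::abort(paste0("[stage ", stage, "] ", conditionMessage(e)),
                   class = class(e), parent = e)
    }
  )
}

#' @export
print.fgr_run <- function(x, ...) {
  cat("<fgr_run> mode:", x$mode, " seed:",
      if (is.null(x$seed)) "<none>" else x$seed, "\n")
  cat(sprintf(
    "  spectra: %d simulated, %d excluded (SAA %d, calibration %d)\n",
    x$counts$n_spectra,
    x$counts$n_excluded_saa + x$counts$n_excluded_calibration,
    x$counts$n_excluded_saa, x$counts$n_excluded_calibration))
  cat(sprintf("  training spectra: %d  test spectra: %d  indeterminate patients: %d\n",
              x$counts$n_training, x$counts$n_test,
              x$counts$n_indeterminate_patients))
  cat(sprintf("  spectrum-level AUC: %.3f  min n per group: %s\n",
              x$roc$auc, x$min_n_per_group))
  cat("  patient-level performance:\n")
  print(x$metrics_patient)
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  readr::write_csv(run$truth, p("ground_truth.csv"))
  readr::write_csv(run$areas, p("marker_areas.csv"))
  readr::write_csv(run$quotients, p("quotients.csv"))
  write_cutoffs(run$cutoffs, p("cutoffs.json"))
  readr::write_csv(run$scores, p("scores.csv"))
  readr::write_csv(run$patient_calls, p("patient_calls.csv"))
  jsonlite::write_json(
    list(
      counts = run$counts,
      patient_level = as.list(glance(run$metrics_patient)),
      spectrum_level = as.list(glance(run$metrics_spectrum)),
      auc = run$roc$auc,
      effect_size = run$effect_size,
      min_n_per_group = run$min_n_per_group
    ),
    p("metrics.json"), auto_unbox = TRUE, digits = NA
  )
  readr::write_csv(run$roc$points, p("roc_points.csv"))
  cfg <- run$config
  cfg$mz_range <- as.list(cfg$mz_range)
  jsonlite::write_json(
    list(
      package = "fgrms",
      version = as.character(utils::packageVersion("fgrms")),
      seed = run$seed, mode = run$mode,
      config = lapply(unclass(cfg), function(v)
        if (is.numeric(v) && !is.null(names(v))) as.list(v) else v)
    ),
    p("manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(out_dir)
}
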