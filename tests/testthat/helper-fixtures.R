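# Fixture builders and independent oracles used across the suite.

# A profile spectrum that is an exact sum of Gaussian peaks (unit-area
# parameterization) on an optional constant baseline. Built directly from
# dnorm, independently of the simulator.
make_gaussian_spectrum <- function(centers, areas, sigma = 4,
                                   mz = seq(4000, 20000, by = 1),
                                   baseline = 0,
                                   patient_id = "P1", series_id = "MS1",
                                   cohort = NA_character_) {
  intensity <- rep(baseline, length(mz))
  for (k in seq_along(centers)) {
    intensity <- intensity + areas[k] * dnorm(mz, centers[k], sigma)
  }
  new_spectrum(mz, intensity, patient_id = patient_id, series_id = series_id,
               cohort = cohort)
}

# Areas that give known quotients; includes calibrant areas.
default_true_areas <- c(
  "8205" = 1400, "8766" = 1200, "8916" = 3520, "9422" = 250, "9713" = 150,
  "6631.6" = 4000, "13762.4" = 4000
)

# One clean ground-truth record for simulate_spectrum().
make_record <- function(artifact = "none", areas = default_true_areas,
                        patient_id = "P1", series_id = "MS1", cohort = "CTRL") {
  tibble::tibble(patient_id = patient_id, cohort = cohort,
                 series_id = series_id, artifact = artifact,
                 true_areas = list(areas))
}

# A distortion-free configuration: no noise, no drift, no artifacts, no
# background peaks, so every true area must be recovered exactly.
clean_config <- function(...) {
  sim_config(noise_sd = 0, calibration_drift_max = 0, baseline_intensity = 0,
             n_background_peaks = 0, p_saa_contamination = 0,
             p_calibration_failure = 0, replicate_sd = 0, ...)
}

# Brute-force Youden oracle: with the fixed direction rule (positive when
# value > threshold), J(c) is a step function changing only at data values,
# so scanning c over {min - 1} and every distinct value enumerates every
# attainable J. Independent of candidate_cutoffs()/youden_scan().
brute_force_youden <- function(values, labels, positive = "FGR") {
  u <- sort(unique(values))
  thresholds <- c(u[1] - 1, u)
  pos <- values[labels == positive]
  neg <- values[labels != positive]
  j <- vapply(thresholds, function(c) {
    mean(pos > c) + mean(neg <= c) - 1
  }, numeric(1))
  list(j_max = max(j), thresholds = thresholds, j = j)
}

# Evaluate J of a specific cutoff directly from the definition.
j_at_cutoff <- function(cutoff, values, labels, positive = "FGR") {
  pos <- values[labels == positive]
  neg <- values[labels != positive]
  mean(pos > cutoff) + mean(neg <= cutoff) - 1
}

# Pairwise (probability-interpretation) AUC oracle.
brute_force_auc <- function(scores, labels, positive = "FGR") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}
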