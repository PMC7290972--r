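test_that("xy text spectra round-trip and bad files are format errors", {
  dir <- withr::local_tempdir()
  tmp <- file.path(dir, "F001_MS1_FGR.txt")
  writeLines(c("4000 0.0", "4001 1.5", "4002 0.5"), tmp)
  sp <- read_spectrum(tmp)
  expect_equal(nrow(sp), 3L)
  expect_equal(attr(sp, "patient_id"), "F001")
  expect_equal(attr(sp, "series_id"), "MS1")
  expect_equal(attr(sp, "cohort"), "FGR")

  sp2 <- make_gaussian_spectrum(8205, 100, mz = seq(8000, 8400, 0.5))
  out <- withr::local_tempfile(pattern = "P9_MS2", fileext = ".txt")
  write_spectrum(sp2, out)
  back <- read_spectrum(out)
  expect_equal(back$mz, sp2$mz, tolerance = 1e-9)
  expect_equal(back$intensity, sp2$intensity, tolerance = 1e-9)

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("4002 1", "4001 1"), bad)
  expect_error(read_spectrum(bad), class = "fgrms_error_format")
  txt <- withr::local_tempfile(fileext = ".txt")
  writeLines("not a spectrum at all", txt)
  expect_error(read_spectrum(txt), class = "fgrms_error_format")
  expect_error(read_spectrum("no/such/file.txt"), class = "fgrms_error_format")
})

test_that("mzML spectra round-trip through mzR", {
  sp <- make_gaussian_spectrum(c(6631.6, 13762.4), c(500, 500),
                               mz = seq(4000, 20000, 2))
  out <- withr::local_tempfile(pattern = "C001_MS1_CTRL", fileext = ".mzML")
  write_spectrum(sp, out, format = "mzml")
  back <- read_spectrum(out, format = "mzml")
  expect_equal(back$mz, sp$mz, tolerance = 1e-6)
  expect_equal(back$intensity, sp$intensity, tolerance = 1e-5)
  expect_equal(attr(back, "patient_id"), "C001")
})

test_that("two-point recalibration maps calibrant apexes onto reference masses", {
  # Grid containing the exact calibrant positions: identity model.
  mz <- sort(unique(c(seq(4000, 20000, 1), 6631.6, 13762.4)))
  sp <- make_gaussian_spectrum(c(6631.6, 13762.4), c(500, 500), mz = mz)
  out <- recalibrate(sp)
  expect_equal(out$model$slope, 1, tolerance = 1e-9)
  expect_equal(out$model$intercept, 0, tolerance = 1e-6)

  # Apexes observed at 6640.0 / 13770.0: the fitted map sends them exactly
  # onto 6631.6 / 13762.4.
  mz2 <- sort(unique(c(seq(4000, 20000, 1), 6640.0, 13770.0)))
  sp2 <- make_gaussian_spectrum(c(6640.0, 13770.0), c(500, 500), mz = mz2)
  out2 <- recalibrate(sp2)
  fit <- function(x) x * out2$model$slope + out2$model$intercept
  expect_equal(fit(6640.0), 6631.6, tolerance = 0.01)
  expect_equal(fit(13770.0), 13762.4, tolerance = 0.01)

  # Idempotence: recalibrating the recalibrated spectrum is the identity.
  out3 <- recalibrate(out2$spectrum)
  expect_equal(out3$model$slope, 1, tolerance = 1e-6)
  expect_equal(out3$model$intercept, 0, tolerance = 1e-3)
})

test_that("suppressed calibrant peaks raise a calibration error", {
  sp <- withr::with_seed(
    5, simulate_spectrum(make_record(artifact = "calibration_failure"),
                         clean_config()))
  expect_error(recalibrate(sp), class = "fgrms_error_calibration")
})

test_that("peak integration recovers analytic Gaussian areas within 1%", {
  for (sigma in c(2, 4, 8)) {
    sp <- make_gaussian_spectrum(9000, 123.4, sigma = sigma,
                                 mz = seq(8000, 10000, 1))
    pk <- integrate_peak(sp, 9000, window_da = max(25, 6 * sigma))
    # Closed-form mass of the Gaussian inside the window.
    w <- max(25, 6 * sigma)
    expected <- 123.4 * (pnorm(w / sigma) - pnorm(-w / sigma))
    expect_equal(pk$area, expected, tolerance = 0.01)
    expect_equal(pk$apex_mz, 9000)
  }
})

test_that("flat and degenerate windows behave as specified", {
  flat <- new_spectrum(seq(8000, 9000, 1), rep(0, 1001))
  pk <- integrate_peak(flat, 8500)
  expect_equal(pk$area, 0)
  expect_equal(pk$flag, "zero_window")
  expect_error(integrate_peak(flat, 8010), class = "fgrms_error_validation")
})

test_that("linear-endpoint baseline removes a constant pedestal", {
  clean <- make_gaussian_spectrum(9000, 200, mz = seq(8000, 10000, 1))
  lifted <- make_gaussian_spectrum(9000, 200, mz = seq(8000, 10000, 1),
                                   baseline = 50)
  a0 <- integrate_peak(clean, 9000, baseline = "none")$area
  a1 <- integrate_peak(lifted, 9000, baseline = "linear_endpoints")$area
  expect_equal(a1, a0, tolerance = 0.02)
})

test_that("marker extraction reproduces simulator ground truth within 1%", {
  rec <- make_record()
  sp <- withr::with_seed(7, simulate_spectrum(rec, clean_config()))
  recal <- recalibrate(sp)
  tab <- extract_marker_areas(recal$spectrum)
  expect_equal(nrow(tab), 5L)
  truth <- rec$true_areas[[1]][c("8205", "8766", "8916", "9422", "9713")]
  expect_equal(tab$area, unname(truth), tolerance = 0.01)
})

test_that("a missing marker is a named marker error", {
  areas <- default_true_areas
  areas[["8205"]] <- 0
  sp <- withr::with_seed(7, simulate_spectrum(make_record(areas = areas),
                                              clean_config()))
  err <- expect_error(extract_marker_areas(recalibrate(sp)$spectrum),
                      class = "fgrms_error_marker")
  expect_equal(err$marker, 8205)
  expect_match(conditionMessage(err), "8205")
})

test_that("areas scale linearly and QC status is scale-invariant", {
  rec <- make_record()
  sp <- withr::with_seed(7, simulate_spectrum(rec, clean_config()))
  sp10 <- new_spectrum(sp$mz, sp$intensity * 10)
  t1 <- extract_marker_areas(recalibrate(sp)$spectrum)
  t10 <- extract_marker_areas(recalibrate(sp10)$spectrum)
  expect_equal(t10$area, 10 * t1$area, tolerance = 1e-9)

  q1 <- qc_check(sp, marker_areas = t1)
  q10 <- qc_check(sp10, marker_areas = t10)
  expect_equal(q1$qc_status, "pass")
  expect_equal(q10$qc_status, q1$qc_status)

  saa <- withr::with_seed(7, simulate_spectrum(make_record(artifact = "saa"),
                                               clean_config()))
  ts <- extract_marker_areas(recalibrate(saa)$spectrum)
  expect_equal(qc_check(saa, marker_areas = ts)$qc_status, "exclude_saa")
  saa2 <- new_spectrum(saa$mz, saa$intensity * 0.1)
  ts2 <- extract_marker_areas(recalibrate(saa2)$spectrum)
  expect_equal(qc_check(saa2, marker_areas = ts2)$qc_status, "exclude_saa")
})

test_that("preprocess_spectra flags artifact spectra with machine-readable reasons", {
  cfg <- clean_config(n_ctrl = 2, n_sga = 0, n_fgr = 2, seed = 21)
  cohort <- simulate_cohort(cfg)
  cohort$artifact[1] <- "saa"
  cohort$artifact[3] <- "calibration_failure"
  cohort$spectrum <- withr::with_seed(21, lapply(seq_len(nrow(cohort)), function(i)
    simulate_spectrum(cohort[i, ], cfg)))
  tab <- preprocess_spectra(cohort)
  expect_equal(tab$qc_status[1], "exclude_saa")
  expect_equal(tab$qc_status[3], "exclude_calibration")
  expect_true(all(tab$qc_status[c(2, 4:8)] == "pass"))
  expect_true(all(!is.na(tab$qc_detail[c(1, 3)])))
  expect_true(all(is.na(tab$mz_8205[3]))) # no areas without calibration
})
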