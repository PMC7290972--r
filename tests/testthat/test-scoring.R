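test_that("quotients follow the three area ratios", {
  q1 <- compute_quotients(c("8205" = 1, "8766" = 1, "8916" = 1,
                            "9422" = 1, "9713" = 1))
  expect_equal(q1$A, 1)
  expect_equal(q1$B, 0.5)
  expect_equal(q1$C, 1 / 3)

  q2 <- compute_quotients(c("8205" = 2, "8766" = 3, "8916" = 6,
                            "9422" = 1, "9713" = 2))
  expect_equal(c(q2$A, q2$B, q2$C), c(3, 1, 1))

  # Ratio scale invariance: multiplying all areas leaves quotients unchanged.
  a <- c("8205" = 2, "8766" = 3, "8916" = 6, "9422" = 1, "9713" = 2)
  expect_equal(compute_quotients(a * 7), compute_quotients(a))

  expect_error(compute_quotients(c("8205" = 0, "8766" = 3, "8916" = 6,
                                   "9422" = 1, "9713" = 2)),
               class = "fgrms_error_validation")
  expect_error(compute_quotients(c("8766" = 3, "8916" = 6, "9422" = 1,
                                   "9713" = 2)),
               class = "fgrms_error_validation")
})

test_that("quotients append to a marker-area table", {
  tab <- tibble::tibble(
    patient_id = c("a", "b"),
    mz_8205 = c(2, 4), mz_8766 = c(3, 6), mz_8916 = c(6, 12),
    mz_9422 = c(1, 2), mz_9713 = c(2, 4)
  )
  out <- compute_quotients(tab)
  expect_equal(out$A, c(3, 3))
  expect_equal(out$B, c(1, 1))
  expect_equal(out$C, c(1, 1))
  expect_error(compute_quotients(tab[-2]), "mz_8205",
               class = "fgrms_error_validation")
})

test_that("single-cut-off scoring is strict at the boundary", {
  expect_equal(score_single(4.3, 4.2), 1)
  expect_equal(score_single(4.2, 4.2), 0) # "higher than" is strict
  expect_equal(score_single(0.1, 4.2), 0)
  expect_equal(score_single(c(1, 5, 4.2), 4.2), c(0, 1, 0))
})

test_that("dual-cut-off scoring opens three regimes with printed boundary semantics", {
  expect_equal(score_dual(3.4, 3.4, 4.2), 0.0) # below or equal to lower
  expect_equal(score_dual(4.0, 3.4, 4.2), 0.5) # above lower, <= upper
  expect_equal(score_dual(4.2, 3.4, 4.2), 0.5) # equal to upper stays 0.5
  expect_equal(score_dual(5.0, 3.4, 4.2), 1.0) # above upper
  expect_error(score_dual(1, 4.2, 3.4), class = "fgrms_error_validation")
  expect_error(score_dual(1, 4.2, 4.2), class = "fgrms_error_validation")
})

test_that("dual scoring is a non-decreasing step function matching single at the ends", {
  v <- seq(0, 10, by = 0.1)
  s <- score_dual(v, 3.4, 4.2)
  expect_true(all(diff(s) >= 0))
  expect_setequal(unique(s), c(0, 0.5, 1))
  # With the upper threshold pushed beyond any value, dual reduces to single.
  expect_equal(score_dual(v, 3.4, .Machine$double.xmax) * 2,
               score_single(v, 3.4))
})

test_that("spectra are classified by the 1.0 cumulative-score discriminator", {
  dual <- cutoffs_paper_ow()
  hi <- score_spectra(tibble::tibble(A = 5.0, B = 8.0, C = 6.0), dual)
  expect_equal(c(hi$score_A, hi$score_B, hi$score_C), c(1, 1, 1))
  expect_equal(hi$cumulative, 3.0)
  expect_equal(hi$call, "FGR")

  lo <- score_spectra(tibble::tibble(A = 3.0, B = 4.0, C = 3.5), dual)
  expect_equal(lo$cumulative, 0.0)
  expect_equal(lo$call, "CTRL")

  # Exactly at the discriminator: 0.5 + 0.5 + 0.0 = 1.0 stays CTRL.
  mid <- score_spectra(tibble::tibble(A = 4.0, B = 5.5, C = 3.0), dual)
  expect_equal(c(mid$score_A, mid$score_B, mid$score_C), c(0.5, 0.5, 0))
  expect_equal(mid$cumulative, 1.0)
  expect_equal(mid$call, "CTRL")

  single <- cutoff_set(4.2, 5.0, 4.0, training_label = "O")
  s <- score_spectra(tibble::tibble(A = 4.3, B = 4.9, C = 4.1), single)
  expect_equal(s$cumulative, 2)
  expect_equal(s$call, "FGR")

  expect_error(score_spectra(tibble::tibble(A = 1, B = 1, C = 1), "not cutoffs"),
               class = "fgrms_error_validation")
})

test_that("raising any quotient never flips a call from FGR to CTRL", {
  dual <- cutoffs_paper_ow()
  withr::with_seed(5, {
    base <- tibble::tibble(A = runif(50, 2, 6), B = runif(50, 3, 9),
                           C = runif(50, 2, 7))
    before <- score_spectra(base, dual)$call
    for (col in c("A", "B", "C")) {
      bumped <- base
      bumped[[col]] <- bumped[[col]] + runif(50, 0, 3)
      after <- score_spectra(bumped, dual)$call
      expect_false(any(before == "FGR" & after == "CTRL"))
    }
  })
})

test_that("cumulative scores are invariant to uniform intensity scaling", {
  rec <- make_record()
  sp <- withr::with_seed(7, simulate_spectrum(rec, clean_config()))
  score_of <- function(spectrum) {
    tab <- extract_marker_areas(recalibrate(spectrum)$spectrum)
    areas <- stats::setNames(tab$area, tab$marker)
    score_spectra(compute_quotients(areas), cutoffs_paper_ow())$cumulative
  }
  scaled <- new_spectrum(sp$mz, sp$intensity * 37)
  expect_equal(score_of(scaled), score_of(sp))
})

test_that("patients are consolidated by replicate unanimity", {
  mk <- function(calls, id = "p") {
    tibble::tibble(patient_id = id, cohort = "FGR", call = calls)
  }
  expect_equal(aggregate_patients(mk(c("FGR", "FGR")))$final, "FGR")
  expect_equal(aggregate_patients(mk(c("FGR", "CTRL")))$final, "indeterminate")
  expect_equal(aggregate_patients(mk("CTRL"))$final, "CTRL")
  expect_error(aggregate_patients(mk(character(0))[0, ]),
               class = "fgrms_error_validation")

  both <- aggregate_patients(dplyr::bind_rows(mk(c("FGR", "FGR"), "x"),
                                              mk(c("FGR", "CTRL"), "y")))
  expect_equal(both$final[both$patient_id == "x"], "FGR")
  expect_equal(both$final[both$patient_id == "y"], "indeterminate")
  expect_equal(both$n_spectra, c(2L, 2L))
})
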