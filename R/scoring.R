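#' Compute the assessment quotients A, B and C
#'
#' Within each spectrum, the five marker areas are brought into context with
#' each other by forming ratios, which normalizes away absolute intensity:
#' \deqn{A = \frac{area(8916)}{area(8205)}, \quad
#'       B = \frac{area(8766)}{area(9422) + area(9713)}, \quad
#'       C = \frac{area(8916)}{area(8766) + area(9422) + area(9713)}.}
#'
#' @param areas Either a data frame with columns `mz_8205`, `mz_8766`,
#'   `mz_8916`, `mz_9422`, `mz_9713` (e.g. from [preprocess_spectra()]); the
#'   quotient columns `A`, `B`, `C` are appended. Or a named numeric vector of
#'   the five areas (names `"8205"`... or `"mz_8205"`...); a one-row tibble
#'   with `A`, `B`, `C` is returned.
#' @return A tibble (see above). Rows with `NA` areas yield `NA` quotients.
#' @examples
#' compute_quotients(c("8205" = 2, "8766" = 3, "8916" = 6,
#'                     "9422" = 1, "9713" = 2))
#' @export
compute_quotients <- function(areas) {
  if (is.data.frame(areas)) {
    need <- marker_col(c(8205, 8766, 8916, 9422, 9713))
    missing_cols <- setdiff(need, names(areas))
    if (length(missing_cols) > 0) {
      stop_validation(paste0("Missing marker area column(s): ",
                             paste(missing_cols, collapse = ", ")))
    }
    denom_ok <- function(x) is.na(x) | x > 0
    if (!all(denom_ok(areas$mz_8205)) ||
        !all(denom_ok(areas$mz_9422 + areas$mz_9713)) ||
        !all(denom_ok(areas$mz_8766 + areas$mz_9422 + areas$mz_9713))) {
      stop_validation("Denominator areas must be strictly positive.")
    }
    return(dplyr::mutate(
      tibble::as_tibble(areas),
      A = .data$mz_8916 / .data$mz_8205,
      B = .data$mz_8766 / (.data$mz_9422 + .data$mz_9713),
      C = .data$mz_8916 / (.data$mz_8766 + .data$mz_9422 + .data$mz_9713)
    ))
  }
  tibble::as_tibble(quotients_from_areas(areas))
}

# Named-vector core used by both the user-facing function and the simulator's
# expected-quotient validation.
quotients_from_areas <- function(areas) {
  names(areas) <- sub("^mz_", "", names(areas))
  need <- c("8205", "8766", "8916", "9422", "9713")
  if (!all(need %in% names(areas))) {
    stop_validation(paste0("`areas` must name all five markers: ",
                           paste(need, collapse = ", ")))
  }
  a <- as.numeric(areas[need])
  if (any(!is.finite(a)) || a[1] <= 0 || (a[2] + a[4] + a[5]) <= 0 ||
      (a[4] + a[5]) <= 0) {
    stop_validation("Marker areas must be finite with positive denominators.")
  }
  list(
    A = a[3] / a[1],
    B = a[2] / (a[4] + a[5]),
    C = a[3] / (a[2] + a[4] + a[5])
  )
}

#' Per-quotient scores
#'
#' `score_single()` implements the single-cut-off rule: score 1 when the
#' quotient value is strictly higher than the cut-off, else 0.
#' `score_dual()` implements the three-regime rule of the combined cut-offs:
#' 0.0 when the value is below or equal to the lower cut-off, 0.5 when above
#' the lower but below or equal to the upper, 1.0 when above the upper.
#' Boundary semantics are exact ("below or equal" vs "higher than"); no
#' epsilon slop. Both are vectorized over `value`.
#'
#' @param value Quotient value(s).
#' @param cutoff Single cut-off (single mode).
#' @param lower,upper Dual cut-offs, `lower < upper`.
#' @return Numeric score(s): `{0, 1}` or `{0.0, 0.5, 1.0}`.
#' @examples
#' score_single(4.3, 4.2)
#' score_dual(c(3.4, 4.0, 5.0), lower = 3.4, upper = 4.2)
#' @export
score_single <- function(value, cutoff) {
  if (any(!is.finite(value)) || !is.finite(cutoff)) {
    stop_validation("`value` and `cutoff` must be finite.")
  }
  as.numeric(value > cutoff)
}

#' @rdname score_single
#' @export
score_dual <- function(value, lower, upper) {
  if (!is.finite(lower) || !is.finite(upper) || lower >= upper) {
    stop_validation("Dual cut-offs require `lower < upper`.")
  }
  if (any(!is.finite(value))) stop_validation("`value` must be finite.")
  ifelse(value > upper, 1.0, ifelse(value > lower, 0.5, 0.0))
}

#' Score spectra and classify them by the cumulative-score discriminator
#'
#' Applies the per-quotient scoring rule (single 0/1 with a [cutoff_set][train_cutoff_set],
#' or dual 0.0/0.5/1.0 with [dual_cutoffs][combine_cutoffs]) to quotients A, B
#' and C, sums them into the cumulative score (0 to 3), and assigns the class:
#' cumulative score at or below the discriminator (default 1.0) calls CTRL,
#' above it calls FGR.
#'
#' @param quotients A data frame with columns `A`, `B`, `C` (e.g. from
#'   [compute_quotients()]); other columns are carried through.
#' @param cutoffs A `cutoff_set` (single mode) or `dual_cutoffs` (dual mode).
#' @param discriminator Cumulative-score discriminator (default 1.0).
#' @return The input tibble with appended columns `score_A`, `score_B`,
#'   `score_C`, `cumulative` and `call` (`"CTRL"`/`"FGR"`).
#' @examples
#' score_spectra(tibble::tibble(A = 5, B = 8, C = 6), cutoffs_paper_ow())
#' @export
score_spectra <- function(quotients, cutoffs, discriminator = 1.0) {
  if (!is.data.frame(quotients) || !all(c("A", "B", "C") %in% names(quotients))) {
    stop_validation("`quotients` must be a data frame with columns A, B, C.")
  }
  q <- tibble::as_tibble(quotients)
  if (inherits(cutoffs, "dual_cutoffs")) {
    tab <- cutoffs$table
    sc <- lapply(c("A", "B", "C"), function(nm) {
      row <- tab[tab$quotient == nm, ]
      score_dual(q[[nm]], row$lower, row$upper)
    })
  } else if (inherits(cutoffs, "cutoff_set")) {
    tab <- cutoffs$table
    sc <- lapply(c("A", "B", "C"), function(nm) {
      row <- tab[tab$quotient == nm, ]
      score_single(q[[nm]], row$cutoff)
    })
  } else {
    stop_validation(
      "`cutoffs` must be a `cutoff_set` (single mode) or `dual_cutoffs` (dual mode).")
  }
  q$score_A <- sc[[1]]
  q$score_B <- sc[[2]]
  q$score_C <- sc[[3]]
  q$cumulative <- q$score_A + q$score_B + q$score_C
  q$call <- ifelse(q$cumulative > discriminator, "FGR", "CTRL")
  q
}

#' Consolidate replicate spectra into patient-level calls
#'
#' A patient's final call is the shared class when all non-excluded replicate
#' spectra agree, and `"indeterminate"` otherwise. Indeterminate patients are
#' excluded from downstream confusion statistics.
#'
#' @param scores A data frame with columns `patient_id` and `call`
#'   (from [score_spectra()]); a `cohort` column, if present, is carried
#'   through as the truth label.
#' @return A tibble with one row per patient: `patient_id`, `cohort` (if
#'   available), `n_spectra`, `final`.
#' @export
aggregate_patients <- function(scores) {
  if (!all(c("patient_id", "call") %in% names(scores))) {
    stop_validation("`scores` must have columns `patient_id` and `call`.")
  }
  if (nrow(scores) == 0L) stop_validation("No score records to aggregate.")
  grouped <- dplyr::group_by(tibble::as_tibble(scores), .data$patient_id)
  out <- dplyr::summarise(
    grouped,
    cohort = if ("cohort" %in% names(scores)) dplyr::first(.data$cohort) else
      NA_character_,
    n_spectra = dplyr::n(),
    final = if (length(unique(.data$call)) == 1L) .data$call[1] else
      "indeterminate",
    .groups = "drop"
  )
  out
}
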