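#' Sentinel augmentation of training quotient values
#'
#' Before scanning candidate cut-offs, the sorted list of training quotient
#' values is extended by two theoretical values: the lowest value minus 1 at
#' the bottom and the highest value plus 1 at the top, so the scan covers
#' "everything below" and "everything above" the observed range. The offset
#' is the absolute constant 1, not relative to scale.
#'
#' @param values Non-empty numeric vector (duplicates preserved).
#' @return Sorted ascending numeric vector of length `length(values) + 2`.
#' @examples
#' augment_with_sentinels(c(2, 5, 3))
#' @export
augment_with_sentinels <- function(values) {
  if (length(values) == 0L) stop_validation("`values` must be non-empty.")
  if (any(!is.finite(values))) stop_validation("`values` must be finite.")
  sorted <- sort(values)
  c(sorted[1] - 1, sorted, sorted[length(sorted)] + 1)
}

#' Candidate cut-offs by interpolation between neighbours
#'
#' Linear interpolation between each pair of neighbouring values in the
#' sentinel-augmented sorted list, at the midpoint (fraction 0.5), yields the
#' test cut-off candidates.
#'
#' @param augmented Sorted numeric vector of length >= 2 (typically from
#'   [augment_with_sentinels()]).
#' @return Numeric vector of midpoints, length `length(augmented) - 1`.
#' @examples
#' candidate_cutoffs(c(1, 2, 3, 5, 6))
#' @export
candidate_cutoffs <- function(augmented) {
  if (length(augmented) < 2L) stop_validation("Need at least 2 values.")
  if (is.unsorted(augmented)) stop_validation("`augmented` must be sorted ascending.")
  (head(augmented, -1) + tail(augmented, -1)) / 2
}

#' Youden-index scan for the best cut-off of one quotient
#'
#' Ranks all training values (both groups pooled), augments with sentinels,
#' forms midpoint candidates, and evaluates every candidate `c` with the fixed
#' direction convention that a spectrum is called FGR-positive when its value
#' is strictly greater than `c` (FGR quotients are the higher ones). At each
#' candidate the Youden index `J = sensitivity + specificity - 1` is computed;
#' the candidate maximizing `J` is the best cut-off, ties broken by the
#' smallest candidate (favouring sensitivity).
#'
#' @param values Numeric quotient values.
#' @param labels Character/factor labels parallel to `values`; `positive`
#'   marks the FGR class, everything else is CTRL.
#' @param positive Positive-class label (default `"FGR"`).
#' @return A list with `best_cutoff`, `j_max`, `sensitivity`, `specificity`
#'   (at the optimum) and `scan`, the full audit table (one row per candidate:
#'   `cutoff`, `sensitivity`, `specificity`, `j`).
#' @examples
#' youden_scan(c(1, 2, 3, 10, 11, 12), rep(c("CTRL", "FGR"), each = 3))$best_cutoff
#' @export
youden_scan <- function(values, labels, positive = "FGR") {
  if (length(values) != length(labels)) {
    stop_validation("`values` and `labels` must have equal length.")
  }
  if (any(!is.finite(values))) stop_validation("`values` must be finite.")
  is_pos <- as.character(labels) == positive
  if (!any(is_pos) || all(is_pos)) {
    stop_validation(
      "Both classes must be present: cannot compute sensitivity and specificity.")
  }
  cands <- candidate_cutoffs(augment_with_sentinels(values))
  pos <- values[is_pos]
  neg <- values[!is_pos]
  sens <- vapply(cands, function(c) mean(pos > c), numeric(1))
  spec <- vapply(cands, function(c) mean(neg <= c), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))[1] # candidates ascend, so [1] is the smallest
  list(
    best_cutoff = cands[best],
    j_max = j[best],
    sensitivity = sens[best],
    specificity = spec[best],
    scan = tibble::tibble(cutoff = cands, sensitivity = sens,
                          specificity = spec, j = j)
  )
}

#' Train a cut-off set on labelled quotients
#'
#' Runs one [youden_scan()] per quotient (A, B, C) on a labelled training
#' table and collects the per-quotient optima.
#'
#' @param quotients Data frame with columns `A`, `B`, `C` and a label column.
#' @param label_col Name of the label column (default `"cohort"`).
#' @param positive Positive-class label (default `"FGR"`).
#' @param training_label Free-text name for this training set (e.g. `"O"`).
#' @return An object of class `cutoff_set`: list with `table` (tibble with
#'   columns `quotient`, `cutoff`, `j_max`, `sensitivity`, `specificity`),
#'   `scans` (per-quotient audit tables) and `training_label`.
#' @seealso [combine_cutoffs()], [score_spectra()], [tidy.cutoff_set()]
#' @export
train_cutoff_set <- function(quotients, label_col = "cohort",
                             positive = "FGR", training_label = "trained") {
  need <- c("A", "B", "C", label_col)
  missing_cols <- setdiff(need, names(quotients))
  if (length(missing_cols) > 0) {
    stop_validation(paste0("`quotients` is missing column(s): ",
                           paste(missing_cols, collapse = ", ")))
  }
  labels <- quotients[[label_col]]
  scans <- lapply(c("A", "B", "C"), function(nm) {
    youden_scan(quotients[[nm]], labels, positive = positive)
  })
  names(scans) <- c("A", "B", "C")
  tab <- tibble::tibble(
    quotient = c("A", "B", "C"),
    cutoff = vapply(scans, `[[`, numeric(1), "best_cutoff"),
    j_max = vapply(scans, `[[`, numeric(1), "j_max"),
    sensitivity = vapply(scans, `[[`, numeric(1), "sensitivity"),
    specificity = vapply(scans, `[[`, numeric(1), "specificity")
  )
  structure(
    list(table = tab, scans = lapply(scans, `[[`, "scan"),
         training_label = training_label),
    class = "cutoff_set"
  )
}

#' Build a cut-off set from fixed values
#'
#' @param A,B,C Cut-off values for the three quotients.
#' @param training_label Name of the source training set.
#' @return A `cutoff_set` (without scan diagnostics).
#' @examples
#' cutoff_set(A = 4.2, B = 5.0, C = 4.0, training_label = "O")
#' @export
cutoff_set <- function(A, B, C, training_label = "fixed") {
  vals <- c(A = A, B = B, C = C)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_validation("Cut-offs must be positive finite numbers.")
  }
  structure(
    list(
      table = tibble::tibble(
        quotient = c("A", "B", "C"), cutoff = unname(vals),
        j_max = NA_real_, sensitivity = NA_real_, specificity = NA_real_
      ),
      scans = NULL, training_label = training_label
    ),
    class = "cutoff_set"
  )
}

#' @export
print.cutoff_set <- function(x, ...) {
  cat(sprintf("<cutoff_set> training set \"%s\"\n", x$training_label))
  print(x$table)
  invisible(x)
}

#' Combine two cut-off sets into dual (lower/upper) cut-offs
#'
#' Per quotient, the lower threshold is the minimum and the upper the maximum
#' of the two sets' cut-offs, opening the three scoring regimes
#' below / in between / above. Equal cut-offs for a quotient leave no middle
#' regime and raise a degenerate-combination error.
#'
#' @param set1,set2 Two [cutoff_set][train_cutoff_set] objects.
#' @return An object of class `dual_cutoffs`: list with `table` (tibble
#'   `quotient`, `lower`, `upper`) and `sources`.
#' @examples
#' combine_cutoffs(cutoff_set(4.2, 5.0, 4.0, "O"), cutoff_set(3.4, 7.0, 5.1, "W"))
#' @export
combine_cutoffs <- function(set1, set2) {
  if (!inherits(set1, "cutoff_set") || !inherits(set2, "cutoff_set")) {
    stop_validation("Both arguments must be `cutoff_set` objects.")
  }
  c1 <- set1$table$cutoff
  c2 <- set2$table$cutoff
  if (any(c1 == c2)) {
    stop_validation(paste0(
      "Degenerate combination: equal cut-offs for quotient(s) ",
      paste(set1$table$quotient[c1 == c2], collapse = ", "),
      " leave no intermediate scoring regime."
    ))
  }
  structure(
    list(
      table = tibble::tibble(
        quotient = set1$table$quotient,
        lower = pmin(c1, c2),
        upper = pmax(c1, c2)
      ),
      sources = c(set1$training_label, set2$training_label)
    ),
    class = "dual_cutoffs"
  )
}

#' @export
print.dual_cutoffs <- function(x, ...) {
  cat(sprintf("<dual_cutoffs> combined from \"%s\" and \"%s\"\n",
              x$sources[1], x$sources[2]))
  print(x$table)
  invisible(x)
}

#' Published cut-off preset
#'
#' The dual cut-offs obtained by combining the cut-offs trained in this
#' study's training set "O" (A 4.2, B 5.0, C 4.0) with those of the preceding
#' study's training set "W" (A 3.4, B 7.0, C 5.1), shipped as a preset so new
#' peak tables can be scored without retraining. These derive from the
#' original cohorts and do not describe simulated data.
#'
#' @return A `dual_cutoffs` object.
#' @examples
#' cutoffs_paper_ow()
#' @export
cutoffs_paper_ow <- function() {
  combine_cutoffs(
    cutoff_set(A = 4.2, B = 5.0, C = 4.0, training_label = "O"),
    cutoff_set(A = 3.4, B = 7.0, C = 5.1, training_label = "W")
  )
}

#' Write / read cut-offs as JSON
#'
#' @param cutoffs A `cutoff_set` or `dual_cutoffs` object.
#' @param path JSON file path.
#' @return `write_cutoffs()`: `path`, invisibly. `read_cutoffs()`: the
#'   restored object.
#' @export
write_cutoffs <- function(cutoffs, path) {
  if (inherits(cutoffs, "dual_cutoffs")) {
    payload <- list(type = "dual", table = cutoffs$table,
                    sources = cutoffs$sources)
  } else if (inherits(cutoffs, "cutoff_set")) {
    payload <- list(type = "single", table = cutoffs$table,
                    training_label = cutoffs$training_label)
  } else {
    stop_validation("`cutoffs` must be a `cutoff_set` or `dual_cutoffs`.")
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cutoffs
#' @export
read_cutoffs <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  tab <- tibble::as_tibble(payload$table)
  if (identical(payload$type, "dual")) {
    structure(list(table = tab, sources = payload$sources),
              class = "dual_cutoffs")
  } else {
    structure(list(table = tab, scans = NULL,
                   training_label = payload$training_label),
              class = "cutoff_set")
  }
}

#' @describeIn train_cutoff_set Per-quotient optima as a tibble.
#' @param x A `cutoff_set` object.
#' @param ... Unused.
#' @export
tidy.cutoff_set <- function(x, ...) x$table

#' @describeIn train_cutoff_set One-row summary (training label, mean J over
#'   the three quotients).
#' @export
glance.cutoff_set <- function(x, ...) {
  tibble::tibble(training_label = x$training_label,
                 mean_j_max = mean(x$table$j_max))
}

#' @describeIn combine_cutoffs Lower/upper thresholds as a tibble.
#' @param x A `dual_cutoffs` object.
#' @param ... Unused.
#' @export
tidy.dual_cutoffs <- function(x, ...) x$table
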