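#' Diagnostic confusion metrics
#'
#' Builds the 2x2 confusion table of predicted calls against gold-standard
#' labels and derives sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' predictive values `PPV = TP/(TP+FP)` and `NPV = TN/(TN+FN)`, false
#' positive/negative rates, accuracy and the Youden index
#' `J = sensitivity + specificity - 1`. A zero denominator yields `NA`
#' (undefined), never an error. Indeterminate calls must be excluded upstream
#' (see [aggregate_patients()]).
#'
#' @param calls Character vector of predicted classes.
#' @param truth Character vector of gold-standard classes, same length.
#' @param positive Positive-class label (default `"FGR"`); every other truth
#'   label counts as negative.
#' @return An object of class `confusion_metrics` (a list of counts and
#'   rates, plus `rounding`, the decimals used in printing).
#' @examples
#' confusion_from_counts(tp = 26, fp = 9, tn = 33, fn = 3)
#' @export
confusion_metrics <- function(calls, truth, positive = "FGR") {
  if (length(calls) != length(truth)) {
    stop_validation("`calls` and `truth` must have equal length.")
  }
  pred_pos <- as.character(calls) == positive
  true_pos <- as.character(truth) == positive
  confusion_from_counts(
    tp = sum(pred_pos & true_pos),
    fp = sum(pred_pos & !true_pos),
    tn = sum(!pred_pos & !true_pos),
    fn = sum(!pred_pos & true_pos)
  )
}

#' @rdname confusion_metrics
#' @param tp,fp,tn,fn Confusion counts.
#' @export
confusion_from_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    stop_validation("Confusion counts must be non-negative integers.")
  }
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- rate(tp, tp + fn)
  spec <- rate(tn, tn + fp)
  structure(
    list(
      tp = tp, fp = fp, tn = tn, fn = fn,
      sensitivity = sens,
      specificity = spec,
      ppv = rate(tp, tp + fp),
      npv = rate(tn, tn + fn),
      fpr = if (is.na(spec)) NA_real_ else 1 - spec,
      fnr = if (is.na(sens)) NA_real_ else 1 - sens,
      accuracy = rate(tp + tn, tp + tn + fp + fn),
      youden_j = if (is.na(sens) || is.na(spec)) NA_real_ else sens + spec - 1,
      rounding = 2L
    ),
    class = "confusion_metrics"
  )
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat("<confusion_metrics>\n")
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  fmt <- function(v) {
    if (is.na(v)) "  --" else
      formatC(round_half_up(v, x$rounding), format = "f", digits = x$rounding)
  }
  cat(sprintf("  sensitivity %s  specificity %s  PPV %s  NPV %s\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$ppv), fmt(x$npv)))
  cat(sprintf("  accuracy %s  Youden J %s\n", fmt(x$accuracy), fmt(x$youden_j)))
  invisible(x)
}

#' @describeIn confusion_metrics One row per metric: `metric`, `value` (raw)
#'   and `reported` (rounded half-up to `rounding` decimals, the presentation
#'   convention).
#' @param x A `confusion_metrics` object.
#' @param ... Unused.
#' @export
tidy.confusion_metrics <- function(x, ...) {
  nm <- c("sensitivity", "specificity", "ppv", "npv", "fpr", "fnr",
          "accuracy", "youden_j")
  vals <- vapply(x[nm], identity, numeric(1))
  tibble::tibble(
    metric = nm,
    value = unname(vals),
    reported = round_half_up(unname(vals), x$rounding)
  )
}

#' @describeIn confusion_metrics One-row summary with counts and raw rates.
#' @export
glance.confusion_metrics <- function(x, ...) {
  tibble::tibble(
    tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn,
    sensitivity = x$sensitivity, specificity = x$specificity,
    ppv = x$ppv, npv = x$npv, accuracy = x$accuracy, youden_j = x$youden_j
  )
}

#' Youden index from sensitivity and specificity
#'
#' @param sensitivity,specificity Rates in `[0, 1]`.
#' @return `J = sensitivity + specificity - 1`, in `[-1, 1]`.
#' @examples
#' youden_index(0.93, 0.93)
#' @export
youden_index <- function(sensitivity, specificity) {
  ok <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x <= 1)
  if (!ok(sensitivity) || !ok(specificity)) {
    stop_validation("`sensitivity` and `specificity` must lie in [0, 1].")
  }
  sensitivity + specificity - 1
}

#' ROC analysis of cumulative scores
#'
#' Computes the area under the ROC curve by the rank (Mann-Whitney)
#' formulation, crediting ties 0.5, together with the ROC points obtained by
#' thresholding at every distinct score ("positive" means score strictly
#' greater than the threshold).
#'
#' @param scores Numeric scores (discrete cumulative scores are fine).
#' @param truth Character labels parallel to `scores`.
#' @param positive Positive-class label (default `"FGR"`).
#' @return An object of class `fgr_roc`: list with `auc`, `points` (tibble
#'   `threshold`, `fpr`, `tpr`), `n_positive`, `n_negative`.
#' @examples
#' roc_auc(c(2, 3, 0, 1), c("FGR", "FGR", "CTRL", "CTRL"))$auc
#' @export
roc_auc <- function(scores, truth, positive = "FGR") {
  if (length(scores) != length(truth)) {
    stop_validation("`scores` and `truth` must have equal length.")
  }
  if (any(!is.finite(scores))) stop_validation("`scores` must be finite.")
  is_pos <- as.character(truth) == positive
  n1 <- sum(is_pos)
  n0 <- sum(!is_pos)
  if (n1 == 0L || n0 == 0L) {
    stop_validation("Both classes must be present for ROC analysis.")
  }
  r <- rank(scores) # midranks credit ties 0.5
  auc <- (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thresholds <- c(-Inf, sort(unique(scores)))
  pts <- tibble::tibble(
    threshold = thresholds,
    tpr = vapply(thresholds, function(t) mean(scores[is_pos] > t), numeric(1)),
    fpr = vapply(thresholds, function(t) mean(scores[!is_pos] > t), numeric(1))
  )
  structure(list(auc = auc, points = pts, n_positive = n1, n_negative = n0),
            class = "fgr_roc")
}

#' @export
print.fgr_roc <- function(x, ...) {
  cat(sprintf("<fgr_roc> AUC = %.3f (%d positive, %d negative)\n",
              x$auc, x$n_positive, x$n_negative))
  invisible(x)
}

#' @describeIn roc_auc ROC points as a tibble.
#' @param x An `fgr_roc` object.
#' @param ... Unused.
#' @export
tidy.fgr_roc <- function(x, ...) x$points

#' @describeIn roc_auc One-row summary (`auc`, class sizes).
#' @export
glance.fgr_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_positive = x$n_positive,
                 n_negative = x$n_negative)
}

#' @describeIn roc_auc ROC curve plot.
#' @param object An `fgr_roc` object.
#' @export
autoplot.fgr_roc <- function(object, ...) {
  pts <- dplyr::arrange(object$points, .data$fpr, .data$tpr)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("ROC, AUC = %.2f", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Distribution of cumulative scores by group
#'
#' @param scores Output of [score_spectra()] with a truth-label column.
#' @param label_col Truth-label column name (default `"cohort"`).
#' @return A ggplot object (stacked count bars per cumulative score).
#' @export
plot_score_distribution <- function(scores, label_col = "cohort") {
  if (!all(c("cumulative", label_col) %in% names(scores))) {
    stop_validation("`scores` needs columns `cumulative` and the label column.")
  }
  ggplot2::ggplot(scores, ggplot2::aes(x = factor(.data$cumulative),
                                       fill = .data[[label_col]])) +
    ggplot2::geom_bar(position = "dodge") +
    ggplot2::labs(x = "Cumulative score", y = "Spectra", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Minimal sample size for comparing two means
#'
#' Normal-approximation sample size per group for a two-sided two-sample
#' comparison of means at standardized effect size `d` (Cohen's d):
#' \deqn{n = \lceil 2\,(z_{1-\alpha/2} + z_{power})^2 / d^2 \rceil.}
#' This closed form approximates the noncentral-t computation of dedicated
#' power software to within about one unit of `n` at `d` near 1.
#'
#' @param effect_size Standardized mean difference (Cohen's d), > 0.
#' @param alpha Two-sided type-I error (default 0.05).
#' @param power Target power 1 - beta (default 0.80).
#' @return Integer sample size per group.
#' @examples
#' min_sample_size(effect_size = 1) # 16 per group
#' @export
min_sample_size <- function(effect_size, alpha = 0.05, power = 0.80) {
  if (!is.numeric(effect_size) || length(effect_size) != 1L ||
      !is.finite(effect_size) || effect_size <= 0) {
    stop_validation("`effect_size` must be a single positive number.")
  }
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop_validation("`alpha` and `power` must lie strictly in (0, 1).")
  }
  z <- qnorm(1 - alpha / 2) + qnorm(power)
  as.integer(ceiling(2 * z^2 / effect_size^2))
}

#' Pooled-SD standardized mean difference (Cohen's d)
#'
#' @param x,y Numeric samples (e.g. cumulative scores of the two groups).
#' @return Absolute standardized mean difference.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  if (nx < 2L || ny < 2L) stop_validation("Need at least 2 values per group.")
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  if (sp == 0) stop_validation("Zero pooled variance: effect size undefined.")
  abs(mean(x) - mean(y)) / sp
}
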