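#' @title Evaluation statistics
#' @name evaluation
#' @description Minute-wise confusion matrices over the five activity
#'   categories, pooled and per-participant accuracies, Spearman rank
#'   association of summary measures with the ordinal categories, and the
#'   two-sample Kolmogorov-Smirnov test.
NULL

#' Minute-wise confusion matrix
#'
#' Counts true x estimated categories over the shared evaluated minutes.
#' Minutes where either series is `nonwear` or `unknown` are excluded, so
#' fold matrices are addable across disjoint minute sets.
#'
#' @param truth,est [label_series()] on the identical epoch grid.
#' @return A `pa_confusion` object: a 5x5 integer matrix (rows = true,
#'   columns = estimated, ordered sleep..vigorous).
#' @export
confusion <- function(truth, est) {
  if (length(truth$epoch_start) != length(est$epoch_start) ||
      !all(truth$epoch_start == est$epoch_start)) {
    stop_wristpa("label series are on different epoch grids",
                 "alignment_error")
  }
  tc <- factor(as.character(truth$category), levels = PA_LEVELS)
  ec <- factor(as.character(est$category), levels = PA_LEVELS)
  keep <- !is.na(tc) & !is.na(ec)
  m <- table(true = tc[keep], estimated = ec[keep])
  structure(unclass(m), class = "pa_confusion")
}

#' @export
print.pa_confusion <- function(x, ...) {
  cat(sprintf("<pa_confusion> %d minutes, accuracy %.3f\n", sum(x),
              accuracy(x)))
  print(unclass(x))
  invisible(x)
}

#' Overall accuracy of a confusion matrix
#'
#' @param cm A `pa_confusion`.
#' @return Trace over total; `NaN` for an empty matrix.
#' @export
accuracy <- function(cm) {
  sum(diag(cm)) / sum(cm)
}

#' Per-category correct fractions
#'
#' @param cm A `pa_confusion`.
#' @return Named vector: for each true category, the fraction of its
#'   minutes estimated correctly (`NaN` for absent categories).
#' @export
per_category_rate <- function(cm) {
  setNames(diag(cm) / rowSums(cm), rownames(cm))
}

#' Add confusion matrices (e.g. across folds)
#'
#' @param e1,e2 `pa_confusion` objects.
#' @return Their element-wise sum.
#' @export
`+.pa_confusion` <- function(e1, e2) {
  structure(unclass(e1) + unclass(e2), class = "pa_confusion")
}

#' Spearman association of a measure with the activity categories
#'
#' Rank correlation (average ranks for ties) between per-minute values and
#' the ordinal category codes sleep=0 < sedentary=1 < light=2 < moderate=3
#' < vigorous=4. A magnitude of 0.3 or more is conventionally read as a
#' statistically strong association in healthcare applications.
#'
#' @param epochs An [epoch_series()].
#' @param labels A [label_series()] on the same grid.
#' @return The correlation coefficient, with attribute `strong` (logical,
#'   |rho| >= 0.3).
#' @export
spearman_assoc <- function(epochs, labels) {
  if (length(epochs$epoch_start) != length(labels$epoch_start) ||
      !all(epochs$epoch_start == labels$epoch_start)) {
    stop_wristpa("epochs and labels are on different grids",
                 "alignment_error")
  }
  code <- pa_code(labels)
  keep <- !is.na(code) & !is.na(epochs$values)
  v <- epochs$values[keep]
  k <- code[keep]
  if (length(v) < 3L) {
    stop_wristpa("need >= 3 paired minutes", "data_error")
  }
  if (length(unique(v)) < 2L || length(unique(k)) < 2L) {
    stop_wristpa("correlation undefined for constant values or labels",
                 "undefined_correlation")
  }
  rho <- stats::cor(v, k, method = "spearman")
  structure(rho, strong = abs(rho) >= 0.3)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' @param a,b Non-empty numeric samples.
#' @param exact Use the exact small-sample p-value instead of the asymptotic
#'   distribution (default `FALSE`; minute-level samples are typically in
#'   the thousands).
#' @param alpha Significance threshold for the decision flag (default 0.01).
#' @return List with `statistic` (supremum ECDF distance D), `p_value`, and
#'   `significant` (p < alpha).
#' @export
ks_two_sample <- function(a, b, exact = FALSE, alpha = 0.01) {
  if (length(a) == 0L || length(b) == 0L) {
    stop_wristpa("both samples must be non-empty", "data_error")
  }
  ht <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       significant = ht$p.value < alpha)
}

#' Per-participant accuracy summary
#'
#' @param folds List of per-participant `pa_confusion` matrices (e.g. from
#'   [lopo_run()]).
#' @return List with `per_participant` (accuracy vector), `mean_accuracy`
#'   (their unweighted mean), `pooled` (summed matrix), and
#'   `pooled_accuracy`. Pooled and mean accuracies differ when participants
#'   contribute unequal minute counts, so both are reported.
#' @export
per_participant_summary <- function(folds) {
  if (length(folds) < 1L) {
    stop_wristpa("need >= 1 fold", "data_error")
  }
  acc <- vapply(folds, accuracy, numeric(1))
  pooled <- Reduce(`+`, folds)
  list(per_participant = acc, mean_accuracy = mean(acc), pooled = pooled,
       pooled_accuracy = accuracy(pooled))
}
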