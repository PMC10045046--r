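# Confusion-matrix metrics for the benign/malignant classifier.

#' Confusion counts for binary classification
#'
#' Counts true/false positives and negatives with a stated positive class.
#' Labels outside the allowed set raise an error.
#'
#' @param predicted,truth equal-length nonempty label vectors.
#' @param positive the positive class (default "malignant").
#' @param classes the allowed label set (default benign/malignant).
#' @return List of class `ConfusionCounts` with `tp`, `tn`, `fp`, `fn`,
#'   `n`, `positive`.
#' @export
confusionCounts <- function(predicted, truth, positive = "malignant",
                            classes = c("benign", "malignant")) {
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  if (!length(truth) || length(predicted) != length(truth))
    stop("predicted and truth must be nonempty and of equal length")
  if (!all(c(predicted, truth) %in% classes))
    stop("label outside the allowed classes: ",
         paste(setdiff(c(predicted, truth), classes), collapse = ", "))
  if (!positive %in% classes) stop("positive class not in classes")
  pp <- predicted == positive
  tp <- truth == positive
  structure(list(tp = sum(pp & tp), tn = sum(!pp & !tp),
                 fp = sum(pp & !tp), fn = sum(!pp & tp),
                 n = length(truth), positive = positive),
            class = "ConfusionCounts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP + TN) / n`, sensitivity `TP / (TP + FN)`, specificity
#' `TN / (TN + FP)`, precision `TP / (TP + FP)` (each in percent) and the
#' F-score `2 * precision * sensitivity / (precision + sensitivity)`.
#' A zero denominator yields an explicit `NA` marker, never a silent 0;
#' the `undefined` field names the affected metrics.
#'
#' @param counts a [confusionCounts()] result, or a list with fields
#'   `tp`, `tn`, `fp`, `fn`.
#' @return List of class `MetricReport`: `accuracy`, `sensitivity`,
#'   `specificity`, `precision`, `fScore` (percent), `n`, `undefined`.
#' @examples
#' m <- classificationMetrics(list(tp = 50, tn = 40, fp = 5, fn = 5))
#' m$accuracy  # 90
#' @export
classificationMetrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  n <- tp + tn + fp + fn
  if (n == 0) stop("all confusion counts are zero")
  rat <- function(num, den) if (den == 0) NA_real_ else num / den * 100
  accuracy <- (tp + tn) / n * 100
  sensitivity <- rat(tp, tp + fn)
  specificity <- rat(tn, tn + fp)
  precision <- rat(tp, tp + fp)
  fScore <- if (is.na(precision) || is.na(sensitivity) ||
                precision + sensitivity == 0) NA_real_
    else 2 * precision * sensitivity / (precision + sensitivity)
  vals <- list(accuracy = accuracy, sensitivity = sensitivity,
               specificity = specificity, precision = precision,
               fScore = fScore)
  undefined <- names(vals)[vapply(vals, is.na, TRUE)]
  structure(c(vals, list(n = n, undefined = undefined)),
            class = "MetricReport")
}

#' @export
print.MetricReport <- function(x, ...) {
  cat(sprintf(
    "MetricReport (n = %d): accuracy %s, sensitivity %s, specificity %s, precision %s, F %s\n",
    x$n, .fmtPct(x$accuracy), .fmtPct(x$sensitivity), .fmtPct(x$specificity),
    .fmtPct(x$precision), .fmtPct(x$fScore)))
  if (length(x$undefined))
    cat("undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

.fmtPct <- function(v) if (is.na(v)) "undefined" else sprintf("%.3f%%", v)

#' Learning-curve report over training-set size
#'
#' Trains and evaluates the classifier at increasing training-set sizes
#' ("number of instances" is parameterized as the training size; the test
#' split stays fixed) and tabulates the confusion metrics per size.
#'
#' @param samples list of [NoduleSample-class].
#' @param sizes training sizes to evaluate.
#' @param config a [cnnConfig()].
#' @param seed RNG seed for the split and subsampling.
#' @return data.frame with one row per size: n_instances plus the metric
#'   columns (NA where undefined).
#' @export
learningCurve <- function(samples, sizes, config = cnnConfig(), seed = 1L) {
  split <- splitDataset(samples, 0.8, seed)
  testSet <- samples[split$test]
  testLabels <- vapply(testSet, sampleLabel, "")
  trainIdx <- split$train
  rows <- lapply(sizes, function(sz) {
    sz <- min(sz, length(trainIdx))
    idx <- withSeed(deriveSeed(seed, sz), sample(trainIdx, sz))
    model <- trainModel(buildModel(config), samples[idx])
    pred <- predictCnn(model, testSet)
    m <- classificationMetrics(confusionCounts(pred$labels, testLabels))
    data.frame(n_instances = sz, accuracy = m$accuracy,
               sensitivity = m$sensitivity, specificity = m$specificity,
               precision = m$precision, fScore = m$fScore)
  })
  do.call(rbind, rows)
}
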