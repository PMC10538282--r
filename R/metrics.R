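#' Confusion counts for binary calls
#'
#' @param labels ground-truth 0/1 vector.
#' @param calls predicted 0/1 vector of the same length.
#' @return named integer vector with elements tp, tn, fp, fn.
#' @export
confusionCounts <- function(labels, calls) {
  if (!length(labels)) stop("empty input")
  if (length(labels) != length(calls)) {
    stop("labels (", length(labels), ") and calls (", length(calls),
         ") differ in length")
  }
  if (!all(labels %in% c(0, 1)) || !all(calls %in% c(0, 1))) {
    stop("labels and calls must be 0 or 1")
  }
  c(tp = sum(labels == 1 & calls == 1),
    tn = sum(labels == 0 & calls == 0),
    fp = sum(labels == 0 & calls == 1),
    fn = sum(labels == 1 & calls == 0))
}

#' Derive Sen/Spe/Acc/Mcc from confusion counts
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), accuracy =
#' (TP+TN)/total, and the Matthews correlation coefficient
#' (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)). A metric whose
#' denominator is zero is reported as `NA` and listed in the report's
#' `undefined` slot — never silently coerced to 0.
#'
#' @param counts named vector/list with tp, tn, fp, fn (e.g. from
#'   [confusionCounts()]).
#' @param auc optional AUC to carry into the report.
#' @return A [MetricsReport-class].
#' @export
computeMetrics <- function(counts, auc = NA_real_) {
  tp <- as.numeric(counts[["tp"]]); tn <- as.numeric(counts[["tn"]])
  fp <- as.numeric(counts[["fp"]]); fn <- as.numeric(counts[["fn"]])
  if (any(c(tp, tn, fp, fn) < 0)) stop("counts must be nonnegative")
  total <- tp + tn + fp + fn
  if (total < 1) stop("at least one sample required")
  undefined <- character(0)
  sen <- if (tp + fn > 0) tp / (tp + fn) else {
    undefined <- c(undefined, "sen"); NA_real_
  }
  spe <- if (tn + fp > 0) tn / (tn + fp) else {
    undefined <- c(undefined, "spe"); NA_real_
  }
  acc <- (tp + tn) / total
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom2 > 0) (tp * tn - fp * fn) / sqrt(denom2) else {
    undefined <- c(undefined, "mcc"); NA_real_
  }
  new("MetricsReport", tp = as.integer(tp), tn = as.integer(tn),
      fp = as.integer(fp), fn = as.integer(fn),
      sen = sen, spe = spe, acc = acc, mcc = mcc, auc = auc,
      undefined = undefined)
}

#' ROC curve and AUC by trapezoidal integration
#'
#' Sweeps the decision threshold over all distinct scores, collects
#' (FPR, TPR) points, and integrates trapezoidally. Tied scores move along
#' the ROC diagonal of their block, so the result equals the Mann-Whitney
#' pair statistic: concordant pairs count 1, ties 1/2.
#'
#' @param labels 0/1 vector with both classes present.
#' @param scores numeric scores (higher = more positive).
#' @return list with `auc` and a data.frame `roc` of threshold/fpr/tpr.
#' @export
rocAuc <- function(labels, scores) {
  if (length(labels) != length(scores)) stop("labels/scores length mismatch")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  nPos <- sum(labels == 1); nNeg <- sum(labels == 0)
  if (nPos == 0 || nNeg == 0) {
    stop("both classes must be present to compute a ROC curve")
  }
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  # collapse tied scores into single threshold steps
  last <- cumsum(rle(sc)$lengths)
  tpCum <- cumsum(lab == 1)[last]
  fpCum <- cumsum(lab == 0)[last]
  tpr <- c(0, tpCum / nPos)
  fpr <- c(0, fpCum / nNeg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(auc = auc,
       roc = data.frame(threshold = c(Inf, sc[last]), fpr = fpr, tpr = tpr))
}

#' Full evaluation of probabilistic predictions
#'
#' Thresholds the probabilities (call = 1 iff prob >= threshold), computes
#' the confusion counts, the derived rates and the AUC in one report.
#'
#' @param labels 0/1 ground truth.
#' @param probs positive-class probabilities.
#' @param threshold decision threshold (default 0.5).
#' @return A [MetricsReport-class] with all metrics filled in.
#' @export
evaluatePredictions <- function(labels, probs, threshold = 0.5) {
  calls <- as.integer(probs >= threshold)
  auc <- rocAuc(labels, probs)$auc
  computeMetrics(confusionCounts(labels, calls), auc = auc)
}

#' Write a MetricsReport as JSON
#'
#' Keys tp, tn, fp, fn, sen, spe, acc, mcc, auc; undefined metrics appear
#' as null.
#'
#' @param x a [MetricsReport-class]
#' @param path output file
#' @return `path`, invisibly.
#' @export
writeMetrics <- function(x, path) {
  jsonlite::write_json(metricsAsList(x), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}
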