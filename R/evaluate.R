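#' Binary confusion matrix (coral positive)
#'
#' @param pred,truth vectors of predicted and true labels, equal length.
#' @param positive label counted as positive (default "coral").
#' @return a \linkS4class{ConfusionMatrix}.
#' @export
confusionCounts <- function(pred, truth, positive = "coral") {
  if (length(pred) != length(truth))
    stop("predicted and true label vectors differ in length")
  p <- as.character(pred) == positive
  t <- as.character(truth) == positive
  new("ConfusionMatrix",
      tp = sum(p & t), fn = sum(!p & t), fp = sum(p & !t), tn = sum(!p & !t))
}

#' Construct a confusion matrix from counts
#'
#' Used when the counts come from a published table rather than from label
#' vectors.
#'
#' @param tp,fn,fp,tn non-negative integer counts.
#' @return a \linkS4class{ConfusionMatrix}.
#' @export
confusionFromCounts <- function(tp, fn, fp, tn)
  new("ConfusionMatrix", tp = as.integer(tp), fn = as.integer(fn),
      fp = as.integer(fp), tn = as.integer(tn))

#' The six accuracy metrics of a binary coral classifier
#'
#' precision = TP/(TP+FP) (1 - user error), recall = TP/(TP+FN) (producer
#' accuracy), specificity = TN/(TN+FP), accuracy = (TP+TN)/n, F-measure =
#' the harmonic mean of precision and recall, and Cohen's kappa
#' \eqn{(p_0 - p_e)/(1 - p_e)} with the chance agreement \eqn{p_e} from
#' the row/column marginals.  With balanced truth classes kappa reduces to
#' \eqn{2 \times accuracy - 1}.  Any metric with a zero denominator is NA
#' (explicit undefined marker), never silently 0.
#'
#' @param cm a \linkS4class{ConfusionMatrix}.
#' @return a \linkS4class{MetricsReport}.
#' @export
classifierMetrics <- function(cm) {
  tp <- cm@tp; fn <- cm@fn; fp <- cm@fp; tn <- cm@tn
  n <- tp + fn + fp + tn
  if (n == 0L) stop("empty evaluation set")
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- div(tp, tp + fp)
  recall <- div(tp, tp + fn)
  specificity <- div(tn, tn + fp)
  accuracy <- (tp + tn) / n
  fMeasure <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  pe <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / n^2
  kappa <- if (pe == 1) NA_real_ else (accuracy - pe) / (1 - pe)
  new("MetricsReport", precision = precision, recall = recall,
      specificity = specificity, accuracy = accuracy, fMeasure = fMeasure,
      kappa = kappa, n = as.integer(n))
}

#' Balanced accuracy
#'
#' Mean of recall and specificity; the headline number for cross-site
#' generalization where class prevalence differs between sites.
#'
#' @param cm a \linkS4class{ConfusionMatrix}.
#' @return numeric in [0, 1].
#' @export
balancedAccuracy <- function(cm) {
  m <- classifierMetrics(cm)
  (m@recall + m@specificity) / 2
}

#' ROC curve and trapezoidal AUC
#'
#' Sweeps the classification threshold over the unique posterior
#' probabilities, recording (false-positive rate, true-positive rate)
#' points from (0,0) to (1,1); the area under the curve is computed by the
#' trapezoidal rule and equals the Mann-Whitney probability that a random
#' coral point outscores a random non-coral point.
#'
#' @param prob numeric vector of coral probabilities in [0, 1].
#' @param labels true labels, both classes present.
#' @param positive positive label (default "coral").
#' @return a \linkS4class{ROCCurve}.
#' @export
rocCurve <- function(prob, labels, positive = "coral") {
  if (any(prob < 0 | prob > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]")
  pos <- as.character(labels) == positive
  nP <- sum(pos); nN <- sum(!pos)
  if (nP == 0L || nN == 0L)
    stop("ROC needs both classes in the truth labels")
  ord <- order(prob, decreasing = TRUE)
  posOrd <- pos[ord]
  keep <- c(diff(prob[ord]) != 0, TRUE)   # last index of each tied score
  tpr <- c(0, cumsum(posOrd)[keep] / nP)
  fpr <- c(0, cumsum(!posOrd)[keep] / nN)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  new("ROCCurve", points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

setMethod("show", "ConfusionMatrix", function(object) {
  cat("Confusion matrix (coral = positive):\n")
  m <- matrix(c(object@tp, object@fn, object@fp, object@tn), 2, 2,
              dimnames = list(truth = c("coral", "non-coral"),
                              predicted = c("coral", "non-coral")))
  print(m)
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf(paste0("MetricsReport (n = %d):\n",
                     "  accuracy    %.4f\n  precision   %.4f\n",
                     "  recall      %.4f\n  specificity %.4f\n",
                     "  F-measure   %.4f\n  kappa       %.4f\n"),
              object@n, object@accuracy, object@precision, object@recall,
              object@specificity, object@fMeasure, object@kappa))
})

setMethod("show", "ROCCurve", function(object) {
  cat(sprintf("ROCCurve: %d points, AUC = %.4f\n",
              nrow(object@points), object@auc))
})

#' Serialize a metrics report to a plain list
#'
#' Values rounded to 4 decimals for reporting (matching the precision used
#' in remote-sensing accuracy tables); NA marks an undefined metric.
#'
#' @param m a \linkS4class{MetricsReport}.
#' @return named list.
#' @export
metricsAsList <- function(m) {
  r4 <- function(x) if (is.na(x)) NA else round(x, 4)
  list(n = m@n, accuracy = r4(m@accuracy), precision = r4(m@precision),
       recall = r4(m@recall), specificity = r4(m@specificity),
       f_measure = r4(m@fMeasure), kappa = r4(m@kappa))
}
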