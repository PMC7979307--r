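#' Confusion counts at a decision threshold
#'
#' A sample is predicted positive iff its probability is greater than or
#' equal to the threshold (ties count positive). The four counts partition
#' the samples.
#'
#' @param labels 0/1 vector.
#' @param probabilities positive-class probabilities, same length.
#' @param threshold decision threshold in `[0, 1]`.
#' @return An object of class `confusion_counts`: list with `tp`, `fp`,
#'   `fn`, `tn` and `threshold`.
#' @export
#' @examples
#' confusion(c(1, 0), c(0.9, 0.1))
confusion <- function(labels, probabilities, threshold = 0.5) {
  if (length(labels) == 0) stop("empty input")
  if (length(labels) != length(probabilities)) stop("length mismatch")
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  if (any(!labels %in% c(0, 1))) stop("labels must be 0 or 1")
  pred <- probabilities >= threshold
  structure(list(tp = sum(pred & labels == 1), fp = sum(pred & labels == 0),
                 fn = sum(!pred & labels == 1), tn = sum(!pred & labels == 0),
                 threshold = threshold),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp=%d fp=%d fn=%d tn=%d (threshold %.3g)\n",
              x$tp, x$fp, x$fn, x$tn, x$threshold))
  invisible(x)
}

safe_ratio <- function(num, den) if (den == 0) NaN else num / den

#' Confusion-matrix statistics
#'
#' Computes accuracy, precision, recall (sensitivity / true-positive rate),
#' specificity, false-positive rate and the F1 score (harmonic mean of
#' precision and recall) from the four confusion counts. A statistic whose
#' denominator is zero is reported as `NaN` and listed in the `undefined`
#' field rather than silently coerced to zero, so degenerate evaluations
#' surface loudly.
#'
#' @param counts a [confusion()] result.
#' @param auc optional area under the ROC curve to carry in the report.
#' @return An object of class `metrics_report`.
#' @export
#' @examples
#' metrics(confusion(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1)))
metrics <- function(counts, auc = NULL) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$tp + counts$fp + counts$fn + counts$tn
  if (total < 1) stop("at least one sample required")
  accuracy <- (counts$tp + counts$tn) / total
  precision <- safe_ratio(counts$tp, counts$tp + counts$fp)
  recall <- safe_ratio(counts$tp, counts$tp + counts$fn)
  specificity <- safe_ratio(counts$tn, counts$tn + counts$fp)
  fpr <- safe_ratio(counts$fp, counts$fp + counts$tn)
  f1 <- if (is.nan(precision) || is.nan(recall) || precision + recall == 0) NaN
        else 2 * precision * recall / (precision + recall)
  vals <- c(accuracy = accuracy, precision = precision, recall = recall,
            specificity = specificity, fpr = fpr, f1 = f1)
  structure(list(accuracy = accuracy, precision = precision, recall = recall,
                 specificity = specificity, fpr = fpr, f1 = f1,
                 auc = auc, counts = counts, threshold = counts$threshold,
                 undefined = names(vals)[is.nan(vals)]),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  for (k in c("accuracy", "precision", "recall", "specificity", "fpr", "f1"))
    cat(sprintf("  %-12s %s\n", k,
                if (is.nan(x[[k]])) "undefined (zero denominator)"
                else sprintf("%.4f", x[[k]])))
  if (!is.null(x$auc)) cat(sprintf("  %-12s %.4f\n", "auc", x$auc))
  print(x$counts)
  invisible(x)
}

#' ROC curve and area under it
#'
#' Sweeps the decision threshold over every observed score, collects
#' (false-positive rate, true-positive rate) points, and integrates the
#' curve by the trapezoidal rule. The result equals the probability that a
#' randomly chosen positive is scored above a randomly chosen negative
#' (ties counting one half) — the Mann-Whitney reading of the AUC.
#'
#' @param labels 0/1 vector with both classes present.
#' @param probabilities scores (any monotone scale).
#' @return List with `auc` and `roc`, a `data.frame` of `threshold`, `fpr`,
#'   `tpr` points from (0,0) to (1,1).
#' @export
#' @examples
#' roc_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))$auc
roc_auc <- function(labels, probabilities) {
  if (length(labels) != length(probabilities)) stop("length mismatch")
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stop("both classes must be present")
  thr <- sort(unique(probabilities), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(probabilities >= t & labels == 1) / np, numeric(1))
  fpr <- vapply(thr, function(t) sum(probabilities >= t & labels == 0) / nn, numeric(1))
  fpr_all <- c(0, fpr); tpr_all <- c(0, tpr)
  if (utils::tail(fpr_all, 1) != 1 || utils::tail(tpr_all, 1) != 1) {
    fpr_all <- c(fpr_all, 1); tpr_all <- c(tpr_all, 1)
  }
  auc <- sum(diff(fpr_all) * (utils::head(tpr_all, -1) + utils::tail(tpr_all, -1)) / 2)
  list(auc = auc,
       roc = data.frame(threshold = c(Inf, thr, -Inf)[seq_along(fpr_all)],
                        fpr = fpr_all, tpr = tpr_all))
}
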