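# Classification metric suite: confusion-count metrics (accuracy, precision,
# recall/sensitivity, specificity, F1, MCC) and threshold-free curves
# (ROC/AUC by trapezoid, PR/AP by step-wise interpolation).

#' Confusion counts
#'
#' @param tp,tn,fp,fn Nonnegative integer counts.
#' @return An object of class `nf_confusion`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0, tp + tn + fp + fn > 0)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn), class = "nf_confusion")
}

# 0-by-convention ratio with a warning naming the degenerate metric.
safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning("degenerate denominator for ", what, "; returning 0 by convention",
            call. = FALSE)
    return(0)
  }
  num / den
}

#' Threshold metrics from confusion counts
#'
#' Exact closed forms: ACC = (TP+TN)/total, precision = TP/(TP+FP), recall =
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), F1 = harmonic mean of
#' precision and recall, and MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)
#' (TN+FP)(TN+FN)).  Degenerate denominators yield 0 with a warning.
#'
#' @param counts An [confusion_counts()] object or a list with tp/tn/fp/fn.
#' @return An `nf_metrics` list: acc, precision, recall, f1, sensitivity,
#'   specificity, mcc.
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  stopifnot(total > 0)
  acc <- (tp + tn) / total
  precision <- safe_ratio(tp, tp + fp, "precision")
  recall <- safe_ratio(tp, tp + fn, "sensitivity")
  specificity <- safe_ratio(tn, tn + fp, "specificity")
  f1 <- if (precision + recall == 0) {
    warning("degenerate denominator for F1; returning 0 by convention",
            call. = FALSE)
    0
  } else 2 * precision * recall / (precision + recall)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) {
    warning("degenerate denominator for MCC; returning 0 by convention",
            call. = FALSE)
    0
  } else (tp * tn - fp * fn) / mcc_den
  structure(list(acc = acc, precision = precision, recall = recall, f1 = f1,
                 sensitivity = recall, specificity = specificity, mcc = mcc),
            class = "nf_metrics")
}

#' ROC and precision-recall curves
#'
#' Threshold sweep over the unique scores (ties grouped at one threshold):
#' the ROC is integrated by trapezoids to give the AUC; the PR curve uses the
#' step-wise interpolation `AP = sum (R_i - R_{i-1}) P_i`.
#'
#' @param scores Positive-class scores, higher = more MCI-like.
#' @param labels 0/1, logical, or factor with the positive class last.
#' @return List with `roc` (fpr, tpr, threshold), `pr` (recall, precision),
#'   `auc`, `ap`.
#' @export
roc_pr <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  P <- sum(labels == 1); N <- sum(labels == 0)
  if (P == 0 || N == 0)
    stop("ROC/PR undefined: both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp <- cumsum(!duplicated(s))             # tie groups share a threshold
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(grp, fromLast = TRUE)
  tp <- tp[last]; fp <- fp[last]; thr <- s[last]
  tpr <- c(0, tp / P); fpr <- c(0, fp / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  prec <- tp / (tp + fp); rec <- tp / P
  ap <- sum(diff(c(0, rec)) * prec)
  list(roc = data.frame(fpr = fpr, tpr = tpr, threshold = c(Inf, thr)),
       pr = data.frame(recall = rec, precision = prec),
       auc = auc, ap = ap)
}

#' Metrics from scores and labels at a threshold
#'
#' @param scores Positive-class scores or probabilities.
#' @param labels True labels (0/1 or factor, positive class last).
#' @param threshold Decision threshold on the score (default 0.5).
#' @return An `nf_metrics` with `auc` and `ap` attached.
#' @export
score_metrics <- function(scores, labels, threshold = 0.5) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(labels))
  pred <- as.integer(scores >= threshold)
  met <- compute_metrics(confusion_counts(
    tp = sum(pred == 1 & labels == 1), tn = sum(pred == 0 & labels == 0),
    fp = sum(pred == 1 & labels == 0), fn = sum(pred == 0 & labels == 1)))
  if (length(unique(labels)) == 2) {
    cur <- roc_pr(scores, labels)
    met$auc <- cur$auc
    met$ap <- cur$ap
  }
  met
}
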