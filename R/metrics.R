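# Classification metrics. AUC uses the rank statistic (ties averaged); AP is
# the threshold-weighted mean of precision with recall increments as weights.

#' Area under the ROC curve by the rank statistic
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1).
#' @return AUC in `[0, 1]`; `NA` if only one class is present.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (as.numeric(n1) * n0)
}

#' Average precision (step-weighted mean of precision)
#'
#' `AP = sum_k (R_k - R_{k-1}) * P_k` over descending score thresholds,
#' where `P_k`/`R_k` are precision and recall at the k-th threshold.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1).
#' @return AP in `(0, 1]`; `NA` if no positive labels.
#' @export
ap_score <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  if (n1 == 0L || n1 == length(labels)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  # collapse tied scores to one threshold (the last index of each tie block)
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Evaluate prediction scores against binary labels
#'
#' Reports accuracy, F1 and Matthews correlation at the 0.5 threshold plus
#' threshold-free AUC ([auc_score()]) and AP ([ap_score()]).
#'
#' @param scores Numeric scores in `[0, 1]`.
#' @param labels Binary labels (0/1), same length.
#' @param threshold Classification threshold (default 0.5).
#' @return A `metric_report` list with `accuracy`, `f1`, `mcc`, `auc`, `ap`.
#' @export
evaluate <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels))
    stop("scores and labels differ in length")
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  acc <- (tp + tn) / length(labels)
  f1 <- if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  mcc_den <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
    sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
  mcc <- if (mcc_den == 0) NA_real_ else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / mcc_den
  structure(list(accuracy = acc, f1 = f1, mcc = mcc,
                 auc = auc_score(scores, labels),
                 ap = ap_score(scores, labels)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("accuracy %.3f | F1 %.3f | MCC %.3f | AUC %.3f | AP %.3f\n",
              x$accuracy, x$f1, x$mcc, x$auc, x$ap))
  invisible(x)
}
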