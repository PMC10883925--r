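# Confusion-matrix metrics: MCC, F1, accuracy, and cross-entropy helpers.
# The positive class is "stable" (label 1) throughout.

#' Build a confusion matrix from binary label vectors
#'
#' @param truth,pred integer vectors of labels in \{0, 1\}, equal length;
#'   the positive class is stable (1).
#' @return object of class `confusion_matrix`: named integer vector with
#'   elements `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_matrix <- function(truth, pred) {
  if (length(truth) != length(pred))
    stop_ns("truth and pred lengths differ (%d vs %d)", length(truth), length(pred))
  if (length(truth) == 0L) stop_ns("cannot build a confusion matrix from zero records")
  truth <- assert_flag01(truth, "truth")
  pred <- assert_flag01(pred, "pred")
  structure(c(TP = sum(truth == 1L & pred == 1L),
              FP = sum(truth == 0L & pred == 1L),
              TN = sum(truth == 0L & pred == 0L),
              FN = sum(truth == 1L & pred == 0L)),
            class = "confusion_matrix")
}

as_cm <- function(cm) {
  if (inherits(cm, "confusion_matrix")) return(cm)
  stopifnot(all(c("TP", "FP", "TN", "FN") %in% names(cm)))
  out <- as.integer(cm[c("TP", "FP", "TN", "FN")])
  names(out) <- c("TP", "FP", "TN", "FN")
  structure(out, class = "confusion_matrix")
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, in `[-1, 1]`.
#' When any factor of the denominator is zero the coefficient is undefined;
#' the conventional value 0 ("no correlation") is returned and the
#' degenerate case is logged.
#'
#' @param cm a [confusion_matrix()] (or named vector with TP/FP/TN/FN).
#' @return scalar in `[-1, 1]`.
#' @examples
#' mcc(confusion_matrix(c(1, 1, 0, 0), c(1, 1, 0, 0)))  # +1
#' @export
mcc <- function(cm) {
  cm <- as_cm(cm)
  tp <- as.numeric(cm[["TP"]]); fp <- as.numeric(cm[["FP"]])
  tn <- as.numeric(cm[["TN"]]); fn <- as.numeric(cm[["FN"]])
  if (tp + fp + tn + fn < 1) stop_ns("empty confusion matrix")
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom2 == 0) {
    log_msg("mcc: degenerate confusion matrix (a marginal is zero); returning 0")
    return(0)
  }
  (tp * tn - fp * fn) / sqrt(denom2)
}

#' F1 score and accuracy
#'
#' `F1 = 2TP / (2TP + FP + FN)` for the stable class (0 by convention when
#' the denominator vanishes); `accuracy = (TP + TN) / total`.  The macro
#' average additionally computes F1 of the unstable class and averages.
#'
#' @param cm a [confusion_matrix()].
#' @param average `"stable"` (default, the positive-class F1) or `"macro"`.
#' @return named numeric vector `c(f1 = , accuracy = )`.
#' @export
f1_accuracy <- function(cm, average = c("stable", "macro")) {
  average <- match.arg(average)
  cm <- as_cm(cm)
  tp <- as.numeric(cm[["TP"]]); fp <- as.numeric(cm[["FP"]])
  tn <- as.numeric(cm[["TN"]]); fn <- as.numeric(cm[["FN"]])
  total <- tp + fp + tn + fn
  if (total < 1) stop_ns("empty confusion matrix")
  f1_pos <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  f1 <- if (average == "stable") f1_pos else {
    f1_neg <- if (2 * tn + fp + fn == 0) 0 else 2 * tn / (2 * tn + fp + fn)
    (f1_pos + f1_neg) / 2
  }
  c(f1 = f1, accuracy = (tp + tn) / total)
}

# binary cross-entropy of predicted stable-class probabilities vs labels
binary_cross_entropy <- function(labels, p_stable, eps = 1e-12) {
  labels <- assert_flag01(labels)
  p <- pmin(pmax(p_stable, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}
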