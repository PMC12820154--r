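#' Binary confusion matrix
#'
#' Counts with pneumonia (label 1) as the positive class.
#'
#' @param y_true 0/1 vector of reference labels.
#' @param y_pred 0/1 vector of predicted labels.
#' @return object of class `confusion_matrix`: list with `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("length mismatch between labels and predictions", call. = FALSE)
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1)))
    stop("labels and predictions must be binary 0/1", call. = FALSE)
  confusion_matrix(tp = sum(y_true == 1 & y_pred == 1),
                   fp = sum(y_true == 0 & y_pred == 1),
                   tn = sum(y_true == 0 & y_pred == 0),
                   fn = sum(y_true == 1 & y_pred == 0))
}

#' @rdname confusion
#' @param tp,fp,tn,fn non-negative counts.
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be >= 0", call. = FALSE)
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion (positive = pneumonia): TP=%d FP=%d TN=%d FN=%d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

safe_ratio <- function(num, den) if (den == 0) 0 else num / den

#' Threshold-level classification metrics
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, and per-class precision, recall and F1
#' (harmonic mean of precision and recall). The positive class is
#' pneumonia; the normal-class metrics are the same formulas with the roles
#' of the classes swapped (normal precision = TN/(TN+FN), normal recall =
#' specificity = TN/(TN+FP)). Zero denominators yield 0 with a degeneracy
#' flag.
#'
#' @param cm a `confusion_matrix`.
#' @return object of class `metric_report`: list with `accuracy`,
#'   `pneumonia` and `normal` (each precision/recall/f1), `degenerate`
#'   (logical), and `percent` — every rate as a half-up-rounded two-decimal
#'   percentage.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$fp + cm$tn + cm$fn
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  degenerate <- FALSE
  prf <- function(tp, fp, fn) {
    if (tp + fp == 0 || tp + fn == 0) degenerate <<- TRUE
    precision <- safe_ratio(tp, tp + fp)
    recall <- safe_ratio(tp, tp + fn)
    f1 <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    list(precision = precision, recall = recall, f1 = f1)
  }
  pos <- prf(cm$tp, cm$fp, cm$fn)
  neg <- prf(cm$tn, cm$fn, cm$fp)   # swapped roles: TN plays TP
  acc <- (cm$tp + cm$tn) / total
  pct <- function(x) round_half_up(100 * x, 2)
  structure(list(
    accuracy = acc, pneumonia = pos, normal = neg, degenerate = degenerate,
    percent = list(accuracy = pct(acc),
                   pneumonia = lapply(pos, pct), normal = lapply(neg, pct))),
    class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  p <- x$percent
  cat(sprintf("accuracy %.2f%%\n", p$accuracy))
  cat(sprintf("pneumonia: recall %.2f%%  precision %.2f%%  F1 %.2f%%\n",
              p$pneumonia$recall, p$pneumonia$precision, p$pneumonia$f1))
  cat(sprintf("normal:    recall %.2f%%  precision %.2f%%  F1 %.2f%%\n",
              p$normal$recall, p$normal$precision, p$normal$f1))
  invisible(x)
}

check_both_classes <- function(labels) {
  if (length(unique(labels)) < 2)
    stop("undefined metric: both classes must be present", call. = FALSE)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC; tied positive/negative scores contribute
#' one half. Equivalent to the trapezoidal area under the empirical ROC.
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels 0/1 labels.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  check_both_classes(labels)
  r <- rank(scores)           # midranks handle ties
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision of the PR curve
#'
#' Step-wise sum of precision times recall increments over descending score
#' thresholds (ties processed as one block).
#'
#' @inheritParams roc_auc
#' @return AP in \[0, 1\].
#' @export
pr_average_precision <- function(scores, labels) {
  check_both_classes(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  n_pos <- sum(y == 1)
  ap <- 0; tp <- 0; fp <- 0; prev_recall <- 0
  i <- 1L
  n <- length(s)
  while (i <= n) {
    j <- i
    while (j < n && s[j + 1] == s[i]) j <- j + 1L
    tp <- tp + sum(y[i:j] == 1)
    fp <- fp + sum(y[i:j] == 0)
    recall <- tp / n_pos
    precision <- tp / (tp + fp)
    ap <- ap + precision * (recall - prev_recall)
    prev_recall <- recall
    i <- j + 1L
  }
  ap
}

#' Youden-J optimal decision threshold
#'
#' Scans all candidate cutoffs (each observed score, decision rule
#' `score >= cutoff` is positive) and returns the cutoff maximising
#' `J = sensitivity + specificity - 1`; ties are broken toward the higher
#' threshold.
#'
#' @inheritParams roc_auc
#' @return list with `threshold` and `J`.
#' @export
youden_threshold <- function(scores, labels) {
  check_both_classes(labels)
  cand <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  best <- NULL
  for (thr in cand) {
    pred <- as.integer(scores >= thr)
    sens <- sum(pred == 1 & labels == 1) / n1
    spec <- sum(pred == 0 & labels == 0) / n0
    J <- sens + spec - 1
    # strict improvement keeps the highest-threshold maximiser
    if (is.null(best) || J > best$J + 1e-12) best <- list(threshold = thr, J = J)
  }
  best
}

#' Full evaluation report from scores
#'
#' Combines argmax-free threshold analysis (AUC, AP, Youden threshold) with
#' the confusion-based metrics at a given operating threshold (default 0.5).
#'
#' @param scores positive-class probabilities.
#' @param labels 0/1 labels.
#' @param threshold operating cutoff for the confusion-based metrics.
#' @return `metric_report` augmented with `auc_roc`, `average_precision`,
#'   `optimal_threshold`, `youden_j`.
#' @export
metric_report <- function(scores, labels, threshold = 0.5) {
  cm <- confusion(labels, as.integer(scores >= threshold))
  rep <- classification_metrics(cm)
  rep$auc_roc <- roc_auc(scores, labels)
  rep$average_precision <- pr_average_precision(scores, labels)
  yj <- youden_threshold(scores, labels)
  rep$optimal_threshold <- yj$threshold
  rep$youden_j <- yj$J
  rep$confusion <- cm
  rep
}

#' Communication cost of one transmitted weight set
#'
#' Bytes are `param_count * bit_precision / 8`. The `"decimal_eq12"`
#' convention divides by 10^6 (megabytes in the decimal sense); the
#' `"binary_mib"` convention divides by 2^20 and is the one under which the
#' published per-round payloads (0.56 / 21.64) are reproduced;
#' `"bytes"` returns raw bytes.
#'
#' @param param_count number of transmitted parameters.
#' @param bit_precision bits per parameter (16, 32 or 64).
#' @param convention `"binary_mib"`, `"decimal_eq12"` or `"bytes"`.
#' @return numeric payload (unrounded; round to 2 decimals for display).
#' @export
communication_cost <- function(param_count, bit_precision = 32L,
                               convention = c("binary_mib", "decimal_eq12",
                                              "bytes")) {
  convention <- match.arg(convention)
  if (param_count < 0) stop("param_count must be >= 0", call. = FALSE)
  if (!bit_precision %in% c(16L, 32L, 64L))
    stop("bit_precision must be 16, 32 or 64", call. = FALSE)
  bytes <- param_count * bit_precision / 8
  switch(convention,
         bytes = bytes,
         decimal_eq12 = bytes / 1e6,
         binary_mib = bytes / 2^20)
}
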