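# Classifier evaluation: the seven confusion-matrix statistics, rank-based
# AUROC, step-integrated AUPRC, and the exact two-sided Fisher test used for
# motif enrichment.

#' Confusion counts
#'
#' @param TP,FP,TN,FN non-negative integer counts. TP/FN count
#'   splicing-affecting variants predicted affecting/neutral; FP/TN count
#'   neutral variants predicted affecting/neutral.
#' @return object of class `ConfusionCounts`.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  v <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(v < 0) || any(v != round(v))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  structure(as.list(v), class = "ConfusionCounts")
}

#' The seven confusion-matrix statistics
#'
#' Accuracy, precision (PPV), recall (sensitivity), specificity, F1, NPV and
#' the Matthews correlation coefficient, each computed by its textbook
#' formula. A statistic whose denominator is zero is reported as `NA`
#' (undefined), never as 0.
#'
#' @param counts a `ConfusionCounts` (or list with TP, FP, TN, FN).
#' @return named numeric vector of the seven statistics.
#' @export
compute_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  n <- TP + FP + TN + FN
  if (n == 0) stop("all-zero confusion counts", call. = FALSE)
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- div(TP, TP + FP)
  recall <- div(TP, TP + FN)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else 2 * precision * recall / (precision + recall)
  mcc_den <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  c(accuracy = div(TP + TN, n),
    precision = precision,
    recall = recall,
    specificity = div(TN, TN + FP),
    f1 = f1,
    npv = div(TN, TN + FN),
    mcc = if (mcc_den == 0) NA_real_ else (TP * TN - FP * FN) / mcc_den)
}

balanced_accuracy <- function(counts) {
  m <- compute_metrics(counts)
  (m[["recall"]] + m[["specificity"]]) / 2
}

check_two_classes <- function(labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) {
    stop("labels must be 0/1 (or logical)", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  labels
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC: the probability that a random positive
#' scores above a random negative, with ties counted one half.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels 0/1 or logical class labels (1 = positive).
#' @return numeric AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- check_two_classes(labels)
  r <- rank(scores, ties.method = "average")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# precision-recall points at every distinct-score threshold, descending
pr_points <- function(scores, labels) {
  labels <- check_two_classes(labels)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  tp <- cumsum(y); fp <- cumsum(1L - y)
  keep <- c(s[-1] != s[-length(s)], TRUE)  # last index of each score group
  data.frame(threshold = s[keep],
             recall = tp[keep] / sum(y),
             precision = tp[keep] / (tp[keep] + fp[keep]))
}

#' Area under the precision-recall curve
#'
#' Step integration of the precision-recall curve over descending score
#' thresholds: `sum (R_i - R_{i-1}) * P_i` across distinct-score groups.
#'
#' @inheritParams auroc
#' @return numeric AUPRC in \[0, 1\].
#' @export
auprc <- function(scores, labels) {
  pts <- pr_points(scores, labels)
  sum(diff(c(0, pts$recall)) * pts$precision)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact two-sided p-value obtained by summing hypergeometric probabilities
#' not exceeding that of the observed table (the classical two-sided
#' convention, as implemented by [stats::fisher.test()]).
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return the exact two-sided p-value.
#' @export
fisher_exact_two_sided <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L))) stop("need a 2x2 table", call. = FALSE)
  if (any(m < 0) || any(m != round(m))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("zero margin in contingency table", call. = FALSE)
  }
  stats::fisher.test(m)$p.value
}
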