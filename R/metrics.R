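#' Thresholded binary classification metrics
#'
#' Computes accuracy, precision, recall, F1 and the Matthews correlation
#' coefficient after thresholding scores (`score >= threshold` predicts the
#' positive class). Degenerate conventions: precision, recall and F1 are 0
#' when their denominator is 0, and MCC is 0 when any confusion-matrix
#' marginal is 0.
#'
#' Note the threshold convention differs from the ensemble voters:
#' metrics count a score exactly at the threshold as positive (`>=`), while
#' voters break an exact tie towards class 0.
#'
#' @param labels Integer vector of true labels in `{0, 1}`.
#' @param scores Numeric vector of positive-class scores.
#' @param threshold Decision threshold (default 0.5).
#' @return A one-row [tibble::tibble()] with columns `accuracy`,
#'   `precision`, `recall`, `f1`, `mcc` and the confusion counts `tp`,
#'   `fp`, `tn`, `fn`.
#' @examples
#' classification_metrics(c(1, 0, 1, 0), c(0.9, 0.2, 0.7, 0.6))
#' @export
classification_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores), length(labels) >= 1L,
            all(labels %in% 0:1))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else 0
  tibble::tibble(
    accuracy = (tp + tn) / length(labels),
    precision = precision, recall = recall, f1 = f1, mcc = mcc,
    tp = tp, fp = fp, tn = tn, fn = fn
  )
}

#' Area under the ROC curve
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, with ties counting one half (the Mann-Whitney form,
#' equal to the trapezoidal ROC area).
#'
#' @inheritParams classification_metrics
#' @return The AUROC in `[0, 1]`.
#' @examples
#' auroc(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.1))  # 0.75
#' @export
auroc <- function(labels, scores) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores), all(labels %in% 0:1))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("auroc requires both classes to be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise (average-precision) estimator: the sum over score thresholds of
#' the recall increment times the precision at that threshold. Step
#' interpolation is used rather than the trapezoid to avoid the optimistic
#' bias of linear PR interpolation.
#'
#' @inheritParams classification_metrics
#' @return The average precision in `(0, 1]`.
#' @examples
#' aupr(c(1, 0, 1), c(0.9, 0.5, 0.4))  # (1 + 2/3) / 2
#' @export
aupr <- function(labels, scores) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores), all(labels %in% 0:1))
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L) stop("aupr requires at least one positive", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  cum_tp <- cumsum(lab)
  cum_pred <- seq_along(lab)
  # evaluate precision/recall only at the last index of each tied score group
  last_of_group <- c(sc[-1] != sc[-length(sc)], TRUE)
  tp <- cum_tp[last_of_group]
  np <- cum_pred[last_of_group]
  prec <- tp / np
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Full evaluation report for binary predictions
#'
#' Combines the thresholded metrics with the ranking metrics AUROC and AUPR
#' into the seven-metric report used throughout the package.
#'
#' @inheritParams classification_metrics
#' @return A one-row tibble with `accuracy`, `auroc`, `recall`,
#'   `precision`, `f1`, `mcc`, `aupr` and `n`.
#' @export
evaluate_predictions <- function(labels, scores, threshold = 0.5) {
  cm <- classification_metrics(labels, scores, threshold)
  tibble::tibble(
    accuracy = cm$accuracy,
    auroc = auroc(labels, scores),
    recall = cm$recall,
    precision = cm$precision,
    f1 = cm$f1,
    mcc = cm$mcc,
    aupr = aupr(labels, scores),
    n = length(labels)
  )
}

#' ROC and precision-recall curve points
#'
#' @inheritParams classification_metrics
#' @return A tibble with columns `curve` ("roc" or "pr"), `x` and `y`
#'   (FPR/TPR for ROC, recall/precision for PR).
#' @export
curve_points <- function(labels, scores) {
  labels <- as.integer(labels)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  last_of_group <- c(sc[-1] != sc[-length(sc)], TRUE)
  tp <- cumsum(lab)[last_of_group]
  np <- seq_along(lab)[last_of_group]
  fp <- np - tp
  n1 <- sum(lab); n0 <- length(lab) - n1
  roc <- tibble::tibble(curve = "roc", x = c(0, fp / n0), y = c(0, tp / n1))
  pr <- tibble::tibble(curve = "pr", x = tp / n1, y = tp / np)
  dplyr::bind_rows(roc, pr)
}

#' Plot ROC and precision-recall curves
#'
#' @inheritParams classification_metrics
#' @return A [ggplot2::ggplot] object with one panel per curve.
#' @export
plot_curves <- function(labels, scores) {
  pts <- curve_points(labels, scores)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~curve, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
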