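# Binary-classification evaluation with "bacterium" as the positive class:
# confusion counts at a probability threshold, the four reported metrics,
# and the ROC curve / AUC by trapezoidal integration.

as_positive <- function(labels, positive) {
  if (is.factor(labels)) labels <- as.character(labels)
  labels == positive
}

#' Confusion counts at a threshold
#'
#' Probabilities are for the positive class (`"bacterium"` by convention);
#' a probability exactly at the threshold is classified positive.
#'
#' @param labels Character/factor vector of true classes.
#' @param probabilities Numeric vector of positive-class probabilities.
#' @param threshold Decision threshold, default 0.5.
#' @param positive Name of the positive class.
#' @return Tibble with one row: `tp`, `fp`, `tn`, `fn`, `threshold`.
#' @export
confusion <- function(labels, probabilities, threshold = 0.5,
                      positive = "bacterium") {
  stopifnot(length(labels) == length(probabilities))
  truth <- as_positive(labels, positive)
  pred <- probabilities >= threshold
  tibble::tibble(
    tp = sum(pred & truth), fp = sum(pred & !truth),
    tn = sum(!pred & !truth), fn = sum(!pred & truth),
    threshold = threshold
  )
}

# Trapezoidal ROC AUC over all score thresholds.
roc_auc <- function(labels, probabilities, positive = "bacterium") {
  rc <- roc_curve(labels, probabilities, positive = positive)
  sum(diff(rc$fpr) * (utils::head(rc$tpr, -1) + utils::tail(rc$tpr, -1)) / 2)
}

#' ROC curve
#'
#' True-positive rate against false-positive rate over all score
#' thresholds; both coordinates are monotone non-decreasing, starting at
#' (0, 0) and ending at (1, 1).
#'
#' @inheritParams confusion
#' @return Tibble with columns `threshold`, `fpr`, `tpr`, of class
#'   `map4np_roc` (so [ggplot2::autoplot()] works).
#' @export
roc_curve <- function(labels, probabilities, positive = "bacterium") {
  truth <- as_positive(labels, positive)
  np <- sum(truth); nn <- sum(!truth)
  if (np == 0 || nn == 0) {
    stop("ROC curve requires both classes present")
  }
  ord <- order(probabilities, decreasing = TRUE)
  truth <- truth[ord]
  prob <- probabilities[ord]
  keep <- c(diff(prob) != 0, TRUE)  # one point per distinct score
  tp <- cumsum(truth)[keep]
  fp <- cumsum(!truth)[keep]
  out <- tibble::tibble(
    threshold = c(Inf, prob[keep]),
    fpr = c(0, fp / nn),
    tpr = c(0, tp / np)
  )
  class(out) <- c("map4np_roc", class(out))
  out
}

#' The four reported metrics plus ROC AUC
#'
#' Standard definitions: precision `tp/(tp+fp)`, recall (TPR) `tp/(tp+fn)`,
#' TNR `tn/(tn+fp)`, `F1 = 2PR/(P+R)`, balanced accuracy `(TPR+TNR)/2`,
#' `MCC = (tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, and ROC
#' AUC by trapezoidal integration over all thresholds. A metric with a zero
#' denominator is reported as 0 and flagged in the `degenerate` column.
#'
#' @inheritParams confusion
#' @return One-row tibble: `roc_auc`, `f1`, `balanced_accuracy`, `mcc`,
#'   `threshold`, `degenerate`.
#' @export
metric_suite <- function(labels, probabilities, threshold = 0.5,
                         positive = "bacterium") {
  cc <- confusion(labels, probabilities, threshold, positive)
  tp <- cc$tp; fp <- cc$fp; tn <- cc$tn; fn <- cc$fn
  degenerate <- FALSE
  safe_div <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  tnr <- safe_div(tn, tn + fp)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  bacc <- (recall + tnr) / 2
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) { degenerate <- TRUE; 0 } else {
    (tp * tn - fp * fn) / mcc_den
  }
  auc <- roc_auc(labels, probabilities, positive)
  tibble::tibble(roc_auc = auc, f1 = f1, balanced_accuracy = bacc, mcc = mcc,
                 threshold = threshold, degenerate = degenerate)
}

#' @export
autoplot.map4np_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate") +
    ggplot2::theme_minimal()
}
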