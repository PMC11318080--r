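#' @include utils.R
NULL

#' Classification metrics on query scores
#'
#' `rocAuc` is the area under the ROC curve, computed as the normalized
#' Mann-Whitney U statistic (ties between a positive and a negative score
#' count 1/2). `prAuc` is the area under the precision-recall curve in its
#' average-precision form (precision at each recall step, tied scores
#' processed as one block). `f1Score` is the F1 of the positive class at the
#' 0.5 probability cutoff (a probability of exactly 0.5 predicts positive);
#' it is 0 when the positive class is never predicted or never present.
#'
#' @param scores numeric vector of scores/probabilities.
#' @param labels numeric vector of 0/1 labels.
#' @return scalar in `[0, 1]`.
#' @examples
#' rocAuc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))  # 1
#' @export
rocAuc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  nPos <- sum(labels == 1)
  nNeg <- sum(labels == 0)
  if (nPos == 0L || nNeg == 0L) {
    stop("ROC-AUC undefined: query set contains a single class")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' @rdname rocAuc
#' @export
prAuc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  nPos <- sum(labels == 1)
  if (nPos == 0L) stop("PR-AUC undefined: no positive labels")
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]
  s <- scores[o]
  # process tied-score blocks together
  n1 <- length(s)
  blockEnd <- c(which(s[-n1] != s[-1L]), n1)
  tp <- cumsum(y)[blockEnd]
  n <- blockEnd
  precision <- tp / n
  recall <- tp / nPos
  dRecall <- diff(c(0, recall))
  sum(precision * dRecall)
}

#' @rdname rocAuc
#' @export
f1Score <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  pred <- predictLabels(scores)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  if (2 * tp + fp + fn == 0L) return(0)
  2 * tp / (2 * tp + fp + fn)
}
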