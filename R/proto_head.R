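#' @include AllClasses.R utils.R
NULL

.PROTO_EPS <- 1e-8
.PROB_CLIP <- 1e-7

#' Distance-weighted class prototype
#'
#' Aggregates the K support representations of one class into a prototype by
#' an inverse-distance weighted sum: each support point's distance is the sum
#' of Euclidean distances to the other points of the class, its weight is the
#' reciprocal of that distance (regularized by epsilon = 1e-8), and weights
#' are normalized to sum to one. Points far from the rest of their class
#' therefore contribute less. With `weighted = FALSE` (the uniform-weight
#' study variant) the prototype reduces to the arithmetic mean. When every
#' distance is below epsilon (duplicate supports, K = 1) the weights are
#' uniform.
#'
#' @param support numeric matrix, K x d, of class support representations.
#' @param weighted logical; inverse-distance weights (default) or uniform.
#' @return list with `prototype` (length d), `weights` (length K, sums to 1)
#'   and `distances` (length K, the per-point distance sums).
#' @examples
#' computePrototype(rbind(c(0, 0), c(1, 0), c(0, 1)))
#' @export
computePrototype <- function(support, weighted = TRUE) {
  S <- as.matrix(support)
  K <- nrow(S)
  if (K < 1L) stop("empty support set")
  if (!all(is.finite(S))) stop("non-finite support representations")
  dm <- as.matrix(stats::dist(S))
  D <- unname(rowSums(dm))
  if (!weighted || all(D < .PROTO_EPS)) {
    a <- rep(1 / K, K)
  } else {
    w <- 1 / (D + .PROTO_EPS)
    a <- w / sum(w)
  }
  list(prototype = drop(crossprod(S, a)), weights = a, distances = D)
}

# Gradient of a scalar loss wrt the support matrix, given dL/dprototype.
# Backpropagates through both the weighted sum and (when active) the
# inverse-distance weights themselves.
prototypeBackward <- function(support, proto, dP, weighted = TRUE) {
  S <- as.matrix(support)
  K <- nrow(S)
  a <- proto$weights
  dS <- outer(a, dP)
  uniform <- !weighted || all(proto$distances < .PROTO_EPS)
  if (!uniform && K > 1L) {
    w <- 1 / (proto$distances + .PROTO_EPS)
    s <- drop(S %*% dP)                        # dL/da_i (pre-normalization)
    dw <- (s - sum(a * s)) / sum(w)
    g <- -(w^2) * dw                           # dL/dD_i
    for (i in seq_len(K - 1L)) {
      for (j in seq.int(i + 1L, K)) {
        diff <- S[i, ] - S[j, ]
        r <- sqrt(sum(diff^2))
        if (r > 1e-12) {
          u <- (g[i] + g[j]) * diff / r
          dS[i, ] <- dS[i, ] + u
          dS[j, ] <- dS[j, ] - u
        }
      }
    }
  }
  dS
}

#' Build positive and negative prototypes for an episode
#'
#' @param supportPos,supportNeg numeric matrices (K x d) of support
#'   representations with label 1 and 0.
#' @param weighted inverse-distance weights (default) or uniform.
#' @return list with elements `pos` and `neg`, each as returned by
#'   [computePrototype()].
#' @export
makePrototypes <- function(supportPos, supportNeg, weighted = TRUE) {
  list(pos = computePrototype(supportPos, weighted),
       neg = computePrototype(supportNeg, weighted))
}

#' Classify query representations against two prototypes
#'
#' Scores each query against the positive and negative prototype with
#' dot-product similarity (default) or negative squared Euclidean distance
#' (the L2 study variant), and converts the two similarities into the
#' positive-class probability by a two-way softmax:
#' `p = exp(s_pos) / (exp(s_pos) + exp(s_neg))`.
#'
#' @param z numeric vector (length d) or matrix (q x d) of query
#'   representations.
#' @param protos prototypes from [makePrototypes()].
#' @param similarity `"dot"` or `"neg_L2"`.
#' @return numeric vector of probabilities in (0, 1).
#' @export
classifyQuery <- function(z, protos, similarity = c("dot", "neg_L2")) {
  similarity <- match.arg(similarity)
  Z <- if (is.matrix(z)) z else matrix(z, 1L)
  pPos <- protos$pos$prototype
  pNeg <- protos$neg$prototype
  if (ncol(Z) != length(pPos)) {
    stop("query dimension ", ncol(Z), " does not match prototype dimension ",
         length(pPos))
  }
  if (similarity == "dot") {
    sPos <- drop(Z %*% pPos)
    sNeg <- drop(Z %*% pNeg)
  } else {
    sPos <- -rowSums(sweep(Z, 2L, pPos)^2)
    sNeg <- -rowSums(sweep(Z, 2L, pNeg)^2)
  }
  sigmoid(sPos - sNeg)
}

# Gradients of the mean episode loss wrt queries and both prototypes.
classifyBackward <- function(Z, protos, similarity, probs, labels) {
  q <- length(probs)
  dLogit <- (probs - labels) / q            # softmax cross-entropy shortcut
  pPos <- protos$pos$prototype
  pNeg <- protos$neg$prototype
  if (similarity == "dot") {
    dZ <- outer(dLogit, pPos - pNeg)
    dPPos <- drop(crossprod(Z, dLogit))
    dPNeg <- -dPPos
  } else {
    # sPos - sNeg = -|z-p+|^2 + |z-p-|^2
    diffPos <- sweep(Z, 2L, pPos)
    diffNeg <- sweep(Z, 2L, pNeg)
    dZ <- dLogit * (-2 * diffPos + 2 * diffNeg)
    dPPos <- drop(crossprod(diffPos, 2 * dLogit))
    dPNeg <- drop(crossprod(diffNeg, -2 * dLogit))
  }
  list(dZ = dZ, dPPos = dPPos, dPNeg = dPNeg)
}

#' Episodic cross-entropy loss
#'
#' Mean binary cross-entropy over the query set. Probabilities are clipped to
#' `[1e-7, 1 - 1e-7]` before taking logs, so a perfect prediction yields the
#' clip-floor loss rather than 0 and a maximally wrong one stays finite.
#'
#' @param probs numeric vector of positive-class probabilities.
#' @param labels numeric vector of 0/1 labels, same length.
#' @return scalar loss.
#' @examples
#' episodeLoss(c(0.5, 0.5), c(1, 0))  # log(2)
#' @export
episodeLoss <- function(probs, labels) {
  if (length(probs) != length(labels)) {
    stop("probs (", length(probs), ") and labels (", length(labels),
         ") differ in length")
  }
  stopifnot(all(labels %in% c(0, 1)))
  p <- pmin(pmax(probs, .PROB_CLIP), 1 - .PROB_CLIP)
  mean(-(labels * log(p) + (1 - labels) * log(1 - p)))
}

#' Predicted labels at the 0.5 threshold
#'
#' @param probs numeric vector of probabilities.
#' @return integer vector of 0/1 labels; a probability of exactly 0.5
#'   predicts positive.
#' @export
predictLabels <- function(probs) as.integer(probs >= 0.5)
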