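#' @include AllClasses.R utils.R chem_data.R
NULL

# Categorical feature vocabularies (see methods vignette): atomic number
# 1..118, chirality tag 0..3, bond type 0..3, bond direction 0..2.
.VOCAB <- list(z = 118L, chir = 4L, bt = 4L, bd = 3L)

#' Encoder configuration
#'
#' Configuration of the graph molecular encoder: a five-layer graph attention
#' network with 100-dimensional node embeddings by default, with GCN, GIN and
#' GraphSAGE as pluggable variants. Edge features (bond type/direction) enter
#' GAT and GIN as additive edge embeddings in message computation; GCN and
#' GraphSAGE ignore them. ReLU is applied between layers (not after the
#' last); attention uses a single head.
#'
#' @param arch one of `"GAT"`, `"GCN"`, `"GIN"`, `"GraphSAGE"`.
#' @param nLayers number of message-passing layers (default 5).
#' @param hiddenDim node embedding width d^g (default 100).
#' @param dropout dropout fraction on node features between layers during
#'   training (default 0).
#' @param pretrainedPath optional checkpoint file to initialize from.
#' @return A config list.
#' @export
encoderConfig <- function(arch = c("GAT", "GCN", "GIN", "GraphSAGE"),
                          nLayers = 5L, hiddenDim = 100L, dropout = 0,
                          pretrainedPath = NULL) {
  arch <- match.arg(arch)
  stopifnot(nLayers >= 1L, hiddenDim >= 1L, dropout >= 0, dropout < 1)
  list(arch = arch, nLayers = as.integer(nLayers),
       hiddenDim = as.integer(hiddenDim), dropout = dropout,
       pretrainedPath = pretrainedPath)
}

glorot <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
}

initLayerParams <- function(arch, d) {
  switch(arch,
    GAT = list(W = glorot(d, d), b = numeric(d),
               aSelf = stats::rnorm(d, sd = 0.1),
               aNbr = stats::rnorm(d, sd = 0.1),
               btEmb = matrix(stats::rnorm(4 * d, sd = 0.1), 4, d),
               bdEmb = matrix(stats::rnorm(3 * d, sd = 0.1), 3, d)),
    GCN = list(W = glorot(d, d), b = numeric(d)),
    GIN = list(eps = 0,
               W1 = glorot(d, d), b1 = numeric(d),
               W2 = glorot(d, d), b2 = numeric(d),
               btEmb = matrix(stats::rnorm(4 * d, sd = 0.1), 4, d),
               bdEmb = matrix(stats::rnorm(3 * d, sd = 0.1), 3, d)),
    GraphSAGE = list(Wself = glorot(d, d), Wnbr = glorot(d, d),
                     b = numeric(d)))
}

# Encoder parameters: atom-feature embedding tables plus per-layer weights.
initEncoderParams <- function(cfg) {
  d <- cfg$hiddenDim
  list(atomZ = matrix(stats::rnorm(.VOCAB$z * d, sd = 0.1), .VOCAB$z, d),
       atomChir = matrix(stats::rnorm(.VOCAB$chir * d, sd = 0.1),
                         .VOCAB$chir, d),
       layers = lapply(seq_len(cfg$nLayers),
                       function(i) initLayerParams(cfg$arch, d)))
}

checkVocab <- function(batch) {
  if (any(batch$z < 1L) || any(batch$z > .VOCAB$z))
    stop("atomic number outside embedding vocabulary (1..118)")
  if (any(batch$chir < 0L) || any(batch$chir >= .VOCAB$chir))
    stop("chirality tag outside embedding vocabulary (0..3)")
  if (length(batch$bt)) {
    if (any(batch$bt < 0L) || any(batch$bt >= .VOCAB$bt))
      stop("bond type outside embedding vocabulary (0..3)")
    if (any(batch$bd < 0L) || any(batch$bd >= .VOCAB$bd))
      stop("bond direction outside embedding vocabulary (0..2)")
  }
  invisible(TRUE)
}

# ---- per-layer forward/backward ------------------------------------------

.LRELU_SLOPE <- 0.2

layerForwardGAT <- function(lp, H, batch, act) {
  n <- nrow(H); E <- length(batch$src)
  HW <- H %*% lp$W
  tDst <- drop(HW %*% lp$aSelf)
  tSelfMsg <- drop(HW %*% lp$aNbr)
  sSelfPre <- tDst + tSelfMsg
  if (E > 0L) {
    M <- HW[batch$src, , drop = FALSE] +
      lp$btEmb[batch$bt + 1L, , drop = FALSE] +
      lp$bdEmb[batch$bd + 1L, , drop = FALSE]
    tMsg <- drop(M %*% lp$aNbr)
    sEdgePre <- tDst[batch$dst] + tMsg
    sEdge <- ifelse(sEdgePre > 0, sEdgePre, .LRELU_SLOPE * sEdgePre)
  } else {
    M <- matrix(0, 0L, ncol(H)); sEdgePre <- numeric(0); sEdge <- numeric(0)
  }
  sSelf <- ifelse(sSelfPre > 0, sSelfPre, .LRELU_SLOPE * sSelfPre)
  mx <- pmax(if (E > 0L) groupMax(sEdge, batch$dst, n) else rep(-Inf, n),
             sSelf)
  eSelf <- exp(sSelf - mx)
  if (E > 0L) {
    eEdge <- exp(sEdge - mx[batch$dst])
    Zv <- drop(groupSum(cbind(eEdge), batch$dst, n)) + eSelf
    alphaE <- eEdge / Zv[batch$dst]
  } else {
    Zv <- eSelf; alphaE <- numeric(0)
  }
  alphaS <- eSelf / Zv
  pre <- sweep(alphaS * HW, 2L, lp$b, "+")
  if (E > 0L) pre <- pre + groupSum(alphaE * M, batch$dst, n)
  out <- if (act) relu(pre) else pre
  list(out = out,
       cache = list(H = H, HW = HW, M = M, alphaE = alphaE, alphaS = alphaS,
                    sEdgePre = sEdgePre, sSelfPre = sSelfPre, pre = pre,
                    act = act))
}

layerBackwardGAT <- function(lp, batch, cache, dOut) {
  n <- nrow(cache$H); E <- length(batch$src)
  dPre <- if (cache$act) dOut * (cache$pre > 0) else dOut
  db <- colSums(dPre)
  HW <- cache$HW; M <- cache$M
  alphaE <- cache$alphaE; alphaS <- cache$alphaS
  # out_v = sum_e alphaE M_e + alphaS HW_v + b
  dAlphaS <- rowSums(dPre * HW)
  dHW <- alphaS * dPre
  if (E > 0L) {
    dPreDst <- dPre[batch$dst, , drop = FALSE]
    dAlphaE <- rowSums(dPreDst * M)
    dM <- alphaE * dPreDst
    Sv <- drop(groupSum(cbind(alphaE * dAlphaE), batch$dst, n)) +
      alphaS * dAlphaS
    dSEdge <- alphaE * (dAlphaE - Sv[batch$dst])
    dSEdgePre <- dSEdge * ifelse(cache$sEdgePre > 0, 1, .LRELU_SLOPE)
  } else {
    dM <- matrix(0, 0L, ncol(HW)); Sv <- alphaS * dAlphaS
    dSEdgePre <- numeric(0)
  }
  dSSelf <- alphaS * (dAlphaS - Sv)
  dSSelfPre <- dSSelf * ifelse(cache$sSelfPre > 0, 1, .LRELU_SLOPE)
  # sEdgePre = tDst[dst] + <aNbr, M_e>; sSelfPre = tDst + <aNbr, HW>
  dTDst <- dSSelfPre
  if (E > 0L) {
    dTDst <- dTDst + drop(groupSum(cbind(dSEdgePre), batch$dst, n))
    dANbr <- colSums(M * dSEdgePre) + colSums(HW * dSSelfPre)
    dM <- dM + outer(dSEdgePre, lp$aNbr)
  } else {
    dANbr <- colSums(HW * dSSelfPre)
  }
  dASelf <- colSums(HW * dTDst)
  dHW <- dHW + outer(dTDst, lp$aSelf) + outer(dSSelfPre, lp$aNbr)
  if (E > 0L) {
    dHW <- dHW + groupSum(dM, batch$src, n)
    dBt <- groupSum(dM, batch$bt + 1L, 4L)
    dBd <- groupSum(dM, batch$bd + 1L, 3L)
  } else {
    dBt <- matrix(0, 4L, ncol(HW)); dBd <- matrix(0, 3L, ncol(HW))
  }
  dW <- crossprod(cache$H, dHW)
  dH <- dHW %*% t(lp$W)
  list(dH = dH, grads = list(W = dW, b = db, aSelf = dASelf, aNbr = dANbr,
                             btEmb = dBt, bdEmb = dBd))
}

gcnCoefs <- function(batch) {
  n <- batch$nNodes
  indeg <- tabulate(batch$dst, nbins = n) + 1   # self loop
  coefE <- if (length(batch$src)) {
    1 / sqrt(indeg[batch$src] * indeg[batch$dst])
  } else numeric(0)
  list(coefE = coefE, coefSelf = 1 / indeg)
}

layerForwardGCN <- function(lp, H, batch, act, coefs) {
  n <- nrow(H)
  HW <- H %*% lp$W
  pre <- coefs$coefSelf * HW
  if (length(batch$src)) {
    pre <- pre + groupSum(coefs$coefE * HW[batch$src, , drop = FALSE],
                          batch$dst, n)
  }
  pre <- sweep(pre, 2L, lp$b, "+")
  out <- if (act) relu(pre) else pre
  list(out = out, cache = list(H = H, HW = HW, pre = pre, act = act,
                               coefs = coefs))
}

layerBackwardGCN <- function(lp, batch, cache, dOut) {
  n <- nrow(cache$H)
  dPre <- if (cache$act) dOut * (cache$pre > 0) else dOut
  db <- colSums(dPre)
  dHW <- cache$coefs$coefSelf * dPre
  if (length(batch$src)) {
    dHW <- dHW + groupSum(cache$coefs$coefE *
                            dPre[batch$dst, , drop = FALSE], batch$src, n)
  }
  list(dH = dHW %*% t(lp$W),
       grads = list(W = crossprod(cache$H, dHW), b = db))
}

layerForwardGIN <- function(lp, H, batch, act) {
  n <- nrow(H)
  agg <- (1 + lp$eps) * H
  if (length(batch$src)) {
    msgPre <- H[batch$src, , drop = FALSE] +
      lp$btEmb[batch$bt + 1L, , drop = FALSE] +
      lp$bdEmb[batch$bd + 1L, , drop = FALSE]
    msg <- relu(msgPre)
    agg <- agg + groupSum(msg, batch$dst, n)
  } else {
    msgPre <- matrix(0, 0L, ncol(H))
  }
  h1 <- sweep(agg %*% lp$W1, 2L, lp$b1, "+")
  a1 <- relu(h1)
  pre <- sweep(a1 %*% lp$W2, 2L, lp$b2, "+")
  out <- if (act) relu(pre) else pre
  list(out = out, cache = list(H = H, msgPre = msgPre, agg = agg, h1 = h1,
                               a1 = a1, pre = pre, act = act))
}

layerBackwardGIN <- function(lp, batch, cache, dOut) {
  n <- nrow(cache$H)
  dPre <- if (cache$act) dOut * (cache$pre > 0) else dOut
  db2 <- colSums(dPre)
  dW2 <- crossprod(cache$a1, dPre)
  dA1 <- dPre %*% t(lp$W2)
  dH1 <- dA1 * (cache$h1 > 0)
  db1 <- colSums(dH1)
  dW1 <- crossprod(cache$agg, dH1)
  dAgg <- dH1 %*% t(lp$W1)
  dEps <- sum(dAgg * cache$H)
  dH <- (1 + lp$eps) * dAgg
  if (length(batch$src)) {
    dMsg <- dAgg[batch$dst, , drop = FALSE] * (cache$msgPre > 0)
    dH <- dH + groupSum(dMsg, batch$src, n)
    dBt <- groupSum(dMsg, batch$bt + 1L, 4L)
    dBd <- groupSum(dMsg, batch$bd + 1L, 3L)
  } else {
    dBt <- matrix(0, 4L, ncol(cache$H)); dBd <- matrix(0, 3L, ncol(cache$H))
  }
  list(dH = dH, grads = list(eps = dEps, W1 = dW1, b1 = db1, W2 = dW2,
                             b2 = db2, btEmb = dBt, bdEmb = dBd))
}

layerForwardSAGE <- function(lp, H, batch, act) {
  n <- nrow(H)
  indeg <- pmax(tabulate(batch$dst, nbins = n), 1)
  nbrMean <- if (length(batch$src)) {
    groupSum(H[batch$src, , drop = FALSE], batch$dst, n) / indeg
  } else matrix(0, n, ncol(H))
  pre <- sweep(H %*% lp$Wself + nbrMean %*% lp$Wnbr, 2L, lp$b, "+")
  out <- if (act) relu(pre) else pre
  list(out = out, cache = list(H = H, nbrMean = nbrMean, indeg = indeg,
                               pre = pre, act = act))
}

layerBackwardSAGE <- function(lp, batch, cache, dOut) {
  n <- nrow(cache$H)
  dPre <- if (cache$act) dOut * (cache$pre > 0) else dOut
  db <- colSums(dPre)
  dWself <- crossprod(cache$H, dPre)
  dWnbr <- crossprod(cache$nbrMean, dPre)
  dH <- dPre %*% t(lp$Wself)
  if (length(batch$src)) {
    dMean <- dPre %*% t(lp$Wnbr)
    dH <- dH + groupSum(dMean[batch$dst, , drop = FALSE] /
                          cache$indeg[batch$dst], batch$src, n)
  }
  list(dH = dH, grads = list(Wself = dWself, Wnbr = dWnbr, b = db))
}

# ---- full encoder ---------------------------------------------------------

encoderForward <- function(params, batch, cfg, training = FALSE) {
  checkVocab(batch)
  H <- params$atomZ[batch$z, , drop = FALSE] +
    params$atomChir[batch$chir + 1L, , drop = FALSE]
  caches <- vector("list", cfg$nLayers)
  dropMasks <- vector("list", cfg$nLayers)
  coefs <- if (cfg$arch == "GCN") gcnCoefs(batch) else NULL
  for (l in seq_len(cfg$nLayers)) {
    act <- l < cfg$nLayers
    lp <- params$layers[[l]]
    fw <- switch(cfg$arch,
      GAT = layerForwardGAT(lp, H, batch, act),
      GCN = layerForwardGCN(lp, H, batch, act, coefs),
      GIN = layerForwardGIN(lp, H, batch, act),
      GraphSAGE = layerForwardSAGE(lp, H, batch, act))
    caches[[l]] <- fw$cache
    H <- fw$out
    if (training && cfg$dropout > 0 && l < cfg$nLayers) {
      mask <- matrix(stats::rbinom(length(H), 1L, 1 - cfg$dropout),
                     nrow(H)) / (1 - cfg$dropout)
      H <- H * mask
      dropMasks[[l]] <- mask
    }
  }
  list(H = H, caches = caches, dropMasks = dropMasks)
}

encoderBackward <- function(params, batch, cfg, fw, dH) {
  grads <- list(atomZ = matrix(0, .VOCAB$z, cfg$hiddenDim),
                atomChir = matrix(0, .VOCAB$chir, cfg$hiddenDim),
                layers = vector("list", cfg$nLayers))
  for (l in rev(seq_len(cfg$nLayers))) {
    if (!is.null(fw$dropMasks[[l]])) dH <- dH * fw$dropMasks[[l]]
    lp <- params$layers[[l]]
    bw <- switch(cfg$arch,
      GAT = layerBackwardGAT(lp, batch, fw$caches[[l]], dH),
      GCN = layerBackwardGCN(lp, batch, fw$caches[[l]], dH),
      GIN = layerBackwardGIN(lp, batch, fw$caches[[l]], dH),
      GraphSAGE = layerBackwardSAGE(lp, batch, fw$caches[[l]], dH))
    grads$layers[[l]] <- bw$grads
    dH <- bw$dH
  }
  grads$atomZ <- groupSum(dH, batch$z, .VOCAB$z)
  grads$atomChir <- groupSum(dH, batch$chir + 1L, .VOCAB$chir)
  grads
}

#' Encode a molecular graph to node embeddings
#'
#' Runs the configured graph encoder over one molecule, returning the N x d^g
#' matrix of node embeddings (N = heavy-atom count). Deterministic given the
#' parameters and graph; permutation-equivariant in the atom order.
#'
#' @param graph a [MolecularGraph-class].
#' @param cfg an [encoderConfig()] list.
#' @param params encoder parameters (from [initAPNParams()] or a checkpoint).
#' @return numeric matrix, N x `cfg$hiddenDim`.
#' @export
encodeGraph <- function(graph, cfg, params) {
  batch <- batchGraphs(list(graph))
  encoderForward(params, batch, cfg)$H
}
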