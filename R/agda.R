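#' @include AllClasses.R utils.R
NULL

#' Initialize AGDA parameters
#'
#' The attribute-guided dual-channel attention module has two single affine
#' layers: `local` maps the concatenation of a node embedding and the
#' attribute vector, `[g_j; a]`, to a d^g-dimensional sigmoid gate over that
#' node; `global` does the same for the molecule-level mean representation.
#'
#' @param dg node embedding dimension d^g.
#' @param da attribute dimension d^a.
#' @param zero logical; initialize all weights and biases at zero (gates of
#'   exactly 0.5, useful for contract checks).
#' @return list with elements `Wl` ((d^g+d^a) x d^g), `bl`, `Wg`, `bg`.
#' @export
agdaParams <- function(dg, da, zero = FALSE) {
  init <- function(nin, nout) {
    if (zero) matrix(0, nin, nout) else glorot(nin, nout)
  }
  list(Wl = init(dg + da, dg), bl = numeric(dg),
       Wg = init(dg + da, dg), bg = numeric(dg))
}

#' Attribute-guided local attention
#'
#' Computes a per-node sigmoid gate from the concatenation of each node
#' embedding with the molecule's attribute vector, and applies it
#' elementwise: `Attn = sigmoid(f_local([g_j; a]))`, `G' = Attn * G`.
#' The same attribute vector is broadcast to every node row.
#'
#' @param G numeric matrix of node embeddings, N x d^g.
#' @param a numeric attribute vector, length d^a.
#' @param params AGDA parameters from [agdaParams()].
#' @return list with `attn` (N x d^g, entries strictly in (0,1)) and `out`
#'   (N x d^g refined embeddings).
#' @export
localAttention <- function(G, a, params) {
  G <- as.matrix(G)
  if (length(a) + ncol(G) != nrow(params$Wl)) {
    stop("attribute length ", length(a), " incompatible with AGDA params (",
         nrow(params$Wl) - ncol(G), " expected)")
  }
  inp <- cbind(G, matrix(a, nrow(G), length(a), byrow = TRUE))
  attn <- sigmoid(sweep(inp %*% params$Wl, 2L, params$bl, "+"))
  list(attn = attn, out = attn * G)
}

#' Attribute-guided global attention
#'
#' Mean-pools the (locally refined) node embeddings into a molecule-level
#' representation `g = mean_j g'_j`, then gates it with a sigmoid computed
#' from `[g; a]`: `z' = sigmoid(f_global([g; a])) * g`.
#'
#' @param Gl numeric matrix of node embeddings (typically the output of
#'   [localAttention()]), N x d^g, N >= 1.
#' @param a numeric attribute vector, length d^a.
#' @param params AGDA parameters from [agdaParams()].
#' @return list with `gMean` (length d^g), `attn` (gate, length d^g) and `z`
#'   (final representation, length d^g).
#' @export
globalAttention <- function(Gl, a, params) {
  Gl <- as.matrix(Gl)
  if (nrow(Gl) < 1L) stop("global attention needs at least one node")
  gMean <- colMeans(Gl)
  inp <- c(gMean, a)
  if (length(inp) != nrow(params$Wg)) {
    stop("attribute length ", length(a), " incompatible with AGDA params")
  }
  attn <- drop(sigmoid(inp %*% params$Wg + params$bg))
  list(gMean = gMean, attn = attn, z = attn * gMean)
}

#' Full AGDA forward pass for one molecule
#'
#' Composes local and global attribute-guided attention into the final
#' molecule representation z'. Ablations: `"no_local"` skips the node-level
#' gate (`g'_j = g_j`); `"no_global"` returns the mean of the locally refined
#' nodes without the molecule-level gate. (To bypass both, use the encoder
#' mean directly rather than this function.)
#'
#' @param G numeric matrix of node embeddings, N x d^g.
#' @param a numeric attribute vector.
#' @param params AGDA parameters from [agdaParams()].
#' @param ablation `"full"`, `"no_local"` or `"no_global"`.
#' @return numeric vector z' of length d^g.
#' @export
agdaForward <- function(G, a, params,
                        ablation = c("full", "no_local", "no_global")) {
  ablation <- match.arg(ablation)
  Gl <- if (ablation == "no_local") as.matrix(G) else
    localAttention(G, a, params)$out
  if (ablation == "no_global") return(colMeans(Gl))
  globalAttention(Gl, a, params)$z
}

# ---- batched AGDA for training -------------------------------------------
# H: nNodes x dg node embeddings for a whole episode batch; A: nMol x da
# attribute rows; mol: node -> molecule membership. Ablation flags noLocal /
# noGlobal / noAttr mirror the w/o L, w/o G and w/o A study variants; with
# noAttr the output is the plain mean of encoder node embeddings.
agdaBatchForward <- function(params, H, A, mol, nMol, noLocal = FALSE,
                             noGlobal = FALSE, noAttr = FALSE) {
  counts <- tabulate(mol, nbins = nMol)
  if (noAttr) {
    M <- groupSum(H, mol, nMol) / counts
    return(list(Z = M, counts = counts, noAttr = TRUE))
  }
  Arow <- A[mol, , drop = FALSE]
  if (noLocal) {
    Hp <- H; gateL <- NULL; inpL <- NULL
  } else {
    inpL <- cbind(H, Arow)
    gateL <- sigmoid(sweep(inpL %*% params$Wl, 2L, params$bl, "+"))
    Hp <- gateL * H
  }
  M <- groupSum(Hp, mol, nMol) / counts
  if (noGlobal) {
    return(list(Z = M, counts = counts, gateL = gateL, inpL = inpL, H = H,
                M = M, noLocal = noLocal, noGlobal = TRUE, noAttr = FALSE))
  }
  inpG <- cbind(M, A)
  gateG <- sigmoid(sweep(inpG %*% params$Wg, 2L, params$bg, "+"))
  list(Z = gateG * M, counts = counts, gateL = gateL, inpL = inpL, H = H,
       M = M, inpG = inpG, gateG = gateG, noLocal = noLocal,
       noGlobal = FALSE, noAttr = FALSE)
}

agdaBatchBackward <- function(params, fw, mol, nMol, dZ, dg) {
  zero <- list(Wl = matrix(0, nrow(params$Wl), ncol(params$Wl)),
               bl = numeric(ncol(params$Wl)),
               Wg = matrix(0, nrow(params$Wg), ncol(params$Wg)),
               bg = numeric(ncol(params$Wg)))
  if (isTRUE(fw$noAttr)) {
    dH <- dZ[mol, , drop = FALSE] / fw$counts[mol]
    return(list(dH = dH, grads = zero))
  }
  grads <- zero
  if (isTRUE(fw$noGlobal)) {
    dM <- dZ
  } else {
    dGateG <- dZ * fw$M
    dM <- dZ * fw$gateG
    dSg <- dGateG * fw$gateG * (1 - fw$gateG)
    grads$Wg <- crossprod(fw$inpG, dSg)
    grads$bg <- colSums(dSg)
    dInpG <- dSg %*% t(params$Wg)
    dM <- dM + dInpG[, seq_len(dg), drop = FALSE]
  }
  dHp <- dM[mol, , drop = FALSE] / fw$counts[mol]
  if (isTRUE(fw$noLocal)) {
    dH <- dHp
  } else {
    dGateL <- dHp * fw$H
    dH <- dHp * fw$gateL
    dSl <- dGateL * fw$gateL * (1 - fw$gateL)
    grads$Wl <- crossprod(fw$inpL, dSl)
    grads$bl <- colSums(dSl)
    dInpL <- dSl %*% t(params$Wl)
    dH <- dH + dInpL[, seq_len(dg), drop = FALSE]
  }
  list(dH = dH, grads = grads)
}
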