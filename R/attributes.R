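#' @include AllClasses.R utils.R backend.R chem_data.R
NULL

.FP_REGISTRY <- data.frame(
  kind = c("ECFP0", "ECFP2", "ECFP4", "ECFP6", "FCFP2", "FCFP4", "FCFP6",
           "RDK5", "RDK6", "RDK7", "HashAP", "HashTT", "MACCS", "Avalon"),
  type = c(rep("circular", 7), rep("path", 5), rep("substructure", 2)),
  dim = c(rep(1024L, 12), 167L, 1024L),
  stringsAsFactors = FALSE)

#' The fingerprint registry
#'
#' The 14 fingerprint families used for attribute extraction: seven circular
#' (ECFP0/2/4/6, FCFP2/4/6; the trailing digit is the diameter, so ECFP4 has
#' Morgan radius 2), five path-based (RDK5/6/7 with maximum path lengths
#' 5/6/7, hashed atom pairs, hashed topological torsions) and two
#' substructure-based (MACCS keys, Avalon). All are folded to 1024 bits
#' except MACCS (167). An optional 15th kind, `"rdkDes"` (a standardized 2D
#' physicochemical descriptor panel), is available to [computeFingerprints()]
#' but excluded from this default registry.
#'
#' @return data.frame with columns `kind`, `type`, `dim`.
#' @examples
#' fingerprintKinds()
#' @export
fingerprintKinds <- function() .FP_REGISTRY

#' Compute molecular fingerprints
#'
#' Generates one fingerprint matrix per requested kind via the RDKit backend.
#' Bit fingerprints are returned as dense 0/1 matrices with the registry
#' dimension; `"rdkDes"` returns a real-valued descriptor matrix.
#'
#' @param smiles character vector of (valid) SMILES.
#' @param kinds character vector of registry kinds (see [fingerprintKinds()]),
#'   optionally including `"rdkDes"`.
#' @return Named list of numeric matrices, one per kind, rows parallel to
#'   `smiles`.
#' @examples
#' \dontrun{
#' fps <- computeFingerprints(c("CCO", "c1ccccc1"), c("MACCS", "ECFP4"))
#' dim(fps$MACCS)   # 2 x 167
#' }
#' @export
computeFingerprints <- function(smiles, kinds) {
  known <- c(.FP_REGISTRY$kind, "rdkDes")
  bad <- setdiff(kinds, known)
  if (length(bad)) {
    stop("unknown fingerprint kind(s): ", paste(bad, collapse = ", "),
         "; valid kinds: ", paste(known, collapse = ", "))
  }
  res <- rdkitBackend(smiles, fingerprints = kinds)
  if (!all(res$ok)) {
    stop("invalid SMILES: '", smiles[which(!res$ok)[1L]], "'")
  }
  out <- lapply(kinds, function(kind) {
    per <- res$fingerprints[[kind]]
    if (kind == "rdkDes") {
      m <- do.call(rbind, per)
    } else {
      d <- .FP_REGISTRY$dim[.FP_REGISTRY$kind == kind]
      m <- matrix(0, length(per), d)
      for (i in seq_along(per)) m[i, per[[i]] + 1] <- 1
    }
    m
  })
  names(out) <- kinds
  out
}

#' Fit a PCA reducer for one fingerprint family
#'
#' Centers the fingerprint matrix and fits a deterministic SVD-based PCA with
#' `min(targetDim, n - 1, ncol)` components. The sign of each component is
#' fixed by making its largest-magnitude loading positive, so the projection
#' is bit-reproducible and independent of any random number stream. When
#' fewer than `targetDim` components exist, projections are zero-padded so
#' the attribute dimension stays `targetDim`.
#'
#' @param fp numeric matrix (molecules x fingerprint dimension), at least 2
#'   rows.
#' @param targetDim output dimensionality (default 100).
#' @param scale logical; standardize columns before PCA (default `FALSE`:
#'   center only).
#' @return A reducer parameter list (`center`, `scale`, `rotation`,
#'   `targetDim`, `inputDim`).
#' @export
fitReducer <- function(fp, targetDim = 100L, scale = FALSE) {
  fp <- as.matrix(fp)
  if (nrow(fp) < 2L) stop("PCA undefined for fewer than 2 rows")
  center <- colMeans(fp)
  x <- sweep(fp, 2L, center)
  scl <- NULL
  if (scale) {
    scl <- apply(fp, 2L, stats::sd)
    scl[scl < 1e-12] <- 1
    x <- sweep(x, 2L, scl, "/")
  }
  k <- min(targetDim, nrow(fp) - 1L, ncol(fp))
  sv <- svd(x, nu = 0, nv = k)
  rot <- sv$v
  # deterministic sign: largest-|loading| entry of each component positive
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  list(center = center, scale = scl, rotation = rot,
       targetDim = as.integer(targetDim), inputDim = ncol(fp))
}

#' Project fingerprints with a fitted reducer
#'
#' Applies the centering and rotation fitted by [fitReducer()], zero-padding
#' to the target dimension when the fitted basis has fewer components.
#'
#' @param fp numeric matrix (molecules x fingerprint dimension).
#' @param reducer a reducer parameter list from [fitReducer()].
#' @param kind source kind label recorded in the result (lower-cased).
#' @return An [AttributeSet-class] with `agg = "none"`.
#' @export
applyReducer <- function(fp, reducer, kind = "attr") {
  fp <- as.matrix(fp)
  if (ncol(fp) != reducer$inputDim) {
    stop("fingerprint dimension ", ncol(fp),
         " does not match reducer input dimension ", reducer$inputDim)
  }
  x <- sweep(fp, 2L, reducer$center)
  if (!is.null(reducer$scale)) x <- sweep(x, 2L, reducer$scale, "/")
  proj <- x %*% reducer$rotation
  if (ncol(proj) < reducer$targetDim) {
    proj <- cbind(proj,
                  matrix(0, nrow(proj), reducer$targetDim - ncol(proj)))
  }
  red <- list(reducer); names(red) <- tolower(kind)
  new("AttributeSet", values = unname(proj), components = tolower(kind),
      agg = "none", reducer = red)
}

#' Compute reduced attributes for a molecule set
#'
#' Convenience wrapper: fingerprints of `kind` for every molecule, PCA to
#' `targetDim` dimensions. By default the reducer is fitted on all molecules;
#' pass `fitRows` to restrict fitting (e.g. to meta-training molecules) for
#' leakage-averse use, while still projecting every molecule.
#'
#' @param molSet a [MoleculeSet-class].
#' @param kind one registry fingerprint kind (see [fingerprintKinds()]).
#' @param targetDim attribute dimensionality (default 100).
#' @param fitRows optional integer vector of molecule indices to fit the
#'   PCA on (default: all).
#' @param scale standardize before PCA (default `FALSE`).
#' @return An [AttributeSet-class].
#' @export
computeAttributes <- function(molSet, kind, targetDim = 100L, fitRows = NULL,
                              scale = FALSE) {
  fp <- computeFingerprints(moleculeSmiles(molSet), kind)[[kind]]
  fitOn <- if (is.null(fitRows)) fp else fp[fitRows, , drop = FALSE]
  red <- fitReducer(fitOn, targetDim = targetDim, scale = scale)
  applyReducer(fp, red, kind = kind)
}

#' Combine attribute sets by addition or concatenation
#'
#' Forms dual or triplet attributes from 2 or 3 single-kind attribute sets.
#' The combined name joins the component names with `"_"` (e.g.
#' `hashap_avalon_ecfp4`). Addition requires identical dimensions; the
#' combined dimension is the sum of part dimensions under concatenation.
#'
#' @param parts list of 2 or 3 [AttributeSet-class] objects with identical
#'   row counts and row order.
#' @param agg `"addition"` or `"concatenation"`.
#' @return An [AttributeSet-class].
#' @examples
#' \dontrun{
#' a2 <- combineAttributes(list(ecfp4, rdk5), "addition")
#' attrName(a2)  # "ecfp4_rdk5"
#' }
#' @export
combineAttributes <- function(parts, agg = c("addition", "concatenation")) {
  agg <- match.arg(agg)
  if (length(parts) < 2L || length(parts) > 3L) {
    stop("combineAttributes needs 2 or 3 parts, got ", length(parts))
  }
  ns <- vapply(parts, function(p) nrow(p@values), integer(1))
  if (length(unique(ns)) != 1L) {
    stop("attribute parts have different row counts: ",
         paste(ns, collapse = ", "))
  }
  vals <- lapply(parts, attrValues)
  if (agg == "addition") {
    ds <- vapply(vals, ncol, integer(1))
    if (length(unique(ds)) != 1L) {
      stop("addition requires identical dimensions, got ",
           paste(ds, collapse = ", "))
    }
    v <- Reduce(`+`, vals)
  } else {
    v <- do.call(cbind, vals)
  }
  comp <- unlist(lapply(parts, function(p) p@components))
  red <- do.call(c, lapply(parts, function(p) p@reducer))
  new("AttributeSet", values = v, components = comp, agg = agg,
      reducer = red)
}

#' Ingest precomputed deep fingerprints
#'
#' Loads a table of molecule-level embeddings exported by a pretrained
#' self-supervised model (one row per molecule: a SMILES key followed by the
#' numeric vector) and aligns it to a molecule set by canonical SMILES.
#' The result is reduced with [fitReducer()]/[applyReducer()] like any
#' fingerprint family.
#'
#' @param path delimited text table with header `smiles, v0, v1, ...`
#'   (CSV or TSV by extension).
#' @param molSet the [MoleculeSet-class] to align to.
#' @param tag short name of the embedding source (e.g. `"molebert"`).
#' @return A numeric matrix (molecules x embedding dim) with attribute
#'   `kind = paste0("DEEP:", tag)`, rows in `molSet` order.
#' @export
loadDeepFingerprints <- function(path, molSet, tag = "deep") {
  if (!file.exists(path)) stop("embedding table not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!"smiles" %in% names(tab)) stop("embedding table needs a 'smiles' column")
  keys <- rdkitBackend(tab$smiles)$canonical
  want <- moleculeSmiles(molSet)
  idx <- match(want, keys)
  if (anyNA(idx)) {
    miss <- utils::head(want[is.na(idx)], 5L)
    stop("embedding table missing ", sum(is.na(idx)), " molecule(s); first: ",
         paste(miss, collapse = ", "))
  }
  m <- as.matrix(tab[idx, setdiff(names(tab), "smiles"), drop = FALSE])
  storage.mode(m) <- "numeric"
  if (!all(is.finite(m))) stop("non-finite deep fingerprint entries")
  attr(m, "kind") <- paste0("DEEP:", tag)
  rownames(m) <- NULL
  m
}

#' Classify the relationship between a combined attribute and its parts
#'
#' Given the ROC-AUC of a model using a combined (dual) attribute and of the
#' two single-attribute models, classifies the pair as mutual promotion
#' (`R1`: combined strictly beats both), mutual inhibition (`R3`: combined
#' strictly below both), or one-sided promotion (`R2`: everything else,
#' including ties). Heatmap encoding: R1 = 1.0, R2 = 0.5, R3 = 0.0.
#'
#' @param aucCombined,aucFp1,aucFp2 finite ROC-AUC scores.
#' @return list with `relation` (`"R1"|"R2"|"R3"`) and `heatmap` (numeric).
#' @examples
#' classifyRelationship(0.8352, 0.8254, 0.8221)$relation  # "R1"
#' @export
classifyRelationship <- function(aucCombined, aucFp1, aucFp2) {
  stopifnot(is.finite(aucCombined), is.finite(aucFp1), is.finite(aucFp2))
  rel <- if (aucCombined > aucFp1 && aucCombined > aucFp2) {
    "R1"
  } else if (aucCombined < aucFp1 && aucCombined < aucFp2) {
    "R3"
  } else {
    "R2"
  }
  list(relation = rel, heatmap = c(R1 = 1.0, R2 = 0.5, R3 = 0.0)[[rel]])
}
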