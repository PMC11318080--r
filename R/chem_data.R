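#' @include AllClasses.R utils.R backend.R
NULL

#' Read a multi-task molecule table
#'
#' Reads a delimited table (CSV or TSV, autodetected from the file extension)
#' with one SMILES column and one column per binary property task. Rows whose
#' SMILES does not parse are skipped and counted; task cells must be 0, 1, or
#' missing (empty string or `NA`). SMILES are canonicalized and each molecule
#' is featurized as a [MolecularGraph-class].
#'
#' @param path path to a `.csv` or `.tsv`/`.txt` table with a header row.
#' @param smilesCol name of the SMILES column (default `"smiles"`).
#' @param taskCols character vector of task column names; default: every
#'   column except `smilesCol`.
#' @param graphs logical; featurize molecular graphs (default `TRUE`).
#' @return A [MoleculeSet-class].
#' @examples
#' \dontrun{
#' ms <- readDataset("tox21.csv", smilesCol = "smiles")
#' }
#' @export
readDataset <- function(path, smilesCol = "smiles", taskCols = NULL,
                        graphs = TRUE) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""), quote = "\"",
                           comment.char = "")
  if (!smilesCol %in% names(tab)) {
    stop("SMILES column '", smilesCol, "' not present in ", path)
  }
  if (is.null(taskCols)) taskCols <- setdiff(names(tab), smilesCol)
  missing <- setdiff(taskCols, names(tab))
  if (length(missing)) stop("task columns absent: ",
                            paste(missing, collapse = ", "))
  moleculeSet(tab[[smilesCol]], tab[taskCols], graphs = graphs)
}

#' Build a MoleculeSet from SMILES and labels
#'
#' In-memory constructor behind [readDataset()]. Unparseable SMILES are
#' dropped (and counted in the returned object); labels are validated to
#' \{0, 1, missing\}.
#'
#' @param smiles character vector of SMILES.
#' @param labels data.frame or matrix of task labels (rows parallel to
#'   `smiles`), entries 0/1/`NA`.
#' @param graphs logical; featurize molecular graphs.
#' @return A [MoleculeSet-class].
#' @export
moleculeSet <- function(smiles, labels, graphs = TRUE) {
  stopifnot(length(smiles) == nrow(labels))
  lab <- as.matrix(labels)
  storage.mode(lab) <- "numeric"
  bad <- which(!is.na(lab) & !(lab %in% c(0, 1)), arr.ind = TRUE)
  if (nrow(bad <- as.matrix(bad))) {
    stop("non-binary label value at row ", bad[1L, 1L], ", task '",
         colnames(lab)[bad[1L, 2L]], "'")
  }
  res <- rdkitBackend(smiles, graphs = graphs)
  keep <- which(res$ok)
  if (!length(keep)) stop("no parseable SMILES in input")
  gl <- if (graphs) {
    lapply(res$graphs[keep], graphFromBackend)
  } else {
    list()
  }
  new("MoleculeSet",
      smiles = res$canonical[keep],
      labels = lab[keep, , drop = FALSE],
      graphs = gl,
      nSkipped = as.integer(length(smiles) - length(keep)))
}

graphFromBackend <- function(g) {
  nf <- cbind(z = g$z, chir = g$chir)
  if (length(g$src)) {
    ei <- cbind(src = g$src, dst = g$dst)
    ef <- cbind(bt = g$bt, bd = g$bd)
  } else {
    ei <- matrix(integer(), 0L, 2L, dimnames = list(NULL, c("src", "dst")))
    ef <- matrix(integer(), 0L, 2L, dimnames = list(NULL, c("bt", "bd")))
  }
  new("MolecularGraph", nodeFeatures = nf, edgeIndex = ei, edgeFeatures = ef)
}

#' Convert a SMILES string to a molecular graph
#'
#' One node per heavy atom (hydrogens implicit), two directed edges per bond.
#' Node features are atomic number and chirality tag; edge features are bond
#' type and bond direction.
#'
#' @param smiles a single SMILES string.
#' @return A [MolecularGraph-class].
#' @examples
#' \dontrun{
#' g <- smilesToGraph("CCO")   # 3 nodes, 4 directed edges
#' }
#' @export
smilesToGraph <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  res <- rdkitBackend(smiles, graphs = TRUE)
  if (!res$ok) stop("invalid SMILES: '", smiles, "'")
  graphFromBackend(res$graphs[[1L]])
}

#' Number of atoms / directed edges of a graph
#' @param graph a [MolecularGraph-class].
#' @return integer count.
#' @export
nAtoms <- function(graph) nrow(graph@nodeFeatures)

#' @rdname nAtoms
#' @export
nDirectedEdges <- function(graph) nrow(graph@edgeIndex)

# Disjoint union of several molecular graphs into one flat batch, the unit
# the encoder operates on. Nodes of molecule i carry membership index i.
batchGraphs <- function(graphList) {
  ns <- vapply(graphList, nAtoms, integer(1))
  offsets <- c(0L, cumsum(ns))
  z <- unlist(lapply(graphList, function(g) g@nodeFeatures[, "z"]))
  chir <- unlist(lapply(graphList, function(g) g@nodeFeatures[, "chir"]))
  src <- integer(0); dst <- integer(0); bt <- integer(0); bd <- integer(0)
  for (i in seq_along(graphList)) {
    g <- graphList[[i]]
    if (nrow(g@edgeIndex)) {
      src <- c(src, g@edgeIndex[, "src"] + offsets[i])
      dst <- c(dst, g@edgeIndex[, "dst"] + offsets[i])
      bt <- c(bt, g@edgeFeatures[, "bt"])
      bd <- c(bd, g@edgeFeatures[, "bd"])
    }
  }
  list(z = as.integer(z), chir = as.integer(chir),
       src = src, dst = dst, bt = bt, bd = bd,
       mol = rep(seq_along(graphList), ns),
       nNodes = sum(ns), nMol = length(graphList))
}
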