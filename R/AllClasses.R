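#' @import methods
NULL

#' MolecularGraph: a featurized molecular graph
#'
#' Heavy-atom graph of one molecule. Nodes carry two categorical features
#' (atomic number, chirality tag); every bond is stored as two directed edges
#' carrying two categorical features (bond type, bond direction). Feature
#' indices follow the RDKit vocabularies documented in the methods vignette:
#' atomic number 1–118, chirality tag 0–3, bond type 0–3 (single, double,
#' triple, aromatic), bond direction 0–2 (none, end-up-right, end-down-right).
#'
#' @slot nodeFeatures integer matrix, N x 2 (columns `z`, `chir`).
#' @slot edgeIndex integer matrix, E x 2 (columns `src`, `dst`, 1-based).
#' @slot edgeFeatures integer matrix, E x 2 (columns `bt`, `bd`).
#' @exportClass MolecularGraph
setClass("MolecularGraph",
  representation(nodeFeatures = "matrix", edgeIndex = "matrix",
                 edgeFeatures = "matrix"))

setValidity("MolecularGraph", function(object) {
  nf <- object@nodeFeatures; ei <- object@edgeIndex; ef <- object@edgeFeatures
  msgs <- character()
  if (nrow(nf) < 1L) msgs <- c(msgs, "node count must be >= 1")
  if (ncol(nf) != 2L) msgs <- c(msgs, "nodeFeatures must have 2 columns")
  if (ncol(ei) != 2L) msgs <- c(msgs, "edgeIndex must have 2 columns")
  if (nrow(ei) != nrow(ef))
    msgs <- c(msgs, "edgeIndex and edgeFeatures row counts differ")
  if (nrow(ei) > 0L) {
    if (min(ei) < 1L || max(ei) > nrow(nf))
      msgs <- c(msgs, "edge endpoints out of node range")
    # every directed edge must have its reverse present
    fwd <- paste(ei[, 1L], ei[, 2L])
    rev <- paste(ei[, 2L], ei[, 1L])
    if (!setequal(fwd, rev))
      msgs <- c(msgs, "edge list is not symmetric (u->v without v->u)")
  }
  if (length(msgs)) msgs else TRUE
})

#' MoleculeSet: a multi-task molecule collection
#'
#' Holds one record per parseable molecule: its canonical SMILES, its binary
#' labels for each property task (`NA` = missing, excluded from episode
#' pools), and its featurized [MolecularGraph-class]. Row order is the stable
#' molecule index used everywhere downstream.
#'
#' @slot smiles character vector of canonical SMILES.
#' @slot labels numeric matrix, molecules x tasks, entries in \{0, 1, NA\}.
#' @slot graphs list of [MolecularGraph-class] objects, parallel to `smiles`.
#' @slot nSkipped integer; rows of the source table dropped as unparseable.
#' @exportClass MoleculeSet
setClass("MoleculeSet",
  representation(smiles = "character", labels = "matrix", graphs = "list",
                 nSkipped = "integer"))

setValidity("MoleculeSet", function(object) {
  msgs <- character()
  n <- length(object@smiles)
  if (nrow(object@labels) != n)
    msgs <- c(msgs, "labels rows must match number of molecules")
  if (length(object@graphs) != 0L && length(object@graphs) != n)
    msgs <- c(msgs, "graphs must be empty or parallel to smiles")
  vals <- object@labels[!is.na(object@labels)]
  if (length(vals) && !all(vals %in% c(0, 1)))
    msgs <- c(msgs, "labels must be 0, 1 or NA")
  if (length(msgs)) msgs else TRUE
})

#' AttributeSet: reduced molecular attribute vectors
#'
#' One attribute vector per molecule: a fingerprint family (or deep embedding)
#' projected to 100 principal components, or a combination of such projections
#' by addition or concatenation. Rows align with the molecule order of the
#' originating [MoleculeSet-class].
#'
#' @slot values numeric matrix, molecules x attribute dimension.
#' @slot components character; source kinds (length 1–3), lower-case.
#' @slot agg one of `"none"`, `"addition"`, `"concatenation"`.
#' @slot reducer list of fitted reducer parameters (per source kind).
#' @exportClass AttributeSet
setClass("AttributeSet",
  representation(values = "matrix", components = "character",
                 agg = "character", reducer = "list"))

setValidity("AttributeSet", function(object) {
  msgs <- character()
  k <- length(object@components)
  if (k < 1L || k > 3L) msgs <- c(msgs, "components must have length 1-3")
  if (!object@agg %in% c("none", "addition", "concatenation"))
    msgs <- c(msgs, "agg must be none/addition/concatenation")
  if (object@agg == "none" && k != 1L)
    msgs <- c(msgs, "agg 'none' requires a single component")
  if (!all(is.finite(object@values)))
    msgs <- c(msgs, "attribute values must be finite")
  if (length(msgs)) msgs else TRUE
})

#' TaskSplit: meta-training / meta-testing task partition
#'
#' Disjoint lists of training and testing property tasks, with per-task pools
#' of (molecule index, label) pairs excluding missing labels. A fraction of
#' each training task's pool is held out for the validation episodes that
#' drive early stopping.
#'
#' @slot trainTasks,testTasks character vectors of task names (disjoint).
#' @slot pools named list; per task, a list with integer vectors `pos` and
#'   `neg` of molecule indices.
#' @slot valPools same shape as `pools`, training tasks only; held-out
#'   molecules used for validation episodes.
#' @exportClass TaskSplit
setClass("TaskSplit",
  representation(trainTasks = "character", testTasks = "character",
                 pools = "list", valPools = "list"))

setValidity("TaskSplit", function(object) {
  msgs <- character()
  if (length(intersect(object@trainTasks, object@testTasks)))
    msgs <- c(msgs, "train and test task lists must be disjoint")
  need <- c(object@trainTasks, object@testTasks)
  if (!all(need %in% names(object@pools)))
    msgs <- c(msgs, "every task needs a pool")
  if (length(msgs)) msgs else TRUE
})

#' APNModel: a trained (or initialized) attribute-guided prototype network
#'
#' Bundles the encoder/gating parameters with the configuration they were
#' built under and the training log.
#'
#' @slot params named list of numeric parameter arrays.
#' @slot config list; architecture and training configuration (see
#'   [trainConfig()]).
#' @slot log data.frame; per-check training diagnostics (episode, loss,
#'   validation ROC-AUC).
#' @exportClass APNModel
setClass("APNModel",
  representation(params = "list", config = "list", log = "data.frame"))

#' EvalReport: repeated-run evaluation results
#'
#' Per-task, per-run ROC-AUC, F1 and PR-AUC on meta-testing tasks, plus the
#' sampling configuration. Use [reportSummary()] for means and standard
#' deviations; summaries are always recomputed from the stored per-run rows.
#'
#' @slot perRun data.frame with columns `task`, `run`, `rocAuc`, `f1`,
#'   `prAuc`.
#' @slot K,q,runs integers; shots per class, query size, runs per task.
#' @exportClass EvalReport
setClass("EvalReport",
  representation(perRun = "data.frame", K = "integer", q = "integer",
                 runs = "integer"))

setValidity("EvalReport", function(object) {
  msgs <- character()
  need <- c("task", "run", "rocAuc", "f1", "prAuc")
  if (!all(need %in% names(object@perRun)))
    msgs <- c(msgs, "perRun must have task/run/rocAuc/f1/prAuc columns")
  m <- as.matrix(object@perRun[, c("rocAuc", "f1", "prAuc")])
  if (length(m) && (min(m) < 0 || max(m) > 1))
    msgs <- c(msgs, "metrics must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})
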