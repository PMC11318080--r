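#' @include AllClasses.R
NULL

#' Accessors for APNet objects
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param object an APNet S4 object.
#' @name accessors
#' @aliases nMolecules moleculeSmiles labelMatrix taskNames molGraphs
#'   attrValues attrName modelParams modelConfig trainingLog reportPerRun
NULL

#' @rdname accessors
#' @export
setGeneric("nMolecules", function(object) standardGeneric("nMolecules"))
#' @rdname accessors
#' @export
setGeneric("moleculeSmiles", function(object) standardGeneric("moleculeSmiles"))
#' @rdname accessors
#' @export
setGeneric("labelMatrix", function(object) standardGeneric("labelMatrix"))
#' @rdname accessors
#' @export
setGeneric("taskNames", function(object) standardGeneric("taskNames"))
#' @rdname accessors
#' @export
setGeneric("molGraphs", function(object) standardGeneric("molGraphs"))
#' @rdname accessors
#' @export
setGeneric("attrValues", function(object) standardGeneric("attrValues"))
#' @rdname accessors
#' @export
setGeneric("attrName", function(object) standardGeneric("attrName"))
#' @rdname accessors
#' @export
setGeneric("modelParams", function(object) standardGeneric("modelParams"))
#' @rdname accessors
#' @export
setGeneric("modelConfig", function(object) standardGeneric("modelConfig"))
#' @rdname accessors
#' @export
setGeneric("trainingLog", function(object) standardGeneric("trainingLog"))
#' @rdname accessors
#' @export
setGeneric("reportPerRun", function(object) standardGeneric("reportPerRun"))

#' @rdname accessors
setMethod("nMolecules", "MoleculeSet", function(object) length(object@smiles))
#' @rdname accessors
setMethod("moleculeSmiles", "MoleculeSet", function(object) object@smiles)
#' @rdname accessors
setMethod("labelMatrix", "MoleculeSet", function(object) object@labels)
#' @rdname accessors
setMethod("taskNames", "MoleculeSet", function(object) colnames(object@labels))
#' @rdname accessors
setMethod("molGraphs", "MoleculeSet", function(object) object@graphs)

#' @rdname accessors
setMethod("attrValues", "AttributeSet", function(object) object@values)
#' @rdname accessors
setMethod("attrName", "AttributeSet",
          function(object) paste(object@components, collapse = "_"))

#' @rdname accessors
setMethod("modelParams", "APNModel", function(object) object@params)
#' @rdname accessors
setMethod("modelConfig", "APNModel", function(object) object@config)
#' @rdname accessors
setMethod("trainingLog", "APNModel", function(object) object@log)

#' @rdname accessors
setMethod("reportPerRun", "EvalReport", function(object) object@perRun)

setMethod("show", "MolecularGraph", function(object) {
  cat("MolecularGraph:", nrow(object@nodeFeatures), "atoms,",
      nrow(object@edgeIndex), "directed edges\n")
})

setMethod("show", "MoleculeSet", function(object) {
  cat("MoleculeSet:", nMolecules(object), "molecules,",
      ncol(object@labels), "tasks")
  if (object@nSkipped > 0L) cat(" (", object@nSkipped, " rows skipped)",
                                sep = "")
  cat("\n")
  if (length(object@graphs)) cat("  graphs: featurized\n")
})

setMethod("show", "AttributeSet", function(object) {
  cat("AttributeSet '", attrName(object), "' (agg=", object@agg, "): ",
      nrow(object@values), " x ", ncol(object@values), "\n", sep = "")
})

setMethod("show", "TaskSplit", function(object) {
  cat("TaskSplit:", length(object@trainTasks), "training tasks,",
      length(object@testTasks), "testing tasks\n")
})

setMethod("show", "APNModel", function(object) {
  cfg <- object@config
  cat("APNModel:", cfg$arch, "encoder,", cfg$nLayers, "layers, d^g =",
      cfg$hiddenDim, "\n")
  cat("  attribute dim:", if (is.null(cfg$attrDim)) "none" else cfg$attrDim,
      "\n")
  if (nrow(object@log)) {
    cat("  trained:", max(object@log$episode), "episodes, best val ROC-AUC",
        sprintf("%.4f", max(object@log$valRocAuc, na.rm = TRUE)), "\n")
  }
})

setMethod("show", "EvalReport", function(object) {
  s <- reportSummary(object)
  cat("EvalReport: K =", object@K, ", q =", object@q, ",", object@runs,
      "runs per task\n")
  print(s$perTask, row.names = FALSE, digits = 4)
  cat(sprintf("  overall: ROC-AUC %.4f (%.4f), F1 %.4f (%.4f), PR-AUC %.4f (%.4f)\n",
              s$overall$rocAuc, s$overall$rocAucSd, s$overall$f1,
              s$overall$f1Sd, s$overall$prAuc, s$overall$prAucSd))
})
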