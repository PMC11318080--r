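#' @include AllClasses.R encoder.R
NULL

#' Save and load parameter checkpoints
#'
#' A checkpoint is a single serialized file holding the parameter tree
#' together with the configuration header it was built under. Loading
#' verifies that the stored architecture, depth, width and attribute
#' dimension match the requested configuration; a save/load round trip is
#' bit-exact.
#'
#' @param params parameter list (as in [initAPNParams()], or a full
#'   [APNModel-class] whose params and config are taken).
#' @param cfg the [encoderConfig()] (plus `attrDim`) the parameters belong
#'   to; ignored when `params` is an `APNModel`.
#' @param path file path.
#' @return `saveCheckpoint`: the path, invisibly. `loadPretrained`: the
#'   parameter list, with the stored config attached as attribute
#'   `"config"`.
#' @export
saveCheckpoint <- function(params, cfg = NULL, path) {
  if (is(params, "APNModel")) {
    cfg <- modelConfig(params)
    params <- modelParams(params)
  }
  if (is.null(cfg)) stop("cfg required when params is a bare list")
  saveRDS(list(config = cfg, params = params), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadPretrained <- function(cfg, path) {
  if (!file.exists(path)) stop("checkpoint file not found: ", path)
  ck <- readRDS(path)
  for (field in c("arch", "nLayers", "hiddenDim")) {
    stored <- ck$config[[field]]
    wanted <- cfg[[field]]
    if (!is.null(wanted) && !identical(stored, wanted)) {
      stop("checkpoint ", field, " (", stored,
           ") does not match requested config (", wanted, ")")
    }
  }
  if (!is.null(cfg$attrDim) && !is.null(ck$config$attrDim) &&
      !identical(as.integer(ck$config$attrDim), as.integer(cfg$attrDim))) {
    stop("checkpoint attrDim (", ck$config$attrDim,
         ") does not match requested config (", cfg$attrDim, ")")
  }
  structure(ck$params, config = ck$config)
}
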