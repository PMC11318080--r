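#' @title RDKit chemistry backend
#'
#' @description APNet delegates all low-level chemistry — SMILES parsing and
#' canonicalization, molecular-graph featurization, fingerprint generation and
#' substructure matching — to RDKit, invoked in batch through a bundled Python
#' helper script. One call handles an entire molecule library, so the process
#' start-up cost is paid once per dataset, not per molecule.
#'
#' @param smiles character vector of SMILES strings.
#' @param graphs logical; return per-molecule graph featurizations?
#' @param fingerprints character vector of fingerprint kinds (see
#'   [fingerprintKinds()]), or `character()`.
#' @param patterns character vector of SMARTS patterns to match, or
#'   `character()`.
#'
#' @return A list with elements `ok` (logical), `canonical` (character, `NA`
#'   where unparseable), and, when requested, `graphs` (list), `fingerprints`
#'   (named list of per-molecule on-bit index vectors, or numeric descriptor
#'   vectors for `"rdkDes"`), and `matches` (list of logical vectors, one
#'   entry per pattern).
#' @keywords internal
rdkitBackend <- function(smiles, graphs = FALSE, fingerprints = character(),
                         patterns = character()) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  python <- backendPython()
  script <- system.file("python", "rdkit_backend.py", package = "APNet")
  if (!nzchar(script)) {
    stop("bundled rdkit_backend.py not found; is APNet installed correctly?")
  }
  infile <- tempfile("apnet_req_", fileext = ".json")
  outfile <- tempfile("apnet_res_", fileext = ".json")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  req <- list(
    smiles = as.list(unname(smiles)),
    graphs = graphs,
    fingerprints = as.list(unname(fingerprints)),
    patterns = as.list(unname(patterns))
  )
  jsonlite::write_json(req, infile, auto_unbox = TRUE, null = "null")
  status <- system2(python, c(script, "--infile", shQuote(infile),
                              "--outfile", shQuote(outfile)),
                    stdout = FALSE, stderr = "")
  if (!identical(status, 0L)) {
    stop("RDKit backend failed (exit status ", status, ")")
  }
  res <- jsonlite::read_json(outfile)
  parseBackendResponse(res, length(smiles), fingerprints, patterns)
}

backendPython <- function() {
  python <- getOption("APNet.python", Sys.which("python"))
  if (!nzchar(python)) {
    stop("no 'python' interpreter found on PATH; set options(APNet.python=)")
  }
  python
}

parseBackendResponse <- function(res, n, fingerprints, patterns) {
  out <- list(
    ok = vapply(res$ok, isTRUE, logical(1)),
    canonical = vapply(res$canonical,
                       function(x) if (is.null(x)) NA_character_ else x,
                       character(1))
  )
  if (!is.null(res$graphs)) {
    out$graphs <- lapply(res$graphs, function(g) {
      if (is.null(g)) return(NULL)
      list(z = as.integer(unlist(g$z)),
           chir = as.integer(unlist(g$chir)),
           src = as.integer(unlist(g$src)),
           dst = as.integer(unlist(g$dst)),
           bt = as.integer(unlist(g$bt)),
           bd = as.integer(unlist(g$bd)))
    })
  }
  if (!is.null(res$fingerprints)) {
    out$fingerprints <- lapply(res$fingerprints, function(kindList) {
      lapply(kindList, function(x) {
        if (is.null(x)) NULL else as.numeric(unlist(x))
      })
    })
  }
  if (!is.null(res$matches)) {
    out$matches <- lapply(res$matches, function(x) {
      if (is.null(x)) rep(NA, length(patterns)) else
        vapply(x, isTRUE, logical(1))
    })
  }
  out
}

#' Check that the RDKit backend is operational
#'
#' Runs a one-molecule round trip through the bundled RDKit helper. Useful for
#' diagnosing installation problems before loading a dataset.
#'
#' @return `TRUE` (invisibly) if the backend works; otherwise an error.
#' @examples
#' \dontrun{checkBackend()}
#' @export
checkBackend <- function() {
  res <- rdkitBackend("CCO")
  stopifnot(res$ok, identical(res$canonical, "CCO"))
  invisible(TRUE)
}
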