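#' @include AllClasses.R utils.R backend.R chem_data.R meta_runner.R
NULL

# Scaffold templates with six substitution slots (%1%..%6%). Slots are
# replaced by "(fragment)" or dropped. All templates parse with every slot
# empty or filled (checked in the test suite).
.SCAFFOLDS <- c(
  "CC%1%C%2%C%3%C%4%C%5%C%6%",
  "C1C%1%C%2%C%3%C%4%C%5%C%6%C1",
  "c1c%1%c%2%c%3%c%4%c1C%5%C%6%",
  "COC%1%C%2%C%3%C%4%C%5%C%6%",
  "C1C%1%C%2%C%3%C%4%CC1C%5%C%6%"
)
.N_SLOTS <- 6L

# Motif-free decorations used to vary molecules independently of the labels.
.DECORATIONS <- c("C", "CC", "CCC", "O", "OC", "N", "NC", "F", "Cl", "CO",
                  "C(C)C", "CCO", "C(C)O")

#' Default motif registry for synthetic property tasks
#'
#' Twelve structural motifs, each defining one binary task: a molecule is
#' positive when the motif occurs as a substructure. Each motif carries a
#' `fragment` (SMILES text embedded into generated molecules; ring closures
#' use digits 8/9 so they never collide with scaffold rings) and a `pattern`
#' (the SMARTS used for labeling). Motifs are chosen to be distinguishable
#' by circular fingerprints (distinct heteroatom/ring environments), and the
#' first nine are conventionally used as training tasks with the final three
#' (iodo, amide, pyrimidine) as unseen test tasks.
#'
#' @return data.frame with columns `name`, `fragment`, `pattern`.
#' @export
defaultMotifs <- function() {
  data.frame(
    name = c("nitro", "nitrile", "cf3", "sulfonamide", "carboxyl", "bromo",
             "furan", "thiophene", "pyridine",
             "iodo", "amide", "pyrimidine"),
    fragment = c("[N+](=O)[O-]", "C#N", "C(F)(F)F", "S(=O)(=O)N", "C(=O)O",
                 "Br", "c8ccco8", "c8cccs8", "c8ccncc8",
                 "I", "C(=O)N", "c8ncccn8"),
    pattern = c("[N+](=O)[O-]", "C#N", "C(F)(F)F", "S(=O)(=O)N", "C(=O)O",
                "Br", "c1ccoc1", "c1ccsc1", "c1ccncc1",
                "I", "C(=O)N", "c1ncccn1"),
    stringsAsFactors = FALSE)
}

#' Specification of a synthetic benchmark
#'
#' @param nMolecules library size (default 2000).
#' @param motifs motif table as in [defaultMotifs()] (one row per task).
#' @param positiveFraction target prevalence of positives per task, in
#'   (0, 1) (default 0.25).
#' @param labelNoise probability of flipping each label, in `[0, 0.5)`
#'   (default 0).
#' @param seed integer seed; generation is fully deterministic given it.
#' @return a spec list.
#' @export
synthSpec <- function(nMolecules = 2000L, motifs = defaultMotifs(),
                      positiveFraction = 0.25, labelNoise = 0, seed = 1L) {
  stopifnot(nMolecules >= 1L,
            positiveFraction > 0, positiveFraction < 1,
            labelNoise >= 0, labelNoise < 0.5,
            all(c("name", "fragment", "pattern") %in% names(motifs)))
  list(nMolecules = as.integer(nMolecules), motifs = motifs,
       positiveFraction = positiveFraction, labelNoise = labelNoise,
       seed = as.integer(seed))
}

# Assemble one raw SMILES: a scaffold decorated with the given fragments
# plus a few plain decorations on random slots.
assembleSmiles <- function(fragments) {
  nExtra <- sample(0:2, 1L)
  fills <- c(fragments,
             sample(.DECORATIONS, min(nExtra, .N_SLOTS - length(fragments)),
                    replace = TRUE))
  if (length(fills) > .N_SLOTS) fills <- sample(fills, .N_SLOTS)
  slots <- rep("", .N_SLOTS)
  if (length(fills)) {
    slots[sample.int(.N_SLOTS, length(fills))] <- paste0("(", fills, ")")
  }
  s <- sample(.SCAFFOLDS, 1L)
  for (k in seq_len(.N_SLOTS)) {
    s <- sub(paste0("%", k, "%"), slots[k], s, fixed = TRUE)
  }
  s
}

# Draw raw molecules with per-task motif inclusion flags.
drawRawMolecules <- function(nDraw, spec) {
  M <- nrow(spec$motifs)
  vapply(seq_len(nDraw), function(i) {
    inc <- stats::runif(M) < spec$positiveFraction
    frags <- spec$motifs$fragment[inc]
    if (length(frags) > .N_SLOTS) frags <- sample(frags, .N_SLOTS)
    assembleSmiles(frags)
  }, character(1))
}

#' Generate a deterministic library of valid molecules
#'
#' Builds `nMolecules` unique, valid, canonical SMILES by decorating simple
#' scaffolds (chains, aliphatic and aromatic rings) with structural motif
#' fragments and plain decorations. Stereocenters are avoided by
#' construction. Generation retries (deterministically, under the spec seed)
#' until the requested number of unique canonical molecules is reached.
#'
#' @param spec a [synthSpec()] list.
#' @return character vector of `nMolecules` unique canonical SMILES.
#' @export
generateLibrary <- function(spec) {
  withSeed(spec$seed, "library", {
    lib <- character(0)
    tries <- 0L
    while (length(lib) < spec$nMolecules && tries < 50L) {
      tries <- tries + 1L
      raw <- drawRawMolecules(
        max(64L, ceiling((spec$nMolecules - length(lib)) * 1.3)), spec)
      res <- rdkitBackend(raw)
      lib <- unique(c(lib, res$canonical[res$ok]))
    }
    if (length(lib) < spec$nMolecules) {
      stop("could not generate ", spec$nMolecules, " unique molecules")
    }
    lib[seq_len(spec$nMolecules)]
  })
}

#' Label a molecule library with motif-defined tasks
#'
#' For each motif task, a molecule's label is 1 exactly when the motif's
#' SMARTS pattern matches, then flipped with probability `labelNoise`.
#' With zero noise the labels are the exact motif-presence indicators.
#'
#' @param library character vector of valid SMILES (e.g. from
#'   [generateLibrary()]).
#' @param spec a [synthSpec()] list.
#' @return data.frame with column `smiles` plus one 0/1 column per motif
#'   task.
#' @export
labelTasks <- function(library, spec) {
  res <- rdkitBackend(library, patterns = spec$motifs$pattern)
  if (!all(res$ok)) stop("library contains invalid SMILES")
  lab <- do.call(rbind, lapply(res$matches, as.numeric))
  colnames(lab) <- spec$motifs$name
  none <- colSums(lab) == 0
  if (any(none)) {
    warning("motif(s) matching nothing in the library: ",
            paste(spec$motifs$name[none], collapse = ", "), call. = FALSE)
  }
  if (spec$labelNoise > 0) {
    lab <- withSeed(spec$seed, "noise", {
      flip <- matrix(stats::runif(length(lab)) < spec$labelNoise,
                     nrow(lab))
      abs(lab - flip)
    })
  }
  data.frame(smiles = library, lab, check.names = FALSE)
}

#' Motif-indicator attributes for a synthetic benchmark
#'
#' The controllable-signal attribute of the synthetic module: one column per
#' motif, 1 where the motif occurs in the molecule. This is the noise-free
#' structural information the synthetic task labels are derived from, so it
#' serves as the attribute with maximal task-relevant signal when studying
#' how attribute quality affects few-shot performance (fingerprint
#' attributes carry the same information diluted among all substructures).
#'
#' @param molSet a [MoleculeSet-class].
#' @param motifs motif table as in [defaultMotifs()].
#' @return An [AttributeSet-class] with one column per motif.
#' @export
motifAttributes <- function(molSet, motifs = defaultMotifs()) {
  res <- rdkitBackend(moleculeSmiles(molSet), patterns = motifs$pattern)
  vals <- do.call(rbind, lapply(res$matches, as.numeric))
  colnames(vals) <- NULL
  new("AttributeSet", values = vals, components = "motifs", agg = "none",
      reducer = list())
}

#' Build a complete synthetic few-shot benchmark
#'
#' Generates the library, labels the motif tasks, featurizes the molecules,
#' and splits the tasks into meta-training and meta-testing sets with
#' disjoint motifs (the unseen-property setting). With the default motif
#' registry and 9/3 split the layout mirrors a 12-assay toxicity panel with
#' 9 training and 3 testing assays. Optionally writes the dataset table
#' (CSV) and the split (JSON) to `outDir`; regeneration under the same seed
#' is byte-identical.
#'
#' @param spec a [synthSpec()] list.
#' @param nTrainTasks,nTestTasks number of training/testing tasks (default
#'   9 and 3); their sum must not exceed the motif count.
#' @param valFraction validation holdout passed to [makeTaskSplit()].
#' @param outDir optional directory to write `dataset.csv` and
#'   `split.json` into.
#' @return list with `table` (the dataset data.frame), `molSet`
#'   (a [MoleculeSet-class] with graphs) and `split` (a
#'   [TaskSplit-class]).
#' @export
makeBenchmark <- function(spec, nTrainTasks = 9L, nTestTasks = 3L,
                          valFraction = 0.2, outDir = NULL) {
  M <- nrow(spec$motifs)
  if (nTrainTasks + nTestTasks > M) {
    stop("need ", nTrainTasks + nTestTasks, " motifs but only ", M,
         " are defined")
  }
  lib <- generateLibrary(spec)
  tab <- labelTasks(lib, spec)
  molSet <- moleculeSet(tab$smiles, tab[spec$motifs$name], graphs = TRUE)
  trainTasks <- spec$motifs$name[seq_len(nTrainTasks)]
  testTasks <- spec$motifs$name[nTrainTasks + seq_len(nTestTasks)]
  split <- makeTaskSplit(molSet, trainTasks, testTasks,
                         valFraction = valFraction, seed = spec$seed)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab, file.path(outDir, "dataset.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(train = trainTasks, test = testTasks),
                         file.path(outDir, "split.json"))
  }
  list(table = tab, molSet = molSet, split = split)
}
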