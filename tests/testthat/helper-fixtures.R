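# Shared fixtures, built once per session. Everything is generated in code:
# a small motif benchmark for unit tests and the full desk-scale benchmark
# for the learnability checks.

.fixtures <- new.env(parent = emptyenv())

tinyBench <- function() {
  if (is.null(.fixtures$tiny)) {
    sp <- synthSpec(nMolecules = 150, seed = 3)
    .fixtures$tinySpec <- sp
    .fixtures$tiny <- makeBenchmark(sp, valFraction = 0.2)
  }
  .fixtures$tiny
}

tinySpec <- function() {
  tinyBench()
  .fixtures$tinySpec
}

tinyAttrs <- function(kind = "ECFP4") {
  key <- paste0("tinyAttr_", kind)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- computeAttributes(tinyBench()$molSet, kind)
  }
  .fixtures[[key]]
}

# Desk-scale benchmark used by the learnability and acceptance checks.
deskBench <- function() {
  if (is.null(.fixtures$desk)) {
    sp <- synthSpec(nMolecules = 2000, seed = 11)
    .fixtures$deskSpec <- sp
    .fixtures$desk <- makeBenchmark(sp)
  }
  .fixtures$desk
}

deskAttrs <- function(kind = "ECFP4") {
  key <- paste0("deskAttr_", kind)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- computeAttributes(deskBench()$molSet, kind)
  }
  .fixtures[[key]]
}

# A random valid featurized graph built directly (no chemistry): a random
# spanning tree plus a few extra undirected edges, features inside the
# embedding vocabularies.
randomGraph <- function(nNodes, seed) {
  withr::with_seed(seed, {
    z <- sample(c(6L, 7L, 8L, 9L, 16L, 17L, 35L), nNodes, replace = TRUE)
    chir <- sample(0:3, nNodes, replace = TRUE)
    und <- if (nNodes > 1L) {
      cbind(2:nNodes, vapply(2:nNodes, function(i) {
        sample.int(i - 1L, 1L)
      }, integer(1)))
    } else {
      matrix(integer(), 0L, 2L)
    }
    if (nNodes > 3L) {
      extra <- t(replicate(2L, sample.int(nNodes, 2L)))
      und <- unique(rbind(und, extra))
      und <- und[und[, 1L] != und[, 2L], , drop = FALSE]
    }
    bt <- sample(0:3, nrow(und), replace = TRUE)
    bd <- sample(0:2, nrow(und), replace = TRUE)
    new("MolecularGraph",
        nodeFeatures = cbind(z = z, chir = chir),
        edgeIndex = cbind(src = c(und[, 1L], und[, 2L]),
                          dst = c(und[, 2L], und[, 1L])),
        edgeFeatures = cbind(bt = c(bt, bt), bd = c(bd, bd)))
  })
}

# Apply a node permutation to a graph: node i becomes position perm[i].
permuteGraph <- function(graph, perm) {
  inv <- order(perm)
  new("MolecularGraph",
      nodeFeatures = graph@nodeFeatures[inv, , drop = FALSE],
      edgeIndex = cbind(src = perm[graph@edgeIndex[, "src"]],
                        dst = perm[graph@edgeIndex[, "dst"]]),
      edgeFeatures = graph@edgeFeatures)
}
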