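test_that("library generation is deterministic, valid and duplicate-free", {
  sp <- synthSpec(nMolecules = 80, seed = 5)
  lib1 <- generateLibrary(sp)
  lib2 <- generateLibrary(sp)
  expect_identical(lib1, lib2)
  expect_length(lib1, 80L)
  expect_length(unique(lib1), 80L)
  res <- APNet:::rdkitBackend(lib1)
  expect_true(all(res$ok))
  # already canonical: re-canonicalization is the identity
  expect_identical(res$canonical, lib1)
})

test_that("noise-free labels equal motif presence on hand-built molecules", {
  sp <- synthSpec(nMolecules = 10, seed = 1)
  lib <- c("CCCC(Br)CC",            # bromo only
           "c1ccncc1CC",            # pyridine only
           "CCC(=O)O",              # carboxyl only
           "O=S(=O)(N)CC#N",        # sulfonamide + nitrile
           "CCCCCC")                # nothing
  expect_warning(tab <- labelTasks(lib, sp), "matching nothing")
  expect_equal(tab$bromo, c(1, 0, 0, 0, 0))
  expect_equal(tab$pyridine, c(0, 1, 0, 0, 0))
  expect_equal(tab$carboxyl, c(0, 0, 1, 0, 0))
  expect_equal(tab$sulfonamide, c(0, 0, 0, 1, 0))
  expect_equal(tab$nitrile, c(0, 0, 0, 1, 0))
  expect_equal(tab$iodo, rep(0, 5))
  expect_warning(labelTasks(lib[5L], sp), "matching nothing")
})

test_that("label noise flips at the requested rate", {
  lib <- moleculeSmiles(deskBench()$molSet)
  spClean <- synthSpec(nMolecules = length(lib), seed = 31, labelNoise = 0)
  spNoisy <- synthSpec(nMolecules = length(lib), seed = 31, labelNoise = 0.1)
  clean <- as.matrix(labelTasks(lib, spClean)[, -1L])
  noisy <- as.matrix(labelTasks(lib, spNoisy)[, -1L])
  flipRate <- mean(clean != noisy)
  expect_gt(flipRate, 0.08)
  expect_lt(flipRate, 0.12)
})

test_that("tasks with disjoint motifs are near-independent", {
  lab <- labelMatrix(deskBench()$molSet)
  phi <- abs(cor(lab))
  diag(phi) <- 0
  expect_lt(max(phi), 0.1)
})

test_that("realized prevalence tracks the target fraction", {
  lab <- labelMatrix(deskBench()$molSet)
  prev <- colMeans(lab)
  target <- 0.25
  expect_true(all(abs(prev - target) < 0.05))
})

test_that("benchmarks mirror a 9/3 unseen-task split and write stable files", {
  bench <- tinyBench()
  expect_length(bench$split@trainTasks, 9L)
  expect_length(bench$split@testTasks, 3L)
  expect_length(intersect(bench$split@trainTasks, bench$split@testTasks), 0L)
  sp <- synthSpec(nMolecules = 40, seed = 6)
  d1 <- file.path(tempdir(), "bench1")
  d2 <- file.path(tempdir(), "bench2")
  b1 <- makeBenchmark(sp, nTrainTasks = 4L, nTestTasks = 2L, outDir = d1)
  b2 <- makeBenchmark(sp, nTrainTasks = 4L, nTestTasks = 2L, outDir = d2)
  expect_identical(readLines(file.path(d1, "dataset.csv")),
                   readLines(file.path(d2, "dataset.csv")))
  expect_identical(readLines(file.path(d1, "split.json")),
                   readLines(file.path(d2, "split.json")))
  spl <- jsonlite::read_json(file.path(d1, "split.json"))
  expect_length(intersect(unlist(spl$train), unlist(spl$test)), 0L)
  expect_error(makeBenchmark(sp, nTrainTasks = 10L, nTestTasks = 5L),
               "motifs")
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("motif-indicator attributes reproduce the noise-free labels", {
  bench <- tinyBench()
  at <- motifAttributes(bench$molSet, tinySpec()$motifs)
  vals <- attrValues(at)
  expect_equal(dim(vals), c(nMolecules(bench$molSet), 12L))
  expect_true(all(vals %in% c(0, 1)))
  expect_equal(unname(vals), unname(labelMatrix(bench$molSet)))
})

test_that("motif-count attributes make unseen synthetic tasks learnable", {
  # the attribute-benefit property at desk scale: with noise-free labels and
  # the maximally informative attribute, a briefly trained model recovers
  # unseen motif tasks from 10-shot supports
  bench <- deskBench()
  at <- motifAttributes(bench$molSet)
  cfg <- trainConfig(K = 10L, q = 32L, episodes = 100L, evalEvery = 50L,
                     valEpisodes = 3L, lr = 5e-4, seed = 11L)
  model <- metaTrain(bench$molSet, at, bench$split, encoderConfig("GAT"),
                     cfg)
  rep <- metaEvaluate(model, bench$molSet, at, bench$split, runs = 10L)
  expect_gte(reportSummary(rep)$overall$rocAuc, 0.85)
})

test_that("label noise at the information ceiling removes learnability", {
  # with labels flipped at 50% there is no signal left: prototype
  # classification on the maximally informative attribute is at chance
  bench <- tinyBench()
  lab <- labelMatrix(bench$molSet)
  at <- attrValues(motifAttributes(bench$molSet, tinySpec()$motifs))
  withr::with_seed(40, {
    aucs <- replicate(60, {
      task <- sample(ncol(lab), 1L)
      y <- lab[, task]
      yNoisy <- abs(y - rbinom(length(y), 1L, 0.5))
      pos <- which(yNoisy == 1)[1:5]
      neg <- which(yNoisy == 0)[1:5]
      qry <- setdiff(seq_along(y), c(pos, neg))
      qry <- qry[!is.na(yNoisy[qry])][1:30]
      protos <- makePrototypes(at[pos, ], at[neg, ])
      rocAuc(classifyQuery(at[qry, ], protos, "dot"), yNoisy[qry])
    })
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.06)
})
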