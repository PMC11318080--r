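test_that("training configuration is validated", {
  expect_error(trainConfig(lr = 1e-4), "learning rate")
  expect_error(trainConfig(lr = 0.1), "learning rate")
  expect_error(trainConfig(ablation = "X"), "ablation")
  cfg <- trainConfig(K = 5L, ablation = c("L", "W"))
  expect_equal(cfg$K, 5L)
})

test_that("task splits are disjoint with NA-free pools", {
  bench <- tinyBench()
  split <- bench$split
  expect_length(intersect(split@trainTasks, split@testTasks), 0L)
  lab <- labelMatrix(bench$molSet)
  for (task in c(split@trainTasks, split@testTasks)) {
    pool <- split@pools[[task]]
    expect_true(all(lab[pool$pos, task] == 1))
    expect_true(all(lab[pool$neg, task] == 0))
  }
  # validation holdout is disjoint from the training pool
  for (task in split@trainTasks) {
    expect_length(intersect(split@pools[[task]]$pos,
                            split@valPools[[task]]$pos), 0L)
  }
})

test_that("episodes have 2K supports disjoint from stratified queries", {
  split <- tinyBench()$split
  withr::with_seed(1, {
    for (rep in 1:1000) {
      task <- sample(split@trainTasks, 1L)
      ep <- sampleEpisode(split, task, 3L, 8L)
      support <- c(ep$supportPos, ep$supportNeg)
      expect_length(support, 6L)
      expect_length(intersect(support, ep$query), 0L)
      expect_setequal(unique(ep$queryLabels), c(0, 1))
    }
  })
  # K=10 gives a support set of size 20
  ep <- withr::with_seed(2, sampleEpisode(split, "nitro", 10L, 16L))
  expect_length(c(ep$supportPos, ep$supportNeg), 20L)
  # fixed seed reproduces the episode exactly
  e1 <- withr::with_seed(7, sampleEpisode(split, "furan", 4L, 8L))
  e2 <- withr::with_seed(7, sampleEpisode(split, "furan", 4L, 8L))
  expect_identical(e1, e2)
})

test_that("scarce classes fall back to replacement sampling or skip", {
  ms <- tinyBench()$molSet
  lab <- labelMatrix(ms)
  scarce <- new("TaskSplit", trainTasks = "t", testTasks = character(),
                pools = list(t = list(pos = which(lab[, "nitro"] == 1)[1:3],
                                      neg = which(lab[, "nitro"] == 0))),
                valPools = list())
  expect_warning(
    ep <- withr::with_seed(3, sampleEpisode(scarce, "t", 5L, 4L)),
    "replacement")
  expect_length(ep$supportPos, 5L)
  tiny <- scarce
  tiny@pools$t$pos <- tiny@pools$t$pos[1L]
  expect_null(suppressWarnings(
    withr::with_seed(3, sampleEpisode(tiny, "t", 5L, 4L))))
})

test_that("a single-task model drives the loss below chance level", {
  bench <- tinyBench()
  at <- motifAttributes(bench$molSet, tinySpec()$motifs)
  split <- makeTaskSplit(bench$molSet, "nitro", "iodo", valFraction = 0,
                         seed = 1L)
  cfg <- trainConfig(K = 3L, q = 8L, episodes = 50L, evalEvery = 10L,
                     valEpisodes = 2L, seed = 4L)
  model <- metaTrain(bench$molSet, at, split, encoderConfig("GAT", 2L, 16L),
                     cfg)
  expect_lt(min(trainingLog(model)$loss), log(2))
})

test_that("fixed-seed training is exactly reproducible", {
  bench <- tinyBench()
  at <- tinyAttrs("ECFP4")
  cfg <- trainConfig(K = 2L, q = 4L, episodes = 15L, evalEvery = 5L,
                     valEpisodes = 2L, seed = 21L)
  ec <- encoderConfig("GAT", 2L, 12L)
  m1 <- metaTrain(bench$molSet, at, bench$split, ec, cfg)
  m2 <- metaTrain(bench$molSet, at, bench$split, ec, cfg)
  expect_identical(modelParams(m1), modelParams(m2))
  expect_identical(trainingLog(m1), trainingLog(m2))
  r1 <- metaEvaluate(m1, bench$molSet, at, bench$split, runs = 3L)
  r2 <- metaEvaluate(m2, bench$molSet, at, bench$split, runs = 3L)
  expect_identical(reportPerRun(r1), reportPerRun(r2))
})

test_that("evaluation never mutates the model parameters", {
  bench <- tinyBench()
  at <- tinyAttrs("ECFP4")
  cfg <- trainConfig(K = 2L, q = 4L, episodes = 5L, evalEvery = 5L,
                     valEpisodes = 1L, seed = 8L)
  model <- metaTrain(bench$molSet, at, bench$split,
                     encoderConfig("GCN", 2L, 8L), cfg)
  before <- modelParams(model)
  invisible(metaEvaluate(model, bench$molSet, at, bench$split, runs = 2L))
  expect_identical(modelParams(model), before)
})

test_that("the attribute-free variant runs end to end", {
  bench <- tinyBench()
  cfg <- trainConfig(K = 2L, q = 4L, episodes = 8L, evalEvery = 4L,
                     valEpisodes = 1L, seed = 9L, ablation = "A")
  model <- metaTrain(bench$molSet, NULL, bench$split,
                     encoderConfig("GAT", 2L, 8L), cfg)
  rep <- metaEvaluate(model, bench$molSet, NULL, bench$split, runs = 2L)
  expect_true(all(reportPerRun(rep)$rocAuc >= 0 &
                    reportPerRun(rep)$rocAuc <= 1))
})

test_that("report summaries are recomputed from stored per-run rows", {
  bench <- tinyBench()
  at <- tinyAttrs("ECFP4")
  cfg <- trainConfig(K = 3L, q = 8L, episodes = 1L, evalEvery = 1L,
                     valEpisodes = 1L, seed = 10L)
  model <- metaTrain(bench$molSet, at, bench$split,
                     encoderConfig("GAT", 2L, 8L), cfg)
  rep <- metaEvaluate(model, bench$molSet, at, bench$split, runs = 4L)
  pr <- reportPerRun(rep)
  s <- reportSummary(rep)
  expect_equal(s$overall$rocAuc, mean(pr$rocAuc), tolerance = 1e-15)
  for (task in unique(pr$task)) {
    expect_equal(s$perTask$rocAuc[s$perTask$task == task],
                 mean(pr$rocAuc[pr$task == task]), tolerance = 1e-15)
  }
  expect_true(all(s$perTask$rocAucSd >= 0))
})

test_that("the attribute screen ranks attributes and classifies pairs", {
  bench <- tinyBench()
  a <- tinyAttrs("ECFP4")
  b <- tinyAttrs("RDK5")
  ab <- combineAttributes(list(a, b), "addition")
  aCopy <- a
  cfg <- trainConfig(K = 2L, q = 4L, episodes = 6L, evalEvery = 3L,
                     valEpisodes = 1L, seed = 12L)
  res <- attributeScreen(bench$molSet,
                         list(ecfp4 = a, rdk5 = b, ecfp4_rdk5 = ab,
                              ecfp4copy = aCopy),
                         bench$split, encoderConfig("GAT", 2L, 8L), cfg,
                         runs = 2L)
  expect_equal(nrow(res$table), 4L)
  expect_true(!is.unsorted(rev(res$table$rocAuc)))
  # identical attribute matrices under identical seeds -> identical scores
  expect_equal(res$table$rocAuc[res$table$attribute == "ecfp4"],
               res$table$rocAuc[res$table$attribute == "ecfp4copy"])
  expect_equal(res$relationships$pair, "ecfp4_rdk5")
  expect_true(res$relationships$heatmap %in% c(0, 0.5, 1))
})
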