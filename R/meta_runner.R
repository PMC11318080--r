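#' @include AllClasses.R utils.R chem_data.R encoder.R agda.R proto_head.R
#' @include metrics.R optim.R
NULL

#' Training configuration
#'
#' Episodic 2-way K-shot training settings. Defaults follow the reference
#' protocol: 10 shots, query size 32, 2000 episodes with Adam, early-stopping
#' patience of 100 validation checks.
#'
#' Ablation flags switch off individual components of the model:
#' `"L"` (no attribute-guided local attention), `"G"` (no global attention),
#' `"S"` (negative-L2 similarity instead of dot product), `"W"` (uniform
#' instead of inverse-distance prototype weights), `"A"` (no attributes at
#' all: representations are plain encoder means and AGDA is bypassed).
#'
#' @param K shots per class (default 10).
#' @param q query-set size (default 32).
#' @param episodes number of training episodes / optimizer steps
#'   (default 2000).
#' @param lr Adam learning rate, in `[5e-4, 5e-2]` (default 1e-3).
#' @param patience early-stopping patience, counted in validation checks
#'   (default 100).
#' @param evalEvery validation cadence in episodes (default 50).
#' @param valEpisodes number of fixed validation episodes (default 4).
#' @param seed root seed; all stochastic stages derive named substreams.
#' @param ablation character vector, any of `"L"`, `"G"`, `"S"`, `"W"`,
#'   `"A"`.
#' @return a config list.
#' @export
trainConfig <- function(K = 10L, q = 32L, episodes = 2000L, lr = 1e-3,
                        patience = 100L, evalEvery = 50L, valEpisodes = 4L,
                        seed = 1L, ablation = character()) {
  stopifnot(K >= 1L, q >= 1L, episodes >= 1L, patience >= 1L)
  if (lr < 5e-4 || lr > 5e-2) {
    stop("learning rate ", lr, " outside the supported range [5e-4, 5e-2]")
  }
  bad <- setdiff(ablation, c("L", "G", "S", "W", "A"))
  if (length(bad)) stop("unknown ablation flag(s): ",
                        paste(bad, collapse = ", "))
  list(K = as.integer(K), q = as.integer(q), episodes = as.integer(episodes),
       lr = lr, patience = as.integer(patience),
       evalEvery = as.integer(evalEvery),
       valEpisodes = as.integer(valEpisodes), seed = as.integer(seed),
       ablation = ablation)
}

#' Build a meta-training / meta-testing task split
#'
#' Partitions the tasks of a molecule set into disjoint training and testing
#' sets and builds per-task pools of molecule indices with non-missing
#' labels. A fraction of each training task's pool is held out as validation
#' molecules for the early-stopping episodes; test-task pools are left whole.
#'
#' @param molSet a [MoleculeSet-class].
#' @param trainTasks,testTasks character vectors of task (column) names.
#' @param valFraction fraction of each training pool held out for validation
#'   episodes (default 0.2).
#' @param seed integer seed for the validation holdout.
#' @return A [TaskSplit-class].
#' @export
makeTaskSplit <- function(molSet, trainTasks, testTasks, valFraction = 0.2,
                          seed = 1L) {
  lab <- labelMatrix(molSet)
  need <- c(trainTasks, testTasks)
  miss <- setdiff(need, colnames(lab))
  if (length(miss)) stop("unknown task(s): ", paste(miss, collapse = ", "))
  pools <- list(); valPools <- list()
  for (task in need) {
    y <- lab[, task]
    pos <- which(!is.na(y) & y == 1)
    neg <- which(!is.na(y) & y == 0)
    if (task %in% trainTasks && valFraction > 0) {
      hold <- withSeed(seed, paste0("valsplit-", task), {
        list(pos = sample(pos, floor(length(pos) * valFraction)),
             neg = sample(neg, floor(length(neg) * valFraction)))
      })
      valPools[[task]] <- hold
      pools[[task]] <- list(pos = setdiff(pos, hold$pos),
                            neg = setdiff(neg, hold$neg))
    } else {
      pools[[task]] <- list(pos = pos, neg = neg)
    }
  }
  new("TaskSplit", trainTasks = trainTasks, testTasks = testTasks,
      pools = pools, valPools = valPools)
}

#' Sample one 2-way K-shot episode
#'
#' Draws K positive and K negative support molecules without replacement from
#' a task pool, then q query molecules from the remainder, stratified to
#' contain both classes whenever the pool allows. Support and query sets are
#' disjoint by construction. If a class has fewer than K members it is
#' sampled with replacement (logged via a warning once per call); with fewer
#' than 2 members the task is unusable and `NULL` is returned.
#'
#' Uses the current RNG state; wrap in `withr::with_seed()` (as
#' [metaTrain()]/[metaEvaluate()] do) for reproducibility.
#'
#' @param split a [TaskSplit-class].
#' @param task task name.
#' @param K shots per class.
#' @param q query-set size.
#' @param useVal draw from the validation holdout pool instead.
#' @return list with `supportPos`, `supportNeg`, `query` (molecule indices),
#'   `queryLabels`, and `task`; or `NULL` if the pool is too small.
#' @export
sampleEpisode <- function(split, task, K, q, useVal = FALSE) {
  pool <- if (useVal) split@valPools[[task]] else split@pools[[task]]
  if (is.null(pool)) stop("no pool for task '", task, "'")
  drawClass <- function(ids) {
    if (length(ids) < 2L) return(NULL)
    if (length(ids) < K) {
      warning("task '", task, "': fewer than K=", K,
              " molecules in one class; sampling with replacement",
              call. = FALSE)
      sample(ids, K, replace = TRUE)
    } else {
      sample(ids, K)
    }
  }
  sPos <- drawClass(pool$pos)
  sNeg <- drawClass(pool$neg)
  if (is.null(sPos) || is.null(sNeg)) return(NULL)
  remPos <- setdiff(pool$pos, sPos)
  remNeg <- setdiff(pool$neg, sNeg)
  if (length(remPos) + length(remNeg) < 1L) return(NULL)
  qPos <- min(ceiling(q / 2), length(remPos))
  qNeg <- min(q - qPos, length(remNeg))
  if (qPos + qNeg < q) qPos <- min(q - qNeg, length(remPos))
  qryPos <- if (qPos > 0L) sample(remPos, qPos) else integer(0)
  qryNeg <- if (qNeg > 0L) sample(remNeg, qNeg) else integer(0)
  qry <- c(qryPos, qryNeg)
  o <- sample.int(length(qry))
  list(supportPos = sPos, supportNeg = sNeg, query = qry[o],
       queryLabels = c(rep(1, qPos), rep(0, qNeg))[o], task = task)
}

#' Initialize APN parameters
#'
#' Random initialization of the encoder embedding tables and layers plus the
#' AGDA gating layers (when an attribute dimension is given).
#'
#' The gate layers use a gate-balanced initialization: the attribute block of
#' each gate weight matrix is drawn with standard deviation
#' `gateGain / attrScale` (where `attrScale` is the root-mean-square norm of
#' the attribute vectors), so the pre-sigmoid attribute contribution has
#' standard deviation about `gateGain` from the start. A plain width-scaled
#' (Glorot) draw over the concatenated `[g; a]` input underweights the
#' attribute channel by an order of magnitude, leaving the gates numb to the
#' attributes; see the methods vignette for the analysis behind the default.
#'
#' @param encoderCfg an [encoderConfig()] list.
#' @param attrDim attribute dimension d^a, or 0 for attribute-free models.
#' @param seed integer seed (substream `"init"`).
#' @param attrScale root-mean-square attribute vector norm,
#'   `sqrt(mean(rowSums(A^2)))`; `NULL` falls back to the width-scaled draw.
#' @param gateGain target pre-sigmoid standard deviation of the attribute
#'   contribution (default 2).
#' @return list with elements `encoder` and `agda`.
#' @export
initAPNParams <- function(encoderCfg, attrDim, seed = 1L, attrScale = NULL,
                          gateGain = 2) {
  withSeed(seed, "init", {
    enc <- initEncoderParams(encoderCfg)
    agda <- if (attrDim > 0L) {
      ap <- agdaParams(encoderCfg$hiddenDim, attrDim)
      if (!is.null(attrScale) && attrScale > 0) {
        dg <- encoderCfg$hiddenDim
        ia <- dg + seq_len(attrDim)
        sdA <- gateGain / attrScale
        ap$Wl[ia, ] <- matrix(stats::rnorm(attrDim * dg, sd = sdA), attrDim)
        ap$Wg[ia, ] <- matrix(stats::rnorm(attrDim * dg, sd = sdA), attrDim)
      }
      ap
    } else {
      agdaParams(encoderCfg$hiddenDim, 1L, zero = TRUE)  # unused placeholder
    }
    list(encoder = enc, agda = agda)
  })
}

# Forward pass molecule indices -> final representations Z (one row per
# molecule), optionally keeping caches for the backward pass.
apnForward <- function(params, encoderCfg, molSet, attrs, idx, ablation,
                       training = FALSE) {
  batch <- batchGraphs(molGraphs(molSet)[idx])
  fwEnc <- encoderForward(params$encoder, batch, encoderCfg,
                          training = training)
  noAttr <- "A" %in% ablation || is.null(attrs)
  A <- if (noAttr) NULL else attrValues(attrs)[idx, , drop = FALSE]
  fwAgda <- agdaBatchForward(params$agda, fwEnc$H, A, batch$mol, batch$nMol,
                             noLocal = "L" %in% ablation,
                             noGlobal = "G" %in% ablation,
                             noAttr = noAttr)
  list(Z = fwAgda$Z, batch = batch, fwEnc = fwEnc, fwAgda = fwAgda)
}

# One training episode: loss + full parameter gradients.
episodeGrad <- function(params, encoderCfg, molSet, attrs, ep, cfg) {
  K <- length(ep$supportPos)
  idx <- c(ep$supportPos, ep$supportNeg, ep$query)
  fw <- apnForward(params, encoderCfg, molSet, attrs, idx, cfg$ablation,
                   training = TRUE)
  Z <- fw$Z
  iPos <- seq_len(K)
  iNeg <- K + seq_len(K)
  iQry <- 2L * K + seq_along(ep$query)
  weighted <- !("W" %in% cfg$ablation)
  similarity <- if ("S" %in% cfg$ablation) "neg_L2" else "dot"
  protos <- makePrototypes(Z[iPos, , drop = FALSE], Z[iNeg, , drop = FALSE],
                           weighted = weighted)
  probs <- classifyQuery(Z[iQry, , drop = FALSE], protos, similarity)
  loss <- episodeLoss(probs, ep$queryLabels)

  bwCls <- classifyBackward(Z[iQry, , drop = FALSE], protos, similarity,
                            probs, ep$queryLabels)
  dZ <- matrix(0, nrow(Z), ncol(Z))
  dZ[iQry, ] <- bwCls$dZ
  dZ[iPos, ] <- prototypeBackward(Z[iPos, , drop = FALSE], protos$pos,
                                  bwCls$dPPos, weighted)
  dZ[iNeg, ] <- prototypeBackward(Z[iNeg, , drop = FALSE], protos$neg,
                                  bwCls$dPNeg, weighted)
  bwAgda <- agdaBatchBackward(params$agda, fw$fwAgda, fw$batch$mol,
                              fw$batch$nMol, dZ, encoderCfg$hiddenDim)
  gEnc <- encoderBackward(params$encoder, fw$batch, encoderCfg, fw$fwEnc,
                          bwAgda$dH)
  list(loss = loss, grads = list(encoder = gEnc, agda = bwAgda$grads),
       probs = probs)
}

# Score a set of fixed episodes with the current parameters (no gradients).
scoreEpisodes <- function(params, encoderCfg, molSet, attrs, episodes, cfg) {
  aucs <- vapply(episodes, function(ep) {
    K <- length(ep$supportPos)
    idx <- c(ep$supportPos, ep$supportNeg, ep$query)
    Z <- apnForward(params, encoderCfg, molSet, attrs, idx,
                    cfg$ablation)$Z
    protos <- makePrototypes(Z[seq_len(K), , drop = FALSE],
                             Z[K + seq_len(K), , drop = FALSE],
                             weighted = !("W" %in% cfg$ablation))
    probs <- classifyQuery(Z[2L * K + seq_along(ep$query), , drop = FALSE],
                           protos,
                           if ("S" %in% cfg$ablation) "neg_L2" else "dot")
    rocAuc(probs, ep$queryLabels)
  }, numeric(1))
  mean(aucs)
}

#' Meta-train an attribute-guided prototype network
#'
#' Runs episodic training: each episode samples a training task uniformly,
#' draws a 2-way K-shot support set and a query set, forwards them through
#' encoder, attribute gating and weighted prototypes, and takes one Adam step
#' on the episodic cross-entropy. Every `evalEvery` episodes the mean ROC-AUC
#' on a fixed set of validation episodes (drawn from held-out molecules of
#' the training tasks) is checked; training stops when it has not improved
#' for `patience` consecutive checks, and the best-scoring parameters are
#' returned.
#'
#' @param molSet a [MoleculeSet-class] with featurized graphs.
#' @param attrs an [AttributeSet-class] aligned to `molSet`, or `NULL` for
#'   an attribute-free model (equivalent to ablation `"A"`).
#' @param split a [TaskSplit-class].
#' @param encoderCfg an [encoderConfig()] list.
#' @param cfg a [trainConfig()] list.
#' @param params optional initial parameters (default: fresh
#'   [initAPNParams()] from `cfg$seed`).
#' @return An [APNModel-class].
#' @export
metaTrain <- function(molSet, attrs, split, encoderCfg = encoderConfig(),
                      cfg = trainConfig(), params = NULL) {
  if (!length(split@trainTasks)) stop("split has no training tasks")
  if (!length(molGraphs(molSet))) stop("molSet has no featurized graphs")
  noAttr <- "A" %in% cfg$ablation || is.null(attrs)
  attrDim <- if (noAttr) 0L else ncol(attrValues(attrs))
  if (is.null(params)) {
    attrScale <- if (noAttr) NULL else
      sqrt(mean(rowSums(attrValues(attrs)^2)))
    params <- initAPNParams(encoderCfg, attrDim, cfg$seed,
                            attrScale = attrScale)
  }

  valEps <- withSeed(cfg$seed, "val", {
    tasks <- rep(split@trainTasks, length.out = max(cfg$valEpisodes, 1L))
    eps <- lapply(tasks, function(task) {
      pool <- if (length(split@valPools)) split@valPools[[task]] else NULL
      if (is.null(pool) || length(pool$pos) < 2L || length(pool$neg) < 2L) {
        sampleEpisode(split, task, cfg$K, cfg$q)
      } else {
        sampleEpisode(split, task, cfg$K, cfg$q, useVal = TRUE)
      }
    })
    Filter(Negate(is.null), eps)
  })

  opt <- adamInit(params, lr = cfg$lr)
  best <- list(params = params, score = -Inf)
  badChecks <- 0L
  log <- data.frame(episode = integer(), loss = numeric(),
                    valRocAuc = numeric())
  withSeed(cfg$seed, "train", {
    for (epi in seq_len(cfg$episodes)) {
      task <- sample(split@trainTasks, 1L)
      ep <- sampleEpisode(split, task, cfg$K, cfg$q)
      if (is.null(ep)) next
      eg <- episodeGrad(params, encoderCfg, molSet, attrs, ep, cfg)
      if (!is.finite(eg$loss) || !paramFinite(eg$grads)) {
        stop("training diverged at episode ", epi, " (non-finite loss)")
      }
      step <- adamStep(opt, params, eg$grads)
      opt <- step$state
      params <- step$params
      if (epi %% cfg$evalEvery == 0L || epi == cfg$episodes) {
        val <- if (length(valEps)) {
          scoreEpisodes(params, encoderCfg, molSet, attrs, valEps, cfg)
        } else NA_real_
        log[nrow(log) + 1L, ] <- list(epi, eg$loss, val)
        if (!is.na(val) && val > best$score + 1e-9) {
          best <- list(params = params, score = val)
          badChecks <- 0L
        } else {
          badChecks <- badChecks + 1L
          if (badChecks >= cfg$patience) break
        }
      }
    }
  })
  if (is.finite(best$score)) params <- best$params
  config <- c(encoderCfg, cfg,
              list(attrDim = attrDim,
                   attrName = if (noAttr) "none" else attrName(attrs)))
  new("APNModel", params = params, config = config, log = log)
}

#' Evaluate a model on meta-testing tasks
#'
#' For each test task and each of `runs` independently seeded runs, samples a
#' support set (2K molecules) and a query set (q molecules) from the task
#' pool, computes prototypes from the support, scores the queries, and
#' records ROC-AUC, F1 and PR-AUC. No parameters are updated. Queries whose
#' sampled labels are single-class are resampled (up to 20 retries).
#'
#' @param model an [APNModel-class].
#' @param molSet the [MoleculeSet-class] evaluated on.
#' @param attrs the [AttributeSet-class] used at training time (or `NULL`).
#' @param split a [TaskSplit-class] with at least one test task.
#' @param runs independent evaluation runs per task (default 20).
#' @param seed root seed for the evaluation substreams (default: the
#'   model's training seed).
#' @param K,q override the model's K and q (defaults: training values).
#' @return An [EvalReport-class].
#' @export
metaEvaluate <- function(model, molSet, attrs, split, runs = 20L,
                         seed = NULL, K = NULL, q = NULL) {
  if (!length(split@testTasks)) stop("split has no test tasks")
  cfg <- model@config
  if (is.null(seed)) seed <- cfg$seed
  if (is.null(K)) K <- cfg$K
  if (is.null(q)) q <- cfg$q
  encoderCfg <- cfg[c("arch", "nLayers", "hiddenDim", "dropout",
                      "pretrainedPath")]
  rows <- list()
  for (task in split@testTasks) {
    for (run in seq_len(runs)) {
      ep <- withSeed(seed, paste0("eval-", task, "-", run), {
        for (try in 1:20) {
          e <- sampleEpisode(split, task, K, q)
          if (!is.null(e) && length(unique(e$queryLabels)) == 2L) break
          e <- NULL
        }
        e
      })
      if (is.null(ep)) {
        warning("task '", task, "': could not sample a two-class query; ",
                "skipping run ", run, call. = FALSE)
        next
      }
      idx <- c(ep$supportPos, ep$supportNeg, ep$query)
      Z <- apnForward(model@params, encoderCfg, molSet, attrs, idx,
                      cfg$ablation)$Z
      protos <- makePrototypes(Z[seq_len(K), , drop = FALSE],
                               Z[K + seq_len(K), , drop = FALSE],
                               weighted = !("W" %in% cfg$ablation))
      probs <- classifyQuery(Z[2L * K + seq_along(ep$query), , drop = FALSE],
                             protos,
                             if ("S" %in% cfg$ablation) "neg_L2" else "dot")
      rows[[length(rows) + 1L]] <- data.frame(
        task = task, run = run,
        rocAuc = rocAuc(probs, ep$queryLabels),
        f1 = f1Score(probs, ep$queryLabels),
        prAuc = prAuc(probs, ep$queryLabels))
    }
  }
  new("EvalReport", perRun = do.call(rbind, rows), K = as.integer(K),
      q = as.integer(q), runs = as.integer(runs))
}

#' Summarize an evaluation report
#'
#' Means and standard deviations of ROC-AUC, F1 and PR-AUC, per task and
#' overall, recomputed from the stored per-run entries. `rowAverage` averages
#' a vector of per-dataset or per-task mean scores into a single headline
#' number, rounded to the given number of digits.
#'
#' @param report an [EvalReport-class].
#' @return list with `perTask` (data.frame) and `overall` (list).
#' @export
reportSummary <- function(report) {
  pr <- report@perRun
  agg <- function(df) {
    list(rocAuc = mean(df$rocAuc), rocAucSd = stats::sd(df$rocAuc),
         f1 = mean(df$f1), f1Sd = stats::sd(df$f1),
         prAuc = mean(df$prAuc), prAucSd = stats::sd(df$prAuc))
  }
  perTask <- do.call(rbind, lapply(split(pr, pr$task), function(d) {
    cbind(data.frame(task = d$task[1L], runs = nrow(d)),
          as.data.frame(agg(d)))
  }))
  rownames(perTask) <- NULL
  list(perTask = perTask, overall = agg(pr))
}

#' @rdname reportSummary
#' @param scores numeric vector of mean scores to average.
#' @param digits rounding applied to the result (default 2, matching the
#'   precision benchmark tables are printed at). Rounds half away from zero
#'   (the convention benchmark tables use), with a small epsilon guarding
#'   against binary floating-point representation of decimal halves.
#' @export
rowAverage <- function(scores, digits = 2L) {
  m <- mean(scores)
  floor(m * 10^digits + 0.5 + 1e-6) / 10^digits
}

#' Screen attributes by training one model per attribute
#'
#' Trains and evaluates one APN per attribute set under identical seeds and
#' configuration, and returns the attributes ranked by mean test ROC-AUC.
#' For dual attributes named `fp1_fp2` whose two singles are also in the
#' screen, the promotion/inhibition relationship and its heatmap encoding
#' are classified via [classifyRelationship()].
#'
#' @param molSet a [MoleculeSet-class].
#' @param attrList named list of [AttributeSet-class] objects (or `NULL`
#'   entries for the attribute-free baseline).
#' @param split a [TaskSplit-class].
#' @param encoderCfg an [encoderConfig()] list.
#' @param cfg a [trainConfig()] list.
#' @param runs evaluation runs per task (default 20).
#' @return list with `table` (ranked data.frame: attribute, rocAuc, sd) and
#'   `relationships` (data.frame with columns pair, relation, heatmap; empty
#'   when no complete pair is present).
#' @export
attributeScreen <- function(molSet, attrList, split,
                            encoderCfg = encoderConfig(),
                            cfg = trainConfig(), runs = 20L) {
  stopifnot(length(attrList) >= 1L, !is.null(names(attrList)))
  scores <- lapply(names(attrList), function(nm) {
    attrs <- attrList[[nm]]
    model <- metaTrain(molSet, attrs, split, encoderCfg, cfg)
    rep <- metaEvaluate(model, molSet, attrs, split, runs = runs)
    s <- reportSummary(rep)$overall
    data.frame(attribute = nm, rocAuc = s$rocAuc, sd = s$rocAucSd)
  })
  tab <- do.call(rbind, scores)
  tab <- tab[order(-tab$rocAuc), ]
  rownames(tab) <- NULL
  lookup <- stats::setNames(tab$rocAuc, tab$attribute)
  rel <- list()
  for (nm in names(attrList)) {
    parts <- strsplit(nm, "_", fixed = TRUE)[[1L]]
    if (length(parts) == 2L && all(parts %in% names(lookup))) {
      r <- classifyRelationship(lookup[[nm]], lookup[[parts[1L]]],
                                lookup[[parts[2L]]])
      rel[[length(rel) + 1L]] <- data.frame(pair = nm,
                                            relation = r$relation,
                                            heatmap = r$heatmap)
    }
  }
  list(table = tab,
       relationships = if (length(rel)) do.call(rbind, rel) else
         data.frame(pair = character(), relation = character(),
                    heatmap = numeric()))
}
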