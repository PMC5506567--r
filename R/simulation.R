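#' Simulation configuration
#'
#' Protocol of the pool-based active-learning simulation: start from a small
#' random initial sample, query in small batches, retrain after every batch,
#' and stop once the training set reaches a word budget that mimics a
#' fixed-length annotation session at about one word per second (120 min ~
#' 7,200 words).
#'
#' @param method Querying engine: \code{"random"}, \code{"uncertainty"} or
#'   \code{"cause"}.
#' @param schema Cluster scoring schema for CAUSE (default \code{"AUCS"}).
#' @param batchSize Sentences queried per iteration (default 5).
#' @param initialSize Size of the random initial sample (default 5).
#' @param stopWordBudget Stop after the first retrain whose training set
#'   holds at least this many words (default 7200).
#' @param kFolds Folds for [crossValidate()] (default 5).
#' @param seed Seed of the single shared RNG of a run.
#' @param crf List of tagger settings: \code{template}, \code{l2},
#'   \code{maxit}, and \code{warmMaxit} (optimiser cap for warm-started
#'   retrains after the first fit; defaults to \code{maxit}).
#' @param topics List of clustering settings used by [prepareClustering()]:
#'   \code{K}, \code{ldaIter}, \code{damping}.
#' @param lengthNormalize Use length-normalised least confidence.
#' @param annotatorNoise Probability that a newly labeled sentence receives
#'   one random span-boundary jitter (+/- one token) before training. The
#'   default 0 is the simulation assumption of an error-free annotator; the
#'   noise model supports robustness studies.
#' @return Classed list \code{SimulationConfig}.
#' @export
simulationConfig <- function(method = c("random", "uncertainty", "cause"),
                             schema = "AUCS", batchSize = 5, initialSize = 5,
                             stopWordBudget = 7200, kFolds = 5, seed = 1,
                             crf = list(), topics = list(),
                             lengthNormalize = FALSE, annotatorNoise = 0) {
  method <- match.arg(method)
  if (batchSize < 1) stop("batchSize must be >= 1")
  if (stopWordBudget < 0) stop("stopWordBudget must be >= 0")
  crf <- utils::modifyList(list(template = featureTemplate(), l2 = 1.0,
                                maxit = 100, warmMaxit = NULL), crf)
  if (is.null(crf$warmMaxit)) crf$warmMaxit <- crf$maxit
  topics <- utils::modifyList(list(K = 50, ldaIter = 300, damping = 0.9),
                              topics)
  structure(list(method = method, schema = schema,
                 batchSize = as.integer(batchSize),
                 initialSize = as.integer(initialSize),
                 stopWordBudget = as.numeric(stopWordBudget),
                 kFolds = as.integer(kFolds), seed = as.integer(seed),
                 crf = crf, topics = topics,
                 lengthNormalize = isTRUE(lengthNormalize),
                 annotatorNoise = as.numeric(annotatorNoise)),
            class = "SimulationConfig")
}

#' Precompute the CAUSE clustering for a pool
#'
#' The required preprocessing of the CAUSE engine, computed once per pool:
#' topic estimation on whole documents, sentence-level topic inference,
#' cosine similarities, affinity propagation. Topic estimation uses
#' unlabeled text only, so including the test documents (when supplied as
#' part of \code{textCorpus}) leaks no labels.
#'
#' @param pool [NERCorpus-class] pool of sentences to cluster.
#' @param cfg A [simulationConfig()] (for \code{topics} settings and seed).
#' @param textCorpus Corpus used for topic estimation (default: the pool).
#' @return List with \code{clustering} ([SentenceClustering-class]),
#'   \code{topics} (sentence topic matrix) and \code{model}
#'   ([TopicModel-class]).
#' @export
prepareClustering <- function(pool, cfg = simulationConfig(),
                              textCorpus = pool) {
  tm <- fitTopics(textCorpus, K = cfg$topics$K, seed = cfg$seed,
                  nIter = cfg$topics$ldaIter)
  theta <- inferSentenceTopics(tm, pool)
  sim <- cosineMatrix(theta)
  cl <- clusterPool(sim, damping = cfg$topics$damping)
  list(clustering = cl, topics = theta, model = tm)
}

#' Run one pool-based active-learning simulation
#'
#' The loop: train on the labeled set, evaluate span-level F on the held-out
#' test set, record the (cumulative training words, F) point, stop once the
#' budget is reached; otherwise decode the unlabeled pool for
#' least-confidence scores, query the next batch with the configured engine
#' (the simulated annotator reveals gold labels verbatim), and repeat. The
#' test set is never queried, trained on, or scored for uncertainty. A
#' single seeded RNG drives every stochastic choice of the run.
#'
#' @param pool,test Disjoint [NERCorpus-class] objects.
#' @param cfg A [simulationConfig()].
#' @param clustering A [SentenceClustering-class] over the pool; required
#'   when \code{cfg$method == "cause"} (see [prepareClustering()]).
#' @return List with \code{curve} ([LearningCurve-class]) and \code{log}
#'   (one row per queried sentence: iteration, method, schema, sid, cluster,
#'   LC score at selection, word count).
#' @export
runSimulation <- function(pool, test, cfg, clustering = NULL) {
  if (length(intersect(sentenceIds(pool), sentenceIds(test))))
    stop("pool and test sets must be disjoint")
  if (cfg$method == "cause" && is.null(clustering))
    stop("CAUSE requires a precomputed pool clustering; see prepareClustering()")
  tpl <- cfg$crf$template
  poolFS <- indexFeatures(pool, tpl)
  testFS <- indexFeatures(test, tpl, dict = poolFS$dict)
  sids <- sentenceIds(pool)
  words <- stats::setNames(wordCounts(pool), sids)
  labels <- nerLabels()
  goldList <- .goldLabelIds(bioEncode(pool), labels)
  goldKeys <- local({
    sp <- entitySpans(test)
    paste(sentenceIds(test)[sp$sentence], sp$start, sp$end, sp$type)
  })
  fScore <- function(predKeys) {
    tp <- sum(predKeys %in% goldKeys)
    prec <- if (length(predKeys)) tp / length(predKeys) else 0
    rec <- if (length(goldKeys)) tp / length(goldKeys) else 0
    if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }
  poolArr <- .assembleFS(poolFS)
  testArr <- .assembleFS(testFS)
  testSids <- sentenceIds(test)

  withSeed(cfg$seed, {
    state <- queryState(pool, clustering)
    init <- initialSample(state, cfg$initialSize,
                          mode = if (cfg$method == "cause") "cause"
                                 else "random")
    state <- markLabeled(state, init)
    goldList <- .annotatorNoise(goldList, match(init, sids),
                                cfg$annotatorNoise, labels)
    log <- data.frame(iteration = 0L, method = cfg$method,
                      schema = if (cfg$method == "cause") cfg$schema else NA,
                      sid = init,
                      cluster = if (nClusters(state@clustering) > 0)
                        unname(clusterLabels(state@clustering)[init])
                      else NA_integer_,
                      lc = NA_real_, words = unname(words[init]),
                      stringsAsFactors = FALSE)
    curveCost <- numeric(0); curveF <- numeric(0)
    weights <- NULL
    it <- 0L
    repeat {
      idx <- match(labeledIds(state), sids)
      weights <- .crfFitCore(poolFS, idx, goldList, labels, cfg$crf$l2,
                             maxit = if (it == 0L) cfg$crf$maxit
                                     else cfg$crf$warmMaxit,
                             init = weights)
      fmeas <- fScore(.decodeKeys(weights, labels, testFS, testArr, testSids,
                                  testFS$nTok))
      cumWords <- sum(words[labeledIds(state)])
      curveCost <- c(curveCost, cumWords)
      curveF <- c(curveF, fmeas)
      if (cumWords >= cfg$stopWordBudget) break
      if (!length(unlabeledIds(state))) {
        warning("pool exhausted before the word budget was reached")
        break
      }
      lcAll <- .lcCore(weights, labels, poolFS, poolArr, sids)
      if (cfg$lengthNormalize)
        lcAll <- 1 - (1 - lcAll)^(1 / pmax(1, poolFS$nTok))
      state <- setUncertainty(state, lcAll[unlabeledIds(state)])
      it <- it + 1L
      batch <- switch(cfg$method,
        random = selectBatchRandom(state, min(cfg$batchSize,
                                              length(unlabeledIds(state)))),
        uncertainty = suppressWarnings(
          selectBatchUncertainty(state, cfg$batchSize)),
        cause = selectBatchCause(state, cfg$batchSize, cfg$schema))
      log <- rbind(log, data.frame(
        iteration = it, method = cfg$method,
        schema = if (cfg$method == "cause") cfg$schema else NA,
        sid = batch,
        cluster = if (nClusters(state@clustering) > 0)
          unname(clusterLabels(state@clustering)[batch]) else NA_integer_,
        lc = unname(state@uncertainty[batch]),
        words = unname(words[batch]), stringsAsFactors = FALSE))
      state <- markLabeled(state, batch)
      goldList <- .annotatorNoise(goldList, match(batch, sids),
                                  cfg$annotatorNoise, labels)
    }
    list(curve = learningCurve(curveCost, curveF, "words"), log = log)
  })
}

#' Average learning curves on a common cost grid
#'
#' Each curve is linearly interpolated onto the union of all cost grids,
#' restricted to the cost range covered by every curve, and the
#' interpolated values are averaged pointwise.
#'
#' @param curves List of [LearningCurve-class] objects.
#' @return A [LearningCurve-class].
#' @export
averageCurves <- function(curves) {
  stopifnot(length(curves) >= 1)
  pts <- lapply(curves, curvePoints)
  lo <- max(vapply(pts, function(p) min(p$cost), 0))
  hi <- min(vapply(pts, function(p) max(p$cost), 0))
  if (hi < lo) stop("curves share no common cost range")
  grid <- sort(unique(unlist(lapply(pts, `[[`, "cost"))))
  grid <- grid[grid >= lo & grid <= hi]
  vals <- vapply(pts, function(p)
    stats::approx(p$cost, p$f, xout = grid, rule = 2)$y, numeric(length(grid)))
  f <- if (length(grid) == 1) mean(vals) else rowMeans(vals)
  learningCurve(grid, f, curves[[1]]@costUnit)
}

#' Cross-validated simulation
#'
#' Deduplicates and splits the corpus into \code{cfg$kFolds} folds; fold i
#' serves as the test set while the remaining folds form the querying pool.
#' For CAUSE, each pool is clustered independently (topic estimation on the
#' full deduplicated corpus text). The per-fold learning curves are averaged
#' with [averageCurves()].
#'
#' @param corpus An [NERCorpus-class].
#' @param cfg A [simulationConfig()].
#' @return List with \code{folds} (per-fold results of [runSimulation()])
#'   and \code{average} ([LearningCurve-class]).
#' @export
crossValidate <- function(corpus, cfg) {
  if (cfg$kFolds < 2) stop("kFolds must be >= 2")
  uniq <- dedupCorpus(corpus)
  folds <- dedupAndSplit(corpus, cfg$kFolds, cfg$seed)
  results <- lapply(seq_along(folds), function(i) {
    testIds <- folds[[i]]
    poolIds <- setdiff(sentenceIds(uniq), testIds)
    pool <- uniq[poolIds]
    test <- uniq[testIds]
    clustering <- NULL
    if (cfg$method == "cause")
      clustering <- prepareClustering(pool, cfg, textCorpus = uniq)$clustering
    runSimulation(pool, test, cfg, clustering)
  })
  list(folds = results,
       average = averageCurves(lapply(results, `[[`, "curve")))
}

# Simulated annotation-error model: with probability p per newly labeled
# sentence, one entity span boundary moves by one token (clamped to the
# sentence and to non-overlap; the move is dropped if no legal jitter exists).
.annotatorNoise <- function(goldList, idxs, p, labels) {
  if (p <= 0) return(goldList)
  for (i in idxs) {
    if (stats::runif(1) >= p) next
    tags <- labels[goldList[[i]] + 1L]
    sp <- bioDecode(tags)
    if (!nrow(sp)) next
    r <- sample.int(nrow(sp), 1)
    s <- sp$start[r]; e <- sp$end[r]
    if (sample(2L, 1) == 1L) s <- s + sample(c(-1L, 1L), 1)
    else e <- e + sample(c(-1L, 1L), 1)
    ok <- s >= 1 && e <= length(tags) && s <= e
    if (ok && nrow(sp) > 1) {
      other <- sp[-r, , drop = FALSE]
      ok <- all(e < other$start | s > other$end)
    }
    if (!ok) next
    sp$start[r] <- s; sp$end[r] <- e
    goldList[[i]] <- match(.spansToTags(length(tags), sp), labels) - 1L
  }
  goldList
}
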