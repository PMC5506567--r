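# small pool/test pair shared across simulation tests
simFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sp <- generatePoolAndTest(generatorConfig(nDocuments = 40, seed = 19),
                                testFraction = 0.25)
      cache <<- sp
    }
    cache
  }
})

fastCfg <- function(method, seed = 1, budget = 600, ...) {
  simulationConfig(method = method, seed = seed, stopWordBudget = budget,
                   crf = list(template = fastTemplate(), maxit = 60,
                              warmMaxit = 20), ...)
}

test_that("a zero budget produces only the initial-model point", {
  sp <- simFixture()
  res <- runSimulation(sp$pool, sp$test, fastCfg("random", budget = 0))
  expect_equal(nrow(curvePoints(res$curve)), 1)
  expect_equal(sum(res$log$words), curvePoints(res$curve)$cost)
})

test_that("simulation runs are reproducible and protocol-faithful", {
  sp <- simFixture()
  cfg <- fastCfg("random", seed = 23)
  r1 <- runSimulation(sp$pool, sp$test, cfg)
  r2 <- runSimulation(sp$pool, sp$test, cfg)
  expect_identical(curvePoints(r1$curve), curvePoints(r2$curve))
  expect_identical(r1$log, r2$log)
  p <- curvePoints(r1$curve)
  # costs strictly increasing; budget respected at the stop
  expect_true(all(diff(p$cost) > 0))
  expect_gte(p$cost[nrow(p)], 600)
  # every iteration after the initial sample queries exactly batchSize
  perIter <- table(r1$log$iteration)
  expect_true(all(perIter[-1] == 5))
  expect_equal(unname(perIter[1]), 5)  # initial sample
  # the test set is never queried
  expect_length(intersect(r1$log$sid, sentenceIds(sp$test)), 0)
  # curve point costs equal cumulative queried words at each retrain
  expect_equal(p$cost[nrow(p)], sum(r1$log$words))
})

test_that("uncertainty and CAUSE runs honour their querying engines", {
  sp <- simFixture()
  prep <- prepareClustering(sp$pool,
                            simulationConfig(seed = 2,
                                             topics = list(K = 8,
                                                           ldaIter = 120)),
                            textCorpus = sp$full)
  ru <- runSimulation(sp$pool, sp$test, fastCfg("uncertainty", seed = 4))
  rc <- runSimulation(sp$pool, sp$test, fastCfg("cause", seed = 4),
                      prep$clustering)
  # CAUSE batches never contain two sentences of one cluster
  byIter <- split(rc$log$cluster[rc$log$iteration > 0],
                  rc$log$iteration[rc$log$iteration > 0])
  expect_false(any(vapply(byIter, anyDuplicated, 0L) > 0))
  # uncertainty picks the top-LC sentences recorded in its own log
  expect_true(all(!is.na(ru$log$lc[ru$log$iteration > 0])))
  # clustering is mandatory for CAUSE
  expect_error(runSimulation(sp$pool, sp$test, fastCfg("cause")),
               "prepareClustering")
  # pool and test must be disjoint
  expect_error(runSimulation(sp$pool, sp$pool, fastCfg("random")),
               "disjoint")
})

test_that("annotator noise perturbs training labels but not the gold corpus", {
  sp <- simFixture()
  clean <- runSimulation(sp$pool, sp$test, fastCfg("random", seed = 31))
  noisy <- runSimulation(sp$pool, sp$test,
                         fastCfg("random", seed = 31, annotatorNoise = 0.5))
  # same queried sentences (noise affects labels, not the random engine
  # draws in lockstep) is not guaranteed, but both must complete and the
  # noisy run must not outperform the clean one at the end by construction
  pc <- curvePoints(clean$curve); pn <- curvePoints(noisy$curve)
  expect_gte(pc$f[nrow(pc)], pn$f[nrow(pn)] - 0.05)
})

test_that("curve averaging interpolates onto the common grid", {
  c1 <- learningCurve(c(0, 10, 20), c(0.1, 0.3, 0.5))
  # averaging identical curves is the identity
  avg <- averageCurves(list(c1, c1, c1))
  expect_equal(curvePoints(avg), curvePoints(c1))
  # two-curve average equals the mean of interpolated values at every point
  c2 <- learningCurve(c(5, 15, 25), c(0.2, 0.2, 0.6))
  avg2 <- averageCurves(list(c1, c2))
  p <- curvePoints(avg2)
  expect_equal(min(p$cost), 5)
  expect_equal(max(p$cost), 20)
  for (i in seq_len(nrow(p))) {
    v1 <- approx(c(0, 10, 20), c(0.1, 0.3, 0.5), p$cost[i])$y
    v2 <- approx(c(5, 15, 25), c(0.2, 0.2, 0.6), p$cost[i])$y
    expect_equal(p$f[i], mean(c(v1, v2)))
  }
  expect_error(averageCurves(list(c1, learningCurve(c(30, 40), c(0, 0)))),
               "common cost range")
})

test_that("cross-validation produces per-fold and averaged curves", {
  corp <- smallGenerated(nDocuments = 20, seed = 29)
  cfg <- simulationConfig(method = "random", seed = 3, stopWordBudget = 250,
                          kFolds = 2,
                          crf = list(template = fastTemplate(), maxit = 40,
                                     warmMaxit = 15))
  cv <- crossValidate(corp, cfg)
  expect_length(cv$folds, 2)
  for (fold in cv$folds)
    expect_gte(nrow(curvePoints(fold$curve)), 2)
  expect_s4_class(cv$average, "LearningCurve")
  # averaged curve lives on the intersection of fold cost ranges
  lo <- max(vapply(cv$folds, function(f) min(curvePoints(f$curve)$cost), 0))
  hi <- min(vapply(cv$folds, function(f) max(curvePoints(f$curve)$cost), 0))
  p <- curvePoints(cv$average)
  expect_true(all(p$cost >= lo & p$cost <= hi))
  expect_error(crossValidate(corp, simulationConfig(kFolds = 1)), "kFolds")
})

test_that("querying curves are invariant to pool sentence order", {
  sp <- simFixture()
  pool <- sp$pool
  set.seed(77)
  perm <- sample(nSentences(pool))
  poolPerm <- pool[perm]
  cfg <- fastCfg("uncertainty", seed = 9, budget = 400)
  r1 <- runSimulation(pool, sp$test, cfg)
  r2 <- runSimulation(poolPerm, sp$test, cfg)
  expect_equal(curvePoints(r1$curve)$cost, curvePoints(r2$curve)$cost)
  expect_equal(curvePoints(r1$curve)$f, curvePoints(r2$curve)$f,
               tolerance = 1e-6)
  expect_identical(sort(r1$log$sid), sort(r2$log$sid))
})
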