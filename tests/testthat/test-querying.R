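# build a query state over n sentences with the given cluster assignment
mkState <- function(n, clusters = NULL, lc = NULL) {
  sids <- sprintf("s%02d", seq_len(n))
  cl <- NULL
  if (!is.null(clusters)) {
    labels <- stats::setNames(as.integer(clusters), sids)
    ex <- vapply(seq_len(max(clusters)),
                 function(c) sids[which(clusters == c)[1]], "")
    cl <- new("SentenceClustering", labels = labels, exemplars = ex)
  }
  st <- queryState(sids, cl)
  if (!is.null(lc)) st <- setUncertainty(st, stats::setNames(lc, sids))
  st
}

test_that("cluster scores follow the MUCS/AUCS/RCS definitions", {
  st <- mkState(4, clusters = c(1, 1, 2, 2), lc = c(0.2, 0.8, 0.5, 0.1))
  cs <- scoreClusters(st, "MUCS")
  expect_equal(cs$score[cs$cluster == 1], 0.8)
  cs <- scoreClusters(st, "AUCS")
  expect_equal(cs$score[cs$cluster == 1], 0.5)
  expect_equal(cs$score[cs$cluster == 2], 0.3)
  # RCS reproducible under a seed
  r1 <- scoreClusters(st, "RCS", seed = 4)
  r2 <- scoreClusters(st, "RCS", seed = 4)
  expect_identical(r1, r2)
  # fully labeled cluster disappears from the scoring
  st2 <- markLabeled(st, c("s01", "s02"))
  cs2 <- scoreClusters(st2, "AUCS")
  expect_identical(cs2$cluster, 2L)
  # only unlabeled sentences contribute to the remaining cluster's score
  expect_equal(cs2$score, 0.3)
  st3 <- markLabeled(st2, c("s03", "s04"))
  expect_error(scoreClusters(st3, "AUCS"), "no unlabeled")
})

test_that("CAUSE selection walks clusters in score order", {
  st <- mkState(6, clusters = c(1, 1, 2, 2, 3, 3),
                lc = c(0.9, 0.9, 0.5, 0.5, 0.1, 0.1))
  # AUCS scores: c1 = 0.9, c2 = 0.5, c3 = 0.1
  expect_identical(selectBatchCause(st, 2), c("s01", "s03"))
  # x equals the number of eligible clusters: one pick from each
  got <- selectBatchCause(st, 3)
  cl <- clusterLabels(st@clustering)[got]
  expect_identical(sort(unname(cl)), 1:3)
  # representative is the max-LC unlabeled member
  st2 <- mkState(4, clusters = c(1, 1, 2, 2), lc = c(0.3, 0.7, 0.2, 0.1))
  expect_identical(selectBatchCause(st2, 1), "s02")
  # fewer clusters than x: remainder filled by plain LC ranking
  got <- selectBatchCause(st2, 3)
  expect_length(got, 3)
  expect_length(unique(got), 3)
  expect_error(selectBatchCause(st2, 0), "batch size")
})

test_that("CAUSE matches the brute-force reference on random pools", {
  for (trial in 1:25) {
    set.seed(trial)
    n <- sample(8:30, 1)
    k <- sample(2:6, 1)
    clusters <- sample(k, n, replace = TRUE)
    clusters[seq_len(k)] <- seq_len(k)    # every cluster inhabited
    lc <- round(runif(n), 2)              # rounding forces ties
    st <- mkState(n, clusters, lc)
    labeled <- sprintf("s%02d", sample(n, sample(0:(n - 6), 1)))
    if (length(labeled)) st <- markLabeled(st, labeled)
    x <- sample(1:6, 1)
    mine <- selectBatchCause(st, x, schema = "AUCS")
    ref <- causeReference(unlabeledIds(st),
                          clusterLabels(st@clustering),
                          st@uncertainty, x, "AUCS")
    expect_identical(mine, ref)
    mineM <- selectBatchCause(st, x, schema = "MUCS")
    refM <- causeReference(unlabeledIds(st),
                           clusterLabels(st@clustering),
                           st@uncertainty, x, "MUCS")
    expect_identical(mineM, refM)
  }
})

test_that("uncertainty selection is a stable top-x sort", {
  st <- mkState(3, lc = c(0.9, 0.1, 0.5))
  expect_identical(selectBatchUncertainty(st, 2), c("s01", "s03"))
  # all-equal scores: first x by ascending sentence id
  st2 <- mkState(4, lc = rep(0.5, 4))
  expect_identical(selectBatchUncertainty(st2, 2), c("s01", "s02"))
  # oversized request returns everything with a warning
  expect_warning(got <- selectBatchUncertainty(st2, 9), "exceeds")
  expect_length(got, 4)
  # sort oracle over many random score sets
  for (trial in 1:200) {
    set.seed(trial)
    n <- sample(3:25, 1)
    lc <- round(runif(n), 1)
    st <- mkState(n, lc = lc)
    x <- sample(seq_len(n), 1)
    sids <- sprintf("s%02d", seq_len(n))
    ref <- sids[order(-lc, sids)][seq_len(x)]
    expect_identical(selectBatchUncertainty(st, x), ref)
  }
})

test_that("random selection is uniform, seeded, and duplicate-free", {
  st <- mkState(10)
  expect_identical(selectBatchRandom(st, 3, seed = 7),
                   selectBatchRandom(st, 3, seed = 7))
  expect_warning(perm <- selectBatchRandom(st, 11, seed = 1), "exceeds")
  expect_setequal(perm, unlabeledIds(st))
  # first-pick frequency over 10,000 seeded draws
  first <- vapply(1:10000, function(s) selectBatchRandom(st, 1, seed = s), "")
  freq <- table(first) / 10000
  expect_true(all(abs(freq - 0.1) < 0.01))
})

test_that("initial sampling covers clusters without replacement", {
  st <- mkState(10, clusters = rep(1:5, each = 2))
  got <- initialSample(st, 5, mode = "cause", seed = 3)
  expect_identical(sort(unname(clusterLabels(st@clustering)[got])), 1:5)
  # n beyond the cluster count cycles through clusters again
  got8 <- initialSample(st, 8, mode = "cause", seed = 3)
  expect_length(unique(got8), 8)
  expect_identical(initialSample(st, 4, mode = "random", seed = 5),
                   initialSample(st, 4, mode = "random", seed = 5))
  expect_error(initialSample(st, 11, mode = "random", seed = 1), "larger")
  # cluster first-pick frequency roughly uniform
  first <- vapply(1:5000, function(s)
    clusterLabels(st@clustering)[initialSample(st, 1, mode = "cause",
                                               seed = s)[1]], 0L)
  freq <- table(first) / 5000
  expect_true(all(abs(freq - 0.2) < 0.02))
})

test_that("selector invariants hold", {
  # all picks unlabeled, no duplicates
  set.seed(99)
  st <- mkState(20, clusters = sample(4, 20, replace = TRUE),
                lc = runif(20))
  st <- markLabeled(st, c("s01", "s05"))
  for (batch in list(selectBatchCause(st, 4),
                     selectBatchUncertainty(st, 4),
                     selectBatchRandom(st, 4, seed = 2))) {
    expect_true(all(batch %in% unlabeledIds(st)))
    expect_false(any(duplicated(batch)))
  }
  # one covering cluster: CAUSE degenerates to uncertainty for x = 1
  st1 <- mkState(8, clusters = rep(1, 8), lc = runif(8))
  expect_identical(selectBatchCause(st1, 1),
                   selectBatchUncertainty(st1, 1))
  # labeled/unlabeled stay a partition
  st2 <- markLabeled(st, selectBatchRandom(st, 3, seed = 1))
  expect_length(intersect(labeledIds(st2), unlabeledIds(st2)), 0)
  expect_setequal(c(labeledIds(st2), unlabeledIds(st2)),
                  c(labeledIds(st), unlabeledIds(st)))
  expect_error(markLabeled(st2, "s01"), "unlabeled")
})
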