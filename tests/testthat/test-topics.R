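test_that("topic estimation recovers the generating topics", {
  corp <- dedupCorpus(smallGenerated(nDocuments = 60, seed = 7, nTopics = 5))
  tm <- fitTopics(corp, K = 5, seed = 3, nIter = 150)
  expect_true(validObject(tm))
  # determinism under the seed
  tm2 <- fitTopics(corp, K = 5, seed = 3, nIter = 150)
  expect_identical(tm@phi, tm2@phi)
  # every sentence lands on the learned topic matching its generating topic:
  # the (generating topic x argmax) contingency is a permutation matrix
  th <- inferSentenceTopics(tm, corp)
  gen <- sentenceData(corp)$topic
  tab <- table(gen, apply(th, 1, which.max))
  purity <- sum(apply(tab, 1, max)) / sum(tab)
  expect_gt(purity, 0.8)
  # top-10 words of each learned topic dominated by one generating topic's
  # lexicon: majority of sentences containing them share that topic
  expect_equal(dim(tab), c(5L, 5L))
})

test_that("degenerate and invalid topic inputs are handled", {
  tiny <- NERCorpus(list(c("word", "another")))
  tm <- fitTopics(tiny, K = 2, seed = 1, nIter = 20)
  expect_true(validObject(tm))
  expect_error(fitTopics(tiny, K = 10, seed = 1), "vocabulary")
  expect_error(fitTopics(tiny, K = 1, seed = 1), "K must be")
  expect_error(fitTopics(NERCorpus(list(), doc = character(0)), K = 2),
               "at least one")
})

test_that("sentence inference yields proper probability vectors", {
  corp <- dedupCorpus(smallGenerated(nDocuments = 40, seed = 11, nTopics = 4))
  tm <- fitTopics(corp, K = 4, seed = 5, nIter = 100)
  th <- inferSentenceTopics(tm, corp)
  expect_equal(unname(rowSums(th)), rep(1, nrow(th)), tolerance = 1e-8)
  expect_true(all(th >= 0))
  # all-OOV sentence: uniform fallback, flagged
  v <- inferSentenceTopics(tm, c("zzzz", "qqqq"))
  expect_true(attr(v, "oov"))
  expect_equal(as.numeric(v), rep(0.25, 4))
  # in-vocabulary sentence is not flagged
  v2 <- inferSentenceTopics(tm, as.list(sentenceTokens(corp))[[1]])
  expect_false(attr(v2, "oov"))
})

test_that("cosine similarity matches hand-computed values", {
  m <- rbind(a = c(0.6, 0.8), b = c(0.8, 0.6), c = c(0.6, 0.8))
  s <- cosineMatrix(m)
  expect_equal(s["a", "b"], 0.96)
  expect_equal(s["a", "c"], 1)
  expect_equal(s, t(s))
  expect_equal(diag(s), c(a = 1, b = 1, c = 1))
  onehot <- diag(3)
  expect_equal(cosineMatrix(onehot)[1, 2], 0)
  expect_error(cosineMatrix(rbind(c(1, 0), c(0, 0))), "zero vector")
  expect_error(cosineMatrix(m[1, , drop = FALSE]), "two vectors")
})

test_that("affinity propagation separates block-structured similarities", {
  v <- rbind(matrix(rep(c(1, 0, 0), 4), ncol = 3, byrow = TRUE),
             matrix(rep(c(0, 1, 0), 5), ncol = 3, byrow = TRUE))
  rownames(v) <- sprintf("s%02d", 1:9)
  cl <- clusterPool(cosineMatrix(v))
  expect_equal(nClusters(cl), 2)
  lab <- clusterLabels(cl)
  expect_length(unique(lab[1:4]), 1)
  expect_length(unique(lab[5:9]), 1)
  expect_false(lab[1] == lab[5])
  # exemplar of cluster c carries label c
  expect_true(validObject(cl))
})

test_that("clustering of a templated pool has recoverable structure", {
  corp <- dedupCorpus(smallGenerated(nDocuments = 60, seed = 17, nTopics = 8,
                                     templatesPerTopic = 1))
  tm <- fitTopics(corp, K = 8, seed = 2, nIter = 150)
  th <- inferSentenceTopics(tm, corp)
  cl <- clusterPool(cosineMatrix(th))
  expect_setequal(names(clusterLabels(cl)), sentenceIds(corp))
  tplId <- sentenceData(corp)$template
  purity <- sum(tapply(seq_along(tplId), clusterLabels(cl),
                       function(ix) max(table(tplId[ix])))) / length(tplId)
  expect_gte(purity, 0.6)
  # permuting the input yields the same partition up to relabelling
  perm <- sample(nrow(th))
  cl2 <- clusterPool(cosineMatrix(th[perm, ]))
  l1 <- clusterLabels(cl)[sentenceIds(corp)]
  l2 <- clusterLabels(cl2)[sentenceIds(corp)]
  expect_equal(length(unique(paste(l1, l2))), length(unique(l1)))
  expect_equal(length(unique(l1)), length(unique(l2)))
})

test_that("affinity propagation agrees with an independent implementation", {
  set.seed(8)
  pts <- rbind(matrix(rnorm(20, mean = 0, sd = 0.05), ncol = 2),
               matrix(rnorm(20, mean = 3, sd = 0.05), ncol = 2))
  s <- -as.matrix(dist(pts))^2
  rownames(s) <- colnames(s) <- sprintf("p%02d", 1:20)
  pref <- median(s[row(s) != col(s)])
  ours <- clusterPool(s, preference = pref, damping = 0.9)
  # sklearn AffinityPropagation as the independent oracle
  csv <- tempfile(fileext = ".csv")
  write.table(s, csv, sep = ",", row.names = FALSE, col.names = FALSE)
  out <- system2("python", c("-c", shQuote(paste0(
    "import numpy as np; from sklearn.cluster import AffinityPropagation; ",
    "S = np.loadtxt('", csv, "', delimiter=','); ",
    "ap = AffinityPropagation(affinity='precomputed', damping=0.9, ",
    "preference=", pref, ", random_state=0).fit(S); ",
    "print(' '.join(map(str, ap.labels_)))"))), stdout = TRUE)
  theirs <- as.integer(strsplit(tail(out, 1), " ")[[1]])
  l1 <- unname(clusterLabels(ours))
  # same partition up to relabelling
  expect_equal(length(unique(paste(l1, theirs))), length(unique(l1)))
  expect_equal(length(unique(l1)), length(unique(theirs)))
})

test_that("clustering sidecar round-trips", {
  corp <- dedupCorpus(smallGenerated(nDocuments = 20, seed = 3, nTopics = 4))
  tm <- fitTopics(corp, K = 4, seed = 2, nIter = 80)
  th <- inferSentenceTopics(tm, corp)
  cl <- clusterPool(cosineMatrix(th))
  f <- tempfile(fileext = ".tsv")
  writeClustering(cl, th, f)
  back <- readClustering(f)
  expect_identical(clusterLabels(back$clustering), clusterLabels(cl))
  expect_identical(clusterExemplars(back$clustering), clusterExemplars(cl))
  expect_equal(back$topics[rownames(th), ], th, tolerance = 1e-6,
               ignore_attr = TRUE)
})
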