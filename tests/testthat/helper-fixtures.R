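# Small corpora and independent oracles used across the suite.

# three-sentence hand corpus with known spans
tinyCorpus <- function() {
  NERCorpus(
    list(c("Dulcolax", "10", "mg"),
         c("denies", "chest", "pain", "today", "."),
         c("hematocrit", "was", "40", ".")),
    spans = data.frame(sentence = c(1, 2, 3),
                       start = c(1, 2, 1),
                       end = c(3, 3, 1),
                       type = c("treatment", "problem", "test")),
    doc = c("d1", "d1", "d2"))
}

smallGenerated <- function(nDocuments = 30, seed = 5, ...) {
  generateCorpus(generatorConfig(nDocuments = nDocuments, seed = seed, ...))
}

# reduced feature template used in fast tests
fastTemplate <- function() featureTemplate(window = 1, affixes = FALSE)

# --- independent oracles ------------------------------------------------------

# exhaustive path enumeration for a CRF model on one sentence (<= 3-4 tokens):
# returns the maximum conditional path probability and the argmax path,
# applying the same BIO legality rule from the label names.
bruteForcePathProb <- function(model, tokens) {
  labels <- model@labels
  L <- length(labels)
  w <- model@weights
  FF <- length(model@features)
  tpl <- structure(model@template, class = "FeatureTemplate")
  bags <- extractFeatures(tokens, tpl)
  emit <- sapply(seq_len(L), function(y)
    sapply(bags, function(b) {
      ids <- match(b, model@features)
      ids <- ids[!is.na(ids)]
      if (length(ids)) sum(w[(ids - 1) * L + y]) else 0
    }))
  if (is.null(dim(emit))) emit <- matrix(emit, nrow = 1)
  trans <- matrix(w[FF * L + seq_len(L * L)], L, L)
  startw <- w[FF * L + L * L + seq_len(L)]
  stopw <- w[FF * L + L * L + L + seq_len(L)]
  okStart <- !startsWith(labels, "I-")
  okTrans <- function(a, b) {
    if (!startsWith(labels[b], "I-")) return(TRUE)
    ty <- substring(labels[b], 3)
    labels[a] %in% paste0(c("B-", "I-"), ty)
  }
  n <- length(tokens)
  paths <- as.matrix(expand.grid(rep(list(seq_len(L)), n)))
  scores <- apply(paths, 1, function(p) {
    if (!okStart[p[1]]) return(-Inf)
    s <- startw[p[1]] + emit[1, p[1]]
    if (n > 1) for (t in 2:n) {
      if (!okTrans(p[t - 1], p[t])) return(-Inf)
      s <- s + trans[p[t - 1], p[t]] + emit[t, p[t]]
    }
    s + stopw[p[n]]
  })
  m <- max(scores)
  logZ <- m + log(sum(exp(scores - m)))
  list(prob = exp(m - logZ),
       path = labels[paths[which.max(scores), ]],
       allProbs = exp(scores - logZ))
}

# literal reference implementation of the CAUSE querying steps: score each
# cluster over its unlabeled sentences, take the top-x clusters, and pick the
# max-LC unlabeled sentence of each; ties by ascending sentence id.
causeReference <- function(unlabeled, clusterOf, lc, x, schema = "AUCS") {
  cl <- clusterOf[unlabeled]
  byCl <- split(unlabeled, cl)
  score <- vapply(byCl, function(ss) {
    if (schema == "MUCS") max(lc[ss]) else mean(lc[ss])
  }, 0)
  ord <- names(byCl)[order(-score, as.numeric(names(byCl)))]
  top <- ord[seq_len(min(x, length(ord)))]
  picks <- vapply(top, function(cc) {
    ss <- byCl[[cc]]
    ss[order(-lc[ss], ss)][1]
  }, "")
  if (length(picks) < x) {
    rest <- setdiff(unlabeled, picks)
    fill <- rest[order(-lc[rest], rest)]
    picks <- c(picks, fill[seq_len(min(x - length(picks), length(fill)))])
  }
  unname(picks)
}

# exhaustive bipartite span matching: maximum number of gold spans matched
# one-to-one by identical predicted spans
matchingOracle <- function(goldSpans, predSpans) {
  if (nrow(goldSpans) == 0 || nrow(predSpans) == 0) return(0L)
  key <- function(d) paste(d$sentence, d$start, d$end, d$type)
  gk <- key(goldSpans); pk <- key(predSpans)
  best <- 0L
  recurse <- function(gLeft, pLeft, matched) {
    best <<- max(best, matched)
    if (!length(gLeft) || !length(pLeft)) return()
    g <- gLeft[1]
    # either leave g unmatched ...
    recurse(gLeft[-1], pLeft, matched)
    # ... or match it to an identical predicted span
    hit <- which(pLeft == g)
    if (length(hit))
      recurse(gLeft[-1], pLeft[-hit[1]], matched + 1L)
  }
  recurse(gk, pk, 0L)
  best
}

# common-grid comparison of two learning curves
gridDominance <- function(a, b) {
  pa <- curvePoints(a); pb <- curvePoints(b)
  lo <- max(min(pa$cost), min(pb$cost))
  hi <- min(max(pa$cost), max(pb$cost))
  grid <- sort(unique(c(pa$cost, pb$cost)))
  grid <- grid[grid >= lo & grid <= hi]
  fa <- stats::approx(pa$cost, pa$f, grid)$y
  fb <- stats::approx(pb$cost, pb$f, grid)$y
  mean(fa >= fb)
}
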