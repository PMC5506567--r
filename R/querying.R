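#' Create an active-learning query state
#'
#' @param pool Sentence ids of the querying pool, or an [NERCorpus-class].
#' @param clustering Optional [SentenceClustering-class] over the pool
#'   (required by the CAUSE selectors).
#' @return A [QueryState-class] with everything unlabeled.
#' @export
queryState <- function(pool, clustering = NULL) {
  sids <- if (is(pool, "NERCorpus")) sentenceIds(pool) else as.character(pool)
  if (is.null(clustering))
    clustering <- new("SentenceClustering",
                      labels = stats::setNames(integer(0), character(0)),
                      exemplars = character(0))
  else if (!all(sids %in% names(clusterLabels(clustering))))
    stop("clustering must cover every pool sentence")
  new("QueryState", labeled = character(0), unlabeled = sids,
      uncertainty = stats::setNames(numeric(0), character(0)),
      clustering = clustering)
}

setMethod("show", "QueryState", function(object) {
  cat(sprintf("QueryState: %d labeled / %d unlabeled%s\n",
              length(object@labeled), length(object@unlabeled),
              if (nClusters(object@clustering) > 0)
                sprintf(", %d clusters", nClusters(object@clustering))
              else ""))
})

#' Query-state accessors and updates
#'
#' @param state A [QueryState-class].
#' @param sids Sentence ids to move from the unlabeled to the labeled set.
#' @param scores Named least-confidence scores (at least the unlabeled set).
#' @return Updated [QueryState-class] (these are pure functions).
#' @name query-state
NULL

#' @rdname query-state
#' @export
labeledIds <- function(state) state@labeled

#' @rdname query-state
#' @export
unlabeledIds <- function(state) state@unlabeled

#' @rdname query-state
#' @export
markLabeled <- function(state, sids) {
  if (!all(sids %in% state@unlabeled))
    stop("can only label sentences from the unlabeled set")
  new("QueryState", labeled = c(state@labeled, sids),
      unlabeled = setdiff(state@unlabeled, sids),
      uncertainty = state@uncertainty, clustering = state@clustering)
}

#' @rdname query-state
#' @export
setUncertainty <- function(state, scores) {
  new("QueryState", labeled = state@labeled, unlabeled = state@unlabeled,
      uncertainty = scores, clustering = state@clustering)
}

.lcFor <- function(state, sids) {
  lc <- state@uncertainty[sids]
  if (anyNA(lc))
    stop("uncertainty scores missing for some unlabeled sentences")
  lc
}

#' Score clusters by the uncertainty of their unlabeled sentences
#'
#' Cluster scoring schemas: \code{MUCS} assigns each cluster the maximum
#' least-confidence score among its sentences, \code{AUCS} the average, and
#' \code{RCS} a random score (all clusters equally important). Only
#' still-unlabeled sentences contribute, and clusters whose sentences are all
#' labeled are excluded.
#'
#' @param state A [QueryState-class] with uncertainty scores and clustering.
#' @param schema One of \code{"AUCS"}, \code{"MUCS"}, \code{"RCS"}.
#' @param seed Optional seed for \code{RCS}; \code{NULL} draws from the
#'   current RNG stream.
#' @return \code{data.frame} with columns \code{cluster}, \code{score},
#'   \code{schema}, one row per eligible cluster, in cluster-id order.
#' @export
scoreClusters <- function(state, schema = c("AUCS", "MUCS", "RCS"),
                          seed = NULL) {
  schema <- match.arg(schema)
  un <- state@unlabeled
  if (!length(un)) stop("no unlabeled sentences left to score")
  if (nClusters(state@clustering) == 0) stop("query state has no clustering")
  cl <- clusterLabels(state@clustering)[un]
  eligible <- sort(unique(cl))
  score <- if (schema == "RCS") {
    r <- if (is.null(seed)) stats::runif(length(eligible))
         else withSeed(seed, stats::runif(length(eligible)))
    stats::setNames(r, eligible)
  } else {
    lc <- .lcFor(state, un)
    agg <- if (schema == "MUCS") vapply(split(lc, cl), max, 0)
           else vapply(split(lc, cl), mean, 0)
    agg[as.character(eligible)]
  }
  data.frame(cluster = eligible, score = unname(score), schema = schema,
             stringsAsFactors = FALSE)
}

#' CAUSE batch selection
#'
#' Cluster ranking followed by representative sampling: clusters are ranked
#' by their uncertainty score (default schema AUCS, the best-performing
#' variant), the top \code{x} clusters are selected, and from each the
#' unlabeled sentence with the highest least-confidence score is taken as
#' the cluster representative. The batch is ordered by cluster rank and
#' contains at most one sentence per cluster. If fewer than \code{x}
#' clusters still hold unlabeled sentences, the remainder is filled by plain
#' least-confidence ranking (graceful degradation near pool exhaustion).
#' Ties (equal cluster score or equal LC) break by ascending id.
#'
#' @param state A [QueryState-class] with uncertainty scores and clustering.
#' @param x Batch size (>= 1).
#' @param schema Cluster scoring schema (default \code{"AUCS"}).
#' @param seed Optional seed for \code{RCS} scoring.
#' @return Ordered character vector of at most \code{x} sentence ids.
#' @export
selectBatchCause <- function(state, x, schema = "AUCS", seed = NULL) {
  if (x <= 0) stop("batch size must be >= 1")
  un <- state@unlabeled
  if (!length(un)) stop("no unlabeled sentences left")
  cs <- scoreClusters(state, schema, seed)
  ord <- cs$cluster[.orderByScoreThenId(cs$score, cs$cluster)]
  top <- ord[seq_len(min(x, length(ord)))]
  cl <- clusterLabels(state@clustering)[un]
  lc <- .lcFor(state, un)
  picks <- vapply(top, function(cc) {
    members <- un[cl == cc]
    members[.orderByScoreThenId(lc[members], members)][1]
  }, "")
  if (length(picks) < x) {
    rest <- setdiff(un, picks)
    if (length(rest)) {
      fill <- rest[.orderByScoreThenId(lc[rest], rest)]
      picks <- c(picks, fill[seq_len(min(x - length(picks), length(fill)))])
    }
  }
  unname(picks)
}

#' Uncertainty (least-confidence) batch selection
#'
#' @param state A [QueryState-class] with uncertainty scores.
#' @param x Batch size (>= 1).
#' @return The top \code{x} unlabeled sentence ids by descending
#'   least-confidence score, ties broken by ascending id. Requests beyond
#'   the unlabeled set return everything with a warning.
#' @export
selectBatchUncertainty <- function(state, x) {
  if (x <= 0) stop("batch size must be >= 1")
  un <- state@unlabeled
  if (!length(un)) stop("no unlabeled sentences left")
  lc <- .lcFor(state, un)
  ord <- un[.orderByScoreThenId(lc, un)]
  if (x > length(ord)) {
    warning("batch size exceeds the unlabeled set; returning all")
    return(ord)
  }
  ord[seq_len(x)]
}

#' Random (passive) batch selection
#'
#' Uniform sampling without replacement from the unlabeled set.
#'
#' @param state A [QueryState-class].
#' @param x Batch size (>= 1).
#' @param seed Optional seed; \code{NULL} draws from the current RNG stream
#'   (one shared seeded generator per simulation run).
#' @return Ordered character vector of sentence ids.
#' @export
selectBatchRandom <- function(state, x, seed = NULL) {
  if (x <= 0) stop("batch size must be >= 1")
  un <- state@unlabeled
  if (!length(un)) stop("no unlabeled sentences left")
  if (x > length(un)) {
    warning("batch size exceeds the unlabeled set; returning a permutation")
    x <- length(un)
  }
  un <- sort(un)   # canonical order: draws do not depend on pool ordering
  draw <- function() un[sample.int(length(un), x)]
  if (is.null(seed)) draw() else withSeed(seed, draw())
}

#' Initial sample before any model exists
#'
#' \code{mode = "random"}: uniform sentences. \code{mode = "cause"}: repeat
#' n times — pick a uniformly random cluster (without replacement across the
#' draws while unexhausted clusters remain), then a uniformly random
#' unlabeled sentence within it.
#'
#' @param state A [QueryState-class] (no uncertainty needed).
#' @param n Number of sentences (<= pool size).
#' @param mode \code{"random"} or \code{"cause"}.
#' @param seed Optional seed; \code{NULL} uses the current RNG stream.
#' @return Ordered character vector of \code{n} sentence ids.
#' @export
initialSample <- function(state, n, mode = c("random", "cause"),
                          seed = NULL) {
  mode <- match.arg(mode)
  un <- sort(state@unlabeled)  # canonical order for pool-order invariance
  if (n > length(un)) stop("initial sample larger than the pool")
  draw <- function() {
    if (mode == "random") return(un[sample.int(length(un), n)])
    if (nClusters(state@clustering) == 0)
      stop("cause-mode initial sampling requires a clustering")
    cl <- clusterLabels(state@clustering)[un]
    picks <- character(0)
    avail <- unique(cl)
    for (i in seq_len(n)) {
      remaining <- setdiff(un, picks)
      clRem <- cl[remaining]
      eligible <- intersect(avail, clRem)
      if (!length(eligible)) {           # all clusters used once: reset
        avail <- unique(clRem)
        eligible <- avail
      }
      cc <- eligible[sample.int(length(eligible), 1)]
      members <- remaining[clRem == cc]
      picks <- c(picks, members[sample.int(length(members), 1)])
      avail <- setdiff(avail, cc)
    }
    picks
  }
  if (is.null(seed)) draw() else withSeed(seed, draw())
}
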