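#' Estimate a topic model on whole documents
#'
#' Latent Dirichlet allocation by collapsed Gibbs sampling, estimated on
#' document-level samples (each document is the concatenation of its
#' sentences' lowercased tokens): document-level estimation yields more
#' coherent topics than sentence-level estimation on short clinical
#' sentences. Only the unlabeled text is used — entity annotations never
#' enter the model. Deterministic under \code{seed}.
#'
#' @param x An [NERCorpus-class]; its document structure defines the
#'   estimation samples.
#' @param K Number of topics (>= 2).
#' @param seed Integer seed.
#' @param nIter Gibbs sweeps (default 300).
#' @param alpha Document-topic Dirichlet hyperparameter (default 50/K).
#' @param eta Topic-word Dirichlet hyperparameter (default 0.1).
#' @return A [TopicModel-class].
#' @export
fitTopics <- function(x, K, seed = 1, nIter = 300, alpha = 50 / K,
                      eta = 0.1) {
  if (nSentences(x) < 1) stop("topic estimation needs at least one document")
  if (K < 2) stop("K must be >= 2")
  docs <- documents(x)
  toks <- as.list(sentenceTokens(x))
  idx <- split(seq_len(nSentences(x)),
               factor(docIds(x), levels = unique(docIds(x))))
  docWords <- lapply(idx, function(i)
    tolower(unlist(toks[i], use.names = FALSE)))
  vocab <- unique(unlist(docWords, use.names = FALSE))
  if (K > length(vocab)) stop("K exceeds the vocabulary size")
  words <- match(unlist(docWords, use.names = FALSE), vocab) - 1L
  docPtr <- c(0L, cumsum(lengths(docWords)))
  res <- withSeed(seed, .lda_gibbs(as.integer(words), as.integer(docPtr),
                                   as.integer(K), length(vocab),
                                   alpha, eta, as.integer(nIter)))
  phi <- res$phi
  colnames(phi) <- vocab
  new("TopicModel", phi = phi, vocab = vocab, alpha = alpha,
      fingerprint = sprintf("docs=%d tokens=%d vocab=%d K=%d iter=%d",
                            length(docWords), length(words), length(vocab),
                            K, nIter))
}

setMethod("show", "TopicModel", function(object) {
  cat(sprintf("TopicModel: K=%d topics over %d terms (%s)\n",
              nrow(object@phi), length(object@vocab), object@fingerprint))
})

#' @describeIn fitTopics Number of topics of a fitted model.
#' @param model A [TopicModel-class].
#' @export
nTopics <- function(model) nrow(model@phi)

#' Infer topic vectors for sentences
#'
#' Deterministic fold-in under the fitted topic-word distributions: an EM
#' fixed point for each sentence's topic mixture. Out-of-vocabulary tokens
#' are ignored; a sentence that is entirely out of vocabulary receives the
#' uniform vector and is flagged in the \code{"oov"} attribute.
#'
#' @param model A [TopicModel-class].
#' @param x An [NERCorpus-class], or a character vector of tokens for a
#'   single sentence.
#' @param nIter Fixed-point iterations (default 50).
#' @return A numeric matrix (sentences x K, rows named by sentence id and
#'   summing to 1) with logical attribute \code{"oov"}; for a single token
#'   vector, a length-K probability vector.
#' @export
inferSentenceTopics <- function(model, x, nIter = 50) {
  single <- is.character(x)
  toks <- if (single) list(x) else as.list(sentenceTokens(x))
  ids <- lapply(toks, function(tk) {
    m <- match(tolower(tk), model@vocab)
    as.integer(m[!is.na(m)] - 1L)
  })
  theta <- .lda_infer(model@phi, ids, model@alpha, as.integer(nIter))
  oov <- lengths(ids) == 0
  if (single) {
    v <- theta[1, ]
    attr(v, "oov") <- oov[1]
    return(v)
  }
  rownames(theta) <- sentenceIds(x)
  attr(theta, "oov") <- oov
  theta
}

#' Pairwise cosine similarity matrix
#'
#' @param vectors Numeric matrix, one row per sentence (rows named by
#'   sentence id); at least two rows, no zero rows.
#' @return Symmetric matrix with unit diagonal, entries in [-1, 1].
#' @export
cosineMatrix <- function(vectors) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) < 2) stop("need at least two vectors")
  nrm <- sqrt(rowSums(vectors^2))
  if (any(nrm == 0)) stop("zero vector has no cosine similarity")
  a <- vectors / nrm
  s <- tcrossprod(a)
  s[s > 1] <- 1
  s[s < -1] <- -1
  diag(s) <- 1
  dimnames(s) <- list(rownames(vectors), rownames(vectors))
  s
}

#' Cluster the sentence pool by affinity propagation
#'
#' Exemplar-based clustering on the pairwise similarity matrix, computed once
#' over the full pool before the active-learning loop and never updated. The
#' shared preference defaults to the median off-diagonal similarity; on
#' non-convergence the update is retried with stronger damping (0.95) before
#' failing with diagnostics.
#'
#' @param sim Similarity matrix from [cosineMatrix()] (rows named by
#'   sentence id).
#' @param preference Shared exemplar preference (default: median off-diagonal
#'   similarity).
#' @param damping Message damping factor in [0.5, 1) (default 0.9).
#' @param maxit Maximum message-passing iterations.
#' @param convits Iterations of a stable exemplar set required to declare
#'   convergence.
#' @return A [SentenceClustering-class].
#' @export
clusterPool <- function(sim, preference = NULL, damping = 0.9, maxit = 500,
                        convits = 30) {
  sim <- as.matrix(sim)
  if (nrow(sim) != ncol(sim)) stop("similarity matrix must be square")
  if (max(abs(sim - t(sim))) > 1e-8) stop("similarity matrix must be symmetric")
  sids <- rownames(sim)
  if (is.null(sids)) sids <- sprintf("s%05d", seq_len(nrow(sim)))
  if (is.null(preference))
    preference <- stats::median(sim[row(sim) != col(sim)])
  ladder <- unique(c(damping, 0.95, 0.98))
  res <- NULL
  for (d in ladder) {
    res <- .ap_cluster(sim, preference, d,
                       as.integer(if (d == damping) maxit else maxit * 2),
                       as.integer(convits))
    if (isTRUE(res$converged)) break
  }
  if (!isTRUE(res$converged))
    stop(sprintf(paste0("affinity propagation did not converge (n=%d, ",
                        "preference=%.4g, damping %s, %d iterations)"),
                 nrow(sim), preference, paste(ladder, collapse = "/"),
                 res$iterations))
  exIdx <- res$exemplars                     # 1-based point indices
  cl <- match(res$assign, exIdx)             # cluster id per point
  labels <- stats::setNames(as.integer(cl), sids)
  new("SentenceClustering", labels = labels, exemplars = sids[exIdx])
}

setMethod("show", "SentenceClustering", function(object) {
  cat(sprintf("SentenceClustering: %d sentences in %d clusters\n",
              length(object@labels), length(object@exemplars)))
})

#' Clustering accessors
#'
#' @param x A [SentenceClustering-class].
#' @return \code{clusterLabels}: named integer vector of cluster ids;
#'   \code{clusterExemplars}: exemplar sentence id per cluster;
#'   \code{nClusters}: number of clusters.
#' @name clustering-accessors
NULL

#' @rdname clustering-accessors
#' @export
clusterLabels <- function(x) x@labels

#' @rdname clustering-accessors
#' @export
clusterExemplars <- function(x) x@exemplars

#' @rdname clustering-accessors
#' @export
nClusters <- function(x) length(x@exemplars)

#' Persist / load the clustering sidecar
#'
#' Tab-separated table with one row per pool sentence: sentence id, cluster
#' id, exemplar flag, and the K topic probabilities. Reused across
#' simulation runs so the (expensive) preprocessing happens once.
#'
#' @param clustering A [SentenceClustering-class].
#' @param topics Numeric matrix of sentence topic vectors (rows named by
#'   sentence id, aligned with the clustering).
#' @param path Output/input file.
#' @return \code{writeClustering}: invisibly \code{path};
#'   \code{readClustering}: list with elements \code{clustering} and
#'   \code{topics}.
#' @export
writeClustering <- function(clustering, topics, path) {
  sids <- names(clusterLabels(clustering))
  stopifnot(identical(sort(sids), sort(rownames(topics))))
  tp <- topics[sids, , drop = FALSE]
  df <- data.frame(sid = sids, cluster = unname(clusterLabels(clustering)),
                   exemplar = as.integer(sids %in%
                                           clusterExemplars(clustering)),
                   tp, check.names = FALSE)
  colnames(df)[-(1:3)] <- paste0("t", seq_len(ncol(tp)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeClustering
#' @export
readClustering <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  labels <- stats::setNames(as.integer(df$cluster), df$sid)
  ex <- df$sid[df$exemplar == 1]
  ex <- ex[order(labels[ex])]
  topics <- as.matrix(df[, grep("^t[0-9]+$", colnames(df)), drop = FALSE])
  rownames(topics) <- df$sid
  list(clustering = new("SentenceClustering", labels = labels,
                        exemplars = ex),
       topics = topics)
}
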