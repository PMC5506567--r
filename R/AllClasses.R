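#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom IRanges CharacterList
NULL

#' Entity types recognised by the package
#'
#' The three clinical concept classes handled throughout: medical problems,
#' treatments, and lab tests.
#'
#' @return Character vector of the three entity type names.
#' @export
entityTypes <- function() c("problem", "treatment", "test")

#' Annotated sentence corpus
#'
#' An \code{NERCorpus} holds an ordered collection of pre-tokenized sentences,
#' each belonging to a source document, together with typed entity span
#' annotations. Spans are token intervals, 1-based and end-inclusive (the
#' IRanges convention), and spans within a sentence never overlap.
#'
#' @slot tokens A \code{CharacterList}; element i is the token vector of
#'   sentence i. Tokens are non-empty and contain no whitespace.
#' @slot spans A \code{DataFrame} with columns \code{sentence} (integer index
#'   into the corpus), \code{start}, \code{end} (1-based inclusive token
#'   positions) and \code{type} (one of \code{entityTypes()}).
#' @slot sid Character vector of stable, unique sentence identifiers.
#' @slot doc Character vector; \code{doc[i]} is the source document of
#'   sentence i.
#' @slot meta A \code{DataFrame} of optional per-sentence metadata (zero rows
#'   when absent). The synthetic generator records the generating topic and
#'   template here.
#'
#' @seealso [NERCorpus()], [readBIO()], [corpusStats()]
#' @export
setClass("NERCorpus",
  representation(
    tokens = "CharacterList",
    spans  = "DataFrame",
    sid    = "character",
    doc    = "character",
    meta   = "DataFrame"
  )
)

setValidity("NERCorpus", function(object) {
  n <- length(object@tokens)
  msg <- character()
  if (length(object@sid) != n) msg <- c(msg, "length(sid) != number of sentences")
  if (length(object@doc) != n) msg <- c(msg, "length(doc) != number of sentences")
  if (anyDuplicated(object@sid)) msg <- c(msg, "sentence ids must be unique")
  lens <- lengths(object@tokens)
  if (n > 0 && any(lens < 1)) msg <- c(msg, "every sentence needs at least one token")
  toks <- unlist(object@tokens, use.names = FALSE)
  if (length(toks) && (any(!nzchar(toks)) || any(grepl("[[:space:]]", toks))))
    msg <- c(msg, "tokens must be non-empty and free of whitespace")
  sp <- object@spans
  need <- c("sentence", "start", "end", "type")
  if (!all(need %in% colnames(sp))) {
    msg <- c(msg, "spans must have columns sentence, start, end, type")
  } else if (nrow(sp) > 0) {
    if (any(is.na(sp$sentence)) || any(sp$sentence < 1L) || any(sp$sentence > n))
      msg <- c(msg, "span sentence index out of range")
    else {
      if (any(sp$start < 1L) || any(sp$end < sp$start) ||
          any(sp$end > lens[sp$sentence]))
        msg <- c(msg, "span boundaries out of sentence range")
      if (!all(sp$type %in% entityTypes()))
        msg <- c(msg, "span type outside {problem, treatment, test}")
      # no overlap within a sentence
      o <- order(sp$sentence, sp$start)
      ss <- sp$sentence[o]; st <- sp$start[o]; en <- sp$end[o]
      if (nrow(sp) > 1) {
        same <- ss[-1] == ss[-length(ss)]
        if (any(same & st[-1] <= en[-length(en)]))
          msg <- c(msg, "spans overlap within a sentence")
      }
    }
  }
  mt <- object@meta
  if (nrow(mt) > 0 && nrow(mt) != n)
    msg <- c(msg, "meta must have zero rows or one row per sentence")
  if (length(msg)) msg else TRUE
})

#' Sentence clustering result
#'
#' Partition of a sentence pool produced by affinity propagation, with one
#' exemplar sentence per cluster.
#'
#' @slot labels Integer vector of cluster ids (1..nClusters), named by
#'   sentence id.
#' @slot exemplars Character vector of exemplar sentence ids, one per cluster;
#'   \code{exemplars[c]} carries label \code{c}.
#' @export
setClass("SentenceClustering",
  representation(labels = "integer", exemplars = "character")
)

setValidity("SentenceClustering", function(object) {
  msg <- character()
  k <- length(object@exemplars)
  if (is.null(names(object@labels))) msg <- c(msg, "labels must be named by sentence id")
  if (length(object@labels) && (min(object@labels) < 1L || max(object@labels) > k))
    msg <- c(msg, "cluster labels out of 1..nClusters range")
  if (k > 0) {
    ex <- object@exemplars
    if (!all(ex %in% names(object@labels)))
      msg <- c(msg, "exemplars must be pool sentences")
    else if (!all(object@labels[ex] == seq_len(k)))
      msg <- c(msg, "exemplar of cluster c must carry label c")
  }
  if (length(msg)) msg else TRUE
})

#' Fitted topic model
#'
#' Latent Dirichlet allocation model estimated by collapsed Gibbs sampling on
#' whole documents. Per-topic word distributions are row-stochastic.
#'
#' @slot phi Numeric matrix, K x V; row k is the word distribution of topic k
#'   (columns named by vocabulary term).
#' @slot vocab Character vector of vocabulary terms (lowercased).
#' @slot alpha Document-topic Dirichlet hyperparameter used at estimation.
#' @slot fingerprint One-line summary of the estimation corpus (document,
#'   token and vocabulary counts) for provenance checks.
#' @export
setClass("TopicModel",
  representation(phi = "matrix", vocab = "character", alpha = "numeric",
                 fingerprint = "character")
)

setValidity("TopicModel", function(object) {
  msg <- character()
  if (ncol(object@phi) != length(object@vocab))
    msg <- c(msg, "phi must have one column per vocabulary term")
  rs <- rowSums(object@phi)
  if (nrow(object@phi) > 0 && any(abs(rs - 1) > 1e-8))
    msg <- c(msg, "each topic's word probabilities must sum to 1")
  if (nrow(object@phi) > 0 && min(object@phi) < 0)
    msg <- c(msg, "word probabilities must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Trained sequence tagger
#'
#' A linear-chain conditional random field over BIO tags. Emission weights
#' couple token features to labels; transition weights couple adjacent labels,
#' with boundary (start/stop) weights. Transitions that would produce an
#' illegal BIO sequence (an I- tag not preceded by a matching B-/I- tag) are
#' structurally excluded during training and decoding.
#'
#' @slot labels Character vector of tag labels (closed over B-/I-/O tags of
#'   the entity types for NER use; arbitrary label sets are permitted for toy
#'   models).
#' @slot features Character vector naming the emission feature dictionary.
#' @slot weights Numeric parameter vector: emission weights (feature-major,
#'   label-minor), then the L x L transition matrix (column-major), then L
#'   start weights and L stop weights.
#' @slot template Feature template used at training time (see
#'   [featureTemplate()]).
#' @slot version Model format tag.
#' @export
setClass("CRFModel",
  representation(labels = "character", features = "character",
                 weights = "numeric", template = "list", version = "character")
)

setValidity("CRFModel", function(object) {
  L <- length(object@labels); FF <- length(object@features)
  want <- FF * L + L * L + 2L * L
  if (length(object@weights) != want)
    return(sprintf("weights length %d, expected %d (F*L + L^2 + 2L)",
                   length(object@weights), want))
  TRUE
})

#' Active-learning query state
#'
#' Book-keeping for one pool-based active-learning run: the labeled/unlabeled
#' partition of the pool, current least-confidence scores, and (for CAUSE)
#' the fixed pool clustering.
#'
#' @slot labeled Character vector of labeled sentence ids (annotation order).
#' @slot unlabeled Character vector of still-unlabeled sentence ids.
#' @slot uncertainty Named numeric vector of least-confidence scores; empty
#'   until a model exists. Scores are required for the unlabeled set when an
#'   uncertainty-driven selector runs.
#' @slot clustering A \code{SentenceClustering} over the pool (may be empty
#'   for non-CAUSE methods).
#' @export
setClass("QueryState",
  representation(labeled = "character", unlabeled = "character",
                 uncertainty = "numeric", clustering = "SentenceClustering")
)

setValidity("QueryState", function(object) {
  msg <- character()
  if (length(intersect(object@labeled, object@unlabeled)))
    msg <- c(msg, "labeled and unlabeled sets must be disjoint")
  if (anyDuplicated(object@labeled) || anyDuplicated(object@unlabeled))
    msg <- c(msg, "sentence ids must be unique within each set")
  if (length(msg)) msg else TRUE
})

#' Learning curve
#'
#' Ordered (cost, F-measure) points tracing model quality against cumulative
#' annotation cost, the object summarised by [alcScore()].
#'
#' @slot points A \code{data.frame} with numeric columns \code{cost}
#'   (strictly increasing, nonnegative) and \code{f} (in [0, 1]).
#' @slot costUnit Either \code{"words"} (simulation) or \code{"minutes"}
#'   (user-study style logs).
#' @export
setClass("LearningCurve",
  representation(points = "data.frame", costUnit = "character")
)

setValidity("LearningCurve", function(object) {
  msg <- character()
  p <- object@points
  if (!all(c("cost", "f") %in% colnames(p)))
    msg <- c(msg, "points needs columns cost and f")
  else {
    if (nrow(p) > 1 && any(diff(p$cost) <= 0))
      msg <- c(msg, "costs must be strictly increasing")
    if (nrow(p) > 0 && (any(p$cost < 0) || any(p$f < 0 | p$f > 1)))
      msg <- c(msg, "cost must be >= 0 and f in [0, 1]")
  }
  if (!object@costUnit %in% c("words", "minutes"))
    msg <- c(msg, "costUnit must be 'words' or 'minutes'")
  if (length(msg)) msg else TRUE
})
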