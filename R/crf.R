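#' NER tag label set
#'
#' BIO labels over the three clinical entity types, \code{"O"} first.
#' @return Character vector of 7 labels.
#' @export
nerLabels <- function() {
  c("O", as.vector(outer(c("B-", "I-"), entityTypes(), paste0)))
}

#' Feature template for the CRF tagger
#'
#' Controls the per-token feature bag: lowercased word forms in a symmetric
#' window (sentence boundaries contribute \code{<B>}/\code{<E>} markers),
#' character prefixes/suffixes of the current word, and orthographic flags
#' (capitalised, all-digits, contains-digit, punctuation). A bias feature is
#' always present. The default (window 2, affix lengths 3 and 4) is a compact
#' version of standard CRF NER templates; large simulation sweeps use
#' \code{featureTemplate(window = 1, affixes = FALSE)} for speed.
#'
#' @param window Word-form window half-width (0 disables context words).
#' @param affixes Include prefix/suffix features of the current word.
#' @param affixLengths Affix lengths used when \code{affixes} is TRUE.
#' @param ortho Include orthographic flag features.
#' @return Classed list \code{FeatureTemplate}.
#' @export
featureTemplate <- function(window = 2, affixes = TRUE, affixLengths = c(3, 4),
                            ortho = TRUE) {
  structure(list(window = as.integer(window), affixes = isTRUE(affixes),
                 affixLengths = as.integer(affixLengths),
                 ortho = isTRUE(ortho)),
            class = "FeatureTemplate")
}

#' Extract per-token features for one sentence
#'
#' Deterministic: identical sentences yield identical feature bags.
#'
#' @param tokens Character vector of tokens.
#' @param template A [featureTemplate()].
#' @return A list with one character vector of feature strings per token.
#' @export
extractFeatures <- function(tokens, template = featureTemplate()) {
  n <- length(tokens)
  lw <- tolower(tokens)
  w <- template$window
  cols <- list(rep("b", n))
  if (w > 0) {
    padded <- c(rep("<B>", w), lw, rep("<E>", w))
    for (o in -w:w)
      cols[[length(cols) + 1L]] <- paste0("w", o, "=", padded[seq_len(n) + w + o])
  } else {
    cols[[length(cols) + 1L]] <- paste0("w0=", lw)
  }
  if (template$affixes) {
    nc <- nchar(lw)
    for (k in template$affixLengths) {
      cols[[length(cols) + 1L]] <-
        ifelse(nc >= k, paste0("p", k, "=", substr(lw, 1, k)), NA_character_)
      cols[[length(cols) + 1L]] <-
        ifelse(nc >= k, paste0("s", k, "=", substr(lw, nc - k + 1, nc)),
               NA_character_)
    }
  }
  if (template$ortho) {
    cols[[length(cols) + 1L]] <- ifelse(grepl("^[A-Z]", tokens), "CAP",
                                        NA_character_)
    cols[[length(cols) + 1L]] <- ifelse(grepl("^[0-9]+$", tokens), "DIGITS",
                                        NA_character_)
    cols[[length(cols) + 1L]] <- ifelse(grepl("[0-9]", tokens), "HASDIGIT",
                                        NA_character_)
    cols[[length(cols) + 1L]] <- ifelse(grepl("^[[:punct:]]+$", tokens),
                                        "PUNCT", NA_character_)
  }
  m <- do.call(cbind, cols)
  lapply(seq_len(n), function(i) { v <- m[i, ]; v[!is.na(v)] })
}

#' Precompute an indexed feature set for a corpus
#'
#' Maps every token's feature bag to integer ids against a feature
#' dictionary. Computed once and reused across the retrain/decode cycles of a
#' simulation run. With \code{dict = NULL} the dictionary is built from this
#' corpus; otherwise features absent from \code{dict} are dropped (their
#' weight is structurally zero).
#'
#' @param x An [NERCorpus-class].
#' @param template A [featureTemplate()].
#' @param dict Optional fixed feature dictionary (character vector).
#' @return Classed list \code{FeatureSet} with per-sentence id vectors.
#' @export
indexFeatures <- function(x, template = featureTemplate(), dict = NULL) {
  toks <- as.list(sentenceTokens(x))
  bags <- lapply(toks, extractFeatures, template = template)
  flat <- unlist(bags, use.names = FALSE)
  if (is.null(dict)) dict <- unique(flat)
  ids <- match(flat, dict)
  perTok <- unlist(lapply(bags, lengths), use.names = FALSE)
  tokGrp <- rep(seq_along(perTok), times = perTok)
  keep <- !is.na(ids)
  cnt <- tabulate(tokGrp[keep], nbins = length(perTok))
  nTok <- lengths(toks)
  featBySent <- split(ids[keep] - 1L,
                      rep(seq_along(nTok), times = .regroup(cnt, nTok)))
  cntBySent <- split(cnt, rep(seq_along(nTok), times = nTok))
  structure(list(dict = dict, feat = .fillEmpty(featBySent, length(nTok)),
                 tokCnt = cntBySent, nTok = as.integer(nTok),
                 sid = sentenceIds(x), template = template),
            class = "FeatureSet")
}

# sum per-token feature counts within each sentence
.regroup <- function(cnt, nTok) {
  grp <- rep(seq_along(nTok), times = nTok)
  as.integer(rowsum(cnt, grp)[, 1])
}

.fillEmpty <- function(lst, n) {
  out <- rep(list(integer(0)), n)
  names(out) <- as.character(seq_len(n))
  out[names(lst)] <- lst
  unname(out)
}

# assemble the flattened arrays the C++ kernels expect, for a sentence subset
.assembleFS <- function(fs, subset = NULL) {
  if (is.null(subset)) subset <- seq_along(fs$nTok)
  list(featIdx = as.integer(unlist(fs$feat[subset], use.names = FALSE)),
       tokPtr = as.integer(c(0L, cumsum(unlist(fs$tokCnt[subset],
                                               use.names = FALSE)))),
       sentPtr = as.integer(c(0L, cumsum(fs$nTok[subset]))))
}

# BIO legality masks for a label set: transitions into I-x require B-x or I-x;
# a sequence cannot start with I-x. Non-BIO label names are unconstrained.
.bioMasks <- function(labels) {
  L <- length(labels)
  startOK <- !startsWith(labels, "I-")
  transOK <- matrix(TRUE, L, L)
  for (j in seq_len(L)) {
    if (startsWith(labels[j], "I-")) {
      ty <- substring(labels[j], 3)
      transOK[, j] <- labels %in% paste0(c("B-", "I-"), ty)
    }
  }
  list(startOK = startOK, transOK = transOK)
}

#' Construct a CRF model from explicit parameters
#'
#' Mainly for toy models with hand-set weights; [crfTrain()] is the fitting
#' entry point.
#'
#' @param labels Label set.
#' @param features Feature dictionary.
#' @param weights Parameter vector of length
#'   \code{length(features) * L + L^2 + 2L} (defaults to zeros).
#' @param template Feature template (stored for decoding convenience).
#' @return A [CRFModel-class].
#' @export
crfModel <- function(labels, features = character(0), weights = NULL,
                     template = featureTemplate()) {
  L <- length(labels)
  want <- length(features) * L + L * L + 2L * L
  if (is.null(weights)) weights <- numeric(want)
  new("CRFModel", labels = labels, features = features,
      weights = as.numeric(weights), template = unclass(template),
      version = "activeNER-crf-1")
}

setMethod("show", "CRFModel", function(object) {
  cat(sprintf("CRFModel (%s): %d labels, %d features, %d weights\n",
              object@version, length(object@labels), length(object@features),
              length(object@weights)))
})

#' Train the CRF tagger
#'
#' L2-regularised maximum likelihood by L-BFGS. Training is deterministic
#' given the training sentences (in order), the template, and the
#' hyperparameters. Illegal BIO transitions carry no probability mass during
#' training or decoding.
#'
#' @param x An [NERCorpus-class] of labeled sentences (>= 1).
#' @param template A [featureTemplate()].
#' @param l2 L2 penalty weight (default 1).
#' @param maxit Maximum L-BFGS iterations.
#' @param labels Label set (default [nerLabels()]).
#' @param featureSet Optional precomputed [indexFeatures()] result for the
#'   corpus that \code{subset} indexes into (simulation fast path).
#' @param subset Sentence indices of \code{featureSet} to train on.
#' @param init Optional initial weight vector (warm start).
#' @return A [CRFModel-class].
#' @export
crfTrain <- function(x, template = featureTemplate(), l2 = 1.0, maxit = 100,
                     labels = nerLabels(), featureSet = NULL, subset = NULL,
                     init = NULL) {
  if (is.null(featureSet)) {
    if (nSentences(x) < 1) stop("training requires at least one sentence")
    featureSet <- indexFeatures(x, template)
    subset <- seq_len(nSentences(x))
    tagCorpus <- x
  } else {
    if (is.null(subset)) subset <- seq_along(featureSet$nTok)
    if (!length(subset)) stop("training requires at least one sentence")
    tagCorpus <- x
    template <- featureSet$template
  }
  goldList <- .goldLabelIds(bioEncode(tagCorpus), labels)
  w <- .crfFitCore(featureSet, subset, goldList, labels, l2, maxit, init)
  crfModel(labels, featureSet$dict, w, template)
}

.goldLabelIds <- function(tags, labels) {
  lapply(tags, function(tg) {
    ids <- match(tg, labels)
    if (anyNA(ids)) stop("gold tag outside the model label set")
    ids - 1L
  })
}

# inner fitting loop shared by crfTrain and the simulation fast path
.crfFitCore <- function(featureSet, subset, goldList, labels, l2, maxit,
                        init = NULL) {
  arr <- .assembleFS(featureSet, subset)
  gold <- unlist(goldList[subset], use.names = FALSE)
  masks <- .bioMasks(labels)
  L <- length(labels)
  FF <- length(featureSet$dict)
  nw <- FF * L + L * L + 2L * L
  par <- if (!is.null(init) && length(init) == nw) init else numeric(nw)

  cache <- new.env(parent = emptyenv())
  evalBoth <- function(p) {
    if (is.null(cache$p) || !identical(p, cache$p)) {
      cache$r <- .crf_nll_grad(p, arr$featIdx, arr$tokPtr, arr$sentPtr, gold,
                               L, FF, masks$transOK, masks$startOK, l2)
      cache$p <- p
    }
    cache$r
  }
  fit <- stats::optim(par, fn = function(p) evalBoth(p)$nll,
                      gr = function(p) evalBoth(p)$grad,
                      method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e7))
  fit$par
}

# decode with a prebuilt flattened array and return 1 - P(best path) per
# sentence: the LC scores
.lcCore <- function(weights, labels, featureSet, arr, sids) {
  masks <- .bioMasks(labels)
  out <- .crf_decode_all(weights, arr$featIdx, arr$tokPtr, arr$sentPtr,
                         length(labels), length(featureSet$dict),
                         masks$transOK, masks$startOK, TRUE)
  stats::setNames(1 - pmin(1, pmax(0, exp(out$logProb))), sids)
}

# decode with a prebuilt array and return span keys "sid start end type"
.decodeKeys <- function(weights, labels, featureSet, arr, sids, nTok) {
  masks <- .bioMasks(labels)
  out <- .crf_decode_all(weights, arr$featIdx, arr$tokPtr, arr$sentPtr,
                         length(labels), length(featureSet$dict),
                         masks$transOK, masks$startOK, FALSE)
  .pathsToKeys(out$paths, labels, sids, nTok)
}

# Vectorised BIO span extraction over a list of 0-based label-id paths.
# Assumes the label set is ordered "O", then B-/I- pairs per type (the
# nerLabels() layout), so B ids are even, I ids odd, type = (id - 2) %/% 2.
.pathsToKeys <- function(paths, labels, sids, nTok) {
  v <- unlist(paths, use.names = FALSE) + 1L
  if (!length(v)) return(character(0))
  n <- length(v)
  sent <- rep.int(seq_along(nTok), nTok)
  pos <- sequence(nTok)
  isEnt <- v > 1L
  typ <- (v - 2L) %/% 2L            # 0 = problem, 1 = treatment, 2 = test
  isB <- isEnt & (v %% 2L == 0L)
  prevEnt <- c(FALSE, isEnt[-n])
  prevTyp <- c(-1L, typ[-n])
  prevSent <- c(0L, sent[-n])
  cont <- isEnt & !isB & prevEnt & prevTyp == typ & prevSent == sent
  startsAt <- which(isEnt & !cont)
  if (!length(startsAt)) return(character(0))
  nxtCont <- c(cont[-1], FALSE)
  endsAt <- which(isEnt & !nxtCont)
  types <- entityTypes()[typ[startsAt] + 1L]
  paste(sids[sent[startsAt]], pos[startsAt], pos[endsAt], types)
}

#' Decode sentences with a trained model
#'
#' Viterbi best path per sentence under the BIO transition constraints,
#' together with the exact conditional probability of that path (best-path
#' score minus the log partition function over legal paths).
#'
#' @param model A [CRFModel-class].
#' @param x An [NERCorpus-class] to decode.
#' @param featureSet Optional precomputed [indexFeatures()] built with
#'   \code{dict = model@features}.
#' @param subset Sentence indices to decode (default all).
#' @return A \code{DataFrame} with columns \code{tags} (CharacterList),
#'   \code{prob} (best-path conditional probability) and \code{nTokens},
#'   row names the sentence ids.
#' @export
crfDecode <- function(model, x, featureSet = NULL, subset = NULL) {
  if (!is(model, "CRFModel")) stop("decode requires a trained CRFModel")
  if (is.null(featureSet) && nSentences(x) == 0) stop("nothing to decode")
  if (is.null(featureSet))
    featureSet <- indexFeatures(x, structure(model@template,
                                             class = "FeatureTemplate"),
                                dict = model@features)
  if (is.null(subset)) subset <- seq_along(featureSet$nTok)
  arr <- .assembleFS(featureSet, subset)
  masks <- .bioMasks(model@labels)
  out <- .crf_decode_all(model@weights, arr$featIdx, arr$tokPtr, arr$sentPtr,
                         length(model@labels), length(model@features),
                         masks$transOK, masks$startOK)
  tags <- lapply(out$paths, function(p) model@labels[p + 1L])
  prob <- pmin(1, pmax(0, exp(out$logProb)))
  S4Vectors::DataFrame(tags = IRanges::CharacterList(tags), prob = prob,
                       nTokens = featureSet$nTok[subset],
                       row.names = featureSet$sid[subset])
}

#' Least-confidence uncertainty score
#'
#' \code{1 - P(best path | sentence)}; higher means more uncertain. The
#' optional length-normalised variant uses \code{1 - P^(1/n)} so that long
#' sentences are not penalised purely for their length.
#'
#' @param pred A decode result from [crfDecode()], or a numeric vector of
#'   best-path probabilities.
#' @param lengthNormalize Use the per-token geometric mean of the path
#'   probability.
#' @return Named numeric vector of scores in [0, 1].
#' @export
leastConfidence <- function(pred, lengthNormalize = FALSE) {
  if (is.numeric(pred)) return(1 - pred)
  p <- pred$prob
  if (lengthNormalize) p <- p^(1 / pmax(1, pred$nTokens))
  stats::setNames(1 - p, rownames(pred))
}

#' Convert decoded tags into a predicted corpus
#'
#' @param model A [CRFModel-class].
#' @param x Corpus to predict on.
#' @param ... Passed to [crfDecode()].
#' @return An [NERCorpus-class] with predicted spans (tokens unchanged).
#' @export
predictCorpus <- function(model, x, ...) {
  dec <- crfDecode(model, x, ...)
  spans <- do.call(rbind, lapply(seq_len(nrow(dec)), function(i) {
    d <- bioDecode(dec$tags[[i]])
    if (nrow(d)) cbind(sentence = i, d) else NULL
  }))
  NERCorpus(as.list(sentenceTokens(x)), spans = spans, sid = sentenceIds(x),
            doc = docIds(x))
}

#' Persist / restore a trained model
#'
#' Single-file serialisation with a version tag checked on load.
#'
#' @param model A [CRFModel-class].
#' @param path File path.
#' @return \code{saveCRFModel}: invisibly \code{path}; \code{readCRFModel}:
#'   the model.
#' @export
saveCRFModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveCRFModel
#' @export
readCRFModel <- function(path) {
  m <- readRDS(path)
  if (!is(m, "CRFModel") || !identical(m@version, "activeNER-crf-1"))
    stop("not an activeNER CRF model file")
  m
}
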