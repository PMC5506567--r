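#' Span-level NER evaluation
#'
#' Default matching is exact: a predicted span is a true positive iff its
#' start, end and entity type all equal a gold span of the same sentence;
#' each gold span is matched at most once. The optional \code{"overlap"}
#' criterion relaxes the boundary requirement: a predicted span matches an
#' as-yet-unmatched gold span of the same type that it overlaps. Precision,
#' recall and F follow the usual definitions with 0/0 treated as 0.
#'
#' @param gold,pred [NERCorpus-class] objects aligned by sentence id with
#'   identical token sequences.
#' @param matching \code{"exact"} (default) or \code{"overlap"}.
#' @return Named list: \code{tp}, \code{fp}, \code{fn}, \code{precision},
#'   \code{recall}, \code{f}.
#' @export
evaluateNER <- function(gold, pred, matching = c("exact", "overlap")) {
  matching <- match.arg(matching)
  if (!identical(sentenceIds(gold), sentenceIds(pred)))
    stop("gold and predicted corpora must share sentence ids in order")
  if (!identical(as.list(sentenceTokens(gold)),
                 as.list(sentenceTokens(pred))))
    stop("gold and predicted corpora must share token sequences")
  key <- function(x) {
    sp <- entitySpans(x)
    paste(sentenceIds(x)[sp$sentence], sp$start, sp$end, sp$type)
  }
  gk <- key(gold); pk <- key(pred)
  tp <- if (matching == "exact") {
    # non-overlap within a sentence makes span keys unique per corpus
    sum(pk %in% gk)
  } else {
    .overlapTP(as.data.frame(entitySpans(gold)),
               as.data.frame(entitySpans(pred)))
  }
  fp <- length(pk) - tp
  fn <- length(gk) - tp
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(tp = tp, fp = fp, fn = fn, precision = prec, recall = rec, f = f)
}

# greedy one-to-one overlap matching per (sentence, type); spans within a
# sentence never overlap each other, so matches are unambiguous up to order
.overlapTP <- function(gsp, psp) {
  if (nrow(gsp) == 0 || nrow(psp) == 0) return(0L)
  tp <- 0L
  usedGold <- rep(FALSE, nrow(gsp))
  for (i in seq_len(nrow(psp))) {
    cand <- which(!usedGold & gsp$sentence == psp$sentence[i] &
                    gsp$type == psp$type[i] &
                    gsp$start <= psp$end[i] & psp$start[i] <= gsp$end)
    if (length(cand)) {
      usedGold[cand[1]] <- TRUE
      tp <- tp + 1L
    }
  }
  tp
}

#' Learning-curve constructor
#'
#' @param cost Nonnegative, strictly increasing annotation costs.
#' @param f F-measures in [0, 1].
#' @param costUnit \code{"words"} or \code{"minutes"}.
#' @return A [LearningCurve-class].
#' @export
learningCurve <- function(cost, f, costUnit = "words") {
  new("LearningCurve",
      points = data.frame(cost = as.numeric(cost), f = as.numeric(f)),
      costUnit = costUnit)
}

#' @describeIn learningCurve The (cost, f) points as a data.frame.
#' @param curve A [LearningCurve-class].
#' @export
curvePoints <- function(curve) curve@points

setMethod("show", "LearningCurve", function(object) {
  p <- object@points
  cat(sprintf("LearningCurve: %d points, cost %s .. %s %s, final F %.3f\n",
              nrow(p), format(min(p$cost)), format(max(p$cost)),
              object@costUnit, p$f[nrow(p)]))
})

#' Area under the learning curve (ALC)
#'
#' The area under the observed curve (trapezoidal rule from the first to the
#' last cost point) divided by the maximum area — the observed cost span
#' times the best F-measure achievable in a session of that length (0.75 by
#' default). A constant curve at the ceiling scores 1.
#'
#' @param curve A [LearningCurve-class] with at least two points.
#' @param bestF Best achievable F-measure (default 0.75).
#' @return ALC score (in [0, 1] whenever the curve stays below
#'   \code{bestF}).
#' @export
alcScore <- function(curve, bestF = 0.75) {
  p <- curvePoints(curve)
  if (nrow(p) < 2) stop("ALC needs at least two curve points")
  actual <- sum(diff(p$cost) * (utils::head(p$f, -1) + utils::tail(p$f, -1)) / 2)
  maximum <- (p$cost[nrow(p)] - p$cost[1]) * bestF
  actual / maximum
}

#' Session metrics from integer counts
#'
#' Derived ratios of an annotation session, exactly as computed in the
#' reported characteristic tables: all ratios at full precision (use
#' [roundHalfUp()] for presentation).
#'
#' @param sentences,words,entities,entityWords Integer session counts.
#' @param duration Session duration in minutes (> 0).
#' @return One-row \code{data.frame} with columns \code{annotated_sentences},
#'   \code{words}, \code{entities}, \code{entity_words},
#'   \code{sentences_per_min}, \code{words_per_sentence},
#'   \code{words_per_min}, \code{entities_per_min},
#'   \code{entities_per_sentence}, \code{entity_density}. Ratios over zero
#'   denominators are \code{NA}.
#' @export
sessionMetricsFromCounts <- function(sentences, words, entities, entityWords,
                                     duration) {
  if (duration <= 0) stop("session duration must be positive")
  rat <- function(a, b) if (b > 0) a / b else NA_real_
  data.frame(annotated_sentences = sentences, words = words,
             entities = entities, entity_words = entityWords,
             sentences_per_min = sentences / duration,
             words_per_sentence = rat(words, sentences),
             words_per_min = words / duration,
             entities_per_min = entities / duration,
             entities_per_sentence = rat(entities, sentences),
             entity_density = rat(entityWords, words))
}

#' Metrics of an annotation session
#'
#' Counts and speed/quality ratios for a session in which \code{annotated}
#' holds the sentences the user produced. When a gold corpus is supplied,
#' annotation quality is the span-level F-measure of the user's spans
#' against the gold annotation of the same sentences.
#'
#' @param annotated [NERCorpus-class] of user-annotated sentences.
#' @param duration Session duration in minutes (> 0).
#' @param gold Optional gold [NERCorpus-class] covering the annotated
#'   sentence ids.
#' @return One-row \code{data.frame} as in [sessionMetricsFromCounts()],
#'   plus \code{annotation_quality_f} (NA without gold).
#' @export
sessionMetrics <- function(annotated, duration, gold = NULL) {
  st <- suppressWarnings(corpusStats(annotated))
  out <- sessionMetricsFromCounts(st$sentence_count, st$word_count,
                                  st$entity_count, st$entity_word_count,
                                  duration)
  out$annotation_quality_f <- NA_real_
  if (!is.null(gold) && nSentences(annotated) > 0) {
    g <- gold[sentenceIds(annotated)]
    out$annotation_quality_f <- evaluateNER(g, annotated)$f
  }
  out
}
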