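#' Configuration for the synthetic clinical-corpus generator
#'
#' The generator emulates a pool of short clinical sentences with latent topic
#' structure: each document draws a topic mixture, each sentence draws a topic
#' and then a slot template of that topic's clinical flavour (medication-list,
#' problem-description, or lab-result sentences). Slots are filled from
#' per-topic lexicons, so sentences generated from the same template share
#' their context words and differ only in the slot fillers — the structure a
#' cluster-based querying engine exploits. Defaults are calibrated to the
#' characteristics of de-identified clinical-note corpora used for concept
#' extraction: about 11 words per sentence, about 1.3 entities per sentence,
#' and entity density (entity words / total words) near 0.24.
#'
#' @param nDocuments Number of documents.
#' @param sentencesPerDocument Integer range \code{c(min, max)} of sentences
#'   drawn per document.
#' @param nTopics Number of latent topics.
#' @param templatesPerTopic Sentence templates per topic.
#' @param entityLexiconSize Words per (topic, entity-type) lexicon.
#' @param contextLexiconSize Topic-specific context words per topic.
#' @param targetWordsPerSentence,targetEntityDensity Calibration targets the
#'   template inventory was designed around (documentation of intent; the
#'   realised values are checked with [corpusStats()]).
#' @param noiseRate Probability that a non-entity word is replaced by a random
#'   vocabulary word.
#' @param includeEntities If \code{FALSE}, entity slots are replaced by
#'   context words (entity-free corpus, used for degenerate-case checks).
#' @param seed Integer seed; generation is fully deterministic given the
#'   config.
#' @return A \code{GeneratorConfig} (classed list).
#' @export
generatorConfig <- function(nDocuments = 560,
                            sentencesPerDocument = c(8L, 12L),
                            nTopics = 10,
                            templatesPerTopic = 3,
                            entityLexiconSize = 60,
                            contextLexiconSize = 12,
                            targetWordsPerSentence = 11,
                            targetEntityDensity = 0.24,
                            noiseRate = 0.05,
                            includeEntities = TRUE,
                            seed = 42) {
  cfg <- list(nDocuments = as.integer(nDocuments),
              sentencesPerDocument = as.integer(sentencesPerDocument),
              nTopics = as.integer(nTopics),
              templatesPerTopic = as.integer(templatesPerTopic),
              entityLexiconSize = as.integer(entityLexiconSize),
              contextLexiconSize = as.integer(contextLexiconSize),
              targetWordsPerSentence = targetWordsPerSentence,
              targetEntityDensity = targetEntityDensity,
              noiseRate = noiseRate,
              includeEntities = isTRUE(includeEntities),
              seed = as.integer(seed))
  counts <- c(cfg$nDocuments, cfg$nTopics, cfg$templatesPerTopic,
              cfg$entityLexiconSize, cfg$contextLexiconSize,
              cfg$sentencesPerDocument)
  if (any(counts < 1)) stop("generator config: all counts must be positive")
  if (cfg$noiseRate < 0 || cfg$noiseRate > 1)
    stop("generator config: noiseRate must be in [0, 1]")
  if (cfg$targetEntityDensity < 0 || cfg$targetEntityDensity > 1)
    stop("generator config: targetEntityDensity must be in [0, 1]")
  if (cfg$targetWordsPerSentence <= 0)
    stop("generator config: targetWordsPerSentence must be positive")
  class(cfg) <- "GeneratorConfig"
  cfg
}

# pseudo-word factory: pronounceable syllable compounds, deterministic under
# the current RNG state
.makeWords <- function(n, minSyl = 2, maxSyl = 3) {
  syl <- c("lor", "ta", "mex", "vin", "dro", "cil", "pam", "zo", "ker", "ni",
           "fen", "gra", "sul", "det", "ora", "bix", "cal", "rup", "tin",
           "mal", "sev", "qua", "dol", "pre", "hy", "os", "ern", "ul")
  out <- character(0)
  while (length(out) < n) {
    cand <- vapply(seq_len(n), function(i)
      paste(sample(syl, sample(minSyl:maxSyl, 1), replace = TRUE),
            collapse = ""), "")
    out <- unique(c(out, cand))
  }
  out[seq_len(n)]
}

.numLexicon <- c("5", "10", "20", "25", "40", "50", "80", "100", "125",
                 "250", "500")

# slot constructors for the template DSL
.lit <- function(w) list(kind = "lit", value = w)
.ctx <- function() list(kind = "ctx")
.num <- function() list(kind = "num")
.ent <- function(etype, width) list(kind = "ent", etype = etype,
                                    width = as.integer(width))

# Template inventory per clinical flavour. Each template is a list of slots;
# lengths average ~11 words with ~2.6 entity words, matching the calibration
# targets of the default config.
.flavourTemplates <- function(flavour) {
  switch(flavour,
    medication = list(
      list(.ctx(), .lit(":"), .ent("treatment", 2), .num(),
        .lit("mg"), .lit("p.o."), .lit("q."), .ctx(), .lit("day"),
        .lit("prn"), .lit(".")),
      list(.ctx(), .lit("assessment"), .lit(":"), .ent("treatment", 2),
        .lit("reviewed"), .lit("today"), .ctx(), .ctx(), .num(), .lit(".")),
      list(.lit("started"), .lit("on"), .ent("treatment", 1), .lit("and"),
        .ent("treatment", 3), .num(), .lit("mg"), .ctx(), .ctx(),
        .lit("tonight"), .lit("."))
    ),
    problem = list(
      list(.lit("patient"), .lit("reports"), .ent("problem", 3), .lit("and"),
        .ent("problem", 1), .lit("since"), .ctx(), .ctx(), .ctx(), .lit(".")),
      list(.ctx(), .lit("assessment"), .lit(":"), .ent("problem", 2),
        .lit("reviewed"), .lit("today"), .ctx(), .ctx(), .num(), .lit(".")),
      list(.lit("denies"), .ent("problem", 1), .lit("or"),
        .ent("problem", 2), .ctx(), .ctx(), .ctx(), .lit("."))
    ),
    lab = list(
      list(.ent("test", 2), .lit("was"), .num(), .lit("on"), .ctx(), .ctx(),
        .ctx(), .lit("this"), .lit("morning"), .lit(".")),
      list(.ctx(), .lit("assessment"), .lit(":"), .ent("test", 2),
        .lit("reviewed"), .lit("today"), .ctx(), .ctx(), .num(), .lit(".")),
      list(.ent("test", 3), .lit("of"), .num(), .lit("and"), .ent("test", 1),
        .num(), .ctx(), .ctx(), .lit("pending"), .ctx(), .lit("."))
    )
  )
}

.buildWorld <- function(cfg) {
  K <- cfg$nTopics
  flavours <- c("medication", "problem", "lab")[(seq_len(K) - 1) %% 3 + 1]
  lex <- lapply(seq_len(K), function(k) {
    ents <- lapply(entityTypes(), function(e)
      .makeWords(cfg$entityLexiconSize))
    names(ents) <- entityTypes()
    list(entities = ents, context = .makeWords(cfg$contextLexiconSize))
  })
  templates <- lapply(seq_len(K), function(k) {
    pool <- .flavourTemplates(flavours[k])
    pool[((seq_len(cfg$templatesPerTopic) - 1) %% length(pool)) + 1]
  })
  noiseVocab <- unique(c(unlist(lapply(lex, `[[`, "context")), "day", "exam",
                         "stable", "visit", "pending"))
  list(flavours = flavours, lexicons = lex, templates = templates,
       noiseVocab = noiseVocab)
}

.fillTemplate <- function(tpl, lexicon, cfg, world) {
  words <- character(); starts <- integer(); ends <- integer()
  types <- character()
  for (slot in tpl) {
    if (slot$kind == "ent" && !cfg$includeEntities)
      slot <- list(kind = "ctx")
    if (slot$kind == "lit") {
      words <- c(words, slot$value)
    } else if (slot$kind == "ctx") {
      words <- c(words, sample(lexicon$context, 1))
    } else if (slot$kind == "num") {
      words <- c(words, sample(.numLexicon, 1))
    } else {
      # entity width varies around the template's nominal width, so span
      # boundaries are not recoverable from context position alone
      wd <- if (slot$width == 1L) 1L
            else sample((slot$width - 1L):(slot$width + 1L), 1)
      w <- sample(lexicon$entities[[slot$etype]], wd, replace = FALSE)
      starts <- c(starts, length(words) + 1L)
      words <- c(words, w)
      ends <- c(ends, length(words))
      types <- c(types, slot$etype)
    }
  }
  if (cfg$noiseRate > 0) {
    inEnt <- rep(FALSE, length(words))
    for (j in seq_along(starts)) inEnt[starts[j]:ends[j]] <- TRUE
    hit <- which(!inEnt & stats::runif(length(words)) < cfg$noiseRate)
    if (length(hit))
      words[hit] <- sample(world$noiseVocab, length(hit), replace = TRUE)
  }
  list(words = words,
       spans = data.frame(start = starts, end = ends, type = types,
                          stringsAsFactors = FALSE))
}

#' Generate a topic-structured synthetic clinical corpus
#'
#' See [generatorConfig()] for the generative process. The generating topic
#' and template of every sentence are recorded in the corpus metadata
#' (columns \code{topic}, \code{template}), which downstream purity checks
#' use as ground truth.
#'
#' @param cfg A [generatorConfig()].
#' @return An [NERCorpus-class] with per-sentence \code{topic} and
#'   \code{template} metadata.
#' @export
generateCorpus <- function(cfg) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  withSeed(cfg$seed, {
    world <- .buildWorld(cfg)
    K <- cfg$nTopics
    # mildly skewed topic prior: earlier topics more prevalent, as concept
    # categories are in real notes
    alphaK <- 0.4 * 0.85^(seq_len(K) - 1)
    toks <- list(); spans <- NULL; doc <- character(); topic <- integer()
    template <- integer()
    si <- 0L
    for (d in seq_len(cfg$nDocuments)) {
      g <- stats::rgamma(K, shape = alphaK)
      theta <- g / sum(g)
      ns <- sample(cfg$sentencesPerDocument[1]:cfg$sentencesPerDocument[2], 1)
      for (s in seq_len(ns)) {
        z <- sample.int(K, 1, prob = theta)
        ti <- sample.int(length(world$templates[[z]]), 1)
        filled <- .fillTemplate(world$templates[[z]][[ti]],
                                world$lexicons[[z]], cfg, world)
        si <- si + 1L
        toks[[si]] <- filled$words
        if (nrow(filled$spans))
          spans <- rbind(spans, cbind(sentence = si, filled$spans))
        doc[si] <- sprintf("d%03d", d)
        topic[si] <- z
        template[si] <- (z - 1L) * cfg$templatesPerTopic + ti
      }
    }
    NERCorpus(toks, spans = spans, doc = doc,
              meta = data.frame(topic = topic, template = template))
  })
}

#' Generate a deduplicated pool / test split
#'
#' Generates a corpus, removes duplicate surface strings (pools for querying
#' consist of unique sentences), and splits the unique sentences into a
#' querying pool and an independent test set, stratified by generating topic.
#'
#' @param cfg A [generatorConfig()].
#' @param testFraction Fraction of unique sentences held out for testing
#'   (strictly between 0 and 1).
#' @param seed Integer seed for the split (independent of the generation
#'   seed in \code{cfg}).
#' @return A list with elements \code{pool}, \code{test} (disjoint
#'   [NERCorpus-class] objects) and \code{full} (the deduplicated corpus,
#'   whose document structure is the input for topic estimation).
#' @export
generatePoolAndTest <- function(cfg, testFraction = 0.2, seed = cfg$seed + 1L) {
  if (testFraction <= 0 || testFraction >= 1)
    stop("testFraction must be strictly between 0 and 1")
  corpus <- dedupCorpus(generateCorpus(cfg))
  topic <- sentenceData(corpus)$topic
  testIdx <- withSeed(seed, {
    unlist(lapply(split(seq_len(nSentences(corpus)), topic), function(ix) {
      nTest <- round(length(ix) * testFraction)
      if (nTest >= 1) sample(ix, nTest) else integer(0)
    }), use.names = FALSE)
  })
  testIdx <- sort(testIdx)
  list(pool = corpus[setdiff(seq_len(nSentences(corpus)), testIdx)],
       test = corpus[testIdx],
       full = corpus)
}
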