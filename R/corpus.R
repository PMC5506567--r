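#' Construct an annotated sentence corpus
#'
#' @param tokens A list (or \code{CharacterList}) of character vectors, one
#'   per sentence.
#' @param spans A \code{data.frame}/\code{DataFrame} with columns
#'   \code{sentence}, \code{start}, \code{end}, \code{type}, or \code{NULL}
#'   for an unannotated corpus. Positions are 1-based token indices,
#'   end-inclusive.
#' @param sid Sentence identifiers; defaults to positional ids
#'   \code{"s00001"}, ... so that a corpus written to and re-read from BIO
#'   format compares equal.
#' @param doc Document id per sentence (recycled if length 1).
#' @param meta Optional per-sentence metadata \code{data.frame}.
#' @return An [NERCorpus-class] object.
#' @examples
#' corp <- NERCorpus(list(c("Dulcolax", "10", "mg")),
#'                   spans = data.frame(sentence = 1, start = 1, end = 1,
#'                                      type = "treatment"))
#' corpusStats(corp)
#' @export
NERCorpus <- function(tokens, spans = NULL, sid = NULL, doc = "doc1",
                      meta = NULL) {
  tokens <- IRanges::CharacterList(tokens)
  n <- length(tokens)
  if (is.null(sid)) sid <- sprintf("s%05d", seq_len(n))
  doc <- rep_len(as.character(doc), n)
  if (is.null(spans)) {
    spans <- S4Vectors::DataFrame(sentence = integer(), start = integer(),
                                  end = integer(), type = character())
  } else {
    spans <- S4Vectors::DataFrame(sentence = as.integer(spans$sentence),
                                  start = as.integer(spans$start),
                                  end = as.integer(spans$end),
                                  type = as.character(spans$type))
    o <- order(spans$sentence, spans$start)
    spans <- spans[o, , drop = FALSE]
  }
  if (is.null(meta)) meta <- S4Vectors::DataFrame(matrix(nrow = 0, ncol = 0))
  else meta <- S4Vectors::DataFrame(meta)
  new("NERCorpus", tokens = tokens, spans = spans, sid = as.character(sid),
      doc = doc, meta = meta)
}

#' @describeIn NERCorpus Number of sentences.
#' @param x,object An \code{NERCorpus}.
#' @export
nSentences <- function(x) length(x@tokens)

#' Corpus accessors
#'
#' @param x An [NERCorpus-class].
#' @return \code{sentenceTokens}: a \code{CharacterList} of token vectors;
#'   \code{sentenceIds}, \code{docIds}: character vectors; \code{entitySpans}:
#'   a \code{DataFrame} of typed spans; \code{sentenceData}: the per-sentence
#'   metadata; \code{sentenceStrings}: whitespace-joined surface forms;
#'   \code{wordCounts}: tokens per sentence; \code{documents}: list mapping
#'   doc id to its ordered sentence ids.
#' @name corpus-accessors
NULL

#' @rdname corpus-accessors
#' @export
sentenceTokens <- function(x) x@tokens

#' @rdname corpus-accessors
#' @export
sentenceIds <- function(x) x@sid

#' @rdname corpus-accessors
#' @export
docIds <- function(x) x@doc

#' @rdname corpus-accessors
#' @export
entitySpans <- function(x) x@spans

#' @rdname corpus-accessors
#' @export
sentenceData <- function(x) x@meta

#' @rdname corpus-accessors
#' @export
sentenceStrings <- function(x) {
  unlist(lapply(as.list(x@tokens), paste, collapse = " "), use.names = FALSE)
}

#' @rdname corpus-accessors
#' @export
wordCounts <- function(x) lengths(x@tokens)

#' @rdname corpus-accessors
#' @export
documents <- function(x) split(x@sid, factor(x@doc, levels = unique(x@doc)))

setMethod("show", "NERCorpus", function(object) {
  cat(sprintf("NERCorpus: %d sentences, %d documents, %d entity spans\n",
              nSentences(object), length(unique(object@doc)),
              nrow(object@spans)))
  if (nSentences(object) > 0) {
    i <- 1L
    cat("  [1] ", paste(object@tokens[[i]], collapse = " "), "\n", sep = "")
  }
})

#' Subset a corpus by sentence
#'
#' @param x An [NERCorpus-class].
#' @param i Integer/logical indices or sentence ids.
#' @param j,...,drop Ignored.
#' @return An \code{NERCorpus} with spans and metadata carried along.
#' @export
setMethod("[", "NERCorpus", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@sid)
  i <- seq_len(nSentences(x))[i]
  if (anyNA(i)) stop("unknown sentence selection")
  keep <- x@spans$sentence %in% i
  sp <- x@spans[keep, , drop = FALSE]
  sp$sentence <- match(sp$sentence, i)
  meta <- if (nrow(x@meta) > 0) x@meta[i, , drop = FALSE]
          else x@meta
  new("NERCorpus", tokens = x@tokens[i], spans = sp, sid = x@sid[i],
      doc = x@doc[i], meta = meta)
})

#' Compare two corpora for annotation equality
#'
#' Tokens, sentence ids, document assignment and entity spans must all agree;
#' per-sentence metadata is ignored (it does not survive BIO serialisation).
#'
#' @param a,b [NERCorpus-class] objects.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
corpusIdentical <- function(a, b) {
  isTRUE(identical(as.list(a@tokens), as.list(b@tokens)) &&
         identical(a@sid, b@sid) && identical(a@doc, b@doc) &&
         identical(as.data.frame(a@spans), as.data.frame(b@spans)))
}

#' Concatenate corpora
#'
#' @param x,... \code{NERCorpus} objects.
#' @return A single \code{NERCorpus}; sentence ids must not collide.
#' @export
setMethod("c", "NERCorpus", function(x, ...) {
  parts <- c(list(x), list(...))
  toks <- do.call(c, lapply(parts, function(p) as.list(p@tokens)))
  off <- cumsum(c(0L, vapply(parts, nSentences, 1L)))
  sp <- do.call(rbind, lapply(seq_along(parts), function(k) {
    s <- as.data.frame(parts[[k]]@spans)
    s$sentence <- s$sentence + off[k]
    s
  }))
  metas <- lapply(parts, function(p) as.data.frame(p@meta))
  meta <- if (all(vapply(metas, nrow, 1L) > 0) &&
              length(unique(lapply(metas, colnames))) == 1)
    do.call(rbind, metas) else NULL
  NERCorpus(toks, spans = sp,
            sid = unlist(lapply(parts, sentenceIds), use.names = FALSE),
            doc = unlist(lapply(parts, docIds), use.names = FALSE),
            meta = meta)
})

# ---- BIO tag encoding / decoding --------------------------------------------

#' Encode sentence spans as BIO tags
#'
#' Each entity span of type t becomes a \code{B-t} tag on its first token and
#' \code{I-t} on the rest; all other tokens are tagged \code{O}.
#'
#' @param x An [NERCorpus-class].
#' @param i Sentence index; \code{NULL} encodes every sentence.
#' @return A character vector of tags for one sentence, or a list of them.
#' @export
bioEncode <- function(x, i = NULL) {
  if (is.null(i)) {
    sp <- split(as.data.frame(x@spans),
                factor(x@spans$sentence, levels = seq_len(nSentences(x))))
    return(Map(.spansToTags, lengths(x@tokens), sp))
  }
  .spansToTags(length(x@tokens[[i]]),
               as.data.frame(x@spans[x@spans$sentence == i, , drop = FALSE]))
}

.spansToTags <- function(n, spans) {
  tags <- rep("O", n)
  if (nrow(spans)) for (r in seq_len(nrow(spans))) {
    s <- spans$start[r]; e <- spans$end[r]; t <- spans$type[r]
    tags[s] <- paste0("B-", t)
    if (e > s) tags[(s + 1):e] <- paste0("I-", t)
  }
  tags
}

#' Decode a BIO tag sequence into entity spans
#'
#' Contiguous \code{B-t}, \code{I-t} runs become spans. An \code{I-t} that is
#' not preceded by a \code{B-t}/\code{I-t} of the same type opens a new span
#' (conventional repair of malformed sequences).
#'
#' @param tags Character vector of BIO tags.
#' @return A \code{data.frame} with columns \code{start}, \code{end},
#'   \code{type}.
#' @export
bioDecode <- function(tags) {
  start <- integer(); end <- integer(); type <- character()
  open <- NA_character_; s0 <- 0L
  for (i in seq_along(tags)) {
    tg <- tags[i]
    if (tg == "O") {
      if (!is.na(open)) { start <- c(start, s0); end <- c(end, i - 1L); type <- c(type, open) }
      open <- NA_character_
    } else {
      pre <- substr(tg, 1, 1); ty <- substring(tg, 3)
      if (pre == "B" || is.na(open) || ty != open) {
        if (!is.na(open)) { start <- c(start, s0); end <- c(end, i - 1L); type <- c(type, open) }
        open <- ty; s0 <- i
      }
    }
  }
  if (!is.na(open)) { start <- c(start, s0); end <- c(end, length(tags)); type <- c(type, open) }
  data.frame(start = start, end = end, type = type,
             stringsAsFactors = FALSE)
}

# ---- BIO file format --------------------------------------------------------

.validTags <- function() c("O", as.vector(outer(c("B-", "I-"), entityTypes(),
                                                paste0)))

#' Read a BIO/CoNLL token-per-line corpus
#'
#' One \code{token<TAB>tag} pair per line, a blank line between sentences, and
#' \code{-DOCSTART- <doc_id>} lines marking document boundaries. Sentence ids
#' are assigned positionally (\code{"s00001"}, ...).
#'
#' @param path File to read.
#' @return An [NERCorpus-class].
#' @export
readBIO <- function(path) {
  if (!file.exists(path)) stop("cannot read BIO file: ", path)
  lines <- readLines(path)
  isDoc <- startsWith(lines, "-DOCSTART-")
  isSep <- !nzchar(trimws(lines)) & !isDoc
  isTok <- !isDoc & !isSep
  docAt <- cumsum(isDoc)
  docNames <- trimws(sub("^-DOCSTART-", "", lines[isDoc]))
  grp <- cumsum(isSep | isDoc)
  tokLines <- which(isTok)
  if (!length(tokLines))
    return(NERCorpus(list(), doc = character(0)))
  parts <- strsplit(lines[tokLines], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop(sprintf("line %d: expected 'token<TAB>tag'", tokLines[bad[1]]))
  tok <- vapply(parts, `[`, "", 1L)
  tag <- vapply(parts, `[`, "", 2L)
  badTag <- which(!tag %in% .validTags())
  if (length(badTag))
    stop(sprintf("line %d: unknown tag label '%s'",
                 tokLines[badTag[1]], tag[badTag[1]]))
  g <- factor(grp[tokLines], levels = unique(grp[tokLines]))
  toks <- split(tok, g)
  tagsL <- split(tag, g)
  docPer <- docAt[tokLines][!duplicated(g)]
  doc <- ifelse(docPer == 0, "doc1", docNames[pmax(docPer, 1)])
  spans <- do.call(rbind, lapply(seq_along(tagsL), function(i) {
    d <- bioDecode(tagsL[[i]])
    if (nrow(d)) cbind(sentence = i, d) else NULL
  }))
  NERCorpus(unname(toks), spans = spans, doc = doc)
}

#' Write a corpus in BIO/CoNLL format
#'
#' Inverse of [readBIO()]: re-reading the written file yields an equal corpus
#' (positional sentence ids; per-sentence metadata is not serialised).
#'
#' @param x An [NERCorpus-class].
#' @param path Output file.
#' @return Invisibly, \code{path}.
#' @export
writeBIO <- function(x, path) {
  tags <- bioEncode(x)
  out <- character()
  docs <- documents(x)
  idx <- match(x@sid, x@sid)  # positional
  for (d in names(docs)) {
    out <- c(out, paste0("-DOCSTART- ", d))
    for (sid in docs[[d]]) {
      i <- match(sid, x@sid)
      out <- c(out, paste(x@tokens[[i]], tags[[i]], sep = "\t"), "")
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

# ---- corpus statistics ------------------------------------------------------

#' Corpus characteristics
#'
#' Counts of sentences, words and entities, plus the derived ratios: words
#' per sentence, entities per sentence, and entity density (the number of
#' words inside entity spans divided by the total number of words). Ratios
#' are returned at full precision; use [roundHalfUp()] at reporting time.
#'
#' @param x An [NERCorpus-class].
#' @return One-row \code{data.frame} with columns \code{sentence_count},
#'   \code{word_count}, \code{entity_count}, \code{entity_word_count},
#'   \code{words_per_sentence}, \code{entities_per_sentence},
#'   \code{entity_density}. For an empty corpus the ratio columns are
#'   \code{NA} and a warning is raised.
#' @export
corpusStats <- function(x) {
  sc <- nSentences(x)
  wc <- sum(lengths(x@tokens))
  ec <- nrow(x@spans)
  ewc <- if (ec) sum(x@spans$end - x@spans$start + 1L) else 0L
  if (sc == 0) {
    warning("empty corpus: ratio statistics are undefined")
    return(data.frame(sentence_count = 0L, word_count = 0L, entity_count = 0L,
                      entity_word_count = 0L, words_per_sentence = NA_real_,
                      entities_per_sentence = NA_real_,
                      entity_density = NA_real_))
  }
  data.frame(sentence_count = sc, word_count = wc, entity_count = ec,
             entity_word_count = ewc,
             words_per_sentence = wc / sc,
             entities_per_sentence = ec / sc,
             entity_density = if (wc > 0) ewc / wc else NA_real_)
}

#' Deduplicate and split a corpus into folds
#'
#' Removes duplicate sentences (exact match of the whitespace-joined token
#' string, first occurrence kept), then randomly partitions the unique
#' sentences into \code{k} folds whose sizes differ by at most one.
#'
#' @param x An [NERCorpus-class].
#' @param k Number of folds (>= 2).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return A list of \code{k} character vectors of sentence ids.
#' @export
dedupAndSplit <- function(x, k, seed) {
  if (k < 2) stop("k must be >= 2")
  keep <- !duplicated(sentenceStrings(x))
  sids <- x@sid[keep]
  n <- length(sids)
  if (k > n) stop("more folds than unique sentences")
  perm <- withSeed(seed, sample.int(n))
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  split(sids[perm], rep(seq_len(k), times = sizes))
}

#' Drop duplicate sentences
#'
#' @param x An [NERCorpus-class].
#' @return The corpus restricted to the first occurrence of each distinct
#'   surface string.
#' @export
dedupCorpus <- function(x) x[!duplicated(sentenceStrings(x))]
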