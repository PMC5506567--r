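test_that("BIO tags decode to the spans that produced them", {
  corp <- tinyCorpus()
  tags <- bioEncode(corp)
  expect_equal(tags[[1]], c("B-treatment", "I-treatment", "I-treatment"))
  expect_equal(tags[[2]], c("O", "B-problem", "I-problem", "O", "O"))
  # inverse pair on every sentence of a generated fixture
  gen <- smallGenerated()
  gtags <- bioEncode(gen)
  sp <- as.data.frame(entitySpans(gen))
  for (i in seq_len(nSentences(gen))) {
    dec <- bioDecode(gtags[[i]])
    ref <- sp[sp$sentence == i, c("start", "end", "type")]
    rownames(ref) <- NULL
    expect_equal(dec, ref)
  }
  # sentence with no spans is all O
  noSpan <- NERCorpus(list(c("plain", "text")))
  expect_equal(bioEncode(noSpan, 1), c("O", "O"))
  # I- without a matching opener starts a new span (repair)
  expect_equal(bioDecode(c("I-test", "I-problem")),
               data.frame(start = 1:2, end = 1:2,
                          type = c("test", "problem")))
})

test_that("BIO files round-trip and are idempotent", {
  f <- tempfile(fileext = ".bio")
  direct <- c("Dulcolax\tB-treatment", "10\tI-treatment", "mg\tI-treatment")
  writeLines(c("-DOCSTART- d1", direct, ""), f)
  corp <- readBIO(f)
  expect_equal(nSentences(corp), 1)
  expect_equal(as.data.frame(entitySpans(corp)),
               data.frame(sentence = 1L, start = 1L, end = 3L,
                          type = "treatment"))
  # empty file
  writeLines(character(0), f)
  expect_equal(nSentences(readBIO(f)), 0)
  # generated fixture: read(write(c)) == c and write is idempotent bytewise
  gen <- smallGenerated(nDocuments = 6)
  writeBIO(gen, f)
  back <- readBIO(f)
  expect_true(corpusIdentical(gen, back))
  f2 <- tempfile(fileext = ".bio")
  writeBIO(back, f2)
  expect_identical(readLines(f), readLines(f2))
  # empty and unannotated corpora serialise cleanly
  writeBIO(NERCorpus(list(), doc = character(0)), f)
  expect_equal(nSentences(readBIO(f)), 0)
  writeBIO(NERCorpus(list(c("just", "words"))), f)
  expect_true(all(grepl("\tO$", grep("\t", readLines(f), value = TRUE))))
})

test_that("malformed BIO input is rejected with a line number", {
  f <- tempfile()
  writeLines(c("ok\tO", "bad\tB-drug"), f)
  expect_error(readBIO(f), "line 2.*B-drug")
  writeLines(c("no tab here"), f)
  expect_error(readBIO(f), "line 1")
  expect_error(readBIO(file.path(tempdir(), "absent.bio")), "cannot read")
})

test_that("corpus statistics match direct ratios and add over unions", {
  one <- NERCorpus(list(c("a", "b", "c", "d")),
                   spans = data.frame(sentence = 1, start = 2, end = 2,
                                      type = "problem"))
  st <- corpusStats(one)
  expect_equal(st$entity_density, 0.25)
  expect_equal(st$words_per_sentence, 4)
  # additivity: stats of a concatenation equal stats from summed counts
  a <- smallGenerated(nDocuments = 4, seed = 1)
  b <- smallGenerated(nDocuments = 4, seed = 2)
  sb <- b
  ab <- c(a, NERCorpus(as.list(sentenceTokens(b)),
                       spans = as.data.frame(entitySpans(b)),
                       sid = paste0("x", sentenceIds(b)), doc = docIds(b)))
  sa <- corpusStats(a); sbb <- corpusStats(b); sab <- corpusStats(ab)
  expect_equal(sab$word_count, sa$word_count + sbb$word_count)
  expect_equal(sab$entity_count, sa$entity_count + sbb$entity_count)
  expect_equal(sab$words_per_sentence,
               (sa$word_count + sbb$word_count) /
                 (sa$sentence_count + sbb$sentence_count))
  expect_warning(st0 <- corpusStats(NERCorpus(list(), doc = character(0))),
                 "undefined")
  expect_true(is.na(st0$words_per_sentence))
})

test_that("presentation rounding is half-up at two decimals", {
  expect_equal(roundHalfUp(7.875), 7.88)
  expect_equal(roundHalfUp(11.0749), 11.07)
  expect_equal(roundHalfUp(1.005), 1.01)
  expect_equal(roundHalfUp(-1.005), -1.01)
})

test_that("dedup-and-split yields balanced, seed-stable, exhaustive folds", {
  ten <- NERCorpus(lapply(1:10, function(i) c("w", as.character(i))))
  folds <- dedupAndSplit(ten, 5, seed = 3)
  expect_equal(lengths(folds), rep(2L, 5), ignore_attr = TRUE)
  expect_setequal(unlist(folds), sentenceIds(ten))
  expect_identical(folds, dedupAndSplit(ten, 5, seed = 3))
  expect_false(identical(folds, dedupAndSplit(ten, 5, seed = 4)))
  expect_error(dedupAndSplit(ten, 11, seed = 1), "folds")
  expect_error(dedupAndSplit(ten, 1, seed = 1), "k must be")
  # duplicates removed before splitting
  dup <- NERCorpus(rep(list(c("same", "line")), 4))
  expect_error(dedupAndSplit(dup, 2, seed = 1), "folds")
  # uneven: 11 unique sentences into 5 folds -> sizes differ by at most one
  eleven <- NERCorpus(lapply(1:11, function(i) c("w", as.character(i))))
  f11 <- dedupAndSplit(eleven, 5, seed = 9)
  expect_true(max(lengths(f11)) - min(lengths(f11)) <= 1)
})

test_that("corpus validity catches malformed objects", {
  expect_error(NERCorpus(list(c("a b"))), "whitespace")
  expect_error(NERCorpus(list(character(0))), "at least one token")
  expect_error(NERCorpus(list(c("a", "b")),
                         spans = data.frame(sentence = 1, start = 1, end = 3,
                                            type = "problem")),
               "range")
  expect_error(NERCorpus(list(c("a", "b", "c")),
                         spans = data.frame(sentence = c(1, 1),
                                            start = c(1, 2), end = c(2, 3),
                                            type = "problem")),
               "overlap")
  expect_error(NERCorpus(list(c("a")), sid = c("s1", "s2")), "length")
  expect_error(NERCorpus(list(c("a"), c("b")), sid = c("s1", "s1")),
               "unique")
})
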