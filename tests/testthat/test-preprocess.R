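# Tokenization, stop words, MWE merging, lemmatization, vectorization.

test_that("tokenize_clean handles empty text, negations and numbers", {
  cfg <- preprocess_config()
  expect_identical(tokenize_clean("", cfg), character())

  toks <- tokenize_clean(
    "Es ist keine Nekrose und nicht ein Tumor erkennbar.", cfg)
  expect_true("keine" %in% toks)   # negation survives the stop list
  expect_true("nicht" %in% toks)
  expect_false("es" %in% toks)     # plain stop words removed
  expect_false("und" %in% toks)

  toks <- tokenize_clean(
    "Am 12.05.2021 zeigte sich 5% Schaden, Oxford m1 e0, Fall 4711.", cfg)
  # independent digit-only scan on the output
  expect_false(any(grepl("^[0-9]+$", toks)))
  expect_true(all(c("m1", "e0") %in% toks)) # grading codes are kept
  expect_false("4711" %in% toks)
})

test_that("stop-word configuration edits are applied and consistent", {
  cfg <- preprocess_config(stopword_additions = c("ca", "zzz"),
                           stopword_removals = c("kein", "keine"))
  expect_true(all(c("ca", "zzz") %in% cfg$stopwords))
  expect_length(intersect(cfg$stopword_removals, cfg$stopwords), 0)
  # vocabulary shrinks monotonically as stop words are added
  txt <- "ca zzz befund niere glomerulus"
  base <- tokenize_clean(txt, preprocess_config())
  more <- tokenize_clean(txt, cfg)
  expect_true(all(more %in% base))
  expect_lt(length(more), length(base))
})

test_that("merge_mwe is leftmost-longest and matches the reference", {
  expect_identical(
    merge_mwe(c("lupus", "nephritis"), list(c("lupus", "nephritis"))),
    "lupus_nephritis"
  )
  expect_identical(merge_mwe(c("a", "b", "c"), list()), c("a", "b", "c"))
  # overlapping patterns: leftmost wins
  expect_identical(
    merge_mwe(c("a", "b", "c"), list(c("a", "b"), c("b", "c"))),
    c("a_b", "c")
  )
  # randomized property check against the recursive reference
  set.seed(42)
  mwes <- list(c("x", "y"), c("y", "z", "w"), c("z", "w"))
  for (i in 1:25) {
    toks <- sample(c("x", "y", "z", "w", "q"), sample(3:12, 1),
                   replace = TRUE)
    expect_identical(merge_mwe(toks, mwes), merge_mwe_oracle(toks, mwes))
  }
})

test_that("lemmatize preserves length and applies replacements", {
  expect_identical(lemmatize(c("a", "b")), c("a", "b"))
  expect_identical(
    lemmatize(c("glomerulis", "tubuli"),
              replacements = c(glomerulis = "glomerulus")),
    c("glomerulus", "tubuli")
  )
  set.seed(7)
  for (i in 1:10) {
    toks <- sample(letters, sample(0:20, 1), replace = TRUE)
    expect_length(lemmatize(toks, toupper), length(toks))
  }
})

test_that("the pipeline is idempotent on its own output", {
  cfg <- preprocess_config(
    mwe_list = list(c("lupus", "nephritis")),
    lemma_replacements = c(glomerulis = "glomerulus")
  )
  txt <- "Keine Lupus Nephritis, aber 3 Glomerulis mit 5% Schaden."
  once <- preprocess_text(txt, cfg)
  twice <- preprocess_text(paste(once, collapse = " "), cfg)
  expect_identical(twice, once)
})

test_that("vectorize: counts, conservation, and hand-computed tf-idf", {
  docs <- toy_docs(list(c("a", "a", "b"), c("a", "c"), c("c", "b", "c")))
  dtm <- vectorize(docs, "count")
  m <- as.matrix(dtm$matrix)
  expect_equal(unname(m["d1", ]), c(2, 1, 0))
  # column sums equal corpus term frequencies
  expect_equal(unname(Matrix::colSums(dtm$matrix)), c(3, 2, 3))

  tf <- vectorize(docs, "tfidf")
  # closed-form smoothed idf on the 3-doc toy: df(a)=2, df(b)=2, df(c)=2
  idf <- log((1 + 3) / (1 + c(a = 2, b = 2, c = 2))) + 1
  row1 <- c(2 * idf["a"], 1 * idf["b"], 0)
  row1 <- row1 / sqrt(sum(row1^2))
  expect_equal(unname(as.matrix(tf$matrix)["d1", ]), unname(row1),
               tolerance = 1e-12)
  # unit L2 rows
  expect_equal(unname(Matrix::rowSums(tf$matrix^2)), rep(1, 3),
               tolerance = 1e-12)
  # a term present in every doc gets the minimal idf
  docs2 <- toy_docs(list(c("x", "u"), c("x", "v"), c("x", "w")))
  tf2 <- vectorize(docs2, "tfidf")
  idf2 <- log((1 + 3) / (1 + Matrix::colSums(vectorize(docs2, "count")$matrix > 0))) + 1
  expect_equal(unname(which.min(idf2)), which(tf2$vocabulary == "x"))

  expect_error(vectorize(toy_docs(list(character()))), "vocabulary")
})

test_that("DTM export round-trips through MatrixMarket", {
  docs <- toy_docs(list(c("a", "b"), c("b", "c", "c")))
  dtm <- vectorize(docs, "count")
  dir <- withr::local_tempdir()
  write_dtm(dtm, dir)
  back <- read_dtm(dir)
  expect_equal(as.matrix(back$matrix), as.matrix(dtm$matrix))
  expect_identical(back$vocabulary, dtm$vocabulary)
  expect_identical(back$doc_ids, dtm$doc_ids)
})
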