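# Tokenization and normalization of German section texts, and construction
# of count / tf-idf document-term matrices.
#
# Pipeline order is fixed: lowercase -> punctuation strip -> tokenize ->
# number removal -> stop words -> lemmatize -> MWE merge. Re-running the
# pipeline on its own output is a no-op.

#' Load the packaged German stop-word list
#'
#' @return Character vector of stop words.
#' @export
german_stopwords <- function() {
  path <- system.file("extdata", "stopwords_de.txt", package = "nephrotext")
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Preprocessing configuration
#'
#' The active stop-word set is `union(stopwords, stopword_additions)` minus
#' `stopword_removals`. By default the German negations ("kein", "keine",
#' "nicht", ...) are removed from the stop list so they survive filtering —
#' in pathology reports the absence of a finding ("keine Nekrose") is
#' itself diagnostic — and the abbreviation "ca" (approx.) is added.
#'
#' @param stopwords Base stop-word list.
#' @param stopword_removals Terms deleted from the base list (negations).
#' @param stopword_additions Terms added to the list.
#' @param mwe_list List of character vectors, each a multi-word expression
#'   (length >= 2) to merge into a single underscore-joined token.
#' @param lemma_replacements Named character vector, term -> replacement,
#'   applied after the lemmatizer.
#' @param lemmatizer Pluggable vectorized term -> term function (identity
#'   by default; a German lemmatizer can be adapted here).
#' @param remove_numbers Drop digit-only and digit-punctuation tokens
#'   (dates, "5%", report ids). Alphanumeric grading codes like "m1" or
#'   "e0" are kept: they are diagnostic vocabulary.
#' @param lowercase,strip_punct Case folding / punctuation stripping flags.
#' @return A `preprocess_config` object.
#' @export
preprocess_config <- function(stopwords = german_stopwords(),
                              stopword_removals = c(
                                "kein", "keine", "keinem", "keinen",
                                "keiner", "keines", "nicht", "nichts",
                                "ohne"
                              ),
                              stopword_additions = c("ca"),
                              mwe_list = list(),
                              lemma_replacements = character(),
                              lemmatizer = identity,
                              remove_numbers = TRUE,
                              lowercase = TRUE,
                              strip_punct = TRUE) {
  if (length(mwe_list) &&
      any(vapply(mwe_list, length, integer(1)) < 2)) {
    stop("every multi-word expression must have at least 2 tokens")
  }
  active <- setdiff(union(tolower(stopwords), tolower(stopword_additions)),
                    tolower(stopword_removals))
  structure(
    list(
      stopwords = active,
      stopword_removals = tolower(stopword_removals),
      stopword_additions = tolower(stopword_additions),
      mwe_list = mwe_list,
      lemma_replacements = lemma_replacements,
      lemmatizer = lemmatizer,
      remove_numbers = remove_numbers,
      lowercase = lowercase,
      strip_punct = strip_punct
    ),
    class = "preprocess_config"
  )
}

#' Tokenize and clean one text
#'
#' Applies case folding, punctuation stripping, whitespace tokenization,
#' number removal and stop-word filtering (with negations retained per the
#' configuration). Lemmatization and MWE merging are separate steps; see
#' [preprocess_text()] for the full pipeline.
#'
#' @param text A character scalar.
#' @param config A [preprocess_config()].
#' @return Character vector of tokens (empty for empty text).
#' @export
tokenize_clean <- function(text, config = preprocess_config()) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(character())
  x <- text
  if (config$lowercase) x <- tolower(x)
  if (config$strip_punct) {
    # keep underscores: they join already-merged multi-word expressions
    x <- gsub("[^[:alnum:][:space:]_]", " ", x, perl = TRUE)
  }
  toks <- strsplit(trimws(x), "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (config$remove_numbers) {
    numeric_like <- grepl("^[[:digit:][:punct:]]+$", toks) &
      grepl("[[:digit:]]", toks)
    toks <- toks[!numeric_like]
  }
  toks[!(toks %in% config$stopwords)]
}

#' Apply a lemmatizer and custom replacements to tokens
#'
#' @param tokens Character vector.
#' @param lemmatizer Vectorized term -> term function.
#' @param replacements Named character vector (term -> replacement),
#'   applied after the lemmatizer.
#' @return Character vector of the same length.
#' @export
lemmatize <- function(tokens, lemmatizer = identity,
                      replacements = character()) {
  if (length(tokens) == 0) return(character())
  out <- as.character(lemmatizer(tokens))
  if (length(out) != length(tokens)) {
    stop("lemmatizer must preserve token count")
  }
  if (length(replacements)) {
    hit <- out %in% names(replacements)
    out[hit] <- unname(replacements[out[hit]])
  }
  out
}

#' Merge multi-word expressions into single tokens
#'
#' Leftmost-longest matching: at each position the longest matching
#' expression wins and the scan continues after it.
#'
#' @param tokens Character vector (same case as `mwe_list`).
#' @param mwe_list List of character vectors of length >= 2.
#' @return Character vector with matched sequences joined by `_`.
#' @export
merge_mwe <- function(tokens, mwe_list = list()) {
  if (length(tokens) == 0 || length(mwe_list) == 0) return(tokens)
  lens <- vapply(mwe_list, length, integer(1))
  ord <- order(-lens) # try longest first at each position
  mwe_list <- mwe_list[ord]
  lens <- lens[ord]
  out <- character(0)
  i <- 1L
  n <- length(tokens)
  while (i <= n) {
    matched <- 0L
    for (m in seq_along(mwe_list)) {
      L <- lens[m]
      if (i + L - 1L <= n &&
          identical(tokens[i:(i + L - 1L)], mwe_list[[m]])) {
        matched <- L
        out <- c(out, paste(mwe_list[[m]], collapse = "_"))
        break
      }
    }
    if (matched > 0L) i <- i + matched else {
      out <- c(out, tokens[i])
      i <- i + 1L
    }
  }
  out
}

#' Full preprocessing pipeline for one text
#'
#' @inheritParams tokenize_clean
#' @return Character vector of normalized tokens.
#' @export
preprocess_text <- function(text, config = preprocess_config()) {
  toks <- tokenize_clean(text, config)
  toks <- lemmatize(toks, config$lemmatizer, config$lemma_replacements)
  merge_mwe(toks, config$mwe_list)
}

#' Preprocess one section of every corpus report into token documents
#'
#' @param corpus A `nephro_corpus`.
#' @param section Section to tokenize.
#' @param config A [preprocess_config()].
#' @return List of `token_doc` objects (`doc_id`, `tokens`).
#' @export
preprocess_corpus <- function(corpus,
                              section = c("diagnosis", "microscopy",
                                          "clinical"),
                              config = preprocess_config()) {
  section <- match.arg(section)
  texts <- corpus_section(corpus, section)
  mapply(function(id, txt) {
    token_doc(id, preprocess_text(txt, config))
  }, names(texts), texts, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' @rdname preprocess_corpus
#' @param doc_id Document identifier.
#' @param tokens Character vector of tokens.
#' @export
token_doc <- function(doc_id, tokens) {
  structure(list(doc_id = doc_id, tokens = as.character(tokens)),
            class = "token_doc")
}

#' Build a document-term matrix from token documents
#'
#' Count mode stores raw term frequencies. tf-idf mode multiplies counts by
#' a smoothed inverse document frequency, `idf = ln((1 + n) / (1 + df)) + 1`,
#' and L2-normalizes each document row; the smoothing keeps idf positive
#' for ubiquitous terms and avoids division by zero for unseen ones.
#'
#' @param docs List of [token_doc()] objects.
#' @param mode `"count"` or `"tfidf"`.
#' @return A `nephro_dtm`: list with sparse `matrix`
#'   (`Matrix::dgCMatrix`), `vocabulary`, `doc_ids` and `mode`.
#' @export
vectorize <- function(docs, mode = c("count", "tfidf")) {
  mode <- match.arg(mode)
  stopifnot(length(docs) >= 1)
  doc_ids <- unname(vapply(docs, `[[`, character(1), "doc_id"))
  if (anyDuplicated(doc_ids)) stop("duplicate doc ids")
  all_tokens <- lapply(docs, `[[`, "tokens")
  vocab <- sort(unique(unlist(all_tokens)))
  if (length(vocab) == 0) stop("empty vocabulary: no tokens in any document")
  triplets <- lapply(seq_along(docs), function(i) {
    tok <- all_tokens[[i]]
    if (length(tok) == 0) return(NULL)
    tab <- table(tok)
    cbind(i = i, j = match(names(tab), vocab), x = as.numeric(tab))
  })
  triplets <- do.call(rbind, triplets)
  m <- Matrix::sparseMatrix(
    i = triplets[, "i"], j = triplets[, "j"], x = triplets[, "x"],
    dims = c(length(docs), length(vocab)),
    dimnames = list(doc_ids, vocab)
  )
  if (mode == "tfidf") m <- apply_tfidf(m)
  new_dtm(m, vocab, doc_ids, mode)
}

new_dtm <- function(m, vocabulary, doc_ids, mode) {
  structure(
    list(matrix = m, vocabulary = vocabulary, doc_ids = doc_ids,
         mode = mode),
    class = "nephro_dtm"
  )
}

#' @export
print.nephro_dtm <- function(x, ...) {
  cat(sprintf("<nephro_dtm> %d docs x %d terms (%s mode)\n",
              nrow(x$matrix), ncol(x$matrix), x$mode))
  invisible(x)
}

#' @export
dim.nephro_dtm <- function(x) dim(x$matrix)

# Smoothed tf-idf with per-document L2 normalization.
apply_tfidf <- function(m) {
  dn <- dimnames(m)
  n <- nrow(m)
  df <- Matrix::colSums(m > 0)
  idf <- log((1 + n) / (1 + df)) + 1
  m <- m %*% Matrix::Diagonal(x = idf)
  norms <- sqrt(Matrix::rowSums(m^2))
  norms[norms == 0] <- 1
  m <- as(Matrix::Diagonal(x = 1 / norms) %*% m, "CsparseMatrix")
  dimnames(m) <- dn
  m
}

#' Convert a count-mode DTM to tf-idf
#'
#' @param dtm A count-mode `nephro_dtm`.
#' @return A tf-idf-mode `nephro_dtm` over the same vocabulary.
#' @export
dtm_tfidf <- function(dtm) {
  stopifnot(inherits(dtm, "nephro_dtm"))
  if (dtm$mode != "count") stop("expected a count-mode matrix")
  m <- apply_tfidf(dtm$matrix)
  dimnames(m) <- dimnames(dtm$matrix)
  new_dtm(m, dtm$vocabulary, dtm$doc_ids, "tfidf")
}

#' Export / import a DTM as MatrixMarket plus sidecar text files
#'
#' Writes `matrix.mtx`, `vocabulary.txt` and `doc_ids.txt` into `dir`.
#'
#' @param dtm A `nephro_dtm`.
#' @param dir Output directory (created if missing).
#' @return `write_dtm` returns `dir` invisibly; `read_dtm` the `nephro_dtm`.
#' @export
write_dtm <- function(dtm, dir) {
  stopifnot(inherits(dtm, "nephro_dtm"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(dtm$matrix, file.path(dir, "matrix.mtx"))
  writeLines(dtm$vocabulary, file.path(dir, "vocabulary.txt"),
             useBytes = TRUE)
  writeLines(dtm$doc_ids, file.path(dir, "doc_ids.txt"), useBytes = TRUE)
  writeLines(dtm$mode, file.path(dir, "mode.txt"))
  invisible(dir)
}

#' @rdname write_dtm
#' @export
read_dtm <- function(dir) {
  m <- as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  vocab <- readLines(file.path(dir, "vocabulary.txt"), encoding = "UTF-8")
  ids <- readLines(file.path(dir, "doc_ids.txt"), encoding = "UTF-8")
  mode <- readLines(file.path(dir, "mode.txt"))[1]
  if (nrow(m) != length(ids) || ncol(m) != length(vocab)) {
    stop("matrix dimensions do not match sidecar files")
  }
  dimnames(m) <- list(ids, vocab)
  new_dtm(m, vocab, ids, mode)
}
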