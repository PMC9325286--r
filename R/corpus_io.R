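# Reading raw reports, splitting them into sections by German header tags,
# and persisting the sectioned corpus as line-delimited JSON records.

#' Construct a raw (unsegmented) report
#'
#' @param id Unique report identifier.
#' @param text Full report text (may be empty; segmentation handles it).
#' @param authors Optional character vector of author codes.
#' @return A `raw_report` object.
#' @export
raw_report <- function(id, text, authors = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(text), length(text) == 1L)
  structure(
    list(id = id, text = text, authors = authors),
    class = "raw_report"
  )
}

#' Read raw reports from disk
#'
#' Accepts either a directory of UTF-8 plain-text files (one report per
#' file, id = file name without extension, filename order) or a single
#' line-delimited JSON file with fields `id`, `text` and optionally
#' `authors`.
#'
#' @param path Directory of `.txt` files or a `.jsonl` file.
#' @param format `"auto"` (default), `"dir"` or `"jsonl"`.
#' @return A list of [raw_report()] objects, input order preserved.
#' @export
read_raw <- function(path, format = c("auto", "dir", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("path does not exist: ", path)
  if (format == "auto") {
    format <- if (dir.exists(path)) "dir" else "jsonl"
  }
  reports <- if (format == "dir") {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    lapply(files, function(f) {
      txt <- paste(readLines(f, encoding = "UTF-8", warn = FALSE),
                   collapse = "\n")
      raw_report(sub("\\.txt$", "", basename(f)), txt)
    })
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    lapply(lines, function(ln) {
      rec <- jsonlite::fromJSON(ln)
      if (is.null(rec$id) || is.null(rec$text)) {
        stop("record is missing an 'id' or 'text' field")
      }
      raw_report(as.character(rec$id), as.character(rec$text),
                 authors = if (!is.null(rec$authors)) {
                   as.character(unlist(rec$authors))
                 })
    })
  }
  ids <- vapply(reports, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate report ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  reports
}

#' Default section header tags
#'
#' The German header keywords marking the three report sections: clinical
#' information ("Klinische Angaben"), microscopic description
#' ("Mikroskopie") and the diagnosis/conclusion ("Beurteilung").
#'
#' @return Named list mapping section roles to ordered keyword vectors.
#' @export
default_section_tags <- function() {
  list(
    clinical   = c("Klinische Angaben"),
    microscopy = c("Mikroskopie"),
    diagnosis  = c("Beurteilung")
  )
}

# Locate the first occurrence of any keyword for one section role.
# Matching is case-insensitive, anchored at a line start, and tolerates an
# optional trailing colon. Returns c(start, end) in character positions or
# NULL.
find_tag <- function(text, keywords) {
  best <- NULL
  for (kw in keywords) {
    pat <- paste0("(?im)^[ \\t]*", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", kw),
                  "[ \\t]*:?")
    m <- regexpr(pat, text, perl = TRUE)
    if (m[1] != -1L) {
      cand <- c(m[1], m[1] + attr(m, "match.length") - 1L)
      if (is.null(best) || cand[1] < best[1]) best <- cand
    }
  }
  best
}

#' Split one raw report into its sections
#'
#' Text between a matched section tag and the next tag (or the end of the
#' report) becomes that section's content. A report lacking a nonempty
#' microscopy or diagnosis section is excluded rather than erroring: the
#' function then returns `NULL`.
#'
#' @param report A [raw_report()].
#' @param tags Tag configuration as from [default_section_tags()].
#' @return A `sectioned_report` (list with `id`, `clinical`, `microscopy`,
#'   `diagnosis`, `authors`) or `NULL` when the report cannot be segmented.
#' @export
segment_report <- function(report, tags = default_section_tags()) {
  stopifnot(inherits(report, "raw_report"))
  stopifnot(all(c("microscopy", "diagnosis") %in% names(tags)))
  text <- report$text
  hits <- list()
  for (role in names(tags)) {
    pos <- find_tag(text, tags[[role]])
    if (!is.null(pos)) hits[[role]] <- pos
  }
  if (!all(c("microscopy", "diagnosis") %in% names(hits))) return(NULL)
  ord <- order(vapply(hits, `[`, numeric(1), 1))
  hits <- hits[ord]
  starts <- vapply(hits, `[`, numeric(1), 1)
  ends <- vapply(hits, `[`, numeric(1), 2)
  sections <- list()
  for (i in seq_along(hits)) {
    from <- ends[i] + 1L
    to <- if (i < length(hits)) starts[i + 1L] - 1L else nchar(text)
    sections[[names(hits)[i]]] <-
      trimws(substr(text, from, to))
  }
  if (!nzchar(sections$microscopy %||% "") ||
      !nzchar(sections$diagnosis %||% "")) {
    return(NULL)
  }
  structure(
    list(
      id = report$id,
      clinical = sections$clinical %||% NA_character_,
      microscopy = sections$microscopy,
      diagnosis = sections$diagnosis,
      authors = report$authors
    ),
    class = "sectioned_report"
  )
}

#' Segment a whole set of raw reports into a corpus
#'
#' @param raws List of [raw_report()] objects.
#' @param tags Tag configuration.
#' @return A `nephro_corpus`: list with `reports` (list of
#'   `sectioned_report`), `excluded` (count) and `excluded_ids`.
#' @export
segment_corpus <- function(raws, tags = default_section_tags()) {
  ids <- vapply(raws, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate report ids in input")
  seg <- lapply(raws, segment_report, tags = tags)
  keep <- !vapply(seg, is.null, logical(1))
  new_corpus(seg[keep], excluded_ids = ids[!keep])
}

new_corpus <- function(reports, excluded_ids = character()) {
  ids <- vapply(reports, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate report ids in corpus")
  structure(
    list(
      reports = reports,
      excluded = length(excluded_ids),
      excluded_ids = excluded_ids
    ),
    class = "nephro_corpus"
  )
}

#' @export
length.nephro_corpus <- function(x) length(x$reports)

#' @export
print.nephro_corpus <- function(x, ...) {
  cat(sprintf(
    "<nephro_corpus> %d sectioned reports (%d excluded at segmentation)\n",
    length(x$reports), x$excluded
  ))
  invisible(x)
}

#' Extract one section from every report of a corpus
#'
#' @param corpus A `nephro_corpus`.
#' @param section `"diagnosis"`, `"microscopy"` or `"clinical"`.
#' @return Named character vector (names = report ids).
#' @export
corpus_section <- function(corpus,
                           section = c("diagnosis", "microscopy",
                                       "clinical")) {
  section <- match.arg(section)
  out <- vapply(corpus$reports, function(r) {
    as.character(r[[section]] %||% NA_character_)
  }, character(1))
  names(out) <- corpus_ids(corpus)
  out
}

#' @rdname corpus_section
#' @export
corpus_ids <- function(corpus) {
  vapply(corpus$reports, `[[`, character(1), "id")
}

#' Author codes per report
#'
#' Multi-author reports are collapsed into one combined code (sorted,
#' joined with `+`), mirroring how jointly written reports are displayed
#' as a separate category in author-confound plots.
#'
#' @param corpus A `nephro_corpus`.
#' @return Named character vector; `NA` where no authors are recorded.
#' @export
corpus_authors <- function(corpus) {
  out <- vapply(corpus$reports, function(r) {
    if (is.null(r$authors) || length(r$authors) == 0) {
      NA_character_
    } else {
      paste(sort(unique(r$authors)), collapse = "+")
    }
  }, character(1))
  names(out) <- corpus_ids(corpus)
  out
}

#' Basic corpus statistics
#'
#' Whitespace-token counts over the concatenated microscopy and diagnosis
#' sections.
#'
#' @param corpus A nonempty `nephro_corpus`.
#' @return List with `n_reports`, `total_words`, `mean_words_per_report`.
#' @export
corpus_stats <- function(corpus) {
  stopifnot(inherits(corpus, "nephro_corpus"))
  if (length(corpus$reports) == 0) stop("corpus is empty")
  words <- vapply(corpus$reports, function(r) {
    txt <- trimws(paste(r$microscopy, r$diagnosis))
    if (!nzchar(txt)) return(0L)
    length(strsplit(txt, "[[:space:]]+")[[1]])
  }, integer(1))
  list(
    n_reports = length(words),
    total_words = sum(words),
    mean_words_per_report = sum(words) / length(words)
  )
}

#' Persist / load a sectioned corpus as line-delimited JSON
#'
#' The first line is a metadata record carrying the exclusion count; each
#' following line is one report. `load_corpus(write_corpus(x))` is the
#' identity.
#'
#' @param corpus A `nephro_corpus`.
#' @param path Output file path.
#' @return `write_corpus` returns `path` invisibly; `load_corpus` returns
#'   the corpus.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "nephro_corpus"))
  meta <- jsonlite::toJSON(
    list(record_type = "corpus_meta", excluded = corpus$excluded,
         excluded_ids = as.list(corpus$excluded_ids)),
    auto_unbox = TRUE
  )
  recs <- vapply(corpus$reports, function(r) {
    jsonlite::toJSON(
      list(
        id = r$id,
        clinical = if (is.na(r$clinical %||% NA)) NULL else r$clinical,
        microscopy = r$microscopy,
        diagnosis = r$diagnosis,
        authors = if (is.null(r$authors)) NULL else as.list(r$authors)
      ),
      auto_unbox = TRUE, null = "null"
    )
  }, character(1))
  writeLines(c(meta, recs), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_corpus
#' @export
load_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0) stop("empty corpus file")
  meta <- jsonlite::fromJSON(lines[1])
  if (!identical(meta$record_type, "corpus_meta")) {
    stop("not a corpus file: missing metadata record")
  }
  reports <- lapply(lines[-1], function(ln) {
    rec <- jsonlite::fromJSON(ln)
    for (f in c("id", "microscopy", "diagnosis")) {
      if (is.null(rec[[f]]) || !nzchar(rec[[f]])) {
        stop("corpus record is missing required field '", f, "'")
      }
    }
    structure(
      list(
        id = rec$id,
        clinical = rec$clinical %||% NA_character_,
        microscopy = rec$microscopy,
        diagnosis = rec$diagnosis,
        authors = if (!is.null(rec$authors)) as.character(unlist(rec$authors))
      ),
      class = "sectioned_report"
    )
  })
  new_corpus(reports,
             excluded_ids = as.character(unlist(meta$excluded_ids)))
}
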