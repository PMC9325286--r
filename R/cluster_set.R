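# The cluster-set container: one complete assignment of documents to
# clusters, with -1 as the outlier sentinel.

#' Construct a cluster-set
#'
#' @param labels Integer vector with values in `{-1, 0, ..., K-1}`; `-1`
#'   marks outliers rejected by density-based methods.
#' @param doc_ids Document identifiers aligned with `labels`.
#' @param method Name of the clustering backend.
#' @param params Named list of backend parameters.
#' @param seed Seed the backend ran under.
#' @return A `cluster_set` object.
#' @export
cluster_set <- function(labels, doc_ids, method, params = list(),
                        seed = NA_integer_) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(doc_ids))
  if (any(labels < -1L)) stop("labels must be -1 (outlier) or >= 0")
  pos <- sort(unique(labels[labels >= 0L]))
  if (length(pos) && !identical(pos, seq_along(pos) - 1L)) {
    stop("nonnegative labels must be compact: 0..K-1")
  }
  structure(
    list(labels = labels, doc_ids = as.character(doc_ids),
         method = method, params = params, seed = seed),
    class = "cluster_set"
  )
}

# Relabel arbitrary assignments to compact 0..K-1 (order of first
# appearance of the sorted original labels), keeping -1 as is.
compact_labels <- function(labels) {
  labels <- as.integer(labels)
  pos <- sort(unique(labels[labels >= 0L]))
  out <- labels
  out[labels >= 0L] <- match(labels[labels >= 0L], pos) - 1L
  out
}

#' Number of clusters in a cluster-set
#'
#' @param cs A `cluster_set`.
#' @return Count of distinct nonnegative labels.
#' @export
n_clusters <- function(cs) {
  stopifnot(inherits(cs, "cluster_set"))
  length(unique(cs$labels[cs$labels >= 0L]))
}

#' Number of documents kept (not flagged as outliers)
#'
#' @param cs A `cluster_set`.
#' @return Integer count of documents with label `>= 0`.
#' @export
corpus_size_kept <- function(cs) {
  stopifnot(inherits(cs, "cluster_set"))
  sum(cs$labels >= 0L)
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf(
    "<cluster_set> method=%s: %d docs, %d clusters, %d outliers\n",
    x$method, length(x$labels), n_clusters(x), sum(x$labels == -1L)
  ))
  invisible(x)
}

#' Warn when the cluster count leaves the intended band
#'
#' The analysis aims for a manageable number of diagnostic groups (at
#' least `lo`, at most `hi`, inclusive). Leaving the band is reported but
#' never an error: some backends legitimately land outside it.
#'
#' @param cs A `cluster_set`.
#' @param lo,hi Inclusive bounds (defaults 10 and 20).
#' @return Character vector of warning messages (empty when within
#'   bounds); the messages are also signalled as R warnings.
#' @export
check_cluster_bounds <- function(cs, lo = 10L, hi = 20L) {
  k <- n_clusters(cs)
  msgs <- character()
  if (k < lo) {
    msgs <- c(msgs, sprintf(
      "cluster count %d is below the intended minimum of %d", k, lo))
  }
  if (k > hi) {
    msgs <- c(msgs, sprintf(
      "cluster count %d is above the intended maximum of %d", k, hi))
  }
  for (m in msgs) warning(m, call. = FALSE)
  msgs
}

#' Persist / load a cluster-set as a tab-separated record file
#'
#' The file has one `doc_id`/`label` row per document plus a JSON header
#' comment carrying method, params and seed.
#'
#' @param cs A `cluster_set`.
#' @param path Output file.
#' @return `write_cluster_set` returns `path` invisibly.
#' @export
write_cluster_set <- function(cs, path) {
  meta <- jsonlite::toJSON(
    list(method = cs$method, params = cs$params, seed = cs$seed),
    auto_unbox = TRUE, digits = NA
  )
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# ", meta), con)
  writeLines("doc_id\tlabel", con)
  writeLines(paste(cs$doc_ids, cs$labels, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_cluster_set
#' @export
read_cluster_set <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!startsWith(lines[1], "# ")) stop("missing cluster-set header")
  meta <- jsonlite::fromJSON(substring(lines[1], 3))
  body <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  cluster_set(
    labels = as.integer(vapply(body, `[`, character(1), 2)),
    doc_ids = vapply(body, `[`, character(1), 1),
    method = meta$method,
    params = as.list(meta$params),
    seed = meta$seed
  )
}
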