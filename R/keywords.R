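# Per-cluster keyword extraction: cluster-level tf-idf over pooled
# pseudo-documents, and linear-SVM weight analysis restricted to
# correctly predicted documents. Plus attachment of human cluster-name
# annotations.

#' Cluster keywords by pooled tf-idf
#'
#' Each cluster's documents are pooled into one pseudo-document; tf-idf is
#' computed across the pseudo-documents (so the idf contrasts clusters,
#' not documents) and the `top_n` highest-scoring terms per cluster are
#' returned. Ties break lexicographically; zero-scoring terms are never
#' listed.
#'
#' @param C Count-mode `nephro_dtm` aligned with `cs`.
#' @param cs A [cluster_set()] with >= 2 clusters.
#' @param top_n Keywords per cluster.
#' @return A `keyword_table`: `data.frame` with `cluster`, `rank`,
#'   `term`, `score`, `method = "tfidf"`.
#' @export
keywords_tfidf <- function(C, cs, top_n = 10L) {
  stopifnot(inherits(C, "nephro_dtm"), inherits(cs, "cluster_set"))
  if (C$mode != "count") stop("keyword tf-idf starts from term counts")
  labs <- sort(unique(cs$labels[cs$labels >= 0L]))
  if (length(labs) < 2) {
    stop("tf-idf keywords need >= 2 clusters (idf is degenerate)")
  }
  pooled <- do.call(rbind, lapply(labs, function(j) {
    Matrix::colSums(C$matrix[cs$labels == j, , drop = FALSE])
  }))
  m <- Matrix::Matrix(pooled, sparse = TRUE)
  dimnames(m) <- list(as.character(labs), C$vocabulary)
  scores <- as.matrix(apply_tfidf(m))
  kw <- keyword_rows(scores, labs, C$vocabulary, top_n)
  kw$method <- "tfidf"
  class(kw) <- c("keyword_table", class(kw))
  kw
}

#' Cluster keywords by SVM weight analysis
#'
#' Fits a one-vs-rest linear SVM to predict the cluster of each document,
#' keeps only the documents the model predicts correctly, re-fits on that
#' subset, and reports each cluster's `top_n` features by positive
#' weight. A cluster with no correctly predicted documents gets an empty
#' list, with a warning.
#'
#' @param X tf-idf `nephro_dtm` (or matrix) of the diagnosis documents,
#'   aligned with `cs`.
#' @param cs A [cluster_set()] with >= 2 clusters.
#' @param top_n Keywords per cluster.
#' @param seed Integer seed for the SVM.
#' @return A `keyword_table` with `method = "svm"`.
#' @export
keywords_svm <- function(X, cs, top_n = 10L, seed = 1L) {
  stopifnot(inherits(cs, "cluster_set"))
  m <- if (inherits(X, "nephro_dtm")) X$matrix else X
  vocab <- colnames(m)
  keep <- which(cs$labels >= 0L)
  y <- cs$labels[keep]
  labs <- sort(unique(y))
  if (length(labs) < 2) stop("SVM keywords need >= 2 clusters")
  Xk <- m[keep, , drop = FALSE]
  fit <- svm_sgd_fit(Xk, y, seed = stage_seed(seed, "kw/fit1"))
  correct <- predict(fit, Xk) == y
  missing_cl <- setdiff(labs, unique(y[correct]))
  if (length(missing_cl)) {
    warning("no correctly predicted documents for cluster(s) ",
            paste(missing_cl, collapse = ", "),
            "; their keyword lists are empty")
  }
  fit2 <- svm_sgd_fit(Xk[correct, , drop = FALSE], y[correct],
                      seed = stage_seed(seed, "kw/fit2"))
  W <- matrix(0, length(labs), ncol(m),
              dimnames = list(as.character(labs), vocab))
  W[as.character(fit2$classes), ] <- fit2$W
  W[W < 0] <- 0
  kw <- keyword_rows(W, labs, vocab, top_n)
  kw$method <- "svm"
  class(kw) <- c("keyword_table", class(kw))
  kw
}

# Shared ranking: top_n positive-score terms per cluster, ties broken
# lexicographically.
keyword_rows <- function(scores, labs, vocab, top_n) {
  out <- lapply(seq_along(labs), function(r) {
    sc <- scores[r, ]
    pos <- which(sc > 0)
    if (length(pos) == 0) return(NULL)
    ord <- pos[order(-sc[pos], vocab[pos])]
    ord <- head(ord, top_n)
    data.frame(
      cluster = labs[r],
      rank = seq_along(ord),
      term = vocab[ord],
      score = unname(sc[ord]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Write / read a keyword table as TSV
#'
#' Columns: cluster, rank, term, score, method.
#'
#' @param kt A `keyword_table`.
#' @param path Output file.
#' @export
write_keywords <- function(kt, path) {
  df <- as.data.frame(kt)
  df$score <- fmt_num(df$score)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Attach human cluster-name annotations to a keyword table
#'
#' @param kt A `keyword_table`.
#' @param annotation A `data.frame` with columns `cluster`, `name`,
#'   `strength` (`strong`/`weak`), or a path to such a TSV file. Clusters
#'   absent from the annotation stay unnamed.
#' @return A `cluster_naming` `data.frame`: one row per cluster of `kt`
#'   with `cluster`, `name` (`NA` when unnamed) and `strength`
#'   (`strong`, `weak` or `unnamed`).
#' @export
attach_naming <- function(kt, annotation) {
  if (is.character(annotation) && length(annotation) == 1L) {
    annotation <- utils::read.delim(annotation, stringsAsFactors = FALSE)
  }
  clusters <- sort(unique(kt$cluster))
  if (nrow(annotation) > 0) {
    if (anyDuplicated(annotation$cluster)) {
      stop("duplicate cluster index in annotation")
    }
    unknown <- setdiff(annotation$cluster, clusters)
    if (length(unknown)) {
      stop("annotation references unknown cluster(s): ",
           paste(unknown, collapse = ", "))
    }
    if (!all(annotation$strength %in% c("strong", "weak"))) {
      stop("strength must be 'strong' or 'weak'")
    }
  }
  idx <- match(clusters, annotation$cluster)
  out <- data.frame(
    cluster = clusters,
    name = ifelse(is.na(idx), NA_character_, annotation$name[idx]),
    strength = ifelse(is.na(idx), "unnamed", annotation$strength[idx]),
    stringsAsFactors = FALSE
  )
  class(out) <- c("cluster_naming", class(out))
  out
}
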