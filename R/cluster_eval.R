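# Cluster-set evaluation: silhouette score, relative document entropy,
# SVM-based classification accuracy, 2-D projections and the
# author-confound check. Outlier-labelled documents are excluded from
# every metric.

#' Mean silhouette coefficient of a cluster-set
#'
#' Euclidean silhouette over non-outlier documents, computed on the
#' representation the clusterer consumed (tf-idf for bag-of-words
#' backends, the reduced embedding for density-based paths).
#'
#' @param X Representation (`nephro_dtm`, embedding or matrix) aligned
#'   with `cs`.
#' @param cs A [cluster_set()] with at least 2 clusters after outlier
#'   removal.
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
silhouette_score <- function(X, cs) {
  stopifnot(inherits(cs, "cluster_set"))
  M <- as_dense(X)
  stopifnot(nrow(M) == length(cs$labels))
  keep <- cs$labels >= 0L
  labs <- cs$labels[keep]
  if (length(unique(labs)) < 2) {
    stop("silhouette requires at least 2 clusters")
  }
  sil <- cluster::silhouette(labs, stats::dist(M[keep, , drop = FALSE]))
  mean(sil[, "sil_width"])
}

#' Relative document entropy of a cluster-set
#'
#' For every non-outlier document, the Kullback-Leibler divergence
#' (natural log) between the document's term-frequency distribution and
#' the pooled term-frequency distribution of its cluster, both normalized
#' over the cluster vocabulary (terms with nonzero pooled count, which
#' guarantees finiteness: the pool contains the document itself).
#' Divergences are averaged within each cluster, then averaged over
#' clusters with equal weight. Low values mean homogeneous clusters.
#'
#' @param C A count-mode `nephro_dtm` aligned with `cs`.
#' @param cs A [cluster_set()].
#' @return Nonnegative mean KL divergence.
#' @export
relative_entropy <- function(C, cs) {
  stopifnot(inherits(C, "nephro_dtm"), inherits(cs, "cluster_set"))
  if (C$mode != "count") {
    stop("relative entropy is defined on term counts, not tf-idf")
  }
  stopifnot(nrow(C$matrix) == length(cs$labels))
  labs <- sort(unique(cs$labels[cs$labels >= 0L]))
  if (length(labs) == 0) stop("cluster-set has no non-outlier documents")
  per_cluster <- vapply(labs, function(j) {
    rows <- which(cs$labels == j)
    if (length(rows) == 0) stop("empty cluster ", j)
    sub <- C$matrix[rows, , drop = FALSE]
    pooled <- Matrix::colSums(sub)
    dom <- pooled > 0
    q <- pooled[dom] / sum(pooled[dom])
    kls <- vapply(seq_along(rows), function(i) {
      cnt <- sub[i, dom]
      s <- sum(cnt)
      if (s == 0) return(0)
      p <- cnt / s
      nz <- p > 0
      sum(p[nz] * log(p[nz] / q[nz]))
    }, numeric(1))
    mean(kls)
  }, numeric(1))
  mean(per_cluster)
}

#' SVM-based classification accuracy of a cluster-set
#'
#' How well a linear SVM can recover the cluster labels from the
#' diagnosis texts themselves: tf-idf features, stratified k-fold
#' cross-validation over non-outlier documents, pooled out-of-fold
#' accuracy. A cluster-set whose clusters are not linguistically
#' separable scores low even if it looks well shaped.
#'
#' @param diagnosis Either a character vector of diagnosis texts, a list
#'   of [token_doc()]s, or a prebuilt count-mode `nephro_dtm`, aligned
#'   with `cs`.
#' @param cs A [cluster_set()] with >= 2 clusters.
#' @param seed Integer seed (fold assignment and SVM updates).
#' @param folds Fold count (reduced with a warning when the smallest
#'   cluster is smaller).
#' @param config Preprocessing configuration used when `diagnosis` is
#'   raw text.
#' @return Accuracy in `[0, 1]`.
#' @export
cls_accuracy <- function(diagnosis, cs, seed = 1L, folds = 10L,
                         config = preprocess_config()) {
  stopifnot(inherits(cs, "cluster_set"))
  counts <- as_count_dtm(diagnosis, cs$doc_ids, config)
  keep <- cs$labels >= 0L
  y <- cs$labels[keep]
  if (length(unique(y)) < 2) {
    stop("cls accuracy requires at least 2 clusters")
  }
  if (min(table(y)) < 2) {
    warning("clusters with fewer than 2 documents are kept in the ",
            "evaluation but cannot be stratified properly")
  }
  X <- dtm_tfidf(subset_dtm(counts, which(keep)))$matrix
  fold_id <- stratified_folds(y, folds, stage_seed(seed, "clsacc/folds"))
  pred <- integer(length(y))
  for (f in sort(unique(fold_id))) {
    tr <- fold_id != f
    fit <- svm_sgd_fit(X[tr, , drop = FALSE], y[tr],
                       seed = stage_seed(seed, paste0("clsacc/fold", f)))
    pred[!tr] <- predict(fit, X[!tr, , drop = FALSE])
  }
  mean(pred == y)
}

# Coerce raw texts / token docs / a count DTM into a count DTM aligned
# with doc_ids.
as_count_dtm <- function(x, doc_ids, config = preprocess_config()) {
  if (inherits(x, "nephro_dtm")) {
    if (x$mode != "count") stop("expected a count-mode matrix")
    stopifnot(identical(x$doc_ids, as.character(doc_ids)))
    return(x)
  }
  if (is.character(x)) {
    stopifnot(length(x) == length(doc_ids))
    docs <- mapply(function(id, txt) token_doc(id, preprocess_text(txt, config)),
                   doc_ids, x, SIMPLIFY = FALSE)
    return(vectorize(docs, "count"))
  }
  if (is.list(x) && all(vapply(x, inherits, logical(1), "token_doc"))) {
    return(vectorize(x, "count"))
  }
  stop("cannot interpret input as documents")
}

# Row subset of a DTM, preserving mode and vocabulary.
subset_dtm <- function(dtm, rows) {
  new_dtm(dtm$matrix[rows, , drop = FALSE], dtm$vocabulary,
          dtm$doc_ids[rows], dtm$mode)
}

#' Assemble the full metric row for one cluster-set
#'
#' One scorecard row: silhouette score, cls accuracy, relative entropy,
#' cluster count and kept corpus size, plus the representation space the
#' silhouette was computed in.
#'
#' @param counts Count-mode `nephro_dtm` of the diagnosis sections,
#'   aligned with `cs`.
#' @param cs A [cluster_set()].
#' @param representation Representation for the silhouette (defaults to
#'   tf-idf of `counts`); pass the reduced embedding for density-based
#'   backends.
#' @param seed Integer seed for the cls-accuracy folds.
#' @param folds Cross-validation folds for cls accuracy.
#' @return A one-row `data.frame` with columns `method`, `s_score`,
#'   `cls_accuracy`, `rel_entropy`, `n_clusters`, `corpus_size`, `space`.
#' @export
evaluate_clusterset <- function(counts, cs, representation = NULL,
                                seed = 1L, folds = 10L) {
  stopifnot(inherits(counts, "nephro_dtm"), inherits(cs, "cluster_set"))
  if (is.null(representation)) {
    representation <- dtm_tfidf(counts)
    space <- "tfidf"
  } else {
    space <- if (inherits(representation, "reduced_embedding")) {
      "reduced_embedding"
    } else if (inherits(representation, "nephro_embedding")) {
      "embedding"
    } else "tfidf"
  }
  keep <- which(cs$labels >= 0L)
  data.frame(
    method = cs$method,
    s_score = silhouette_score(representation, cs),
    cls_accuracy = cls_accuracy(counts, cs, seed = seed, folds = folds),
    rel_entropy = relative_entropy(counts, cs),
    n_clusters = n_clusters(cs),
    corpus_size = corpus_size_kept(cs),
    space = space,
    stringsAsFactors = FALSE
  )
}

#' Project documents to two dimensions for plotting
#'
#' @param X Representation to project.
#' @param method `"umap"` or `"pca"`.
#' @param seed Integer seed (UMAP only).
#' @param labels Optional cluster labels to attach per point.
#' @param authors Optional author codes to attach per point.
#' @return `data.frame` with `doc_id`, `x`, `y`, `cluster`, `author`.
#' @export
project_2d <- function(X, method = c("umap", "pca"), seed = 1L,
                       labels = NULL, authors = NULL) {
  method <- match.arg(method)
  M <- as_dense(X)
  if (nrow(M) < 3) stop("projection needs at least 3 documents")
  coords <- if (method == "pca") {
    p <- stats::prcomp(M, center = TRUE, scale. = FALSE)
    cbind(p$x[, 1], if (ncol(p$x) >= 2) p$x[, 2] else 0)
  } else {
    reduce_umap(M, n_components = 2L,
                n_neighbors = min(15L, nrow(M) - 1L), seed = seed)$matrix
  }
  ids <- rep_doc_ids(X)
  data.frame(
    doc_id = ids,
    x = coords[, 1],
    y = coords[, 2],
    cluster = if (is.null(labels)) NA_integer_ else as.integer(labels),
    author = if (is.null(authors)) NA_character_ else as.character(authors),
    stringsAsFactors = FALSE
  )
}

#' Quantify the association between clusters and report authors
#'
#' Builds the cluster-by-author contingency table over kept documents and
#' computes Cramér's V. High association flags a cluster-set that may be
#' grouping reports by the authors' writing styles rather than by
#' diagnosis.
#'
#' @param cs A [cluster_set()].
#' @param authors Character vector of author codes aligned with
#'   `cs$doc_ids`; `NA`s are dropped with a warning.
#' @return List with `contingency` (cluster x author table) and
#'   `association` (Cramér's V in `[0, 1]`).
#' @export
author_confound <- function(cs, authors) {
  stopifnot(inherits(cs, "cluster_set"))
  stopifnot(length(authors) == length(cs$labels))
  keep <- cs$labels >= 0L & !is.na(authors)
  if (any(cs$labels >= 0L & is.na(authors))) {
    warning("author codes missing for some kept documents; ",
            "association computed on the available subset")
  }
  tab <- table(cluster = cs$labels[keep], author = authors[keep])
  v <- cramers_v(tab)
  list(contingency = tab, association = v)
}

cramers_v <- function(tab) {
  if (min(dim(tab)) < 2) return(0)
  chi2 <- suppressWarnings(
    stats::chisq.test(tab, correct = FALSE)$statistic
  )
  unname(sqrt(chi2 / (sum(tab) * (min(dim(tab)) - 1))))
}
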