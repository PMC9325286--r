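# Clustering backends over diagnosis-section representations: k-means,
# LDA, the Dirichlet-process multinomial mixture (GSDPMM), HDBSCAN on a
# UMAP-reduced space, and doc2vec document embeddings; plus elbow-based
# selection of k.

# Accept a nephro_dtm or plain matrix and return a dense numeric matrix.
as_dense <- function(X) {
  if (inherits(X, "nephro_dtm")) X <- X$matrix
  if (inherits(X, "nephro_embedding")) X <- X$matrix
  if (inherits(X, "reduced_embedding")) X <- X$matrix
  as.matrix(X)
}

rep_doc_ids <- function(X) {
  if (inherits(X, "nephro_dtm")) return(X$doc_ids)
  if (inherits(X, "nephro_embedding")) return(X$doc_ids)
  if (inherits(X, "reduced_embedding")) return(X$doc_ids)
  rn <- rownames(X)
  if (is.null(rn)) rn <- as.character(seq_len(nrow(X)))
  rn
}

#' k-means clustering of documents
#'
#' @param X A `nephro_dtm` (typically tf-idf) or numeric matrix.
#' @param k Number of clusters, `2 <= k <= n_docs`.
#' @param seed Integer seed.
#' @param nstart Random restarts (best inertia wins).
#' @return A [cluster_set()] without outliers.
#' @export
cluster_kmeans <- function(X, k, seed = 1L, nstart = 30L) {
  M <- as_dense(X)
  if (k < 2 || k > nrow(M)) {
    stop("k must satisfy 2 <= k <= n_docs")
  }
  labels <- if (k == nrow(M)) {
    seq_len(nrow(M)) - 1L # one cluster per document, trivially optimal
  } else {
    fit <- with_local_seed(seed, {
      stats::kmeans(M, centers = k, nstart = nstart, iter.max = 100L)
    })
    fit$cluster - 1L
  }
  cluster_set(
    labels = compact_labels(labels),
    doc_ids = rep_doc_ids(X),
    method = "kmeans",
    params = list(k = k, nstart = nstart),
    seed = seed
  )
}

#' LDA topic-model clustering of documents
#'
#' Runs a collapsed Gibbs sampler for latent Dirichlet allocation on raw
#' term counts and assigns each document to its highest-probability topic
#' (ties break to the lowest topic index). The per-document topic
#' distributions are returned in the `theta` element.
#'
#' @param X A count-mode `nephro_dtm`.
#' @param k Number of topics (>= 1).
#' @param seed Integer seed.
#' @param n_iter Gibbs sweeps.
#' @param alpha,beta Symmetric Dirichlet hyperparameters. The small
#'   default `alpha = 0.05` suits the clustering use of the model: each
#'   document is pushed to concentrate on one topic, and the collapsed
#'   likelihood then ranks chains that split all planted topics above
#'   chains with merged topics.
#' @param nstart Independent chains; the one with the highest collapsed
#'   log-likelihood wins (Gibbs chains for topic models are multimodal,
#'   exactly like k-means restarts).
#' @return A [cluster_set()]; no outliers. The element `theta` holds the
#'   n_docs x k topic-proportion matrix (rows sum to 1).
#' @export
cluster_lda <- function(X, k, seed = 1L, n_iter = 500L,
                        alpha = 0.05, beta = 0.1, nstart = 8L) {
  stopifnot(inherits(X, "nephro_dtm"))
  if (X$mode != "count") {
    stop("LDA requires a count-mode matrix, not tf-idf weights")
  }
  stopifnot(k >= 1)
  stream <- dtm_token_stream(X)
  V <- length(X$vocabulary)
  best <- NULL
  best_ll <- -Inf
  for (r in seq_len(nstart)) {
    fit <- .lda_gibbs(stream$words, stream$docs, nrow(X$matrix),
                      V, as.integer(k), alpha, beta,
                      as.integer(n_iter),
                      as.integer(stage_seed(seed, paste0("lda/run", r))))
    ll <- lda_loglik(fit$ndk, fit$nkw, alpha, beta)
    if (ll > best_ll) {
      best_ll <- ll
      best <- fit
    }
  }
  ndk <- best$ndk
  theta <- (ndk + alpha) / (rowSums(ndk) + k * alpha)
  labels <- max.col(theta, ties.method = "first") - 1L
  cs <- cluster_set(
    labels = compact_labels(labels),
    doc_ids = X$doc_ids,
    method = "lda",
    params = list(k = k, alpha = alpha, beta = beta, n_iter = n_iter,
                  nstart = nstart),
    seed = seed
  )
  cs$theta <- theta
  cs
}

# Collapsed joint log-likelihood of an LDA state (Dirichlet-multinomial
# integrals over both the topic-word and document-topic tables).
lda_loglik <- function(ndk, nkw, alpha, beta) {
  K <- ncol(ndk)
  V <- ncol(nkw)
  word_part <- sum(lgamma(nkw + beta)) - sum(lgamma(rowSums(nkw) + V * beta)) +
    K * (lgamma(V * beta) - V * lgamma(beta))
  doc_part <- sum(lgamma(ndk + alpha)) -
    sum(lgamma(rowSums(ndk) + K * alpha)) +
    nrow(ndk) * (lgamma(K * alpha) - K * lgamma(alpha))
  word_part + doc_part
}

# Expand a count DTM into the flat 0-based token stream the samplers use.
dtm_token_stream <- function(X) {
  m <- as(X$matrix, "TsparseMatrix")
  reps <- as.integer(round(m@x))
  list(
    words = rep.int(m@j, reps),
    docs = rep.int(m@i, reps)
  )
}

#' Dirichlet-process multinomial mixture clustering (GSDPMM)
#'
#' Collapsed Gibbs sampler for the Dirichlet-process multinomial mixture:
#' each sweep reassigns every document to an existing cluster (with
#' probability proportional to its size and term-count fit) or to a new
#' one (driven by `alpha`). The number of occupied clusters is inferred,
#' capped at `K_max`. Labels are taken from the final sweep.
#'
#' @param X A count-mode `nephro_dtm`.
#' @param alpha Dirichlet-process concentration (> 0).
#' @param beta Symmetric Dirichlet smoothing over the vocabulary (> 0);
#'   larger values favour fewer, coarser clusters.
#' @param K_max Cap on the number of clusters.
#' @param n_iter Gibbs sweeps (default 30).
#' @param seed Integer seed.
#' @param nstart Independent chains; the final state with the highest
#'   collapsed posterior wins (the sampler is multimodal: chains
#'   occasionally leave two planted clusters merged).
#' @return A [cluster_set()]; no outliers.
#' @export
cluster_gsdpmm <- function(X, alpha = 1, beta = 0.05, K_max = 50L,
                           n_iter = 30L, seed = 1L, nstart = 3L) {
  stopifnot(inherits(X, "nephro_dtm"))
  if (X$mode != "count") {
    stop("GSDPMM requires a count-mode matrix, not tf-idf weights")
  }
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be positive")
  if (K_max < 1) stop("K_max must be >= 1")
  m <- as(Matrix::t(X$matrix), "CsparseMatrix") # column = document
  labels <- NULL
  best_ll <- -Inf
  for (r in seq_len(nstart)) {
    cand <- .gsdpmm_gibbs(
      doc_ptr = m@p, word_id = m@i, word_ct = m@x,
      vocab_size = length(X$vocabulary),
      alpha = alpha, beta = beta, K_max = as.integer(K_max),
      n_iter = as.integer(n_iter),
      seed = as.integer(stage_seed(seed, paste0("gsdpmm/run", r)))
    )
    ll <- dpmm_loglik(X$matrix, cand, alpha, beta)
    if (ll > best_ll) {
      best_ll <- ll
      labels <- cand
    }
  }
  cluster_set(
    labels = compact_labels(labels),
    doc_ids = X$doc_ids,
    method = "gsdpmm",
    params = list(alpha = alpha, beta = beta, K_max = K_max,
                  n_iter = n_iter, nstart = nstart),
    seed = seed
  )
}

# Collapsed log posterior of a Dirichlet-process multinomial mixture
# state: Chinese-restaurant prior over the partition plus the
# Dirichlet-multinomial integral of each cluster's term counts.
dpmm_loglik <- function(counts, labels, alpha, beta) {
  V <- ncol(counts)
  occ <- sort(unique(labels))
  sizes <- as.numeric(table(labels))
  ll <- length(occ) * log(alpha) + sum(lgamma(sizes))
  for (z in occ) {
    cw <- Matrix::colSums(counts[labels == z, , drop = FALSE])
    nz <- cw[cw > 0]
    ll <- ll + sum(lgamma(nz + beta)) - length(nz) * lgamma(beta) +
      lgamma(V * beta) - lgamma(sum(cw) + V * beta)
  }
  ll
}

#' Train PV-DBOW document embeddings
#'
#' Distributed bag-of-words paragraph vectors: each document vector is
#' trained to predict its own words against negative samples, yielding an
#' embedding in which semantically similar documents are close. Used as
#' the distributed-representation path feeding [reduce_umap()] and
#' [cluster_hdbscan()].
#'
#' @param docs List of [token_doc()] objects (>= 10 documents).
#' @param dim Embedding dimensionality.
#' @param epochs Training epochs.
#' @param seed Integer seed (training is single-threaded, so the result
#'   is reproducible).
#' @param negative Negative samples per positive update.
#' @return A `nephro_embedding`: list with `matrix` (n_docs x dim),
#'   `doc_ids`, `source = "doc2vec"`.
#' @export
embed_doc2vec <- function(docs, dim = 50L, epochs = 25L, seed = 1L,
                          negative = 5L) {
  if (length(docs) < 10) stop("doc2vec needs at least 10 documents")
  doc_ids <- vapply(docs, `[[`, character(1), "doc_id")
  toks <- lapply(docs, `[[`, "tokens")
  vocab <- sort(unique(unlist(toks)))
  if (length(vocab) == 0) stop("empty vocabulary")
  words <- match(unlist(toks), vocab) - 1L
  docs_idx <- rep.int(seq_along(toks) - 1L, lengths(toks))
  freq <- tabulate(words + 1L, nbins = length(vocab))
  # unigram^0.75 negative-sampling table
  w <- freq^0.75
  tab_size <- min(100000L, max(1000L, 50L * length(vocab)))
  neg_table <- rep.int(seq_along(vocab) - 1L,
                       pmax(1L, round(w / sum(w) * tab_size)))
  M <- .doc2vec_train(words, docs_idx, as.integer(neg_table),
                      length(toks), length(vocab), as.integer(dim),
                      as.integer(epochs), 0.05, as.integer(negative),
                      as.integer(seed))
  rownames(M) <- doc_ids
  structure(
    list(matrix = M, doc_ids = doc_ids, source = "doc2vec",
         params = list(dim = dim, epochs = epochs, negative = negative),
         seed = seed),
    class = "nephro_embedding"
  )
}

#' Ingest an externally computed document-embedding matrix
#'
#' @param matrix Numeric matrix (n_docs x d), finite entries.
#' @param doc_ids Document ids aligned with the rows.
#' @return A `nephro_embedding` with `source = "external"`.
#' @export
external_embedding <- function(matrix, doc_ids) {
  matrix <- as.matrix(matrix)
  stopifnot(nrow(matrix) == length(doc_ids), ncol(matrix) > 0)
  if (!all(is.finite(matrix))) stop("embedding entries must be finite")
  rownames(matrix) <- doc_ids
  structure(
    list(matrix = matrix, doc_ids = as.character(doc_ids),
         source = "external", params = list(), seed = NA_integer_),
    class = "nephro_embedding"
  )
}

#' Locate an elbow on a decreasing objective curve
#'
#' Kneedle-style: the elbow is the point with maximum vertical distance
#' between the (normalized) curve and the chord joining its endpoints.
#' Ties break to the smaller k; a flat curve returns the smallest k with
#' a warning.
#'
#' @param k_values Candidate k values (>= 3, increasing).
#' @param objective Objective at each k (e.g. k-means total
#'   within-cluster sum of squares).
#' @return The selected k.
#' @export
elbow_point <- function(k_values, objective) {
  stopifnot(length(k_values) == length(objective), length(k_values) >= 3)
  rng_y <- max(objective) - min(objective)
  if (rng_y == 0) {
    warning("objective curve is flat; returning the smallest k")
    return(k_values[1])
  }
  x <- (k_values - k_values[1]) / (k_values[length(k_values)] - k_values[1])
  y <- (objective - min(objective)) / rng_y
  chord <- y[1] + (y[length(y)] - y[1]) * x
  d <- chord - y
  k_values[which.max(d)] # which.max takes the first (smallest k) on ties
}

#' Elbow-based selection of the number of clusters
#'
#' Computes the clustering objective over a range of k and picks the
#' elbow via [elbow_point()].
#'
#' @param X Representation passed to the backend.
#' @param k_range Candidate k values (>= 3 values).
#' @param backend Currently `"kmeans"` (inertia curve).
#' @param seed Integer seed.
#' @param nstart Restarts per k.
#' @return The selected k.
#' @export
select_k_elbow <- function(X, k_range, backend = "kmeans", seed = 1L,
                           nstart = 5L) {
  if (length(k_range) < 3) stop("k_range must contain at least 3 values")
  backend <- match.arg(backend, "kmeans")
  M <- as_dense(X)
  obj <- vapply(k_range, function(k) {
    fit <- with_local_seed(stage_seed(seed, paste0("elbow/k", k)), {
      stats::kmeans(M, centers = k, nstart = nstart, iter.max = 100L)
    })
    fit$tot.withinss
  }, numeric(1))
  elbow_point(k_range, obj)
}
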