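# Uniform manifold approximation and projection, implemented in-package:
# k-nearest-neighbour graph -> fuzzy simplicial set -> spectral
# initialization -> stochastic-gradient layout (compiled optimizer).
# Intended for corpus-scale inputs (hundreds to a few thousand documents);
# neighbour search uses exact pairwise distances.

# Per-point fuzzy neighbourhood weights: binary-search sigma_i so that
# sum_j exp(-(max(0, d_ij - rho_i)) / sigma_i) = log2(k).
smooth_knn_weights <- function(knn_dist, n_iter = 64L) {
  k <- ncol(knn_dist)
  target <- log2(k)
  t(apply(knn_dist, 1, function(d) {
    rho <- min(d[d > 0], Inf)
    if (!is.finite(rho)) rho <- 0
    adj <- pmax(d - rho, 0)
    lo <- 0; hi <- Inf; sigma <- 1
    for (it in seq_len(n_iter)) {
      val <- sum(exp(-adj / sigma))
      if (abs(val - target) < 1e-5) break
      if (val > target) {
        hi <- sigma
        sigma <- (lo + hi) / 2
      } else {
        lo <- sigma
        sigma <- if (is.finite(hi)) (lo + hi) / 2 else sigma * 2
      }
    }
    exp(-adj / sigma)
  }))
}

# Fit the low-dimensional similarity curve 1 / (1 + a * d^(2b)) to the
# target shape implied by min_dist.
fit_ab <- function(min_dist, spread = 1) {
  xv <- seq(0, spread * 3, length.out = 300)
  yv <- ifelse(xv < min_dist, 1, exp(-(xv - min_dist) / spread))
  fit <- stats::nls(
    yv ~ 1 / (1 + a * xv^(2 * b)),
    start = list(a = 1.5, b = 1),
    control = list(maxiter = 200, warnOnly = TRUE)
  )
  as.list(coef(fit))
}

# Spectral initialization: eigenvectors of the symmetric normalized graph
# Laplacian for the smallest nonzero eigenvalues.
spectral_init <- function(P, d) {
  n <- nrow(P)
  deg <- Matrix::rowSums(P)
  deg[deg == 0] <- 1e-12
  Dinv <- Matrix::Diagonal(x = 1 / sqrt(deg))
  L <- Matrix::Diagonal(n) - Dinv %*% P %*% Dinv
  eig <- eigen(as.matrix(Matrix::symmpart(L)), symmetric = TRUE)
  # columns are ordered by decreasing eigenvalue; skip the trivial last one
  idx <- seq(n - 1, max(n - d, 1))
  V <- eig$vectors[, idx, drop = FALSE]
  if (ncol(V) < d) V <- cbind(V, matrix(0, n, d - ncol(V)))
  scale_f <- 10 / max(abs(V))
  V * scale_f
}

#' Reduce a representation with UMAP
#'
#' Builds the fuzzy k-nearest-neighbour graph of the input, initializes
#' the embedding from the graph Laplacian's spectrum, and optimizes the
#' layout with stochastic gradient descent (attraction along edges,
#' repulsion against negative samples). Deterministic given `seed`.
#'
#' @param X A `nephro_dtm`, `nephro_embedding` or numeric matrix.
#' @param n_components Output dimensionality `d' >= 2` (5 is a good
#'   default before density-based clustering, 2 for plotting).
#' @param n_neighbors Neighbourhood size (must be < n_docs).
#' @param min_dist Minimum spacing in the embedding.
#' @param seed Integer seed.
#' @param n_epochs Optimization epochs.
#' @return A `reduced_embedding`: list with `matrix` (n_docs x d'),
#'   `doc_ids`, `params` and `seed`.
#' @export
reduce_umap <- function(X, n_components = 5L, n_neighbors = 15L,
                        min_dist = 0.1, seed = 1L, n_epochs = 200L) {
  M <- as_dense(X)
  n <- nrow(M)
  if (n <= n_neighbors) {
    stop("need more documents than n_neighbors")
  }
  if (n_components < 2) stop("n_components must be >= 2")
  D <- as.matrix(stats::dist(M))
  knn_idx <- t(apply(D, 1, function(r) order(r)[2:(n_neighbors + 1)]))
  knn_dist <- t(vapply(seq_len(n), function(i) D[i, knn_idx[i, ]],
                       numeric(n_neighbors)))
  W <- smooth_knn_weights(knn_dist)
  P <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = n_neighbors),
    j = as.integer(t(knn_idx)),
    x = as.numeric(t(W)),
    dims = c(n, n)
  )
  # fuzzy set union
  Pt <- Matrix::t(P)
  G <- P + Pt - P * Pt
  emb <- spectral_init(G, n_components)
  noise_seed <- stage_seed(seed, "umap/init-noise")
  emb <- emb + with_local_seed(noise_seed, {
    matrix(stats::rnorm(length(emb), sd = 1e-4), nrow(emb))
  })

  Gt <- as(G, "TsparseMatrix")
  keep <- Gt@x > 0
  wts <- Gt@x[keep]
  head <- Gt@i[keep]
  tail <- Gt@j[keep]
  eps <- max(wts) / wts # epochs between samples of each edge
  ab <- fit_ab(min_dist)
  emb <- .umap_optimize(
    emb, as.integer(head), as.integer(tail), as.numeric(eps),
    a = ab$a, b = ab$b, gamma = 1, initial_alpha = 1,
    n_epochs = as.integer(n_epochs), negative_sample_rate = 5L,
    seed = as.integer(stage_seed(seed, "umap/sgd"))
  )
  rownames(emb) <- rep_doc_ids(X)
  structure(
    list(
      matrix = emb, doc_ids = rep_doc_ids(X),
      params = list(n_components = n_components,
                    n_neighbors = n_neighbors, min_dist = min_dist,
                    n_epochs = n_epochs),
      seed = seed
    ),
    class = "reduced_embedding"
  )
}
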