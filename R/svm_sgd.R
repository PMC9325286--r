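# Linear support-vector machine trained by stochastic subgradient descent
# (Pegasos-style, one-vs-rest). Backs the cluster-set cls-accuracy metric,
# the SVM keyword extraction and the sgd_svm classifier. Weight vectors
# are directly accessible, which the keyword analysis requires.

#' Fit a linear SVM by stochastic subgradient descent
#'
#' One-vs-rest multiclass hinge loss with L2 regularization, optimized by
#' mini-batch subgradient descent with the step schedule
#' `eta_t = 1 / (lambda * (t0 + t))`, `t0 = 1 / lambda`, so early steps
#' are of order one rather than `1 / lambda`.
#'
#' @param X Sparse or dense numeric matrix (n x V), e.g. tf-idf rows.
#' @param y Integer class labels `0..K-1` (or a factor).
#' @param lambda L2 regularization strength.
#' @param n_iter Number of mini-batch updates.
#' @param batch Mini-batch size.
#' @param seed Integer seed (mini-batch sampling).
#' @return An `svm_sgd` model: list with `W` (K x V weights), `b`
#'   (intercepts) and `classes`.
#' @export
svm_sgd_fit <- function(X, y, lambda = 1e-4, n_iter = 300L, batch = 32L,
                        seed = 1L) {
  if (inherits(X, "nephro_dtm")) X <- X$matrix
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  classes <- sort(unique(y))
  K <- length(classes)
  if (K < 2) stop("need at least 2 classes")
  n <- nrow(X); V <- ncol(X)
  ymat <- matrix(-1, n, K)
  for (k in seq_len(K)) ymat[y == classes[k], k] <- 1

  W <- matrix(0, K, V)
  b <- numeric(K)
  t0 <- 1 / lambda
  with_local_seed(seed, {
    for (t in seq_len(n_iter)) {
      idx <- sample.int(n, min(batch, n))
      Xb <- X[idx, , drop = FALSE]
      Yb <- ymat[idx, , drop = FALSE]
      scores <- as.matrix(Xb %*% t(W)) + rep(b, each = length(idx))
      viol <- (Yb * scores) < 1
      eta <- 1 / (lambda * (t0 + t))
      W <- W * (1 - eta * lambda)
      if (any(viol)) {
        G <- Yb * viol # +/-1 where the margin is violated
        W <- W + (eta / length(idx)) * t(as.matrix(Matrix::t(Xb) %*% G))
        b <- b + (eta / length(idx)) * colSums(G)
      }
    }
  })
  colnames(W) <- colnames(X)
  structure(list(W = W, b = b, classes = classes, lambda = lambda),
            class = "svm_sgd")
}

#' @rdname svm_sgd_fit
#' @param object An `svm_sgd` model.
#' @param newdata Matrix of rows to classify.
#' @param ... Unused.
#' @export
predict.svm_sgd <- function(object, newdata, ...) {
  if (inherits(newdata, "nephro_dtm")) newdata <- newdata$matrix
  scores <- as.matrix(newdata %*% t(object$W)) +
    rep(object$b, each = nrow(newdata))
  object$classes[max.col(scores, ties.method = "first")]
}
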