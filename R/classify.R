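# Predicting the diagnostic group from microscopic description sections:
# bag-of-words classifiers (SGD-SVM, MLP, logistic regression,
# multinomial naive Bayes) and small neural classifiers over token
# sequences (bidirectional LSTM, 1-D CNN), all evaluated by stratified
# ten-fold cross-validation with pooled out-of-fold predictions.

CLASSIFIER_NAMES <- c("sgd_svm", "mlp", "logreg", "multinomial_nb",
                      "rnn_embed", "cnn_embed")

#' Specify a classifier
#'
#' @param name One of `"sgd_svm"`, `"mlp"`, `"logreg"`,
#'   `"multinomial_nb"`, `"rnn_embed"`, `"cnn_embed"`.
#' @param hyperparams Named list of overrides (e.g. `epochs`, `hidden`).
#' @param seed Integer seed (required).
#' @return A `classifier_spec` object.
#' @export
classifier_spec <- function(name, hyperparams = list(), seed = 1L) {
  if (!name %in% CLASSIFIER_NAMES) {
    stop("unknown classifier '", name, "'; expected one of: ",
         paste(CLASSIFIER_NAMES, collapse = ", "))
  }
  if (is.null(seed) || is.na(seed)) stop("classifier seed is required")
  structure(list(name = name, hyperparams = hyperparams,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

# ---------------------------------------------------------------------------
# Multinomial naive Bayes with Laplace smoothing. Accepts fractional
# "counts" (tf-idf weights), like the usual text-classification usage.
nb_fit <- function(X, y, alpha = 1) {
  classes <- sort(unique(y))
  V <- ncol(X)
  counts <- do.call(rbind, lapply(classes, function(k) {
    Matrix::colSums(X[y == k, , drop = FALSE])
  }))
  log_theta <- log(counts + alpha) -
    log(rowSums(counts) + alpha * V)
  log_prior <- log(as.numeric(table(factor(y, classes))) / length(y))
  list(classes = classes, log_theta = log_theta, log_prior = log_prior)
}

nb_predict <- function(model, X) {
  scores <- as.matrix(X %*% t(model$log_theta)) +
    rep(model$log_prior, each = nrow(X))
  model$classes[max.col(scores, ties.method = "first")]
}

nb_posterior <- function(model, X) {
  scores <- as.matrix(X %*% t(model$log_theta)) +
    rep(model$log_prior, each = nrow(X))
  p <- exp(scores - apply(scores, 1, max))
  p / rowSums(p)
}

# ---------------------------------------------------------------------------
# Single-hidden-layer MLP with softmax output, trained with Adam on
# cross-entropy (dense matrix arithmetic; input rows are tf-idf vectors).
mlp_fit <- function(X, y, hidden = 64L, epochs = 30L, batch = 32L,
                    lr = 1e-3, l2 = 1e-5, seed = 1L) {
  X <- as.matrix(X)
  classes <- sort(unique(y))
  K <- length(classes)
  yk <- match(y, classes)
  n <- nrow(X); V <- ncol(X)
  with_local_seed(seed, {
    W1 <- matrix(stats::rnorm(V * hidden, sd = sqrt(2 / V)), V, hidden)
    b1 <- numeric(hidden)
    W2 <- matrix(stats::rnorm(hidden * K, sd = sqrt(2 / hidden)), hidden, K)
    b2 <- numeric(K)
    adam <- adam_state(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2), lr)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = batch)) {
        idx <- ord[start:min(start + batch - 1, n)]
        Xb <- X[idx, , drop = FALSE]
        H <- pmax(Xb %*% W1 + rep(b1, each = length(idx)), 0)
        logits <- H %*% W2 + rep(b2, each = length(idx))
        P <- softmax_rows(logits)
        G <- P
        G[cbind(seq_along(idx), yk[idx])] <-
          G[cbind(seq_along(idx), yk[idx])] - 1
        G <- G / length(idx)
        grads <- list(
          W1 = crossprod(Xb, (G %*% t(W2)) * (H > 0)) + l2 * W1,
          b1 = colSums((G %*% t(W2)) * (H > 0)),
          W2 = crossprod(H, G) + l2 * W2,
          b2 = colSums(G)
        )
        upd <- adam_step(adam, grads)
        adam <- upd$state
        W1 <- upd$params$W1; b1 <- upd$params$b1
        W2 <- upd$params$W2; b2 <- upd$params$b2
      }
    }
    list(classes = classes, W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  })
}

mlp_predict <- function(model, X) {
  X <- as.matrix(X)
  H <- pmax(X %*% model$W1 + rep(model$b1, each = nrow(X)), 0)
  logits <- H %*% model$W2 + rep(model$b2, each = nrow(X))
  model$classes[max.col(logits, ties.method = "first")]
}

softmax_rows <- function(logits) {
  e <- exp(logits - apply(logits, 1, max))
  e / rowSums(e)
}

# Minimal Adam optimizer over a named list of arrays.
adam_state <- function(params, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  list(
    lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0,
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    params = params
  )
}

adam_step <- function(state, grads) {
  state$t <- state$t + 1
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- state$beta1 * state$m[[nm]] + (1 - state$beta1) * g
    state$v[[nm]] <- state$beta2 * state$v[[nm]] + (1 - state$beta2) * g^2
    mhat <- state$m[[nm]] / (1 - state$beta1^state$t)
    vhat <- state$v[[nm]] / (1 - state$beta2^state$t)
    state$params[[nm]] <- state$params[[nm]] -
      state$lr * mhat / (sqrt(vhat) + state$eps)
  }
  list(state = state, params = state$params)
}

# ---------------------------------------------------------------------------

#' Cross-validated training and evaluation of one classifier
#'
#' Stratified k-fold cross-validation; out-of-fold predictions are pooled
#' and all metrics (macro / weighted F1, Cohen's kappa, per-class F1 with
#' support, confusion matrix) are computed once on the pooled set, so the
#' confusion matrix is a single well-defined object.
#'
#' Bag-of-words specs consume tf-idf of the preprocessed description
#' tokens (idf fitted on each training fold); neural specs consume padded
#' token-id sequences with jointly trained embeddings.
#'
#' @param descriptions List of [token_doc()]s (or character texts)
#'   aligned with `labels$doc_ids`.
#' @param labels A [cluster_set()]; outlier documents are dropped.
#' @param spec A [classifier_spec()].
#' @param folds Fold count (default 10; reduced with a warning when the
#'   smallest class is smaller).
#' @param config Preprocessing configuration for raw-text input.
#' @return An `eval_report`: list with `f1_macro`, `f1_weighted`,
#'   `kappa`, `per_class` (sorted by descending F1), `confusion`,
#'   `folds`, `seed`, `method`.
#' @export
train_predict_cv <- function(descriptions, labels, spec, folds = 10L,
                             config = preprocess_config()) {
  stopifnot(inherits(labels, "cluster_set"),
            inherits(spec, "classifier_spec"))
  docs <- as_token_docs(descriptions, labels$doc_ids, config)
  keep <- which(labels$labels >= 0L)
  docs <- docs[keep]
  y <- labels$labels[keep]
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("need at least 2 classes")
  sizes <- table(y)
  if (any(sizes < 2)) {
    stop("class(es) of size 1: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  fold_id <- stratified_folds(y, folds, stage_seed(spec$seed, "cv/folds"))
  n_folds <- length(unique(fold_id))
  pred <- integer(length(y))

  neural <- spec$name %in% c("rnn_embed", "cnn_embed")
  if (!neural) {
    counts <- vectorize(docs, "count")
    for (f in sort(unique(fold_id))) {
      tr <- fold_id != f
      mats <- fold_tfidf(counts$matrix, tr)
      pred[!tr] <- fit_predict_bow(
        spec, mats$train, y[tr], mats$test,
        seed = stage_seed(spec$seed, paste0("cv/fold", f))
      )
    }
  } else {
    enc <- encode_sequences(docs, cap_quantile = 0.95)
    for (f in sort(unique(fold_id))) {
      tr <- fold_id != f
      model <- neural_fit(spec, enc$ids[tr, , drop = FALSE], y[tr],
                          vocab_size = enc$vocab_size,
                          seed = stage_seed(spec$seed, paste0("cv/fold", f)))
      pred[!tr] <- neural_predict(model, enc$ids[!tr, , drop = FALSE])
    }
  }
  eval_report(y, pred, classes, n_folds, spec)
}

as_token_docs <- function(x, doc_ids, config) {
  if (is.character(x)) {
    stopifnot(length(x) == length(doc_ids))
    return(mapply(function(id, txt) token_doc(id, preprocess_text(txt, config)),
                  doc_ids, x, SIMPLIFY = FALSE))
  }
  if (is.list(x) && all(vapply(x, inherits, logical(1), "token_doc"))) {
    stopifnot(length(x) == length(doc_ids))
    return(x)
  }
  stop("descriptions must be texts or token_doc objects")
}

# tf-idf with idf fitted on the training rows only (shared vocabulary).
fold_tfidf <- function(counts, train_mask) {
  tr <- counts[train_mask, , drop = FALSE]
  te <- counts[!train_mask, , drop = FALSE]
  ntr <- nrow(tr)
  df <- Matrix::colSums(tr > 0)
  idf <- log((1 + ntr) / (1 + df)) + 1
  weigh <- function(m) {
    m <- m %*% Matrix::Diagonal(x = idf)
    norms <- sqrt(Matrix::rowSums(m^2))
    norms[norms == 0] <- 1
    as(Matrix::Diagonal(x = 1 / norms) %*% m, "CsparseMatrix")
  }
  list(train = weigh(tr), test = weigh(te))
}

fit_predict_bow <- function(spec, Xtr, ytr, Xte, seed) {
  hp <- spec$hyperparams
  switch(spec$name,
    sgd_svm = {
      fit <- svm_sgd_fit(Xtr, ytr,
                         lambda = hp$lambda %||% 1e-4,
                         n_iter = hp$n_iter %||% 300L,
                         batch = hp$batch %||% 32L, seed = seed)
      predict(fit, Xte)
    },
    mlp = {
      fit <- mlp_fit(Xtr, ytr,
                     hidden = hp$hidden %||% 64L,
                     epochs = hp$epochs %||% 30L,
                     batch = hp$batch %||% 32L,
                     lr = hp$lr %||% 1e-3, seed = seed)
      mlp_predict(fit, Xte)
    },
    logreg = {
      classes <- sort(unique(ytr))
      fit <- glmnet::glmnet(Xtr, factor(ytr, classes),
                            family = "multinomial", alpha = 0,
                            lambda = hp$lambda %||% 1e-3,
                            standardize = FALSE)
      p <- predict(fit, Xte, type = "class")
      as.integer(p)
    },
    multinomial_nb = {
      fit <- nb_fit(Xtr, ytr, alpha = hp$alpha %||% 1)
      nb_predict(fit, Xte)
    },
    stop("not a bag-of-words classifier: ", spec$name)
  )
}

# Pooled-prediction evaluation report.
eval_report <- function(y, pred, classes, n_folds, spec) {
  conf <- table(true = factor(y, classes), pred = factor(pred, classes))
  per <- per_class_f1(conf)
  support <- as.integer(rowSums(conf))
  f1_macro <- mean(per)
  f1_weighted <- sum(per * support) / sum(support)
  structure(
    list(
      f1_macro = f1_macro,
      f1_weighted = f1_weighted,
      kappa = cohens_kappa(conf),
      per_class = {
        df <- data.frame(cluster = classes, f1 = per, support = support)
        df[order(-df$f1, df$cluster), , drop = FALSE]
      },
      confusion = unclass(conf),
      folds = n_folds,
      seed = spec$seed,
      method = spec$name
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %s: weighted F1 %.3f, macro F1 %.3f, kappa %.3f (%d folds)\n",
    x$method, x$f1_weighted, x$f1_macro, x$kappa, x$folds
  ))
  invisible(x)
}

per_class_f1 <- function(conf) {
  tp <- diag(conf)
  prec <- ifelse(colSums(conf) > 0, tp / colSums(conf), 0)
  rec <- ifelse(rowSums(conf) > 0, tp / rowSums(conf), 0)
  ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
}

#' Cohen's kappa from a confusion matrix
#'
#' @param conf Square contingency table of true vs predicted labels.
#' @return Kappa in `[-1, 1]`; 1 iff the matrix is diagonal.
#' @export
cohens_kappa <- function(conf) {
  n <- sum(conf)
  po <- sum(diag(conf)) / n
  pe <- sum(rowSums(conf) * colSums(conf)) / n^2
  if (pe == 1) return(ifelse(po == 1, 1, 0))
  (po - pe) / (1 - pe)
}

#' Rank correlation between class support and per-class F1
#'
#' Tests the qualitative claim that low-support diagnostic groups are
#' harder to recognize.
#'
#' @param report An `eval_report` with >= 4 classes.
#' @return List with `rho` (Spearman) and `defined` (`FALSE` when the
#'   per-class F1 vector is constant and the correlation is undefined).
#' @export
support_vs_f1 <- function(report) {
  stopifnot(inherits(report, "eval_report"))
  pc <- report$per_class
  if (nrow(pc) < 4) stop("need at least 4 classes")
  if (stats::sd(pc$f1) == 0 || stats::sd(pc$support) == 0) {
    return(list(rho = NA_real_, defined = FALSE))
  }
  list(rho = stats::cor(pc$support, pc$f1, method = "spearman"),
       defined = TRUE)
}

#' Run several classifiers and rank them
#'
#' @param descriptions As in [train_predict_cv()].
#' @param labels A [cluster_set()].
#' @param specs List of [classifier_spec()]s.
#' @param folds Fold count.
#' @param config Preprocessing configuration.
#' @return List with `table` (one row per spec, ranked by descending
#'   weighted F1) and `reports` (the full `eval_report`s, same order as
#'   `specs`).
#' @export
compare_classifiers <- function(descriptions, labels, specs,
                                folds = 10L,
                                config = preprocess_config()) {
  stopifnot(length(specs) >= 1)
  reports <- lapply(specs, function(sp) {
    train_predict_cv(descriptions, labels, sp, folds = folds,
                     config = config)
  })
  tab <- do.call(rbind, lapply(reports, function(r) {
    data.frame(classifier = r$method, f1_weighted = r$f1_weighted,
               f1_macro = r$f1_macro, kappa = r$kappa,
               stringsAsFactors = FALSE)
  }))
  ord <- order(-tab$f1_weighted)
  list(table = tab[ord, , drop = FALSE], reports = reports)
}
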