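# Description-section classification: cross-validated metrics, naive
# Bayes arithmetic, kappa properties, neural architectures.

coupled_corpus <- function(K = 4, per_group = 20, overlap = 0,
                           coupling = 1, seed = 17) {
  sc <- small_corpus(K = K, per_group = per_group, overlap = overlap,
                     seed = seed, coupling = coupling)
  mx <- preprocess_corpus(sc$corpus, "microscopy")
  cs <- cluster_set(sc$truth, corpus_ids(sc$corpus), "planted")
  list(mx = mx, cs = cs)
}

test_that("classifier_spec validates names and seeds", {
  expect_error(classifier_spec("bert"), "unknown classifier")
  expect_error(classifier_spec("sgd_svm", seed = NA), "seed")
  expect_s3_class(classifier_spec("mlp", seed = 2), "classifier_spec")
})

test_that("separable corpus: SGD-SVM reaches perfect pooled metrics", {
  d <- coupled_corpus()
  rep <- train_predict_cv(d$mx, d$cs, classifier_spec("sgd_svm", seed = 3))
  expect_equal(rep$f1_macro, 1)
  expect_equal(rep$f1_weighted, 1)
  expect_equal(rep$kappa, 1)
  # confusion conserves documents and is diagonal at kappa = 1
  expect_equal(sum(rep$confusion), corpus_size_kept(d$cs))
  expect_equal(sum(rep$confusion) , sum(diag(rep$confusion)))
  expect_equal(sum(rep$per_class$support), corpus_size_kept(d$cs))
})

test_that("kappa: chance level for constant prediction, bounded by accuracy", {
  conf_const <- matrix(c(30, 30, 0, 0), 2, 2) # always predicts class 1
  expect_equal(cohens_kappa(conf_const), 0)
  set.seed(3)
  for (i in 1:10) {
    conf <- matrix(rpois(9, 10), 3, 3)
    acc <- sum(diag(conf)) / sum(conf)
    expect_lte(cohens_kappa(conf), acc + 1e-12)
  }
  expect_equal(cohens_kappa(diag(c(5, 8, 2))), 1)
})

test_that("multinomial NB posterior matches hand-computed Bayes arithmetic", {
  # 4 docs, 2 classes, vocabulary {a, b}; Laplace alpha = 1
  X <- Matrix::Matrix(matrix(c(
    2, 0,
    1, 1,
    0, 2,
    1, 3
  ), 4, 2, byrow = TRUE), sparse = TRUE)
  y <- c(0, 0, 1, 1)
  fit <- nephrotext:::nb_fit(X, y, alpha = 1)
  # class counts: c0 = (3, 1), c1 = (1, 5); theta = (count+1)/(total+2)
  expect_equal(exp(fit$log_theta[1, ]), c(4, 2) / 6, tolerance = 1e-12)
  expect_equal(exp(fit$log_theta[2, ]), c(2, 6) / 8, tolerance = 1e-12)
  xnew <- Matrix::Matrix(matrix(c(2, 1), 1, 2), sparse = TRUE)
  post <- nephrotext:::nb_posterior(fit, xnew)
  # unnormalized: p(c) * prod theta^x with equal priors 1/2
  u0 <- 0.5 * (4 / 6)^2 * (2 / 6)
  u1 <- 0.5 * (2 / 8)^2 * (6 / 8)
  expect_equal(as.numeric(post), c(u0, u1) / (u0 + u1), tolerance = 1e-12)
})

test_that("weighted F1 is invariant under class relabeling", {
  d <- coupled_corpus(K = 3, per_group = 15, overlap = 0.5, seed = 23)
  rep1 <- train_predict_cv(d$mx, d$cs, classifier_spec("multinomial_nb",
                                                       seed = 4))
  # permute the label indices
  perm <- c(2L, 0L, 1L)
  cs2 <- cluster_set(perm[d$cs$labels + 1L], d$cs$doc_ids, "perm")
  rep2 <- train_predict_cv(d$mx, cs2, classifier_spec("multinomial_nb",
                                                      seed = 4))
  expect_equal(rep2$f1_weighted, rep1$f1_weighted, tolerance = 1e-12)
  expect_equal(rep2$kappa, rep1$kappa, tolerance = 1e-12)
})

test_that("validation: size-1 classes are rejected by name, unknown specs fail", {
  d <- coupled_corpus(K = 3, per_group = 10, seed = 29)
  labs <- d$cs$labels
  labs[labs == 2L][-1] <- 1L # leave exactly one doc in class 2
  cs <- cluster_set(labs, d$cs$doc_ids, "toy")
  expect_error(
    train_predict_cv(d$mx, cs, classifier_spec("sgd_svm", seed = 1)),
    "size 1.*2"
  )
})

test_that("determinism: identical spec and seed give identical reports", {
  d <- coupled_corpus(K = 3, per_group = 12, overlap = 0.4, seed = 31)
  r1 <- train_predict_cv(d$mx, d$cs, classifier_spec("sgd_svm", seed = 9))
  r2 <- train_predict_cv(d$mx, d$cs, classifier_spec("sgd_svm", seed = 9))
  expect_identical(r1$confusion, r2$confusion)
  expect_identical(r1$f1_weighted, r2$f1_weighted)
})

test_that("support_vs_f1 computes Spearman rho with sane edge cases", {
  conf <- diag(c(40, 30, 20, 10))
  conf[1, 2] <- 0
  spec <- classifier_spec("sgd_svm", seed = 1)
  rep <- nephrotext:::eval_report(
    y = rep(0:3, times = c(40, 30, 20, 10)),
    pred = rep(0:3, times = c(40, 30, 20, 10)),
    classes = 0:3, n_folds = 10, spec = spec
  )
  out <- support_vs_f1(rep)
  expect_false(out$defined) # constant F1 vector -> flagged undefined

  rep$per_class$f1 <- c(0.9, 0.7, 0.5, 0.3)
  rep$per_class$support <- c(100, 60, 30, 10)
  out2 <- support_vs_f1(rep)
  expect_equal(out2$rho, 1)
  rep$per_class <- rep$per_class[1:3, ]
  expect_error(support_vs_f1(rep), "4 classes")
})

test_that("compare_classifiers returns one ranked row per spec", {
  d <- coupled_corpus(K = 3, per_group = 12, overlap = 0.3, seed = 37)
  specs <- list(classifier_spec("sgd_svm", seed = 2),
                classifier_spec("multinomial_nb", seed = 2))
  cmp <- compare_classifiers(d$mx, d$cs, specs, folds = 5)
  expect_equal(nrow(cmp$table), 2)
  expect_true(!is.unsorted(rev(cmp$table$f1_weighted)))
  expect_length(cmp$reports, 2)
})

test_that("neural models: softmax rows, parameter counts, toy capacity", {
  set.seed(1)
  docs <- c(
    lapply(1:20, function(i) {
      token_doc(paste0("a", i), sample(c("alpha", "beta", "gamma"), 8, TRUE))
    }),
    lapply(1:20, function(i) {
      token_doc(paste0("b", i), sample(c("delta", "eps", "zeta"), 8, TRUE))
    })
  )
  y <- rep(0:1, each = 20)
  enc <- encode_sequences(docs)
  V <- enc$vocab_size; d <- 16L; h <- 16L; K <- 2L; nf <- 32L

  cnn <- classifier_spec("cnn_embed", list(epochs = 50, emb_dim = d,
                                           hidden = h), seed = 3)
  m <- build_neural(cnn, V, K)
  P <- neural_forward(m, enc$ids[1:6, , drop = FALSE])
  expect_equal(rowSums(P), rep(1, 6), tolerance = 1e-12)
  expect_equal(m$n_params,
               V * d + (3 * d * nf + nf) + (nf * h + h) + (h * K + K))
  fit <- neural_fit(cnn, enc$ids, y, V, seed = 3)
  expect_equal(mean(neural_predict(fit, enc$ids) == y), 1)

  rnn <- classifier_spec("rnn_embed", list(epochs = 50, emb_dim = d,
                                           hidden = h), seed = 3)
  mr <- build_neural(rnn, V, K)
  expect_equal(mr$n_params,
               V * d + 2 * (d * 4 * h + h * 4 * h + 4 * h) +
                 (2 * h * K + K))
  Pr <- neural_forward(mr, enc$ids[1:6, , drop = FALSE])
  expect_equal(rowSums(Pr), rep(1, 6), tolerance = 1e-12)
  fr <- neural_fit(rnn, enc$ids, y, V, seed = 3)
  expect_equal(mean(neural_predict(fr, enc$ids) == y), 1)

  expect_error(build_neural(classifier_spec("mlp", seed = 1), V, K),
               "cnn_embed or rnn_embed")
  # empty sequences are dropped from training with a warning
  ids2 <- rbind(enc$ids, 0L)
  expect_warning(neural_fit(cnn, ids2, c(y, 0L), V, seed = 3), "dropped")
})

test_that("neural CV path works end to end on a small corpus", {
  d <- coupled_corpus(K = 2, per_group = 15, seed = 41)
  rep <- train_predict_cv(
    d$mx, d$cs,
    classifier_spec("cnn_embed", list(epochs = 12, emb_dim = 12,
                                      hidden = 12), seed = 6),
    folds = 3
  )
  expect_gte(rep$f1_weighted, 0.9) # separable two-group toy
})
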