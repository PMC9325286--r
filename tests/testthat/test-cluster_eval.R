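# Cluster-set metrics: silhouette, relative entropy, cls accuracy,
# projections and the author confound.

test_that("silhouette equals the brute-force oracle and handles limits", {
  # duplicated points in two far-apart clusters: a = 0 limit -> 1
  X <- rbind(matrix(0, 4, 2), matrix(10, 4, 2))
  cs <- cluster_set(rep(0:1, each = 4), paste0("d", 1:8), "toy")
  expect_equal(silhouette_score(X, cs), 1)

  # 6 planar points, 2 clusters: exact match with the O(n^2) oracle
  set.seed(5)
  X6 <- matrix(rnorm(12), 6, 2)
  lab <- c(0, 0, 0, 1, 1, 1)
  cs6 <- cluster_set(lab, paste0("d", 1:6), "toy")
  expect_equal(silhouette_score(X6, cs6), silhouette_oracle(X6, lab),
               tolerance = 1e-12)

  expect_error(
    silhouette_score(X6, cluster_set(rep(0, 6), paste0("d", 1:6), "t")),
    "at least 2"
  )
})

test_that("silhouette and relative entropy ignore outlier documents", {
  set.seed(8)
  X <- rbind(matrix(rnorm(20, sd = .2), 10, 2),
             matrix(rnorm(20, sd = .2) + 5, 10, 2))
  lab <- rep(0:1, each = 10)
  docs <- toy_docs(lapply(1:20, function(i) {
    sample(c("a", "b", "c"), 5, TRUE)
  }))
  counts <- vectorize(docs, "count")
  cs <- cluster_set(lab, counts$doc_ids, "toy")
  base_sil <- silhouette_score(X, cs)
  base_re <- relative_entropy(counts, cs)

  # add outlier docs: both metrics unchanged
  X2 <- rbind(X, matrix(50, 3, 2))
  docs2 <- c(docs, toy_docs(rep(list(c("z", "z")), 3),
                            ids = paste0("o", 1:3)))
  counts2 <- vectorize(docs2, "count")
  cs2 <- cluster_set(c(lab, rep(-1L, 3)), counts2$doc_ids, "toy")
  expect_equal(silhouette_score(X2, cs2), base_sil, tolerance = 1e-12)
  # vocabulary differs but cluster domains are identical
  expect_equal(relative_entropy(counts2, cs2), base_re, tolerance = 1e-12)
})

test_that("relative entropy: zero limits and brute-force agreement", {
  # identical documents per cluster -> 0
  docs <- toy_docs(c(rep(list(c("a", "a", "b")), 3),
                     rep(list(c("c", "d")), 3)))
  counts <- vectorize(docs, "count")
  cs <- cluster_set(rep(0:1, each = 3), counts$doc_ids, "toy")
  expect_equal(relative_entropy(counts, cs), 0)

  # singleton cluster contributes 0
  docs1 <- toy_docs(list(c("a", "b"), c("c", "c"), c("c", "d")))
  c1 <- vectorize(docs1, "count")
  cs1 <- cluster_set(c(0L, 1L, 1L), c1$doc_ids, "toy")
  expect_equal(
    relative_entropy(c1, cluster_set(c(0L, 1L, 2L), c1$doc_ids, "t")),
    0
  )

  # 2-cluster 4-doc toy with distinct counts: hand-summed KL
  docs4 <- toy_docs(list(
    c("a", "a", "b"), c("a", "b", "b", "b"),
    c("x", "y"), c("x", "x", "x", "y")
  ))
  c4 <- vectorize(docs4, "count")
  cs4 <- cluster_set(c(0L, 0L, 1L, 1L), c4$doc_ids, "toy")
  expect_equal(relative_entropy(c4, cs4),
               relative_entropy_oracle(as.matrix(c4$matrix),
                                       c(0, 0, 1, 1)),
               tolerance = 1e-12)
  # strictly positive when any cluster mixes different distributions
  expect_gt(relative_entropy(c4, cs4), 0)
  # duplication of identical docs keeps the all-identical case at 0
  expect_error(relative_entropy(dtm_tfidf(c4), cs4), "counts")
})

test_that("cls accuracy: separable limit and permutation null", {
  sc <- small_corpus(K = 2, per_group = 30, overlap = 0, seed = 21)
  counts <- vectorize(preprocess_corpus(sc$corpus, "diagnosis"), "count")
  cs <- cluster_set(sc$truth, counts$doc_ids, "planted")
  expect_gte(cls_accuracy(counts, cs, seed = 2), 0.99)

  # random label permutations on balanced clusters: accuracy ~ 1/2
  accs <- vapply(1:20, function(r) {
    set.seed(100 + r)
    perm <- sample(sc$truth)
    cls_accuracy(counts, cluster_set(perm, counts$doc_ids, "perm"),
                 seed = r, folds = 5)
  }, numeric(1))
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 3 * se + 0.02)

  expect_error(
    cls_accuracy(counts, cluster_set(rep(0, 60), counts$doc_ids, "t")),
    "at least 2"
  )
})

test_that("evaluate_clusterset assembles a coherent scorecard row", {
  sc <- small_corpus(K = 3, per_group = 20, overlap = 0, seed = 31)
  counts <- vectorize(preprocess_corpus(sc$corpus, "diagnosis"), "count")
  cs <- cluster_set(sc$truth, counts$doc_ids, "planted")
  row <- evaluate_clusterset(counts, cs, seed = 1)
  expect_gt(row$s_score, 0.3) # tf-idf space: positive, well separated
  expect_gte(row$cls_accuracy, 0.99)
  expect_lt(row$rel_entropy, relative_entropy(
    counts, cluster_set(sample(sc$truth), counts$doc_ids, "perm")
  ))
  expect_equal(row$n_clusters, n_clusters(cs))
  expect_equal(row$corpus_size, corpus_size_kept(cs))
})

test_that("project_2d: PCA matches eigendecomposition, rank-1 collapses", {
  # collinear points: second component has zero variance
  X <- cbind(1:6, 2 * (1:6) + 3, -(1:6))
  pr <- project_2d(X, "pca")
  expect_equal(stats::var(pr$y), 0, tolerance = 1e-20)

  # 5-point toy: coordinates match the covariance eigendecomposition
  set.seed(4)
  X5 <- matrix(rnorm(15), 5, 3)
  pr5 <- project_2d(X5, "pca")
  Xc <- scale(X5, scale = FALSE)
  eig <- eigen(crossprod(Xc) / (nrow(Xc) - 1), symmetric = TRUE)
  expected <- Xc %*% eig$vectors[, 1:2]
  # eigenvectors are sign-ambiguous; compare up to per-axis sign
  for (j in 1:2) {
    got <- pr5[[c("x", "y")[j]]]
    expect_true(isTRUE(all.equal(got, expected[, j], tolerance = 1e-8)) ||
                isTRUE(all.equal(got, -expected[, j], tolerance = 1e-8)))
  }
  expect_error(project_2d(X5[1:2, ], "pca"), "at least 3")

  u1 <- project_2d(X5, "umap", seed = 3)
  u2 <- project_2d(X5, "umap", seed = 3)
  expect_identical(u1, u2)
})

test_that("author confound: independence, identity, conservation", {
  set.seed(6)
  n <- 600
  labels <- sample(0:3, n, replace = TRUE)
  ids <- paste0("d", 1:n)
  cs <- cluster_set(labels, ids, "toy")

  indep <- author_confound(cs, sample(c("A0", "A1", "A2"), n, TRUE))
  expect_lt(indep$association, 0.1)
  expect_equal(sum(indep$contingency), corpus_size_kept(cs))

  ident <- author_confound(cs, paste0("A", labels))
  expect_equal(ident$association, 1, tolerance = 1e-12)

  authors <- paste0("A", labels)
  authors[1:10] <- NA
  expect_warning(part <- author_confound(cs, authors), "missing")
  expect_equal(sum(part$contingency), n - 10)
})
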