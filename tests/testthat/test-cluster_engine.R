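# Clustering backends: recovery on separable corpora, determinism,
# degenerate cases, elbow selection, cluster-count bounds.

make_toy_dtms <- function(K = 3, per_group = 15, seed = 3) {
  sc <- small_corpus(K = K, per_group = per_group, overlap = 0,
                     seed = seed)
  docs <- preprocess_corpus(sc$corpus, "diagnosis")
  counts <- vectorize(docs, "count")
  list(counts = counts, tfidf = dtm_tfidf(counts), truth = sc$truth,
       docs = docs)
}

test_that("k-means: separable recovery, k = n, determinism, validation", {
  d <- make_toy_dtms()
  cs <- cluster_kmeans(d$tfidf, 3, seed = 1)
  expect_equal(adjusted_rand_index(cs$labels, d$truth), 1)
  expect_equal(corpus_size_kept(cs), length(cs$labels)) # no outliers

  n <- nrow(d$tfidf$matrix)
  singletons <- cluster_kmeans(d$tfidf, n, seed = 1, nstart = 1)
  expect_equal(n_clusters(singletons), n)

  again <- cluster_kmeans(d$tfidf, 3, seed = 1)
  expect_identical(cs$labels, again$labels)
  expect_error(cluster_kmeans(d$tfidf, 1), "k must")
  expect_error(cluster_kmeans(d$tfidf, n + 1), "k must")
})

test_that("LDA: generative recovery, k = 1, theta normalization, mode check", {
  d <- make_toy_dtms(seed = 11)
  cs <- cluster_lda(d$counts, 3, seed = 2)
  expect_equal(adjusted_rand_index(cs$labels, d$truth), 1)
  expect_equal(unname(rowSums(cs$theta)), rep(1, nrow(cs$theta)),
               tolerance = 1e-12)

  one <- cluster_lda(d$counts, 1, seed = 2, nstart = 1, n_iter = 5)
  expect_true(all(one$labels == 0))
  expect_error(cluster_lda(d$tfidf, 3), "count-mode")
})

test_that("GSDPMM: collapse on identical docs, recovery, validation", {
  ident <- vectorize(toy_docs(rep(list(c("w1", "w2", "w2")), 12)), "count")
  cs <- cluster_gsdpmm(ident, seed = 1, nstart = 1)
  expect_equal(n_clusters(cs), 1)

  d <- make_toy_dtms(K = 2, per_group = 20, seed = 4)
  cs <- cluster_gsdpmm(d$counts, K_max = 10, seed = 1)
  expect_equal(n_clusters(cs), 2)
  expect_equal(adjusted_rand_index(cs$labels, d$truth), 1)

  expect_error(cluster_gsdpmm(d$counts, alpha = -1), "positive")
  expect_error(cluster_gsdpmm(d$tfidf), "count-mode")
})

test_that("GSDPMM stationary distribution matches brute-force enumeration", {
  # 3 documents, tiny vocabulary: enumerate all 5 partitions, compute the
  # exact collapsed DPMM posterior independently, and compare with the
  # sampler's empirical distribution over many short independent chains.
  docs <- toy_docs(list(c("u", "u", "v"), c("u", "v"), c("x", "x")))
  counts <- vectorize(docs, "count")
  alpha <- 0.7; beta <- 0.4
  V <- ncol(counts$matrix)
  cm <- as.matrix(counts$matrix)

  part_loglik <- function(partition) {
    ll <- 0
    for (blk in partition) {
      ll <- ll + log(alpha) + lgamma(length(blk))
      cw <- colSums(cm[blk, , drop = FALSE])
      ll <- ll + lgamma(V * beta) - lgamma(sum(cw) + V * beta) +
        sum(lgamma(cw + beta) - lgamma(beta))
    }
    ll
  }
  partitions <- list(
    list(1:3), list(c(1, 2), 3), list(c(1, 3), 2), list(c(2, 3), 1),
    list(1, 2, 3)
  )
  lp <- vapply(partitions, part_loglik, numeric(1))
  exact <- exp(lp - max(lp)); exact <- exact / sum(exact)

  canon <- function(labels) {
    paste(match(labels, unique(labels)), collapse = "")
  }
  keys <- vapply(partitions, function(p) {
    lab <- integer(3)
    for (b in seq_along(p)) lab[p[[b]]] <- b
    canon(lab)
  }, character(1))

  n_runs <- 600
  hits <- setNames(numeric(length(keys)), keys)
  for (r in seq_len(n_runs)) {
    cs <- cluster_gsdpmm(counts, alpha = alpha, beta = beta, K_max = 5,
                         n_iter = 8, seed = r, nstart = 1)
    hits[canon(cs$labels)] <- hits[canon(cs$labels)] + 1
  }
  empirical <- hits / n_runs
  expect_lt(sum(abs(empirical - exact)) / 2, 0.08) # total variation
})

test_that("GSDPMM occupied-cluster count is nonincreasing in beta", {
  d <- make_toy_dtms(K = 4, per_group = 15, seed = 8)
  ks <- vapply(c(0.01, 0.2, 2), function(b) {
    n_clusters(cluster_gsdpmm(d$counts, beta = b, seed = 5, nstart = 1))
  }, numeric(1))
  expect_true(all(diff(ks) <= 0))
})

test_that("doc2vec embeddings separate disjoint-vocabulary groups", {
  d <- make_toy_dtms(K = 2, per_group = 20, seed = 6)
  emb <- embed_doc2vec(d$docs, dim = 24, epochs = 15, seed = 3)
  expect_equal(dim(emb$matrix), c(40, 24))
  expect_true(all(is.finite(emb$matrix)))

  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  n <- nrow(emb$matrix)
  sims <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
    cosine(emb$matrix[i, ], emb$matrix[j, ])
  }))
  same <- outer(d$truth, d$truth, "==")
  diag(same) <- NA
  expect_gt(mean(sims[same & !is.na(same)]),
            mean(sims[!same & !is.na(same)]))

  again <- embed_doc2vec(d$docs, dim = 24, epochs = 15, seed = 3)
  expect_identical(emb$matrix, again$matrix)
  expect_error(embed_doc2vec(d$docs[1:5], dim = 8), "at least 10")
})

test_that("elbow selection finds planted k and handles degenerate curves", {
  # analytic curve with the maximum chord distance exactly at k = 3
  k <- 2:8
  obj <- c(100, 40, 35, 31, 28, 26, 25)
  expect_equal(elbow_point(k, obj), 3)
  expect_warning(flat <- elbow_point(k, rep(5, 7)), "flat")
  expect_equal(flat, 2)

  d5 <- make_toy_dtms(K = 5, per_group = 15, seed = 10)
  expect_equal(select_k_elbow(d5$tfidf, 2:12, seed = 1), 5)
})

test_that("cluster-count bounds warn outside [10, 20] only", {
  mk <- function(K) {
    cluster_set(rep(0:(K - 1), each = 2), paste0("d", 1:(2 * K)), "x")
  }
  expect_length(suppressWarnings(check_cluster_bounds(mk(16))), 0)
  expect_warning(msgs <- check_cluster_bounds(mk(7)), "below")
  expect_length(msgs, 1)
  expect_length(suppressWarnings(check_cluster_bounds(mk(10))), 0)
  expect_length(suppressWarnings(check_cluster_bounds(mk(20))), 0)
})

test_that("cluster-set persistence round-trips", {
  cs <- cluster_set(c(0L, 1L, -1L, 0L), paste0("d", 1:4), "hdbscan",
                    params = list(min_cluster_size = 5), seed = 3L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cluster_set(cs, path)
  back <- read_cluster_set(path)
  expect_identical(back$labels, cs$labels)
  expect_identical(back$doc_ids, cs$doc_ids)
  expect_identical(back$method, cs$method)
})
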