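# Keyword extraction and cluster naming.

planted_kw_corpus <- function(K = 4, per_group = 20, seed = 13) {
  sc <- small_corpus(K = K, per_group = per_group, overlap = 0,
                     seed = seed)
  docs <- preprocess_corpus(sc$corpus, "diagnosis")
  counts <- vectorize(docs, "count")
  list(counts = counts, tfidf = dtm_tfidf(counts),
       cs = cluster_set(sc$truth, counts$doc_ids, "planted"))
}

test_that("tf-idf keywords: unique markers rank first, hand-checked toy", {
  docs <- toy_docs(list(
    c("marker0", "marker0", "marker0", "common", "filler"),
    c("marker0", "marker0", "common", "filler"),
    c("marker1", "marker1", "marker1", "common", "other"),
    c("marker1", "marker1", "common", "other")
  ))
  counts <- vectorize(docs, "count")
  cs <- cluster_set(c(0L, 0L, 1L, 1L), counts$doc_ids, "toy")
  kt <- keywords_tfidf(counts, cs, top_n = 2)
  expect_equal(kt$term[kt$cluster == 0 & kt$rank == 1], "marker0")
  expect_equal(kt$term[kt$cluster == 1 & kt$rank == 1], "marker1")

  # hand tf-idf on the two pooled pseudo-documents (n = 2):
  # cluster-exclusive terms: df = 1 -> idf = ln(3/2)+1; common: df = 2
  # -> idf = ln(3/3)+1 = 1. Pooled cluster-0 counts: marker0 = 5,
  # common = 2, filler = 2.
  idf_excl <- log(3 / 2) + 1
  raw <- c(marker0 = 5 * idf_excl, common = 2 * 1, filler = 2 * idf_excl)
  expected <- raw[order(-raw, names(raw))] / sqrt(sum(raw^2))
  got <- kt[kt$cluster == 0, ]
  expect_equal(got$term, names(expected)[1:2])
  expect_equal(got$score, unname(expected[1:2]), tolerance = 1e-12)
  # "common" occurs equally in both clusters and never makes a top list
  expect_false("common" %in% kt$term)

  expect_error(
    keywords_tfidf(counts, cluster_set(rep(0, 4), counts$doc_ids, "t")),
    "2 clusters"
  )
})

test_that("tf-idf keyword scores are nonincreasing and terms unique", {
  d <- planted_kw_corpus()
  kt <- keywords_tfidf(d$counts, d$cs, top_n = 10)
  for (cl in unique(kt$cluster)) {
    sub <- kt[kt$cluster == cl, ]
    expect_true(all(diff(sub$score) <= 1e-12))
    expect_false(anyDuplicated(sub$term) > 0)
  }
})

test_that("planted markers are recovered by both extraction methods", {
  d <- planted_kw_corpus(K = 5, per_group = 20)
  kt <- keywords_tfidf(d$counts, d$cs, top_n = 10)
  ks <- keywords_svm(d$tfidf, d$cs, top_n = 10, seed = 2)
  frac_marked <- function(kw) {
    mean(vapply(split(kw, kw$cluster), function(sub) {
      sum(grepl(sprintf("^grp%d_dx_", sub$cluster[1]), sub$term)) >= 3
    }, logical(1)))
  }
  expect_gte(frac_marked(kt), 0.9)
  expect_gte(frac_marked(ks), 0.9)
  # the two methods agree on at least one marker per cluster
  for (cl in unique(kt$cluster)) {
    both <- intersect(kt$term[kt$cluster == cl], ks$term[ks$cluster == cl])
    expect_gte(sum(grepl("_dx_", both)), 1)
  }
})

test_that("SVM keywords come from the cluster's own vocabulary when separable", {
  d <- planted_kw_corpus(K = 3, per_group = 15)
  ks <- keywords_svm(d$tfidf, d$cs, top_n = 10, seed = 1)
  for (cl in unique(ks$cluster)) {
    terms <- ks$term[ks$cluster == cl]
    own <- grepl(sprintf("^grp%d_", cl), terms)
    other_marker <- grepl("^grp", terms) & !own
    expect_equal(sum(other_marker), 0)
  }
})

test_that("SGD-SVM weights match the brute-force maximum-margin QP", {
  X <- Matrix::Matrix(matrix(c(
    2, 0, 1,
    1, 0, 2,
    0, 2, 1,
    0, 1, 2
  ), 4, 3, byrow = TRUE), sparse = TRUE)
  y <- c(0, 0, 1, 1)
  fit <- svm_sgd_fit(X, y, lambda = 1e-4, n_iter = 2000, batch = 4,
                     seed = 1)
  w <- fit$W[2, ] - fit$W[1, ]

  # enumerate support-vector subsets for the hard-margin QP
  Xd <- as.matrix(X)
  yy <- ifelse(y == 1, 1, -1)
  best <- NULL
  combs <- unlist(lapply(2:4, function(k) combn(4, k, simplify = FALSE)),
                  recursive = FALSE)
  for (S in combs) {
    A <- rbind(
      cbind(Xd[S, , drop = FALSE] %*% t(Xd[S, , drop = FALSE]) *
              outer(yy[S], yy[S]), yy[S]),
      c(yy[S], 0)
    )
    sol <- tryCatch(solve(A, c(rep(1, length(S)), 0)),
                    error = function(e) NULL)
    if (is.null(sol)) next
    a <- sol[seq_along(S)]
    if (any(a < -1e-9)) next
    wq <- colSums(a * yy[S] * Xd[S, , drop = FALSE])
    if (all(yy * (Xd %*% wq + sol[length(sol)]) >= 1 - 1e-6)) {
      if (is.null(best) || sum(wq^2) < best$n2 - 1e-9) {
        best <- list(w = wq, n2 = sum(wq^2))
      }
    }
  }
  cosine <- sum(w * best$w) / sqrt(sum(w^2) * sum(best$w^2))
  expect_gt(cosine, 0.99)
})

test_that("cluster naming joins annotations and validates them", {
  d <- planted_kw_corpus(K = 4, per_group = 10)
  kt <- keywords_tfidf(d$counts, d$cs)
  ann <- data.frame(cluster = c(0, 1), name = c("lupus", "iga"),
                    strength = c("strong", "weak"))
  nm <- attach_naming(kt, ann)
  expect_equal(sum(nm$strength == "unnamed"), 2)
  expect_equal(nm$name[nm$cluster == 0], "lupus")

  empty <- attach_naming(kt, data.frame(cluster = integer(),
                                        name = character(),
                                        strength = character()))
  expect_true(all(empty$strength == "unnamed"))

  expect_error(
    attach_naming(kt, data.frame(cluster = c(1, 1), name = c("a", "b"),
                                 strength = c("strong", "strong"))),
    "duplicate"
  )
  expect_error(
    attach_naming(kt, data.frame(cluster = 99, name = "x",
                                 strength = "strong")),
    "unknown"
  )
})

test_that("extraction is deterministic and robust to ubiquitous additions", {
  d <- planted_kw_corpus(K = 3, per_group = 12)
  k1 <- keywords_svm(d$tfidf, d$cs, seed = 5)
  k2 <- keywords_svm(d$tfidf, d$cs, seed = 5)
  expect_identical(k1, k2)

  # adding a doc of already-ubiquitous terms does not change other
  # clusters' distinctive-term rankings: make "ubiq" ubiquitous first
  toks <- lapply(seq_len(nrow(d$counts$matrix)), function(i) {
    c(rep(d$counts$vocabulary, as.integer(d$counts$matrix[i, ])), "ubiq")
  })
  docs1 <- toy_docs(toks, ids = d$counts$doc_ids)
  counts1 <- vectorize(docs1, "count")
  kt <- keywords_tfidf(counts1, d$cs)
  docs2 <- c(docs1, toy_docs(list(rep("ubiq", 5)), ids = "extra"))
  counts2 <- vectorize(docs2, "count")
  cs2 <- cluster_set(c(d$cs$labels, 0L), counts2$doc_ids, "toy")
  kt2 <- keywords_tfidf(counts2, cs2)
  for (cl in c(1, 2)) {
    old <- kt$term[kt$cluster == cl & grepl("^grp", kt$term)]
    new <- kt2$term[kt2$cluster == cl & grepl("^grp", kt2$term)]
    expect_identical(new, old)
  }
})
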