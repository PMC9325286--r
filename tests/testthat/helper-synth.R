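# Shared fixtures: all corpora are generated in code, none stored.

# Small segmented synthetic corpus plus aligned planted labels.
small_corpus <- function(K = 4, per_group = 25, overlap = 0, seed = 1,
                         ...) {
  sp <- synth_spec(K = K, sizes = rep(per_group, K), overlap = overlap,
                   seed = seed, ...)
  gen <- synth_generate(sp)
  corpus <- segment_corpus(gen$raw_reports)
  truth <- gen$truth$group[match(corpus_ids(corpus), gen$truth$id)]
  list(corpus = corpus, truth = truth, gen = gen)
}

# Token docs built directly (no text round trip).
toy_docs <- function(token_lists, ids = NULL) {
  if (is.null(ids)) ids <- paste0("d", seq_along(token_lists))
  mapply(token_doc, ids, token_lists, SIMPLIFY = FALSE,
         USE.NAMES = FALSE)
}

# Independent O(n^2) silhouette oracle (Euclidean).
silhouette_oracle <- function(X, labels) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) {
      s[i] <- 0
      next
    }
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(D[i, labels == cl])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Independent relative-entropy oracle: explicit per-document KL sums.
relative_entropy_oracle <- function(counts_matrix, labels) {
  labs <- sort(unique(labels[labels >= 0]))
  cluster_means <- vapply(labs, function(j) {
    rows <- which(labels == j)
    pooled <- colSums(counts_matrix[rows, , drop = FALSE])
    dom <- which(pooled > 0)
    q <- pooled[dom] / sum(pooled[dom])
    kls <- vapply(rows, function(i) {
      cnt <- counts_matrix[i, dom]
      if (sum(cnt) == 0) return(0)
      p <- cnt / sum(cnt)
      keep <- p > 0
      sum(p[keep] * log(p[keep] / q[keep]))
    }, numeric(1))
    mean(kls)
  }, numeric(1))
  mean(cluster_means)
}

# Leftmost-longest MWE reference: straightforward recursive definition,
# independent of the package's scanning implementation.
merge_mwe_oracle <- function(tokens, mwe_list) {
  if (length(tokens) == 0) return(character())
  lens <- vapply(mwe_list, length, integer(1))
  for (L in sort(unique(lens), decreasing = TRUE)) {
    for (m in mwe_list[lens == L]) {
      if (length(tokens) >= L && identical(tokens[1:L], m)) {
        return(c(paste(m, collapse = "_"),
                 merge_mwe_oracle(tokens[-(1:L)], mwe_list)))
      }
    }
  }
  c(tokens[1], merge_mwe_oracle(tokens[-1], mwe_list))
}

# Generative Dirichlet-process multinomial mixture sample for recovery
# checks: CRP partition, per-cluster term distributions from a symmetric
# Dirichlet.
rdpmm_docs <- function(n_docs, vocab_size, doc_len, alpha, beta, seed) {
  withr_seed <- function(expr) {
    set.seed(seed)
    expr
  }
  withr_seed({
    z <- integer(n_docs)
    z[1] <- 1
    for (i in 2:n_docs) {
      sizes <- table(z[1:(i - 1)])
      probs <- c(as.numeric(sizes), alpha)
      pick <- sample(seq_along(probs), 1, prob = probs)
      z[i] <- if (pick > length(sizes)) length(sizes) + 1 else pick
    }
    K <- max(z)
    theta <- matrix(rgamma(K * vocab_size, shape = beta), K, vocab_size)
    theta <- theta / rowSums(theta)
    docs <- lapply(seq_len(n_docs), function(i) {
      words <- sample.int(vocab_size, doc_len, replace = TRUE,
                          prob = theta[z[i], ])
      token_doc(paste0("d", i), paste0("w", words))
    })
    list(docs = docs, z = z, K = K)
  })
}
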