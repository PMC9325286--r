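# Hierarchical density-based clustering (HDBSCAN) on a low-dimensional
# representation: mutual-reachability distances -> minimum spanning tree
# -> condensed cluster tree -> excess-of-mass cluster selection. Points
# that never join a stable cluster are labelled -1 (outliers).

# Prim's algorithm on a dense distance matrix; returns an (n-1) x 3
# matrix of edges (u, v, weight).
mst_prim <- function(D) {
  n <- nrow(D)
  in_tree <- logical(n)
  in_tree[1] <- TRUE
  best_d <- D[1, ]
  best_from <- rep(1L, n)
  edges <- matrix(0, n - 1, 3)
  for (step in seq_len(n - 1)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best_d[cand])]
    edges[step, ] <- c(best_from[j], j, best_d[j])
    in_tree[j] <- TRUE
    upd <- which(!in_tree & D[j, ] < best_d)
    best_from[upd] <- j
    best_d[upd] <- D[j, upd]
  }
  edges
}

# Single-linkage dendrogram from MST edges. Leaves are 1..n; internal
# nodes n+1..2n-1 in merge order. Returns children/height/size arrays.
single_linkage_tree <- function(edges, n) {
  ord <- order(edges[, 3])
  edges <- edges[ord, , drop = FALSE]
  uf <- seq_len(n)
  find <- function(x) {
    while (uf[x] != x) {
      uf[x] <<- uf[uf[x]]
      x <- uf[x]
    }
    x
  }
  total <- 2L * n - 1L
  comp_node <- seq_len(n)
  left <- integer(total); right <- integer(total)
  height <- numeric(total); size <- rep(1L, total)
  nxt <- n
  for (e in seq_len(nrow(edges))) {
    ru <- find(edges[e, 1])
    rv <- find(edges[e, 2])
    na <- comp_node[ru]; nb <- comp_node[rv]
    nxt <- nxt + 1L
    left[nxt] <- na; right[nxt] <- nb
    height[nxt] <- edges[e, 3]
    size[nxt] <- size[na] + size[nb]
    uf[ru] <- rv
    comp_node[rv] <- nxt
  }
  list(left = left, right = right, height = height, size = size, n = n)
}

tree_leaves <- function(tree, node) {
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (nd <= tree$n) out <- c(out, nd)
    else stack <- c(stack, tree$left[nd], tree$right[nd])
  }
  out
}

#' Density-based clustering with HDBSCAN
#'
#' @param E A `reduced_embedding` (or numeric matrix) — typically the
#'   output of [reduce_umap()], since density estimation degrades in very
#'   high-dimensional spaces.
#' @param min_cluster_size Smallest cluster size considered real (>= 2).
#' @param min_samples Neighbourhood size for the core-distance estimate
#'   (defaults to `min_cluster_size`).
#' @return A [cluster_set()] with labels in `{-1, 0..K-1}`; `-1` marks
#'   outliers, which downstream metrics exclude.
#' @export
cluster_hdbscan <- function(E, min_cluster_size = 15L,
                            min_samples = min_cluster_size) {
  if (min_cluster_size < 2) stop("min_cluster_size must be >= 2")
  M <- as_dense(E)
  n <- nrow(M)
  if (n < 2 * min_cluster_size) {
    stop("too few points for the requested min_cluster_size")
  }
  D <- as.matrix(stats::dist(M))
  core <- vapply(seq_len(n), function(i) {
    sort(D[i, ])[min_samples + 1L] # self sits at rank 1
  }, numeric(1))
  MR <- pmax(D, outer(core, rep(1, n)), outer(rep(1, n), core))
  tree <- single_linkage_tree(mst_prim(MR), n)
  labels <- extract_eom_labels(tree, min_cluster_size)
  params <- list(min_cluster_size = min_cluster_size,
                 min_samples = min_samples)
  if (inherits(E, "reduced_embedding")) params$reducer <- E$params
  cluster_set(
    labels = compact_labels(labels),
    doc_ids = rep_doc_ids(E),
    method = "hdbscan",
    params = params,
    seed = if (inherits(E, "reduced_embedding")) E$seed else NA_integer_
  )
}

# Condense the dendrogram (clusters smaller than min_cluster_size fall
# out as points), compute cluster stabilities, select clusters by excess
# of mass, and label points. Returns 0-based labels with -1 for noise.
extract_eom_labels <- function(tree, min_cluster_size) {
  n <- tree$n
  lambda_of <- function(h) 1 / max(h, 1e-10)

  cl_parent <- integer(0)   # condensed-tree parent of each cluster
  cl_birth <- numeric(0)    # lambda at which the cluster appears
  new_cluster <- function(parent, birth) {
    cl_parent[length(cl_parent) + 1L] <<- parent
    cl_birth[length(cl_birth) + 1L] <<- birth
    length(cl_parent)
  }
  root_cl <- new_cluster(0L, 0)

  pt_cluster <- integer(n)  # condensed cluster each point falls out of
  pt_lambda <- numeric(n)
  stability <- numeric(1)   # grown alongside cl_parent
  child_mass <- list()      # per cluster: child-cluster (lambda, size) rows

  add_stability <- function(cl, lam, size) {
    while (length(stability) < cl) stability[length(stability) + 1L] <<- 0
    stability[cl] <<- stability[cl] + (lam - cl_birth[cl]) * size
  }

  stack <- list(c(node = 2L * n - 1L, cl = root_cl))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- fr[["node"]]; cl <- fr[["cl"]]
    if (node <= n) { # isolated leaf reached directly (degenerate)
      pt_cluster[node] <- cl
      pt_lambda[node] <- lambda_of(0)
      next
    }
    a <- tree$left[node]; b <- tree$right[node]
    sa <- tree$size[a]; sb <- tree$size[b]
    lam <- lambda_of(tree$height[node])
    if (sa >= min_cluster_size && sb >= min_cluster_size) {
      ca <- new_cluster(cl, lam)
      cb <- new_cluster(cl, lam)
      add_stability(cl, lam, sa)
      add_stability(cl, lam, sb)
      stack[[length(stack) + 1L]] <- c(node = a, cl = ca)
      stack[[length(stack) + 1L]] <- c(node = b, cl = cb)
    } else {
      for (child in c(a, b)) {
        if (tree$size[child] >= min_cluster_size) {
          stack[[length(stack) + 1L]] <- c(node = child, cl = cl)
        } else {
          for (leaf in tree_leaves(tree, child)) {
            pt_cluster[leaf] <- cl
            pt_lambda[leaf] <- lam
            add_stability(cl, lam, 1L)
          }
        }
      }
    }
  }
  n_cl <- length(cl_parent)
  while (length(stability) < n_cl) stability[length(stability) + 1L] <- 0

  # excess-of-mass selection, bottom-up; the root is never selected
  selected <- logical(n_cl)
  subtree_stab <- stability
  if (n_cl >= 2) {
    for (cl in n_cl:2) {
      kids <- which(cl_parent == cl)
      if (length(kids) == 0) {
        selected[cl] <- TRUE
      } else {
        kid_total <- sum(subtree_stab[kids])
        if (stability[cl] >= kid_total) {
          selected[cl] <- TRUE
          # deselect all descendants
          desc <- kids
          while (length(desc)) {
            selected[desc] <- FALSE
            desc <- which(cl_parent %in% desc)
          }
        } else {
          subtree_stab[cl] <- kid_total
        }
      }
    }
  }
  selected[1] <- FALSE

  sel_ids <- which(selected)
  labels <- rep(-1L, n)
  if (length(sel_ids)) {
    relabel <- setNames(seq_along(sel_ids) - 1L, sel_ids)
    for (p in seq_len(n)) {
      cl <- pt_cluster[p]
      while (cl > 0) {
        if (selected[cl]) {
          labels[p] <- relabel[[as.character(cl)]]
          break
        }
        cl <- cl_parent[cl]
      }
    }
  }
  labels
}
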