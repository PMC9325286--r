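# Internal helpers shared across modules.

#' Derive a stage-specific RNG seed from a global seed
#'
#' Component seeds are derived from the global study seed and the stage name
#' so that no two pipeline stages reuse the same random stream, while the
#' whole study stays reproducible from a single integer.
#'
#' @param seed Global integer seed.
#' @param stage Character stage name, e.g. `"cluster/kmeans"`.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647 # 2^31 - 1, Mersenne prime used by Lehmer generators
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% m
  s <- ((seed %% m) * 48271 + h) %% m
  as.integer(s + 1)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Stratified fold assignment: returns an integer vector of fold ids in
# 1..n_folds, balanced within each class. Fold count is reduced (with a
# warning) when the smallest class has fewer members than `n_folds`.
stratified_folds <- function(y, n_folds = 10L, seed = 1L) {
  y <- as.integer(y)
  min_class <- min(table(y))
  if (min_class < n_folds) {
    n_folds <- max(2L, as.integer(min_class))
    warning(sprintf(
      "smallest class has %d members; reducing fold count to %d",
      min_class, n_folds
    ))
  }
  folds <- integer(length(y))
  with_local_seed(seed, {
    for (cl in sort(unique(y))) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

# Adjusted Rand index between two label vectors (used only against
# synthetic planted truth). Chance-corrected; 1 = identical partitions.
#' Adjusted Rand index between two partitions
#'
#' @param a,b Integer or factor label vectors of equal length.
#' @return The adjusted Rand index in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Deterministic number formatting for persisted artifacts: round-trippable
# and byte-stable across runs.
fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.12g", x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
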