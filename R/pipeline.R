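# Orchestration of the full two-stage study: segment -> preprocess ->
# cluster (all configured backends) -> evaluate (scorecard) -> select the
# best cluster-set -> extract keywords -> classify descriptions.
# Everything is driven by one configuration and one global seed;
# per-stage seeds are derived with stage_seed() so no stage reuses
# another's random stream.

KNOWN_BACKENDS <- c("kmeans", "lda", "gsdpmm", "hdbscan",
                    "doc2vec_hdbscan")

#' Configuration for a full study run
#'
#' @param corpus_source Either `list(type = "synthetic", spec =
#'   synth_spec(...))` or `list(type = "files", path = <dir or jsonl>)`.
#' @param backends Named list of backend parameter lists; names from
#'   `"kmeans"`, `"lda"`, `"gsdpmm"`, `"hdbscan"`,
#'   `"doc2vec_hdbscan"`. An empty list entry uses defaults.
#' @param classifiers Character vector of classifier names to compare on
#'   the description sections (see [classifier_spec()]).
#' @param preprocess A [preprocess_config()].
#' @param min_kept_fraction Cluster-sets keeping fewer than this
#'   fraction of documents are not eligible as "best" (heavy outlier
#'   rejection shrinks the labelled corpus too much).
#' @param select_backend Optional manual override of the backend choice.
#' @param folds Cross-validation folds for cls accuracy and
#'   classification.
#' @param seed Global integer seed.
#' @param out_dir Optional directory for persisted artifacts.
#' @return A `run_config` object.
#' @export
run_config <- function(corpus_source,
                       backends = list(kmeans = list(k = 12L),
                                       lda = list(k = 12L),
                                       gsdpmm = list(),
                                       hdbscan = list()),
                       classifiers = c("sgd_svm", "logreg",
                                       "multinomial_nb"),
                       preprocess = preprocess_config(),
                       min_kept_fraction = 0.65,
                       select_backend = NULL,
                       folds = 10L,
                       seed = 1L,
                       out_dir = NULL) {
  unknown <- setdiff(names(backends), KNOWN_BACKENDS)
  if (length(unknown)) {
    stop("unknown clustering backend(s): ",
         paste(unknown, collapse = ", "))
  }
  bad <- setdiff(classifiers, CLASSIFIER_NAMES)
  if (length(bad)) {
    stop("unknown classifier(s): ", paste(bad, collapse = ", "))
  }
  structure(
    list(corpus_source = corpus_source, backends = backends,
         classifiers = classifiers, preprocess = preprocess,
         min_kept_fraction = min_kept_fraction,
         select_backend = select_backend, folds = folds,
         seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

# Run one clustering backend on the prepared representations.
run_backend <- function(name, params, counts, tfidf, token_docs, seed) {
  switch(name,
    kmeans = list(
      cs = cluster_kmeans(tfidf, k = params$k %||% 12L,
                          seed = stage_seed(seed, "cluster/kmeans")),
      representation = tfidf
    ),
    lda = list(
      cs = cluster_lda(counts, k = params$k %||% 12L,
                       seed = stage_seed(seed, "cluster/lda"),
                       n_iter = params$n_iter %||% 500L),
      representation = tfidf
    ),
    gsdpmm = list(
      cs = cluster_gsdpmm(counts,
                          alpha = params$alpha %||% 1,
                          beta = params$beta %||% 0.05,
                          K_max = params$K_max %||% 50L,
                          n_iter = params$n_iter %||% 30L,
                          seed = stage_seed(seed, "cluster/gsdpmm")),
      representation = tfidf
    ),
    hdbscan = {
      red <- reduce_umap(tfidf,
                         n_components = params$n_components %||% 5L,
                         n_neighbors = params$n_neighbors %||% 15L,
                         min_dist = params$min_dist %||% 0.1,
                         seed = stage_seed(seed, "cluster/hdbscan/umap"))
      list(
        cs = cluster_hdbscan(red,
                             min_cluster_size =
                               params$min_cluster_size %||% 15L),
        representation = red
      )
    },
    doc2vec_hdbscan = {
      emb <- embed_doc2vec(token_docs,
                           dim = params$dim %||% 50L,
                           epochs = params$epochs %||% 25L,
                           seed = stage_seed(seed, "cluster/doc2vec"))
      red <- reduce_umap(emb,
                         n_components = params$n_components %||% 5L,
                         n_neighbors = params$n_neighbors %||% 15L,
                         min_dist = params$min_dist %||% 0.1,
                         seed = stage_seed(seed, "cluster/doc2vec/umap"))
      cs <- cluster_hdbscan(red,
                            min_cluster_size =
                              params$min_cluster_size %||% 15L)
      cs$method <- "doc2vec_hdbscan"
      list(cs = cs, representation = red)
    },
    stop("unknown backend: ", name)
  )
}

#' Run the full two-stage study
#'
#' Deterministic given the config's seed; intermediate artifacts are
#' persisted to `out_dir` when configured. The "best" cluster-set is
#' chosen by the configured rule: among backends keeping at least
#' `min_kept_fraction` of the documents, rank by cls accuracy
#' (descending), tie-break by relative entropy (ascending); a manual
#' override is available because the final judgement in practice also
#' weighs keyword plausibility, which cannot be automated.
#'
#' @param config A [run_config()].
#' @return A `study_result`: list with `corpus`, `scorecard`,
#'   `cluster_sets`, `selected`, `keywords_tfidf`, `keywords_svm`,
#'   `classifier_table`, `classifier_reports`, `truth` (synthetic runs
#'   only) and `seed`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed

  # --- corpus ---------------------------------------------------------------
  truth <- NULL
  if (identical(config$corpus_source$type, "synthetic")) {
    sp <- config$corpus_source$spec
    sp$seed <- stage_seed(seed, "synth")
    gen <- synth_generate(sp)
    raws <- gen$raw_reports
    truth <- gen$truth
  } else if (identical(config$corpus_source$type, "files")) {
    raws <- read_raw(config$corpus_source$path)
  } else {
    stop("corpus_source$type must be 'synthetic' or 'files'")
  }
  corpus <- segment_corpus(raws)

  # --- preprocessing --------------------------------------------------------
  dx_docs <- preprocess_corpus(corpus, "diagnosis", config$preprocess)
  counts <- vectorize(dx_docs, "count")
  tfidf <- dtm_tfidf(counts)

  # --- clustering + evaluation ---------------------------------------------
  runs <- lapply(names(config$backends), function(nm) {
    run_backend(nm, config$backends[[nm]], counts, tfidf, dx_docs, seed)
  })
  names(runs) <- names(config$backends)
  scorecard <- do.call(rbind, lapply(runs, function(r) {
    evaluate_clusterset(counts, r$cs, representation = r$representation,
                        seed = stage_seed(seed, "eval"),
                        folds = config$folds)
  }))
  rownames(scorecard) <- NULL

  # --- best cluster-set selection -------------------------------------------
  selected <- config$select_backend
  if (is.null(selected)) {
    kept_frac <- scorecard$corpus_size / length(corpus)
    eligible <- which(kept_frac >= config$min_kept_fraction &
                        scorecard$n_clusters >= 2)
    if (length(eligible) == 0) {
      stop("no eligible cluster-set: all backends rejected too many ",
           "documents or collapsed to one cluster")
    }
    ord <- eligible[order(-scorecard$cls_accuracy[eligible],
                          scorecard$rel_entropy[eligible])]
    selected <- scorecard$method[ord[1]]
    selected <- names(runs)[vapply(runs, function(r) {
      r$cs$method == scorecard$method[ord[1]]
    }, logical(1))][1]
  }
  if (!selected %in% names(runs)) {
    stop("selected backend '", selected, "' was not run")
  }
  best <- runs[[selected]]$cs

  # --- keywords -------------------------------------------------------------
  kw_tfidf <- keywords_tfidf(counts, best)
  kw_svm <- keywords_svm(tfidf, best,
                         seed = stage_seed(seed, "keywords"))

  # --- classification of descriptions ---------------------------------------
  mx_docs <- preprocess_corpus(corpus, "microscopy", config$preprocess)
  specs <- lapply(config$classifiers, function(nm) {
    classifier_spec(nm, seed = stage_seed(seed, paste0("classify/", nm)))
  })
  cmp <- compare_classifiers(mx_docs, best, specs, folds = config$folds,
                             config = config$preprocess)

  result <- structure(
    list(
      corpus = corpus,
      scorecard = scorecard[order(-scorecard$s_score), , drop = FALSE],
      cluster_sets = lapply(runs, `[[`, "cs"),
      selected = selected,
      keywords_tfidf = kw_tfidf,
      keywords_svm = kw_svm,
      classifier_table = cmp$table,
      classifier_reports = cmp$reports,
      truth = truth,
      seed = seed
    ),
    class = "study_result"
  )
  if (!is.null(config$out_dir)) persist_study(result, config$out_dir)
  result
}

#' Scorecard export in tabular form
#'
#' Columns: method, s_score, cls_accuracy, rel_entropy, n_clusters,
#' corpus_size; rows sorted by descending silhouette score.
#'
#' @param result A `study_result` (or the scorecard data frame itself).
#' @return A `data.frame`.
#' @export
scorecard_table <- function(result) {
  sc <- if (inherits(result, "study_result")) result$scorecard else result
  stopifnot(nrow(sc) >= 1)
  sc <- sc[order(-sc$s_score),
           c("method", "s_score", "cls_accuracy", "rel_entropy",
             "n_clusters", "corpus_size"), drop = FALSE]
  rownames(sc) <- NULL
  sc
}

#' Write / read the scorecard as TSV
#'
#' @param sc Scorecard `data.frame` (as from [scorecard_table()]).
#' @param path File path.
#' @export
write_scorecard <- function(sc, path) {
  out <- sc
  for (col in c("s_score", "cls_accuracy", "rel_entropy")) {
    out[[col]] <- fmt_num(out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_scorecard
#' @export
read_scorecard <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# Persist every study artifact as deterministic text files.
persist_study <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_corpus(result$corpus, file.path(dir, "corpus.jsonl"))
  write_scorecard(scorecard_table(result), file.path(dir, "scorecard.tsv"))
  for (nm in names(result$cluster_sets)) {
    write_cluster_set(result$cluster_sets[[nm]],
                      file.path(dir, paste0("clusterset_", nm, ".tsv")))
  }
  write_keywords(result$keywords_tfidf, file.path(dir, "keywords_tfidf.tsv"))
  write_keywords(result$keywords_svm, file.path(dir, "keywords_svm.tsv"))
  tab <- result$classifier_table
  tab$f1_weighted <- fmt_num(tab$f1_weighted)
  tab$f1_macro <- fmt_num(tab$f1_macro)
  tab$kappa <- fmt_num(tab$kappa)
  utils::write.table(tab, file.path(dir, "classifiers.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(study_to_json(result), file.path(dir, "study.json"),
             useBytes = TRUE)
  invisible(dir)
}

#' Deterministic JSON serialization of a study result
#'
#' Identical configurations and seeds yield byte-identical output.
#'
#' @param result A `study_result`.
#' @return A JSON string.
#' @export
study_to_json <- function(result) {
  pc <- lapply(result$classifier_reports, function(r) {
    list(method = r$method,
         f1_weighted = round(r$f1_weighted, 12),
         f1_macro = round(r$f1_macro, 12),
         kappa = round(r$kappa, 12),
         per_class = lapply(seq_len(nrow(r$per_class)), function(i) {
           list(cluster = r$per_class$cluster[i],
                f1 = round(r$per_class$f1[i], 12),
                support = r$per_class$support[i])
         }),
         confusion = apply(r$confusion, 1, as.integer, simplify = FALSE))
  })
  sc <- scorecard_table(result)
  sc$s_score <- round(sc$s_score, 12)
  sc$cls_accuracy <- round(sc$cls_accuracy, 12)
  sc$rel_entropy <- round(sc$rel_entropy, 12)
  obj <- list(
    seed = result$seed,
    selected = result$selected,
    scorecard = sc,
    labels = lapply(result$cluster_sets, function(cs) cs$labels),
    keywords_tfidf = result$keywords_tfidf[, c("cluster", "rank", "term")],
    keywords_svm = result$keywords_svm[, c("cluster", "rank", "term")],
    classifiers = pc
  )
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result>\n")
  cat("  selected backend:", x$selected, "\n")
  cat("  scorecard:\n")
  print(scorecard_table(x), digits = 3)
  cat("  classifiers:\n")
  print(x$classifier_table, digits = 3)
  invisible(x)
}
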