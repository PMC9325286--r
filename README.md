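# nephrotext

Two-stage text mining for section-tagged (nephro)pathology reports:

1. **Weak labelling by clustering.** Diagnosis sections ("Beurteilung")
   are clustered, unsupervised, into diagnostic groups with several
   backends — k-means, LDA (collapsed Gibbs), a Dirichlet-process
   multinomial mixture sampler (GSDPMM), and HDBSCAN on UMAP-reduced
   tf–idf or doc2vec representations. Each cluster-set is scored with a
   silhouette score, a *relative document entropy*, and an SVM-based
   *cls accuracy*, and summarised by per-cluster keyword tables
   (cluster-level tf–idf, and linear-SVM weight analysis).
2. **Supervised prediction.** The microscopic description sections
   ("Mikroskopie") are used to predict the diagnostic group under
   stratified ten-fold cross-validation, with bag-of-words classifiers
   (SGD-SVM, MLP, ridge logistic regression, multinomial naive Bayes)
   and small sequence classifiers (1-D CNN, bidirectional LSTM) —
   answering whether the written morphology alone carries the
   diagnosis.

The core quantities, in standard notation: the smoothed tf–idf weight
of term *w* in document *d* is
`tfidf(d, w) = tf(d, w) · (ln((1+n)/(1+df(w))) + 1)` with L2-normalized
rows; the relative document entropy of a cluster-set with clusters
`C_1..C_m` is

```
(1/m) Σ_j (1/|C_j|) Σ_{i ∈ C_j} KL( p_i ‖ q_j )
```

where `p_i` is document *i*'s term-frequency distribution and `q_j` the
pooled distribution of its cluster, both over the cluster vocabulary;
and *cls accuracy* is the cross-validated accuracy of a linear SVM
predicting the cluster labels back from the diagnosis texts.

Because clinical corpora are withheld for privacy, the package includes
a seed-reproducible synthetic report generator (`synth_spec()` /
`synth_generate()`) with planted diagnostic groups, tunable vocabulary
overlap, description–diagnosis coupling, power-law class imbalance,
author-style confounds, outliers and malformed reports — so every
pipeline stage can be validated against known ground truth.

## Worked example

```r
library(nephrotext)

spec   <- synth_spec(K = 6, sizes = c(60, 40, 30, 20, 15, 15),
                     overlap = 0.3, seed = 7)
gen    <- synth_generate(spec)
corpus <- segment_corpus(gen$raw_reports)
corpus
#> <nephro_corpus> 180 sectioned reports (0 excluded at segmentation)

docs   <- preprocess_corpus(corpus, "diagnosis")
counts <- vectorize(docs, "count")

cs <- cluster_gsdpmm(counts, seed = 1)   # infers the cluster count
cs
#> <cluster_set> method=gsdpmm: 180 docs, 6 clusters, 0 outliers

evaluate_clusterset(counts, cs, seed = 1)
#>   method s_score cls_accuracy rel_entropy n_clusters corpus_size space
#> 1 gsdpmm   0.258            1        1.12          6         180 tfidf

head(keywords_tfidf(counts, cs, top_n = 3), 3)
#>   cluster rank       term score method
#> 1       0    1 grp0_dx_01 0.657  tfidf
#> 2       0    2 grp0_dx_02 0.426  tfidf
#> 3       0    3 grp0_dx_03 0.289  tfidf

mx  <- preprocess_corpus(corpus, "microscopy")
rep <- train_predict_cv(mx, cs, classifier_spec("sgd_svm", seed = 2))
rep
#> <eval_report> sgd_svm: weighted F1 1.000, macro F1 1.000, kappa 1.000 (10 folds)

truth <- gen$truth$group[match(corpus_ids(corpus), gen$truth$id)]
adjusted_rand_index(cs$labels, truth)
#> [1] 1
```

The sampler found exactly the six planted groups (ARI = 1 against the
generator's ground truth), the cluster-level tf–idf keywords are the
planted group markers, and the description sections predict the groups
perfectly at this overlap — reading the scorecard row: a modest
silhouette (0.258; tf–idf clusters are rarely convex), perfect cls
accuracy (the clusters are linguistically separable), and a relative
entropy of 1.12 nats reflecting the 30% shared background vocabulary
inside each cluster.

A whole study — all backends, scorecard, best-backend selection,
keywords, classifier comparison, persisted artifacts — is one call:

```r
cfg <- run_config(
  corpus_source = list(type = "synthetic", spec = synth_spec()),
  out_dir = "study_out", seed = 11
)
res <- run_study(cfg)
scorecard_table(res)
```

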