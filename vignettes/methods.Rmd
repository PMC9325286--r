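---
title: "Clustering and weakly supervised classification of nephropathology reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering and weakly supervised classification of nephropathology reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Nephropathology reports are semi-structured German texts with three
sections marked by header keywords: clinical information ("Klinische
Angaben"), the microscopic description ("Mikroskopie"), and the
diagnostic conclusion ("Beurteilung"). Two questions drive the analysis
this package implements:

1. **Task (i), weak labelling.** Can the diagnosis sections be grouped
   *without supervision* into a manageable number of diagnostic groups
   (roughly 10–20), so that each report inherits a label from its
   cluster?
2. **Task (ii), prediction.** Do the microscopic descriptions carry
   enough information to predict that diagnostic group? The description
   acts as a surrogate for image analysis: if a trained pathologist's
   verbal account of the morphology predicts the diagnosis, the
   morphology itself plausibly does too.

Because clinical report corpora are typically withheld for privacy
reasons, the package ships a synthetic report generator
(`synth_spec()` / `synth_generate()`) that emulates the statistical
structure this analysis assumes, with planted ground truth. Every claim
the test suite makes is a claim about recovery of that planted truth —
see "What the synthetic corpus does and does not show" below.

## Pipeline overview

`run_study()` orchestrates the full two-stage analysis:

segment → tokenize/normalize → vectorize → cluster (several backends) →
score each cluster-set → select the best → extract per-cluster keywords
→ classify descriptions against the selected labels.

### Segmentation (`segment_corpus`)

Header tags are matched case-insensitively, anchored at line starts,
with an optional trailing colon; the first occurrence of a tag wins and
the section runs to the next tag or the end of the report. Reports
lacking a nonempty microscopy or diagnosis section are *excluded*, not
errors: exclusion is an expected outcome for malformed archive exports,
and the count is carried in the corpus object. Multiple occurrences of
a tag are not disambiguated further than first-wins; that choice is
ours, made for determinism.

### Preprocessing (`preprocess_config`, `preprocess_text`)

The token pipeline is fixed in this order: lowercase → punctuation
strip → whitespace tokenization → number removal → stop words →
lemmatization → multi-word-expression merge. Re-running the pipeline on
its own output is a no-op, which makes cached token documents safe.

Three choices matter scientifically:

* **Negations are kept.** "keine Nekrose" (no necrosis) and "Nekrose"
  must not collapse to the same bag of words, so German negations are
  removed from the stop list programmatically
  (`stopword_removals`), and the abbreviation "ca" (approx.) is added.
* **Number removal is conservative.** Digit-only and digit-punctuation
  tokens (dates, percentages, case numbers) are dropped, but
  alphanumeric grading codes such as `m1`, `e0`, `t0` are kept — they
  are diagnostic vocabulary (Oxford classification of IgA nephropathy).
* **Lemmatization is pluggable.** The default is the identity, so the
  pipeline is language-neutral and fully testable; a German lemmatizer
  can be passed as a vectorized term→term function, and a custom
  replacement table is applied after it.

tf–idf uses the smoothed variant `idf = ln((1 + n)/(1 + df)) + 1` with
per-document L2 normalization. The smoothing keeps idf strictly
positive for ubiquitous terms and defined for unseen ones; the variant
is stated here because "tf–idf" alone underdetermines the numbers.

### Clustering backends (`cluster_*`)

* `cluster_kmeans` — `stats::kmeans` on tf–idf rows, 30 restarts.
* `cluster_lda` — collapsed Gibbs sampling for latent Dirichlet
  allocation (compiled sampler), document label = argmax topic.
  Defaults are tuned for *clustering* rather than topic browsing: a
  sparse document–topic prior (`alpha = 0.05`) concentrates each
  document on one topic, 8 independent chains are run and the final
  state with the highest collapsed log-likelihood wins. Gibbs chains
  for topic models are multimodal (two planted groups can stay merged
  while a topic sits empty); chain selection by likelihood plays the
  same role restarts play for k-means.
* `cluster_gsdpmm` — a collapsed Gibbs sampler for the
  Dirichlet-process multinomial mixture, which infers the cluster count
  itself. Larger `beta` (vocabulary smoothing) gives fewer, coarser
  clusters; the default 0.05 sits in the range known to work for
  short-text clustering. Three chains, best collapsed posterior wins.
* `cluster_hdbscan` — hierarchical density-based clustering on a
  UMAP-reduced space, the only backend that rejects outliers
  (label −1). Outliers are excluded from every downstream metric and
  from classifier training.
* `embed_doc2vec` — PV-DBOW paragraph vectors as the
  distributed-representation path; `doc2vec → UMAP → HDBSCAN` stands in
  for semantic-similarity clustering of documents. Externally computed
  embedding matrices can be ingested with `external_embedding()`.

UMAP and HDBSCAN are implemented in-package (no R implementation is
available in this stack): UMAP as fuzzy k-NN graph → spectral
initialization → compiled stochastic-gradient layout; HDBSCAN as
mutual-reachability minimum spanning tree → condensed tree →
excess-of-mass cluster selection. Both are exact-neighbour
implementations intended for corpus scale (up to a few thousand
documents), not for millions of points. Defaults: `d' = 5` components
before clustering, `d' = 2` for plotting, `n_neighbors = 15`,
`min_dist = 0.1`.

`select_k_elbow` picks k by the maximum distance between the inertia
curve and its endpoint chord (ties to the smaller k; a flat curve
returns the smallest k with a warning). `check_cluster_bounds` warns —
never errors — when a cluster-set leaves the intended 10–20 band,
since some backends legitimately land outside it.

### Cluster-set evaluation (`evaluate_clusterset`)

Three complementary metrics per cluster-set:

* **Silhouette score** (`cluster::silhouette`, Euclidean), computed on
  the representation the clusterer actually consumed — tf–idf for
  bag-of-words backends, the reduced embedding for density-based paths.
  Which space was used is recorded in the scorecard row, because the
  choice changes the number and is otherwise invisible.
* **Relative document entropy**: for each kept document, the KL
  divergence (natural log) between its term distribution and its
  cluster's pooled term distribution, averaged within clusters, then
  averaged over clusters with equal weight. Both distributions are
  normalized over the *cluster vocabulary* (terms with nonzero pooled
  count); since the pool contains the document, the divergence is
  always finite without smoothing. Zero means perfectly homogeneous
  clusters; singleton clusters contribute zero by construction.
* **cls accuracy**: the cross-validated accuracy of a linear SVM
  predicting the cluster labels from the diagnosis texts themselves. A
  cluster-set that looks compact but is not linguistically separable
  scores low. Cross-validation is used because in-sample accuracy
  would be optimistically biased.

`author_confound` reports the cluster × author contingency table and
Cramér's V, to flag cluster-sets that group reports by the authors'
writing styles rather than by diagnosis.

### Keywords (`keywords_tfidf`, `keywords_svm`)

The tf–idf method pools each cluster into one pseudo-document and
recomputes tf–idf *across pseudo-documents*, so idf contrasts clusters.
The SVM method fits a one-vs-rest linear SVM on the kept documents,
keeps only the correctly predicted ones, re-fits, and reports the
top-10 features by positive weight per cluster. Re-fitting on the
correctly predicted subset is one of two defensible readings of
"restricted to correctly predicted documents" (the other being
per-document explanation aggregation); it was chosen for simplicity
and is stated here because the lists differ slightly between readings.
Ties everywhere break lexicographically, for reproducibility.
`attach_naming` joins human annotations (name + strong/weak strength);
unnamed clusters are expected and allowed.

### Classification (`train_predict_cv`, `compare_classifiers`)

Stratified 10-fold cross-validation; out-of-fold predictions are pooled
and all metrics — macro and weighted F1, Cohen's kappa, per-class F1
with support, the confusion matrix — are computed once on the pooled
set. Pooling makes kappa and the confusion matrix single well-defined
objects; per-fold averaging would leave the confusion matrix ambiguous.
Both F1 averages are reported because "the F1-score" of a multiclass
comparison underdetermines the averaging. Classes smaller than the fold
count trigger a documented fold-count reduction with a warning; classes
of size 1 are a validation error naming the class.

Bag-of-words classifiers (`sgd_svm`, `mlp`, `logreg`,
`multinomial_nb`) consume tf–idf of the description tokens, with idf
fitted on each training fold only (the vocabulary itself is shared —
standard transductive bag-of-words). The SGD-SVM is a mini-batch
subgradient linear SVM with step size `1/(λ(t0+t))`, `t0 = 1/λ`; the
classical `1/(λt)` schedule takes steps of size `1/λ` early on and
does not converge in realistic iteration budgets. The MLP is one
hidden ReLU layer trained with Adam. Logistic regression goes through
`glmnet` (ridge, multinomial). Multinomial naive Bayes uses Laplace
smoothing and accepts fractional tf–idf "counts", as is conventional.

The sequence classifiers (`cnn_embed`, `rnn_embed`) consume padded
token-id sequences capped at the 95th-percentile document length, with
embeddings trained jointly by backpropagation: the CNN is a 1-D
convolution with 32 kernels of width 3 (ReLU) → max pooling over time →
a ReLU dense layer → softmax; the RNN is a bidirectional LSTM whose
final states feed a softmax head. Documents that are empty after
preprocessing are dropped from training with a warning. These are
small, exactly specified networks for desk-scale corpora, not
general-purpose deep-learning machinery.

`support_vs_f1` computes the Spearman correlation between per-class
support and per-class F1 — the quantitative form of "rarer diagnoses
are harder to predict".

### Study orchestration (`run_study`)

All randomness derives from one global seed via
`stage_seed(seed, stage_name)` (a Lehmer-style hash), so no two stages
share a random stream and the whole study is byte-reproducible: two
runs with the same config serialize to identical JSON
(`study_to_json`). The "best" cluster-set rule is explicit and
configurable: among backends keeping at least 65% of documents
(heavy outlier rejection shrinks the labelled corpus too much), rank by
cls accuracy, tie-break by relative entropy. A manual override
(`select_backend`) exists because in practice the final judgement also
weighs keyword plausibility, which resists automation.

## The synthetic corpus

`synth_generate()` draws, per report: a diagnostic group (explicit
sizes, or a power-law profile with exponent 1.5 and a floor of 8
documents — a long-tailed case mix, at desk scale, like real diagnosis
frequencies); diagnosis-section tokens from a mixture
`(1 − overlap) · group-markers + overlap · shared background` with
Zipf-shaped within-group weights; description-section tokens likewise,
from the same group with probability `coupling`, else from a random
group; author function words spliced in at a 10% rate, with authors
tied to groups by `author_cluster_bias`; a fraction of outlier reports
drawn from background only; and a fraction of malformed reports that
drop a required section tag. `synth_audit()` checks the generated
marker frequencies against the generating distribution (chi-square,
conditioning on marker terms, which the background never emits) and the
malformed/outlier counts against binomial 99% bounds.

**What passing tests show, and what they do not.** The generator plants
group-exclusive marker vocabularies; real diagnosis sections share
vocabulary heavily, grade findings on continuous scales, and encode
diagnoses in word *combinations* rather than single markers. Recovery
of planted truth therefore validates the machinery — segmentation,
vectorization, the samplers, the metrics, the cross-validation
bookkeeping — not the claim that real reports cluster this cleanly. On
real corpora the interesting regime is precisely the one the overlap
and coupling dials emulate: partial separability and imperfect
description–diagnosis coupling.

## Problem sizes and experimental conditions

The recovery experiments run at K = 12 groups × 50 documents
(n = 600), vocabulary 2000, the desk-scale default. Balanced sizes are
used for the exact-recovery experiments deliberately: under a strong
power-law mix, k-means provably prefers splitting the large head group
over separating 8-document tail groups (the inertia gain from the head
exceeds the orthogonality penalty of merging two tiny groups), so
exact recovery is not a property any inertia-based method can have
there. Imbalance is studied where it is the point: the
support-difficulty experiment uses power-law sizes at overlap 0.7 and
coupling 0.8 over 10 seeds, where small classes visibly lose F1 and
the Spearman correlation between support and F1 is positive.

## Numerical choices and degenerate inputs

* KL divergences use natural log; silhouette uses Euclidean distance.
* Keyword and label ties break lexicographically / to the lowest index.
* `k = n` in k-means returns the exact one-document-per-cluster
  solution directly.
* Empty documents vectorize to zero rows (allowed); an empty vocabulary
  is an error.
* HDBSCAN merge heights of zero (duplicate points) are capped before
  inversion to keep condensed-tree stabilities finite.
* The UMAP spectral initializer falls back to zero-padding when the
  neighbourhood graph has fewer nontrivial eigenvectors than requested
  components, and adds seeded noise of s.d. 1e-4 to break symmetry.

## Known limitations

* Transformer-based embeddings and fine-tuning are out of scope; the
  package ingests externally computed embedding matrices instead.
* The neighbour search in UMAP/HDBSCAN is exact (O(n²) memory in the
  distance matrix): fine for thousands of documents, wrong tool for
  millions.
* The German lemmatizer is an interface, not an implementation; with
  the identity default, morphological variants remain distinct terms.
* Cluster naming is a human step; the package only joins annotations.
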