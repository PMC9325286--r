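Package: nephrotext
Title: Clustering and Weakly Supervised Classification of Nephropathology Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A two-stage text-mining pipeline for section-tagged pathology
    reports. Reports are split into clinical, microscopic-description and
    diagnosis sections; diagnosis sections are clustered into diagnostic
    groups with several backends (k-means, latent Dirichlet allocation,
    a collapsed Gibbs sampler for the Dirichlet-process multinomial
    mixture, and density-based clustering on manifold-reduced tf-idf or
    document-embedding representations); cluster-sets are scored with
    silhouette, relative document entropy and an SVM-based classification
    accuracy, and summarised with keyword tables; finally the diagnostic
    group is predicted from the microscopic description with bag-of-words
    and small neural classifiers under stratified cross-validation. A
    seed-reproducible synthetic report generator with planted groups,
    class imbalance, author styles, outliers and malformed reports
    provides ground truth for every stage.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    cluster,
    glmnet,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
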