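Package: psypatterns
Title: Preoperative Psychological Distress Patterns and Surgical Outcome
    Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Identifies latent preoperative psychological distress patterns
    from item-level PHQ-9 and GAD-7 questionnaire responses using a two-stage
    nonlinear-embedding and density-clustering pipeline (UMAP followed by
    HDBSCAN) with symptom-cluster reweighting, noise handling and
    small-cluster merging; quantifies pattern transfer to independent
    cohorts; and estimates covariate-adjusted logistic and linear associations
    between patterns and short- and long-term surgery-related outcomes.
    Includes a calibrated synthetic-cohort generator so the whole pipeline is
    testable without access to patient data, plus cluster-validity metrics
    (silhouette, Dunn's index), K-means and hierarchical baselines, and
    hyperparameter grid search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    MASS,
    Matrix,
    mclust,
    purrr,
    readr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
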