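Package: ehrclust
Title: Embedding-Based Clustering of Standardized EHR Text for Acute
    Kidney Injury Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Converts standardized electronic-health-record code strings
    (';'-separated diagnosis and operation codes) into predictive features
    via text embeddings and spherical k-means soft clustering. Provides
    Bag-of-Terms and deterministic hash embedders behind a pluggable
    embedder contract, spherical k-means with cosine distance and
    multi-restart selection, partition-comparison metrics (adjusted Rand
    index, adjusted mutual information, greedy cluster alignment), KDIGO
    acute kidney injury staging from creatinine ratios and urine-output
    series, repeated cross-validated benchmarking of baseline, expert and
    embedding-based classifiers with threshold-averaged metrics and paired
    tests, weighted-probability ensembles, and explainability utilities
    (cluster-labelling prompts, label alignment across runs, Kendall rank
    correlations of cluster membership with outcomes). A synthetic cohort
    generator with known latent cluster structure supports end-to-end
    recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    randomForest,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
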