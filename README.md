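# ehrclust

Turning standardized EHR text into predictive, explainable features for
postoperative acute kidney injury (AKI).

Pediatric cardiopulmonary-bypass (CPB) records carry two text fields per
operation — diagnoses and procedures — each an ordered, `';'`-separated list
of standardized medical codes with the first code primary. `ehrclust`
converts these fields into features for predicting severe postoperative AKI,
benchmarks them against structured baselines and expert groupings, and maps
the resulting clusters back to natural language. It is aimed at clinical
data scientists evaluating text-embedding pipelines on cohort data, and it
ships a synthetic cohort generator with known ground truth so that every
stage can be validated offline.

## What it computes

**Embeddings.** A Bag-of-Terms (BoT) encoder (one binary indicator per
vocabulary code) and a deterministic hash embedder (each code maps to a
seeded random unit direction; a text embeds as the normalized sum of its
codes' vectors) are built in. Doc2Vec and external LLM embedders plug in
behind the same contract via `register_embedder()`.

**Spherical k-means.** Clustering under the cosine distance

&nbsp;&nbsp;&nbsp;&nbsp;*D*<sub>C</sub>(**x**, **y**) = 1 − **x**·**y** ⁄ (‖**x**‖‖**y**‖),

with centroids re-normalized to unit length each update, multi-restart
selection by total within-cluster distance, and soft membership (the vector
of distances from a record to all k centres) as the feature representation.
`spherical_kmeans()` returns a classed fit with `print`, `predict`
(soft/hard/assignment) and `fitted` methods. On unit-norm data its
assignments coincide with standard k-means; BoT vectors are clustered in
Euclidean mode because their L1 norm (code count) is informative.

**AKI outcomes.** Five outcomes per operation: the postoperative-to-baseline
creatinine ratio, hours of urine output below 0.5 and 0.3 ml/kg/h in the
48-hour window, the KDIGO ordinal stage 0–3 (maximum of the creatinine and
urine pathways), and the severe-AKI indicator (stage ≥ 2).

**Benchmarking.** Repeated k-fold cross-validation with identical folds
across model variants (baseline covariates; baseline + expert one-hot
clusters; baseline + embedding soft memberships; weighted-average
ensembles), threshold-averaged classification metrics (cutoffs 0.1–0.9),
paired fold-level t-tests, ARI/AMI consistency against expert partitions,
run-to-run stability over all run pairs, and greedy cluster alignment by
member overlap.

**Explainability.** Cluster-labeling prompts listing every member's texts by
group, a structured-output label parser, a deterministic lift-based stub
labeler, label alignment across clustering runs, blind partition-comparison
prompts, and Kendall tau-b correlations of cluster membership with each
outcome under Bonferroni correction.

## Worked example

```r
library(ehrclust)

cfg <- sim_config(n_patients = 780, n_latent_clusters = 10,
                  outcome_effects = c(1.5, rep(0, 9)), seed = 42)
synth <- generate_synthetic_cohort(cfg)
outcomes <- compute_aki_outcomes(synth$cohort)
cohort <- synth$cohort
cohort$kdigo_binary <- outcomes$kdigo_binary
mean(cohort$kdigo_binary)
#> severe-AKI prevalence: 0.233

emb <- concat_embeddings(hash_embed(cohort$diagnosis, 1024, seed = 1),
                         hash_embed(cohort$operation, 1024, seed = 2))
fit <- spherical_kmeans(emb, k = 10, n_init = 20, seed = 3)
fit
#> Spherical k-means fit (mode: spherical)
#>   k = 10, n = 780, d = 2048
#>   total within-cluster distance: 515.06
#>   restarts: 20
#>   cluster sizes: 86, 66, 72, 81, 77, 77, 78, 86, 79, 78
adjusted_rand_index(fit$assignment, synth$true_cluster)
#> 0.98
```

The fit recovers the generator's latent clusters almost perfectly (ARI
0.98). Adding its soft memberships to the baseline covariates lifts
cross-validated discrimination:

```r
variants <- list(
  cv_variant("baseline", "baseline"),
  cv_variant("expert", "expert"),
  cv_variant("ai_hash", "ai",
             embedder = embedder_spec("hash", dimension = 1024,
                                      hyperparameters = list(seed = 1)),
             k = 10, n_init = 20))
report <- run_repeated_cv(cohort, variants,
                          cv_config(repeats = 5, folds = 10, master_seed = 7))
summary(report)
#>     model roc_auc accuracy precision    f1 sensitivity specificity
#>    expert   0.623    0.681     0.267 0.181       0.254       0.812
#>   ai_hash   0.611    0.674     0.210 0.153       0.238       0.807
#>  baseline   0.545    0.664     0.175 0.124       0.219       0.800
paired_fold_ttest(report, "ai_hash", "baseline", alternative = "greater")
#> AUC gain ai_hash - baseline: 0.066   one-sided p: 2.5e-10
```

Threshold-averaged precision/F1/sensitivity run low by construction: they
average over the full 0.1–0.9 cutoff grid, most of which is far from the
optimum for a 23% positive rate. Finally, the planted high-risk cluster is
the one whose membership correlates with the KDIGO outcomes:

```r
outcome_cluster_correlation(synth$true_cluster, outcomes[-1],
                            operation_time = cohort$optime_min)
#> <correlation_table> 50 tests (Bonferroni threshold 0.001)
#>        outcome cluster   tau        p
#>  kdigo_ordinal       1 0.144 1.72e-05
#>   kdigo_binary       1 0.190 1.18e-07
```

A command-line wrapper for the CV benchmark lives at
`inst/cli/cv-benchmark.R`:

```sh
Rscript inst/cli/cv-benchmark.R --cohort mycohort \
    --variants baseline,expert,ai:hash:1024 --repeats 20 --folds 10 \
    --seed 1 --out cv-out/
```

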