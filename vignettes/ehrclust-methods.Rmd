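---
title: "Methods: embedding-based clustering of standardized EHR text for AKI prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: embedding-based clustering of standardized EHR text for AKI prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehrclust)
```

## The modelling problem

Each operation record in a pediatric cardiopulmonary-bypass (CPB) cohort
carries two standardized text fields — diagnoses and procedures — written as
`';'`-separated lists of codes with the first code primary, alongside
structured covariates (gender, age, height, weight, operation length) and
postoperative measurements (serum creatinine, hourly urine output). The
package's pipeline is:

1. encode each text field as a numeric vector (Bag-of-Terms or a dense
   embedder);
2. cluster the vectors with spherical k-means;
3. use each record's *soft membership* — its vector of distances to the k
   cluster centres — as k features per field in a binary classifier of
   severe acute kidney injury (AKI), alongside the structured baseline;
4. compare baseline, expert-cluster and embedding-cluster models under
   repeated cross-validation with shared folds;
5. explain the clusters: natural-language labels via prompts over member
   texts, and Kendall correlations of membership with the five AKI
   outcomes.

## Spherical k-means

The core fit is k-means under the cosine distance
$D_C(x, y) = 1 - x^\top y / (\lVert x\rVert\,\lVert y\rVert)$, which
depends only on the angle between vectors and so suits L2-normalized text
embeddings. Assumptions and conventions:

* **Input contract.** Spherical mode requires rows of unit L2 norm and
  refuses anything else; embedders must set the `normalized` flag
  truthfully, and the flag is verified at construction (tolerance 1e-9).
  Bag-of-Terms vectors are *not* normalized — their L1 norm is the number
  of codes, which is clinically informative — so they are clustered in
  Euclidean mode (squared L2). On unit-norm data the two modes give
  identical assignments and differ only in the centroid update; this is
  property-tested.
* **Centroid update.** Member mean, re-normalized to unit length in
  spherical mode (the classical choice; the update minimizes total cosine
  distance for a fixed partition, which also gives the closed form
  $\sum_c (n_c - \lVert s_c \rVert)$ used by the exhaustive test oracle).
* **Initialization and restarts.** Each restart seeds centroids at k
  distinct records drawn uniformly; restart seeds derive from the master
  seed by a counter, so a fixed `(X, k, n_init, seed)` reproduces the fit
  bit for bit. The restart with the smallest total within-cluster distance
  wins. Consistency benchmarking defaults to 10 runs of 10 restarts;
  predictive and stability settings use 100 restarts.
* **Ties and degeneracies.** Equal distances assign to the lowest cluster
  index. An emptied cluster is re-seeded at the point farthest from its
  centroid (k is fixed upstream, so dropping clusters is not an option); a
  guard keeps this from cycling when duplicated rows make an empty cluster
  unfillable. Convergence is declared when assignments stop changing, with
  a 300-iteration cap. In `debug` mode the objective is asserted
  non-increasing across iterations.
* **Soft membership** uses the fit's own metric (cosine in spherical mode).
  The metric for membership extraction is not separately specified
  anywhere authoritative; using the clustering metric keeps training
  assignments equal to the arg-min of the soft vector, and the Euclidean
  alternative remains available through the mode switch.

k is always fixed by the caller: 10 for predictive features, or matched to
the expert partition's group count for consistency scoring (removing k as a
confounder of ARI/AMI). No elbow/silhouette selection is provided.

## Partition metrics

ARI and AMI are owned implementations (they carry the package's central
claims) with installed references as test oracles. AMI uses the
permutation-model expected mutual information and **max** normalization,
$\mathrm{AMI} = (\mathrm{MI} - E[\mathrm{MI}]) / (\max(H_a, H_b) -
E[\mathrm{MI}])$; AMI has several variants, so the choice is stated
explicitly and the oracle comparison requests the same variant. All
internal summations accumulate in sorted order so both metrics are exactly
symmetric in their arguments (floating-point addition is order-sensitive;
the term multisets are not).

Greedy cluster alignment repeatedly matches the pair of clusters sharing
the most members, ties broken to the lowest (first-partition id,
second-partition id). Greedy matching is not optimal; the tests pin a
constructed counterexample (overlap 5/13 against an optimal 8/13) so the
gap is documented rather than hidden.

Kendall correlations use tau-b, which handles the heavy ties of binary
membership indicators, with an O(n log n) rank formulation on the binary
path and the tie-corrected normal approximation for p-values. Bonferroni
correction uses exactly m = outcomes × clusters tests (50 at the defaults:
5 outcomes × 10 clusters).

## KDIGO staging

The ordinal stage is the maximum of a creatinine pathway and a urine
pathway, encoded in the single editable constant `kdigo_cutoffs`:

| stage | creatinine ratio | urine < 0.5 ml/kg/h | urine < 0.3 ml/kg/h |
|------:|------------------|---------------------|---------------------|
| 1 | [1.5, 2.0) | > 6 h and < 12 h | — |
| 2 | [2.0, 3.0) | ≥ 12 h | — |
| 3 | ≥ 3.0 | — | ≥ 24 h |

Boundary conventions: the stage-1 ratio band "1.5–1.9" is read as
[1.5, 2.0) so that it abuts the stage-2 lower bound with no gap at 1.95;
the stage-1 urine rule "more than 6 but less than 12 hours" is the open
interval (6, 12), with 12 h itself already stage 2. Hour counts use a
strict `< threshold` comparison on a 48-value hourly grid (irregular
sampling is out of scope). The anuria-based stage-3 criterion is
deliberately not encoded. Severe AKI is stage ≥ 2; stage-1 cases are
mostly mild with full recovery, so the binary target isolates the
clinically relevant events.

## The synthetic cohort generator

No deposited cohort exists, so the generator is the package's ground-truth
instrument. It emulates:

* **Latent cluster structure.** Each record draws a latent cluster
  (uniform over k, default 10); each cluster owns a private slice of the
  code vocabulary (defaults 282 diagnosis and 179 operation codes,
  matching the scale of a real standardized-code system). With probability
  `cluster_separation` (default 0.9) a code comes from the private slice,
  otherwise uniformly from the whole vocabulary — so separation tunes the
  recoverable signal continuously from none (0) to code-disjoint clusters
  (1), and recovery ARI is property-tested to increase along
  {0.3, 0.6, 0.9}.
* **Correlated but distinct fields.** One latent cluster drives *both*
  fields, but each field refines it into two subclusters (draws biased
  toward the subcluster's half of the private slice with probability
  `field_substructure_bias` = 0.8, chosen once so that the field-matched
  consistency reliably exceeds crossed-field consistency while crossed
  consistency stays clearly positive). Expert labels are the field-specific
  true groups with 15% flip noise — imperfect expert groupings that still
  agree across fields through the shared parent, reproducing the
  diagonal-dominance pattern of matched vs crossed comparisons.
* **Covariates.** Ages log-uniform over 0.1–188.3 months; heights from a
  saturating growth curve with 7% multiplicative noise (so LOESS residuals
  have a standard deviation near 0.07); BMI draws give weights; operation
  times log-normal around a median of 86 minutes with location increasing
  in the cluster index, linking longer bypass times to higher-numbered
  clusters.
* **Outcomes.** Severe-AKI status follows
  $\mathrm{logit}\,P = c + \beta_{\mathrm{cluster}} +
  0.004 \cdot \mathrm{optime}$, with c calibrated by root finding so the
  analytic prevalence matches the 26% target (empirically verified within
  3 percentage points at n = 5000). Each record then receives a KDIGO
  stage (severe rows 2:3 in proportion 121:78, others 0:1 in proportion
  315:266, the staged mix of a realistic cohort) and measurements
  consistent with that stage: a creatinine ratio drawn inside the stage's
  band, and a 48-hour urine series from a gamma model (shape 60 over the
  low-output block, shape 30 elsewhere; the normal-hour mean is mildly
  depressed for high-risk rows so severity is graded rather than
  discontinuous). Urine-hour targets carry margins (e.g. stage-2 targets of
  14–22 h against the 12 h cutoff) so gamma noise rarely crosses a staging
  boundary; the tests tolerate the residual ~2% stage slippage.

What the generator does **not** emulate: real medical-code semantics or
co-occurrence grammar, code-order information beyond the primary position,
expert-grouping logic (labels are noisy relabelings, not clinical rules),
missing data, repeat operations on one patient, or irregular urine
sampling. Tests passing on this generator therefore validate the machinery
— recovery, calibration, protocol arithmetic, determinism — not clinical
performance on real cohorts.

## Embedders

The hash embedder is the offline dense embedder: each code maps through a
seeded 31-ary rolling hash to a fixed random unit direction, and a text
embeds as the normalized sum over its codes. Cluster signal in code usage
thus propagates into embedding geometry with inter-cluster noise of order
$1/\sqrt{d}$; the default experiments use d = 1024, where recovery of
planted clusters from concatenated two-field embeddings is near-perfect
(ARI > 0.9 at separation 0.9), while single-field recovery is much weaker —
concatenation is the recommended clustering input and the concatenated
vector is re-normalized (whether to re-normalize is genuinely open; doing
so keeps the spherical contract). As a bag-of-codes model the hash embedder
deliberately ignores order, a documented limitation relative to contextual
language models. Texts parsing to no codes map to a fixed null unit vector
and are flagged rather than dropped, so row alignment survives.

Doc2Vec and external LLM embedders are adapter kinds: the spec objects
validate the full hyperparameter grid (dbow/dm, epochs 10/100/1000,
dimension 40/400/4000), but invoking them without a registered adapter
raises a capability error. The fine-tuning pair builder emits the
(diagnosis, operation) contrastive pairs an adapter would train on; the
training loop itself is out of scope.

## Cross-validation design

* **Folds** are plain (unstratified) repeated k-fold splits from a fixed
  master seed, identical across all model variants, which is what makes
  the paired fold-level t-tests valid. Stratification is available but off
  by default.
* **Scope.** By default embeddings are clustered once on the full cohort
  before cross-validation (`scope = "global"`), matching the benchmarked
  single-pre-CV-cluster protocol; a warning flags that test rows influence
  cluster geometry. `scope = "fold"` refits vocabulary, embeddings,
  clustering and the height smooth on each training fold and projects test
  rows, for leakage-free estimation.
* **Decision rule.** A record is called positive when its probability is
  ≥ the threshold; metrics average over thresholds 0.1–0.9 in steps of
  0.1. A cutoff with no predicted positives contributes precision 0 (and
  F1 0 when precision + sensitivity is 0), and the count of such cutoffs
  is reported — this convention is why averaged precision/F1 look low
  relative to single-best-threshold values.
* **Degenerate folds.** A single-class training fold predicts the constant
  class rate and is flagged, rather than failing the run.
* **Per-field averaging and ensembles.** Expert and embedding variants fit
  one submodel per text field and average the two probability vectors;
  ensembles are weighted probability averages (AI ensemble 2:1; adding the
  expert model at one tenth of the lead weight, i.e. 2:1:0.2).
* **Classifier.** Logistic regression via `glm.fit` is the default (which
  classifier produced the benchmark's headline numbers is not stated
  anywhere authoritative; logistic is the simplest member of the stated
  family); random forest is available behind the same contract. Collinear
  columns drop out with coefficient 0.
* **Residual height** replaces raw height: per-gender LOESS of height on
  age (span 0.75, degree 1, direct surface so held-out ages extrapolate),
  returning percent deviation from the smooth. At least 30 rows per gender
  are required.

## Explainability conventions

Label prompts state the cohort size, field descriptions, group count and
the labeling request, then list every member line under its `Group N:`
heading with field-name prefixes joined by `" || "`; output is
byte-deterministic and an optional per-cluster member cap elides with
`...`. Responses must be JSON arrays of
`{group_number, short_label, long_label}` — a minimal structured-output
schema — with exactly one label per cluster. The deterministic stub labeler
names each cluster by its three highest-lift codes, which doubles as a
useful fallback on standardized-code data. Labels from repeated clustering
runs align onto the first run via the greedy mapping. The partition
comparison prompt is blind by default: nothing reveals which partition is
machine-made.

The correlation figure convention orders clusters by decreasing mean
operation time, making the link between bypass duration and AKI risk
visible; confidence statements use the tau-b normal approximation
(documented as an approximation) and Bonferroni-adjusted thresholds.

## Problem sizes in the test suite

The suite exercises: exhaustive-search oracle comparisons at n ≤ 10, k ≤ 3
over 100 random instances (a ≥ 95% match rate is asserted — Lloyd restarts
can rarely settle in a local optimum, which is the documented tolerance);
metric oracle agreement on 20 random fixtures each; null calibrations over
50–200 draws; recovery and cross-validated planted-signal experiments at
n = 500–1000 with 3–20 repeats of 10-fold CV; and prevalence calibration at
n = 5000. These sizes were chosen to make every stochastic assertion
comfortably stable under its fixed seed while keeping the default test run
in the low minutes.

## Known limitations

* The hash embedder cannot represent semantics shared across distinct
  codes; consistency values on synthetic data are meaningful only
  relative to each other, not as estimates of real-cohort consistency.
* Global-scope cross-validation reuses clusters fitted on all rows; its
  absolute metrics are optimistic relative to fold scope.
* Greedy cluster alignment is suboptimal on adversarial overlap tables.
* The tau-b p-values are asymptotic; at very small n an exact permutation
  test would be preferable.
* KDIGO staging omits the anuria criterion and assumes a complete hourly
  urine grid.
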