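---
title: "Predicting TNT contamination from microbial community fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting TNT contamination from microbial community fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tntfinger)
```

## The problem

Sediment microbial communities integrate the chemical history of their
habitat. Around munition dumpsites, the explosive
2,4,6-trinitrotoluene (TNT) leaks from corroding casings at
picomole-per-gram levels, is rapidly transformed or dispersed, and is
therefore hard to quantify chemically at any one point in time. The idea
behind this package is to treat the community itself as the sensor: if some
taxa respond to TNT exposure, their joint abundance pattern — a *microbial
fingerprint* — can classify a sediment as TNT-contaminated even when the
compound's concentration hovers near the detection limit, or, in the case
of historical contamination, is no longer detectable at all.

The package implements that analysis end to end for 16S rRNA gene amplicon
count tables with accompanying taxonomy and sample metadata: sample
curation, compositional feature engineering, random-forest classification
with repeated-holdout evaluation, fingerprint extraction via importance
statistics with p-values, proximity-based ordination, and robustness
checks, with a fully seeded synthetic-data generator so every stage is
testable without any external data.

## Curation of small, spatially clustered sample sets

Field campaigns produce technical replicates and tight spatial clusters.
Two curation steps precede any model:

* **Replicate averaging** (`average_replicates()`): each sequencing
  library is converted to relative abundance (percent) first, then
  libraries of the same sediment are averaged arithmetically. Averaging on
  proportions rather than raw counts stops deeply sequenced libraries from
  dominating the mean; output rows sum to 100%.
* **Exclusion guideline** (`apply_exclusion_guideline()`): a subset of
  samples is flagged when all of the following hold — same cruise, same
  experiment, same area, all pairwise distances below 20 m (haversine on a
  6,371 km sphere; sub-meter geodesy is irrelevant at this threshold), and
  a single response class or a strongly imbalanced pair (minority count
  ≤ 1 by default). Such subsets would let a classifier learn the sampling
  context instead of the contamination, so all but one representative
  (lowest sample id, deterministic) are removed. The rule is idempotent.

The response is binarized by `binarize_response()`: `absent` strictly
below the detection limit of 0.01 ng·g⁻¹ ≙ 0.044 pmol·g⁻¹ wet sediment
(`ng_per_g_to_pmol_per_g(0.01, 227.13)`), `present` otherwise; a
concentration exactly at the limit is `present`.

## Feature engineering

Counts become relative abundances (`to_relative_abundance()`); a feature
is kept when it exceeds an abundance threshold in at least one sample
(strictly; `filter_by_threshold()`, default grid
`r paste(default_thresholds(), collapse = ", ")`%); filtered ASV
abundances are then accumulated to a broader taxonomic rank
(`agglomerate_rank()`). The order matters — thresholding happens at ASV
rank *before* agglomeration, and a test pins that order. Features
unannotated at the target rank are reported as
`unclassified <deepest annotated parent>`. Features abundant in negative
controls (strictly more than 35 reads in any control) are removed unless
explicitly exempted (`remove_control_features()`). Community and
environmental tables over the same samples concatenate via
`combine_features()` with per-feature origin tags.

The random forests consume raw relative abundances; z-scoring and one-hot
encoding (`encode_and_scale()`, population standard deviation, recorded in
the matrix's scaling state) are required only by the neural-network
validator, whose input contract refuses unscaled matrices.

## Forests, the mtry factor, and evaluation

Classification forests (via the ranger backend; Gini impurity, unlimited
depth, minimum node size 1) are controlled by two hyperparameters: the
number of trees and the **mtry factor** — the floor-square-root default
for candidate variables per split, multiplied by an integer and capped at
the feature count (`derive_mtry()`; 542 features at factor 5 give 115).
Sparse abundance tables profit from factors above 1 because a square-root
sample of mostly-zero columns rarely contains an informative one.

Evaluation follows a repeated-holdout protocol (`make_splits()`): by
default six pseudo-random 75/25 splits — the training size is rounded
half-down, so 150 samples give 112 train / 38 holdout — without
stratification, reproducible from a seed. Grid search
(`grid_search()`) trains `models_per_combo` forests per combination and
split on the training set only and scores them by **out-of-bag balanced
accuracy** (mean of sensitivity and specificity, `balanced_accuracy()`),
so no holdout sample influences feature filtering or model selection;
`evaluate_holdout()` then refuses any split whose training and holdout
sets overlap. Score distributions between input sets are compared with
Welch's unequal-variance one-way ANOVA plus Tukey's multiple comparisons
at 95% family-wise confidence (`compare_input_sets()`, adjusted p < 0.005
flags significance). Averaging validation scores across splits to pick
hyperparameters leaks a little information across splits; the holdout
scores are the honest final estimate.

## Importance statistics and the fingerprint

Two schemes produce per-feature importance scores with p-values:

* **Corrected impurity with a mirrored null**
  (`importance_corrected_janitza()`). Plain Gini importance is
  non-negative and biased toward high-cardinality features, and a
  non-negative score admits no empirical null. The package therefore
  appends a column-permuted *shadow* copy of every feature and scores each
  feature by its impurity reduction minus its matched shadow's. The shadow
  augmentation is drawn once per call and `m_models` seeded forests are
  averaged on the same augmented data. Averaging over models with
  *re-drawn* shadows would be wrong: the real features' chance association
  with the response persists across models while the shadows' luck
  averages out, which skews the averaged score distribution positive and
  inflates the type-I error; the calibration test on pure noise guards
  exactly this property.
  With the fixed augmentation, non-positive mean scores and their mirror
  images form the empirical null, and
  `p = (#null ≥ observed + 1) / (#null + 1)`. The smallest attainable
  p-value is bounded by the null size, so the scheme needs many features
  (hundreds) to resolve small p-values — appropriate for community
  tables, not for a 41-variable sediment table.
* **Response-permutation importance**
  (`importance_permutation_altmann()`): the observed permutation
  importance is compared against `n_perm` re-trainings on a permuted
  response; `p = (r + 1)/(n_perm + 1)`, never zero, with per-feature
  nulls. Expensive but valid for few features — the natural choice for
  the environmental table.

`select_top_features()` applies strict cutoffs (importance > c, p < α) or
a top-*k* cap, ordered by importance; the selected taxa are the
fingerprint.

## Proximity, ordination, and environmental correlates

The proximity between two samples is the fraction of trees in which they
share a terminal node (`proximity_matrix()`; an exact brute-force count is
pinned by tests). For *unsupervised* structure discovery
(`unsupervised_forest()`), a synthetic copy of the data with every column
independently permuted — all between-variable relationships broken, all
marginals kept — is labelled against the real data and a forest learns to
tell them apart; the proximity among real samples then reflects intrinsic
correlation structure. One caveat we document deliberately: because every
real value has an exact synthetic twin, fully grown trees place an
out-of-bag real sample beside its synthetic twin, so the discrimination
accuracy on structureless i.i.d. data falls *below* 50% rather than
equalling it; on structured data it is far above. The proximity contrast
(within-cluster vs between-cluster) is the meaningful signal, and that is
what the tests assert.

Ordination treats proximity as similarity and runs classical principal
coordinates on `D = 1 − P` (`ordinate_from_proximity()`), falling back to
the square-root-corrected `sqrt(D)` when negative eigenvalues indicate a
non-Euclidean dissimilarity. Axes are eigenvalue-ordered; explained
fractions are relative to the positive eigenvalue sum; axis signs are
fixed so the lexicographically smallest sample id scores non-negatively,
making coordinates (not just geometry) reproducible. Environmental
variables are projected onto the first two axes with `vegan::envfit`
(`fit_environment_vectors()`, 9,999 permutations by default; the display
convention keeps vectors with p < 0.001 and R² > 0.3), and
`spearman_correlation_cluster()` summarizes the rank-correlation structure
of the sediment variables with average-linkage clustering on 1 − |ρ| and a
p < 0.01 significance flag.

## Robustness, the network validator, and resilience

`consistency_analysis()` trains many forests (1,000 at protocol scale)
with distinct seeds on *all* samples and reports per-sample
misclassification rates from out-of-bag predictions only — the only
leak-free reading when training uses every sample. Rates below 0.5% round
to 0 and above 99.5% to 100 (a forest either knows a sample or it does
not); rates inside [0.5, 99.5] are never altered.

The cross-algorithm validator is a deliberately different learner: a dense
network with two rectified-linear hidden layers (50 and 40 units), sigmoid
output, binary cross-entropy, Adam on mini-batches of 4, Glorot-uniform
initialization, and early stopping (patience 2) on the validation fold.
It is implemented directly in the package (R/mlp.R) as a compact,
seed-reproducible dense network. `ann_cross_validate()` runs repeated
threefold cross-validation — 333 repeats at protocol scale, 999 fits,
folds reshuffled every repeat, the left-out fold serving both early
stopping and prediction — and aggregates per-sample misclassification
rates. `cross_algorithm_agreement()` tabulates co-misclassification
between the two algorithms.

`false_positive_resilience()` is the scientific payoff: among truly
TNT-absent samples that the forest nonetheless (sometimes) calls present,
it partitions by metabolite presence (any amino-/diamino-nitrotoluene
above zero). A higher false-positive rate in the metabolite-bearing
partition means the community still carries the imprint of a past
contamination — the fingerprint outlives the compound.

## The synthetic-data generator

`generate_dataset()` emulates the statistical structure the analysis
assumes, with defaults chosen once to represent a realistic campaign: 150
sediments, 600 taxa, TNT prevalence 0.45, library depths
negative-binomial around 80,000 reads (dispersion 10), a latent
grain-size-like gradient `g ~ U(0,1)` driving 60% of the taxa (log-linear
slopes, sd 1.5) and most environmental variables (41 in total, the first
four being softmax grain-size fractions summing to 100%), 25 planted
indicator taxa gaining a ×2 abundance shift in TNT-present samples, and
10% of TNT-absent samples flagged *historical* — indicator shift applied,
metabolites positive, TNT zero. Log-normal taxon baselines (sd 2) with
per-cell log-noise (sd 0.5) are closed compositionally and sampled
multinomially.

Two design points deserve justification. Indicator taxa are drawn from
the *non*-gradient-responsive pool with baseline abundance above the 60th
percentile: a fingerprint taxon whose abundance is at the detection floor
could not indicate anything, and planting indicators below the abundance
filter would conflate the recovery analysis with the filter. The
per-cell noise level is set so that every planted indicator differs
detectably between classes (rank-sum p < 0.01 at defaults) while the
gradient — not TNT — remains the dominant driver of community
composition, which is exactly the regime that makes the classification
problem interesting. What the generator does *not* emulate: phylogenetic
correlation between taxa, PCR and sequencing error, spatial
autocorrelation, and real overdispersion structure — so passing tests
demonstrate that the pipeline's statistics behave as contracted, not that
the real-data accuracies are reproduced.

## Numerical conventions and scales

All randomness flows through explicit integer seeds (forests run
single-threaded for bitwise reproducibility); prediction ties break
toward the class with larger training prevalence, then lexicographically;
constant columns z-score to 0 with a warning; never-out-of-bag samples are
excluded from OOB error with a warning. Tests and examples run the
protocol at desk scales chosen as the package's own defaults — hundreds
of trees, tens to hundreds of models, six splits — while the full-scale
settings of the protocol (10,000 trees, 50 models per grid
combination, 1,000 consistency models, 100 importance models, 1,000
response permutations, 9,999 envfit permutations, 333×3 network fits)
remain plain function arguments.

## A worked run

```{r pipeline, eval = FALSE}
ds <- generate_dataset(synth_config(seed = 1))
res <- run_pipeline(ds$community, ds$taxonomy, ds$samples,
                    rank = "asv", threshold = 0.08,
                    n_trees = 500, mtry_factor = 5,
                    n_top = 25, importance_models = 10,
                    consistency_models = 200, seed = 1)
print(res)
truth_eval(res$top_features, ds)[c("precision", "recall")]
```

## Known limitations

The exclusion guideline cannot reproduce a historical curation exactly
without the original field metadata (how many representatives were kept
per flagged subset is configurable for that reason). The corrected
impurity scheme resolves p-values only down to ~1/(2·#non-positive
scores); with few features use the permutation scheme. The network
validator is a validator, not a tuned competitor: its architecture is
fixed, and no hyperparameter search for it is provided.
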