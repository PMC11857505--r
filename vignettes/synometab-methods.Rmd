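---
title: "Discriminating OA from RA in synovial-fluid NMR profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating OA from RA in synovial-fluid NMR profiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synometab)
```

## The problem

Osteoarthritis (OA) and rheumatoid arthritis (RA) present with similar
joint symptoms but have different etiologies and treatments, so a
differential diagnosis matters. Proton-NMR spectra of synovial fluid,
integrated over chemical-shift intervals ("metabolite bins"), give a
per-patient metabolic fingerprint. The reference cohort this package is
designed around (MetaboLights accession MTBLS564) is tiny and slightly
imbalanced — 10 OA and 14 RA knee-joint patients — which dictates most of
the methodology: univariate screens that are exact at n = 24,
leave-one-out cross-validation (LOOCV) instead of held-out splits, the
Matthews correlation coefficient (MCC) instead of accuracy, and heavy
regularization of the tree ensemble.

The pipeline, end to end:

1. **Cleaning and scaling** — drop uninformative bin columns; evaluate
   five column-wise scalings and keep the one that best separates the
   diagnosis groups by silhouette score.
2. **PLS-DA** — a first, linear ranking of bins by signed coefficient.
3. **Decision-stump screen** — per-bin threshold classifiers scored by
   MCC; bins with MCC exactly 1.0 ("perfect" bins) are set aside and
   described by centroid-distance / three-sigma / Fisher-ratio separation
   metrics.
4. **SVM-RFE + tree ensemble** — on the remaining bins, recursive feature
   elimination under a linear SVM selects `n_rfe` bins, and a bagged
   decision-tree ensemble is scored by LOOCV.
5. **Genetic algorithm** — tunes `n_rfe` plus six ensemble
   hyperparameters under the fitness `MCC^15 * n_rfe^2`.
6. **Shapley attribution** — exact per-bin additive attributions of the
   tuned model's RA probability, compared against the PLS-DA ranking.

`run_report()` executes all of it and returns a machine-readable summary.

## Synthetic cohorts: what they emulate and what they do not

Because the real accession cannot be bundled, `simulate_cohort()`
generates cohorts with the structure the analysis relies on, and the whole
test suite runs on them. Defaults mirror the study conditions: 10 + 14
samples, 200 bins, of which

* **4 perfect bins** — class-conditional uniforms on disjoint intervals.
  On the min-max scale the class supports are separated by a gap of at
  least `gap` (default 0.5, half the normalized range — comparable to the
  strongest bins in the reference cohort, whose centroid distances exceed
  0.6). A decision stump separates them with MCC exactly 1.
* **50 informative bins** — Gaussians whose means differ by
  `effect_size * noise_sd` (default 2 within-class SDs, a strong but
  overlapping univariate effect; 50 mirrors the retention size the tuned
  pipeline reports). Draws whose class supports happen to be disjoint are
  redrawn: with a 2-SD effect about 5% of 10-vs-14 draws would otherwise
  separate perfectly by chance, and non-overlap is exactly the property
  that defines the perfect tier. Without this constraint the "perfect set
  = planted perfect bins" contract would fail stochastically, which is a
  statement about the generator, not about the screen.
* **146 null bins** — identical Gaussians in both classes.

Each bin's elevated class is random; intensities are shifted globally
positive (a location shift preserves every scale-invariant statistic
downstream). `inject_correlation()` optionally rewrites null-bin blocks
with a shared factor to emulate within-pathway correlation.

What the generator does **not** emulate: heteroscedastic and multiplicative
NMR noise, baseline and alignment artifacts, heavy-tailed intensity
distributions, and realistic inter-metabolite correlation between
informative bins. Passing tests therefore demonstrate that the machinery
is correct and recovers planted structure under clean conditions, not that
the biological conclusions of any particular cohort transfer.

## Scaling selection

Five column-wise scalings are compared: z-score, min-max, max-absolute,
robust (median/IQR), and median centering followed by Pareto scaling
(division by the square root of the bin SD — the standard metabolomics
compromise between unit variance and raw scale). Selection maximizes the
mean silhouette width of the *known* OA/RA labelling in the full scaled
bin space (Euclidean distance). Using labels as the cluster assignment
directly measures what is wanted — separation of the diagnosis groups —
rather than the quality of some unsupervised clustering; an unsupervised
assignment can be supplied through the `clusters` argument. Ties break in
the listed order, and a scaling whose precondition fails (zero spread in
some bin) is skipped with a warning. PCA (`pca_explore()`) is exploratory
only: it mean-centers but does not re-scale, and its scores never enter
the classifiers.

## PLS-DA

`fit_plsda()` is a NIPALS PLS1 regression of the class code (OA = 0,
RA = 1) on the scaled bins, with 2 latent components by default (the
coefficient ranking is insensitive to this once the leading covariance
directions are captured; the component count is exposed). A single
response column — rather than one-hot coding — makes the per-bin signed
coefficient well defined: negative means elevated in OA, positive elevated
in RA, and swapping the coding negates every coefficient. `rank_bins()`
returns the top-k per disease. Coefficient magnitudes depend on the
(unknowable) scaling conventions of any particular software, so signs and
order, not magnitudes, are the meaningful output.

## The stump screen and separation metrics

`stump_mcc()` sweeps every midpoint of consecutive sorted unique values
and both polarities, maximizing MCC; among equal-MCC thresholds the
largest-margin one wins, so the boundary sits centrally in the widest
empty interval and the result is deterministic. MCC's 0/0 convention is 0
(random guessing). Bins with MCC exactly 1.0 have non-overlapping class
supports; they are reported with:

* centroid distance `d = |mean_OA - mean_RA|`,
* per-class sample SDs (n−1 denominator; the reference tables are
  reproduced within rounding under this choice, and at n = 10/14 the n
  vs n−1 difference is ~5%, well inside the reported precision),
* the three-sigma verdict `3*sd_OA < d & 3*sd_RA < d`,
* the Fisher discriminant ratio `d^2 / (sd_OA^2 + sd_RA^2)`. The
  within-class variance is the *sum* of the two class variances — the
  only reading consistent with the published four-bin table, against
  which the tests check.

The perfect bins are excluded from the multivariate stage: they are
individually sufficient, and leaving them in would mask what the ensemble
contributes on the harder, overlapping bins.

## SVM-RFE and the ensemble

RFE fits a linear-kernel SVM (cost 1.0; the value is conventional and the
ranking is insensitive to it on separable data) on the surviving bins,
scores bins by squared hyperplane weight, and removes exactly one per
iteration. One-at-a-time elimination makes the retained set for any
`n_keep` a prefix of a single elimination order, so `rfe_rank()` is
computed once and every `n_keep` is a slice — which is what makes the
genetic algorithm affordable.

The classifier is a bagged ensemble of classification trees implemented
in compiled code, because the tuned hyperparameter set — tree count,
maximum depth, minimum samples to split, minimum samples per leaf,
feature-subset size, and a gini/entropy/log-loss criterion — must all be
honoured jointly. Log-loss is the entropy impurity under another name;
both are accepted. The feature subset (`n_f`, resolved from the `log2`
or `sqrt` rule against the retained-bin count) is drawn once per tree
(random-subspace style) rather than per split; at these dimensions
(5 of 50 bins) the decorrelation effect is comparable and the choice
makes exact Shapley attribution tractable (below). Equal-gain splits
resolve to the earliest feature in the tree's (random) subset order and
the lowest threshold, so fits are deterministic given the seed; all
randomness flows through an explicit Mersenne-Twister stream independent
of R's RNG state.

`rf_loocv()` runs one fold per sample with fold seeds derived from the
master seed and pools the 24 held-out RA probabilities; MCC, accuracy,
precision, recall and F1 use the 0.5 probability cut with RA positive,
and ROC-AUC is computed from the pooled probabilities (per-fold AUC is
undefined for single-sample folds).

## Genetic algorithm

Each individual is a full hyperparameter set including `n_rfe`. Fitness
is `max(MCC, 0)^15 * n_rfe^2`: the 15th power makes a perfect LOOCV
classifier about five times ((1/0.9)^15 = 4.86) as selectable as an
MCC-0.9 one, and the quadratic term prefers solutions that keep more bins
at equal MCC (a deliberately conservative bias against tiny, brittle
signatures). Negative MCC is clamped to 0; an odd power would otherwise
produce negative weights.

Per generation, with population 100 and 2 elites: parents are drawn with
replacement proportionally to fitness; each crossover swaps 2 uniformly
chosen hyperparameter slots between 2 parents, yielding offspring in
pairs until 96 new members exist; the 96 offspring plus one copy of each
elite then undergo point mutation (probability 0.9 of reassigning one
slot to a different grid value); finally a pristine copy of each elite is
appended, restoring 100. The pristine copies make the best-ever fitness
monotone non-decreasing, which the tests assert. Evaluations are cached
by the full hyperparameter tuple, so the number of *unique* configurations
explored is countable and repeated individuals cost nothing.

The default grids (see `search_space()`) are this package's design — the
original study's grids are not published. They span 6,771,600
combinations, contain the reported optimum, and a default 35-generation
run touches a few thousand unique sets. The mutated-plus-pristine elite
treatment is likewise one of several defensible readings of the protocol;
the generation arithmetic (96 + 2 + 2 = 100) pins it down.

## Shapley attribution

`shapley_attribution()` explains the tuned ensemble's RA probability (the
probability scale, recorded in the result; "positive pushes toward RA"
then holds by construction since RA is class 1). The value function is
the standard path-dependent conditional expectation: a coalition follows
the tree where its features are known and splits by bootstrap node
proportions where they are not. Because each tree depends only on the
few features it actually splits on, its Shapley values are computed
*exactly* by enumerating that tree's own feature subsets, and summed
across trees — justified by linearity of the Shapley value and the dummy
axiom for unused features. No sampling is involved; local accuracy
(base value + attributions = prediction, per sample) holds to floating
point and is asserted for every sample in the tests, alongside equality
with a full-lattice enumeration oracle on small models.

Attribution is computed in-sample with the final model trained on all 24
samples; per-fold attribution would explain 24 different models rather
than the one reported. Direction per bin is the sign of the correlation
between the bin's values and its attributions. `compare_selections()`
collapses bins to metabolite names and intersects the PLS-DA and
ML-derived per-disease sets; a metabolite appearing in both diseases'
selections (across methods) is flagged ambiguous.

## Numerical choices and degenerate inputs

* Cleaning drops any bin column with a missing value, non-numeric
  content, or zero variance — a stated, conservative operationalization
  of "lacking sufficient information"; cleaning is idempotent.
* Scalings error (naming the bin) on zero denominators rather than
  silently producing NaN; `select_normalization()` degrades gracefully by
  skipping the method.
* A stump over constant values returns MCC 0 with the value itself as
  threshold.
* `mcc()` and the stump use the 0-denominator → 0 convention.
* All-zero PLS coefficients rank bins by id and set a degeneracy flag.
* RFE ties in squared weight remove the later column.
* LOOCV probabilities exactly at 0.5 classify as RA (the larger class);
  constant probability vectors get AUC 0.5.

## Problem sizes used by the shipped checks

The test-suite and acceptance runs use the default 24 x 200 cohorts; the
tuned-pipeline recovery check runs the GA with population 20 for 5
generations over 10 seeds, and the end-to-end report check uses a 24 x 60
cohort with population 10 for 2 generations. These sizes exercise every
code path at full fidelity; scaling the GA back up to the default
population 100 / 35 generations changes runtime, not behaviour, and the
larger setting remains the package default.

## Known limitations

* The evaluation that the GA optimizes is the same LOOCV it reports, and
  RFE sees all samples: with n = 24 this is the study design, but the
  resulting MCC is an optimistically biased estimate of out-of-cohort
  performance. Treat it as model selection, not validation.
* Perfect-MCC screening is a sample property; at n = 24 a truly
  overlapping bin can separate in-sample (the generator controls this for
  tests, reality does not).
* The per-tree (rather than per-split) feature subsetting is a documented
  variant of the classical random forest.
* PLS-DA coefficient magnitudes are convention-dependent; only signs and
  ranks are comparable across implementations.
* `read_maf()` covers the tab-separated metabolite-assignment dialect
  with one row per bin; exotic MAF variants may need the generic
  `read_bin_table()` path instead.
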