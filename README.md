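# synometab

Machine-learning discrimination of **osteoarthritis (OA)** from
**rheumatoid arthritis (RA)** using binned proton-NMR metabolite profiles
of synovial fluid.

The two diseases present similarly but demand different treatment. Given a
small labelled cohort — the reference design is 10 OA vs 14 RA knee-joint
patients (MetaboLights accession MTBLS564) over a few hundred metabolite
bins — the package runs a complete, reproducible selection-and-
classification pipeline and reports which metabolite bins carry the
diagnostic signal. It is written for metabolomics analysts who want the
whole workflow, and for methods people who want its pieces (the stump
screen, the GA tuner, exact tree-ensemble Shapley values) as tested
building blocks.

## What it computes

For a labelled bin matrix `X` (samples × bins, labels OA/RA coded 0/1):

* **Scaling selection** — five column scalings (z-score, min–max,
  max-abs, median/IQR, median + Pareto); the winner maximizes the mean
  silhouette width of the OA/RA labelling in the scaled space.
* **PLS-DA** (NIPALS, single 0/1 response) — signed per-bin coefficients;
  negative ⇒ elevated in OA, positive ⇒ elevated in RA.
* **Decision-stump screen** — per bin, the best single threshold under
  the Matthews correlation coefficient,
  `MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
  Bins with MCC = 1.0 ("perfect" bins) are set aside and described by the
  centroid distance `d = |μ_OA − μ_RA|`, per-class SDs, the three-sigma
  rule (`3σ_OA < d` and `3σ_RA < d`), and the Fisher discriminant ratio
  `FDR = d² / (σ_OA² + σ_RA²)`.
* **SVM-RFE** — linear-SVM recursive feature elimination (one bin per
  iteration) over the non-perfect bins.
* **Tree-ensemble LOOCV** — a bagged decision-tree ensemble (depth,
  split/leaf minima, per-tree feature subsets, gini/entropy/log-loss
  criteria) evaluated by leave-one-out cross-validation; pooled MCC,
  accuracy, precision, recall, F1, ROC-AUC (RA positive).
* **Genetic-algorithm tuning** — population 100, fitness
  `MCC¹⁵ · N_RFE²`, fitness-proportional selection, two-slot crossover,
  point mutation (p = 0.9), two elites (pristine + mutable copies), 35
  generations by default.
* **Exact Shapley attribution** — per-sample additive attributions of the
  tuned model's RA probability (path-dependent expectations, per-tree
  subset enumeration; local accuracy to machine precision), plus a
  PLS-DA-vs-ML marker comparison.

A synthetic-cohort generator (`simulate_cohort()`) reproduces the study's
statistical structure — 10/14 split, 4 perfectly separating bins, 50
moderately informative bins, null remainder — so the full pipeline is
testable offline.

## Worked example

```r
library(synometab)

sim  <- simulate_cohort(seed = 42)          # 24 x 200 synthetic cohort
norm <- select_normalization(sim$matrix)    # pick the best scaling
#> normalization_report: selected 'maxabs' (silhouette 0.3229)

sc <- screen_bins(norm$scaled)              # per-bin stump screen
length(sc$perfect_bins)                     # 4 bins with stump MCC = 1.0

j  <- match(sc$perfect_bins[1], norm$scaled$bins$bin_id)
separation_metrics(norm$scaled$values[, j], norm$scaled$labels)
#> d=0.759  sd_OA=0.071  sd_RA=0.090  FDR=43.80  three-sigma pass

rest <- subset_bins(norm$scaled, sc$rest_bins)
ga   <- run_ga(rest, config = ga_config(n_pop = 20, n_gen = 5, seed = 42))
ga$best_metrics[c("mcc", "accuracy", "roc_auc")]
#> MCC=1.00  acc=1.00  AUC=1.00   (fitness 22500, 106 unique sets evaluated)

model <- rf_fit(subset_bins(rest, ga$best_metrics$retained_bins),
                ga$best, seed = 42)
at <- shapley_attribution(model,
                          subset_bins(rest, ga$best_metrics$retained_bins))
head(rank_attributions(at, 20), 3)
#>   rank                       bin_id  mean_abs_shap direction
#> 1    1 informative_bin_036 [2.0829]     0.0217        OA
#> 2    2 informative_bin_018 [1.2688]     0.0217        OA
#> 3    3 informative_bin_005 [0.6809]     0.0214        OA
```

The stump stage recovers exactly the four planted perfectly separating
bins; the GA-tuned RFE + ensemble reaches a perfect LOOCV MCC on the
overlapping bins; and the top Shapley attributions point at planted
informative bins with the planted effect direction. `run_report()` wraps
all of the above (including the PLS-DA comparison) into one serializable
summary. Real data enter through `read_bin_table()` (samples × bins
TSV/CSV with a label column) or `read_maf()` (MetaboLights
metabolite-assignment files, transposed on read).

## Package layout

* `R/` — bin-matrix container and IO, synthetic cohorts, scalings/PCA/
  silhouette, PLS-DA, stump screen and separation metrics, SVM-RFE,
  ensemble + LOOCV, GA, Shapley, reporting.
* `src/forest.cpp` — the compiled tree grower, predictor, and exact
  Shapley enumeration.
* `vignettes/synometab-methods.Rmd` — model assumptions, parameter
  meanings and defaults, generator design, numerical choices,
  limitations.
* `tests/testthat/` — unit, property and end-to-end suites with
  independent brute-force oracles.
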