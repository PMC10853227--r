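# deltasurv

Delta-radiomics survival modeling for small paired-imaging cohorts.

When a tumour is imaged twice — for instance an amino-acid PET scan during
treatment and a second one at therapy discontinuation — the *change* of
image-derived features between the two time points ("delta radiomics") can
predict progression-free survival (PFS) where either scan alone cannot.
Cohorts in rare cancers are tiny (tens of patients against hundreds of
correlated features), so the pipeline has to be sample-efficient and
leakage-proof. `deltasurv` is aimed at imaging scientists and biostatisticians
who want to run, stress-test or extend such a pipeline.

## What it implements

* **Feature sets** — single-time-point `F₁` and four delta variants:
  absolute `F₁ − F₀`, relative `(F₁ − F₀)/F₀`, and both divided by the
  scan gap in months, separately for radiomic and conventional features.
* **Leakage-safe preprocessing** — zero-variance removal and Z-scoring
  fitted on training folds only; redundancy reduction by **bootstrap
  consensus clustering**: per fold, 500 patient resamples are each
  clustered by absolute Spearman correlation (complete linkage, cut at
  |ρ| = 0.9), a co-association matrix accumulates co-clustering
  frequencies, the final clusters are the connected components at
  co-association ≥ 0.5, and each cluster is represented by its **medoid**.
* **Selectors × regressors** — univariate C-index and mutual-information
  bootstrap filters, LASSO Cox, and recursive feature elimination, crossed
  with CoxPH, ElasticNet Cox, a linear ranking survival SVM and
  component-wise gradient-boosted Cox (16 models, k ∈ {1, 2, 3} features).
* **Evaluation** — Harrell's C-index (exhaustive-pair semantics, ties 0.5),
  IPCW integrated time-dependent AUC, repeated event-stratified CV
  (4 × 25 by default), 1000-resample bootstrap summaries, one-sided
  Mann–Whitney model comparisons with Benjamini–Hochberg correction.
* **Strategies** — the fixed-hyperparameter default strategy over the full
  model grid; a two-stage fine-tuned strategy that optimizes
  hyperparameters on a larger single-scan cohort with a Gaussian-process
  Bayesian search (100 evaluations) and transfers SHAP-top features; Cox
  baselines on conventional features; robustness reports (pairwise
  adjusted Rand index and medoid consistency across folds).
* **Imaging layer** — static tumor-to-brain-ratio (TBR) and dynamic
  time-to-peak (TTP) parametric images, threshold VOI segmentation
  (1.6 × brain mean; 70% of striatal max), the 9 conventional features,
  isotropic resampling, and a compact IBSI-style radiomics extractor
  (first-order, histogram, GLCM incl. Information Correlation 2 and
  Cluster Prominence, morphology, local intensity peak).
* **Synthetic data** — a cohort generator with block-correlated features, a
  planted prognostic delta signal and calibrated survival/censoring, plus a
  dynamic-PET phantom generator, so everything above is testable without
  any patient data.

## Worked example

```r
library(deltasurv)

coh <- generate_cohort(cohort_spec(n_patients = 18, effect_size_beta = 1.5, seed = 1))
coh
#> <ds_cohort> 18 patients, 39 features (9 conventional), 89% events

delta <- build_feature_set(coh, "delta_abs", "radiomics")
pipe  <- ds_pipeline(selector = "rfe", k = 1, regressor = "svm", n_boot_cluster = 100)
cv    <- run_repeated_cv(delta, coh$outcomes, pipe, cv_scheme(4, 10, seed = 1))
glance(cv)
#> # A tibble: 2 × 6
#>   metric       mean     se ci_lower ci_upper n_scores
#> 1 test_cindex 0.881 0.0213    0.835    0.919       40
#> 2 test_iauc   0.927 0.0212    0.879    0.965       40

robustness_report(cv)$mean_ari
#> [1] 0.82
head(shap_rank(cv, delta)$ranking, 3)
#>   feature     mean_abs_shap
#> 1 rad_b01_f02         0.454
#> 2 rad_b01_f05         0.147
#> 3 rad_b01_f03         0.128
```

The generator planted its prognostic signal in the *change* of feature
block 1; the cross-validated delta-absolute pipeline finds it
(`rad_b01_*` features dominate the SHAP ranking), scores a mean held-out
C-index of 0.88 with a bootstrap 95% CI of [0.84, 0.92] on this cohort, and
the feature clustering is reasonably stable across folds (mean pairwise
ARI 0.82). On the same cohort the single-time-point table scores near
chance — the designed contrast between delta and static radiomics.

`plot_cindex_heatmap()`, `plot_shap_importance()`,
`plot_medoid_consistency()` and `autoplot()` visualize strategy grids, SHAP
rankings, medoid stability and CV score distributions; `tidy()`/`glance()`
methods return tibbles throughout.

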