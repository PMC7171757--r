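# radsurv

Radiomics-based survival modelling for node-positive cervical cancer
treated with definitive chemoradiotherapy — an end-to-end, fully tested R
implementation of the workflow: 3-D texture/histogram/shape feature
extraction from segmented tumour and lymph-node ROIs on two MR sequences,
correlation-based feature clustering, bootstrap-aggregated penalized-Cox
feature ranking, random-survival-forest risk models per endpoint, and
survival-metric evaluation. Because the underlying patient images are
private, the package ships a synthetic cohort generator whose texture
latents drive the hazards, so every stage is testable end to end.

## What it computes

For each patient, ROI (tumour, largest involved node) and sequence (T1CE,
T2), 43 features on intensities discretized to 64 grey levels by relative
min–max resampling within the ROI:

- 12 first-order: min, max, mean, population SD, skewness, kurtosis,
  histogram entropy (bits) and uniformity, voxel count, volume (ml),
  sphericity `π^{1/3}(6V)^{2/3}/A`, compacity `A^{3/2}/V`;
- 6 GLCM indices (homogeneity `Σ p/(1+|i−j|)`, energy `Σp²`, contrast
  `Σ(i−j)²p`, correlation, entropy, dissimilarity) on co-occurrences pooled
  over all 13 unique 3-D directions;
- 11 GLRLM (Galloway/Chu) run-length indices, 3 NGLDM (Amadasun–King)
  and 11 GLZLM zone-length indices, all in 3-D.

Downstream: features with |Spearman| > 0.90 are hierarchically clustered
(average linkage on 1−|SC|) and each cluster replaced by the sign-aligned
z-scored average of its members, iterated until no representative pair
exceeds 0.90; the reduced training features are ranked by ridge/lasso/
elastic-net Cox fits over 100 bootstrap resamples with simple-ensemble
(mean-rank) aggregation of the per-resample top-10 lists; a random
survival forest (log-rank splitting, ensemble-mortality risk) is tuned by
cross-validated grid search and fitted per endpoint (LC, RC, DMFS, OS)
and per feature source (tumour, node); models are evaluated with
Harrell's C-index, 36-month IPCW time-dependent AUC, maximally selected
log-rank cutpoints and Kaplan–Meier risk groups, plus univariate/
multivariate Cox hazard-ratio tables.

## Worked example

The tabular shortcut generator plants two informative features (log-hazard
coefficients 0.9 and 0.7) among 15; the selector should find them and the
forest should discriminate on held-out patients:

```r
library(radsurv)
fc <- generate_feature_cohort(n_patients = 200, n_features = 15,
                              effect_sizes = c(0.9, 0.7),
                              censoring_rate = 0.25, seed = 42)
sp <- split_cohort(fc$features, 2/3, seed = 42)
rk <- bootstrap_select(sp$train, fc$outcomes, n_boot = 25, top_k = 5, seed = 42)
head(rk, 3)
#>   feature mean_rank selection_freq
#> 1    f002      1.37          1.000
#> 2    f001      1.63          1.000
#> 3    f004      4.77          0.587
sel <- take_top(rk, 5)
model <- fit_rsf(sp$train[, c("patient_id", sel)], fc$outcomes,
                 hyperparameters = list(mtry = 2L, min_node_size = 6L,
                                        num_trees = 500L), seed = 42)
risk <- predict_risk(model, sp$validation[, c("patient_id", sel)])
idx <- match(sp$validation$patient_id, fc$outcomes$patient_id)
harrell_cindex(risk, fc$outcomes$time_months[idx], fc$outcomes$event[idx])
#> [1] 0.7887324
time_dependent_auc(risk, fc$outcomes$time_months[idx],
                   fc$outcomes$event[idx], t = 36)
#> [1] 0.8409804
```

The two planted features top the consensus ranking with selection
frequency 1, and the validation C-index/AUC are well above the 0.5 of a
random prediction.

The full imaging path is driven the same way from a single config:

```r
res <- run_pipeline(pipeline_config(spec = cohort_spec(seed = 1), seed = 1))
performance_table(res)   # 8 models: 4 endpoints x {tumour, node} features
```

The numbered scripts under `analysis/` run the same stages as a narrative
workflow (simulate → extract → cluster → select/fit → evaluate), writing
tables under `results/`.

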