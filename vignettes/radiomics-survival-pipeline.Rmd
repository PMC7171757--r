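---
title: "Radiomic texture features and survival-forest risk models: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomic texture features and survival-forest risk models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In node-positive cervical cancer treated with definitive chemoradiotherapy,
pre-treatment MR imaging of the primary tumour and of the involved lymph
nodes carries prognostic information beyond stage and size. The question
this package operationalizes is whether quantitative texture, histogram and
shape descriptors ("radiomic features") of the tumour and of the largest
involved node — extracted from contrast-enhanced T1-weighted and T2-weighted
images — predict four time-to-event endpoints: local control (LC), regional
control (RC), distant metastasis-free survival (DMFS) and overall survival
(OS), all measured from the start of chemoradiotherapy. The working
hypothesis mirrored by the synthetic generator is that tumour texture is
most informative for LC while node texture is most informative for the
regional and distant endpoints.

The pipeline is: feature extraction → correlation-based dimensionality
reduction → bootstrap penalized-Cox feature ranking → random survival
forest per endpoint and per feature source → survival-metric evaluation.
Each stage is an exported function; `run_pipeline()` composes them, and the
`analysis/` scripts run them as a narrative workflow.

## Synthetic cohort generator

Real MR data of this kind are not publicly available, so every stage is
exercised on synthetic cohorts drawn by `generate_cohort()`.

* **Geometry.** Each patient has two co-registered 3-D volumes (sequences
  "T1CE" and "T2") on a 96 × 96 × 20 grid at 1 × 1 × 5 mm spacing by
  default — in-plane resolution and 5 mm slices typical of pelvic MR
  protocols. The tumour is an ellipsoid with semi-axes drawn uniformly from
  8–22 mm at the volume centre; the node (semi-axes 4–9 mm) sits beside it
  with a 4 mm gap. Radii that cannot fit inside the volume are rejected at
  specification time with an error naming the offending field.
* **Texture.** Inside each ROI the intensity is a structure mean plus a
  Gaussian random field: white noise smoothed by an isotropic Gaussian
  kernel (FFT convolution, periodic boundary), standardized, and scaled by
  a per-patient *contrast* latent; the kernel width is the per-patient
  *correlation-length* latent (0.5–2.5 voxels). The two sequences share the
  field but differ in structure means and in texture amplitude, emulating
  differing sequence contrast. These two latents per structure give
  first-order features (standard deviation tracks contrast) and texture
  features (homogeneity/coarseness track correlation length) analytic
  handles on the generative truth.
* **Outcomes.** Each endpoint's hazard is log-linear in the standardized
  latents: baseline exponential with scale 60 months (Weibull available
  via `hazard_model = "weibull"`), linear predictor
  `sum(effect_sizes[[endpoint]] * z)`. Latents are standardized with the
  known mean and SD of their uniform ranges, so an effect `b` is a hazard
  ratio `exp(b * sqrt(12)/2)` across the latent's interquartile range. The
  default coupling sends tumour latents to LC and node latents to
  RC/DMFS/OS, making the headline source-ordering recoverable by
  construction. Censoring is administrative: one uniform censoring time per
  patient on (0, tau), with tau calibrated numerically (uniroot on the
  closed-form censored fraction for exponential event times) to the
  requested overall rate, 0.3 by default — follow-up loss in the range
  reported for retrospective chemoradiotherapy cohorts.
* **Randomness.** A single master seed is expanded into named child seeds
  (one per patient, one for event times, one for censoring), so identical
  specs reproduce cohorts bit-identically and adding a consumer never
  shifts existing streams.

What the generator does *not* emulate: MR physics (bias fields, motion,
coil profiles), multi-node anatomy, non-ellipsoidal shapes, and intensity
distributions with scanner-specific units. Passing tests therefore
demonstrate internal correctness and recoverability of planted signal, not
clinical performance on real images.

`generate_feature_cohort()` is a fast tabular shortcut for testing the
selection/modelling/evaluation stages: multivariate-normal features with
AR(1) correlation and an exponential proportional-hazards outcome linear in
the first features.

## Feature extraction

43 features per ROI per sequence — 86 per structure, 172 per patient —
computed on intensities discretized to 64 grey levels by *relative*
resampling between the ROI minimum and maximum:
`level(x) = min(N, floor(N (x - min)/(max - min)) + 1)`. Relative
resampling removes scanner scale and offset: any strictly increasing affine
transform of the intensities leaves every discretized feature unchanged (a
tested invariant).

The catalogue (the counts 12/6/11/3/11 follow the LIFEx-style grouping of
first-order plus four texture families):

* **First-order (12).** min, max, mean, population SD, moment skewness and
  kurtosis (undefined on zero-spread ROIs and reported missing, never
  zero), histogram entropy (bits) and uniformity on the 64-level histogram,
  and four shape descriptors: voxel count, volume in ml, sphericity
  `pi^(1/3) (6V)^(2/3) / A` and compacity `A^(3/2) / V`, with surface area
  A from exposed-voxel-face counting weighted by physical face areas.
  Face counting overestimates smooth-surface area (a digital sphere's
  sphericity is below 1) but preserves the orderings the models consume.
* **GLCM (6).** Co-occurrences at lattice distance 1 pooled over the 13
  unique 3-D directions into one symmetric matrix (LIFEx convention:
  pooled counts, not per-direction averaged indices), normalized;
  homogeneity, energy, contrast, correlation, entropy, dissimilarity.
* **GLRLM (11).** Equal-level runs along the 13 directions pooled into one
  matrix; the Galloway/Chu indices plus run percentage
  `RP = runs / (13 * voxels)`, which stays in (0, 1].
* **NGLDM (3).** Amadasun–King coarseness, contrast and busyness from
  per-voxel absolute differences to the 26-neighbourhood mean (in-ROI
  neighbours only). Coarseness carries an epsilon = 1e-6 denominator guard
  so the uniform-ROI limit is finite (1e6) and documented; busyness and
  contrast are undefined (missing) on single-level ROIs.
* **GLZLM (11).** Zones are maximal 26-connected equal-level components;
  indices mirror the run-length family with zone size, plus zone
  percentage `ZP = zones / voxels`.

Voxels are used as-is (no isotropic resampling), matching 5 mm-slice
acquisition; direction vectors are lattice directions without
physical-distance weighting. Degenerate values propagate as missing;
downstream preparation drops features missing in more than 20% of patients
and median-imputes the rest with training-set medians, because silent zeros
would distort rank correlations.

The compiled kernels are validated against brute-force pure-R enumerations
(all directions, explicit neighbourhoods, label-propagation zones) on
random 4 × 4 × 4 ROIs, and against hand-computed single-matrix-entry cases.

## Correlation clustering

Features with |Spearman| > 0.90 are grouped by agglomerative clustering on
distance 1 − |SC| with average linkage, cut at height 0.10. The absolute
value matters: anticorrelated features belong together and are
sign-inverted before averaging. Each cluster is replaced by the mean of its
members after z-scoring (features of wildly different units — entropy,
millilitres — cannot be averaged raw) and sign alignment with the cluster
anchor (the member with the highest mean |SC| to the others; ties and
near-zero anchor correlations resolve lexicographically and with a logged
+1 sign). Singletons pass through on their original scale.

One pass correctly clusters the *original* features, but the averaged
representatives are new variables and a pair of them can land just above
the threshold. Since the contract is "no representative pair above 0.90",
`reduce_until_stable()` iterates the pass until the audit holds (one to two
passes in practice). The maps — including the member means/SDs used for
z-scoring — are fitted on the training split only and applied frozen to
validation; the split-before-cluster order is a deliberate leakage guard: fitting the
maps on all patients would let validation data shape the representation.

## Feature selection

On the reduced training table, each of 100 bootstrap resamples (size equal
to the training set, drawn with replacement; resamples without events are
redrawn and logged) is ranked three times: ridge, lasso and elastic-net
(mixing 0.5) penalized Cox fits, penalty strength chosen by internal 5-fold
cross-validation of the partial likelihood over a 50-point log-spaced
path, features ordered by decreasing absolute standardized coefficient,
zeroed coefficients after all non-zero ones. The top-10 of every list feeds
a simple-ensemble rank aggregation: a feature's consensus score is its mean
rank over all lists with absent features assigned rank 11; ties break
lexicographically. The three penalties are pooled into one aggregation — pooling treats the
regularizers as exchangeable voters; comparing them separately is the main
alternative and is available by passing a single penalty — and the
consensus top-10 (configurable via `n_select`) enters the forest.

A statistical caveat established while validating this stage: conditional
on a *fixed* cohort, bootstrap selection frequencies are not binomial —
chance feature–outcome associations persist across resamples of the same
patients, and a lucky noise feature is selected consistently. Null
calibration of the selector is therefore tested marginally (a fresh null
cohort per repetition), where the binomial envelope applies.

## Survival modelling

One random survival forest (log-rank splitting, 1000 trees by default) per
endpoint and per feature source — 8 models per run. Hyperparameters (mtry
over {sqrt(p), p/3, p}, minimum node size over {3, 6, 15}) are tuned by
grid search with 5-fold cross-validation stratified by the event
indicator, maximizing out-of-fold Harrell C-index; the full score table is
retained. The predicted risk is the ensemble mortality — the row sum of the
ensemble cumulative hazard over the training event times — so higher risk
means predicted worse outcome. The forest size and grid are package defaults chosen to cover the usual
mtry heuristics at this feature count, and are configurable.

## Evaluation

* **Harrell's C-index**: pairs are comparable iff the smaller observed time
  is an event (tied times are incomparable); tied risks count 1/2. Checked
  against `survival::concordance` and against enumerable 3-patient cases.
* **Time-dependent AUC at 36 months**: cumulative/dynamic estimator with
  inverse-probability-of-censoring weights from the Kaplan–Meier estimate
  of the censoring distribution (cases weighted 1/G(T−), controls 1/G(t)).
  The estimator choice is isolated in one function; without censoring it
  provably collapses to the plain binary AUC (tested identity).
* **Risk groups**: the cutpoint maximizing the two-group log-rank statistic
  over observed training risks, with a guard requiring at least 10% of
  patients per group (configurable; the classical maximally selected
  statistic applies no such bound). Ties take the lower cutoff. The
  training cutpoint is applied frozen to validation.
* **Kaplan–Meier / log-rank / Cox tables**: product-limit estimates with
  3-year values read at 36 months; two-sided log-rank; per-variable
  univariate and joint multivariate proportional-hazards fits with Efron
  ties, flagging monotone-likelihood separation as unstable instead of
  reporting a number, and rejecting duplicated covariates.

## Numerical choices and problem sizes

Degenerate inputs: empty ROIs error explicitly; uniform ROIs map to level
1 and yield the documented limits (entropy 0, uniformity 1, coarseness
1e6, busyness missing); single-voxel ROIs have missing skewness/kurtosis;
constant feature columns are dropped before correlation. All randomness
descends from one master seed through named child streams.

The test suite exercises the full pipeline at reduced problem sizes chosen
to keep the generator-to-evaluation loop fast while preserving every
contract: 40 × 40 × 20 voxel volumes at 1.5 × 1.5 × 3 mm, tumour semi-axes
7–11 mm, node 4–7 mm, 93 patients split 62/31, 8–10 bootstraps in
recovery runs, and strong single-latent effects (hazard ratio about 6.7
across the contrast latent's IQR) when testing signal recovery — the
recovery contract asks for a strong planted effect (HR at least 3 across
the IQR). The full-size defaults remain what `cohort_spec()` and
`pipeline_config()` return.

## Known limitations

* The surface-area estimator biases sphericity low for smooth shapes.
* IPCW AUC uses the simple KM censoring estimate; covariate-dependent
  censoring would need a model-based G.
* The generator's texture latents act globally per structure; real tumours
  are heterogeneous at sub-ROI scales.
* Cox tables report Wald p-values; small-sample likelihood-ratio tests may
  differ.
* With 31 validation patients a C-index has a standard error around 0.07;
  single-seed orderings are noisy, which is why recovery contracts are
  framed over repeated seeds.
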