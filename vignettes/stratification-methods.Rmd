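---
title: "Model-based stratification of multimodal clinical cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based stratification of multimodal clinical cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixstrat)
```

## The problem

Psychiatric diagnoses are defined by symptoms, but the patients sharing a
diagnosis may fall into biologically distinct subgroups. `mixstrat`
implements an unsupervised stratification pipeline for cohorts measured on
many continuous features from several modalities — the motivating setting
is a first-episode schizophrenia cohort with 26 neurocognitive and 19
electrophysiological variables per subject — and asks two questions:

1. Do the patients split into statistically distinct subgroups in a
   low-dimensional latent representation of the feature battery?
2. Do those subgroups differ in something clinically meaningful, such as
   symptom change under treatment?

The pipeline runs: per-feature standardization → probabilistic PCA with
AIC selection of the latent dimension → model-based imputation of subjects
with missing features, with an error gate → Gaussian mixture subgrouping
of patients with leave-one-out cross-validated selection of the number of
components → external validation of the subgroups by a linear SVM on
clinical scores with a permutation test → a univariate characterization
table.

## The latent space: probabilistic PCA and AIC

Features are standardized to zero mean and unit variance; the statistics
are estimated on the complete cases only (sample s.d., denominator
n−1) and then applied to every subject, so subjects entering later
through imputation are on the same scale.

Probabilistic PCA models a standardized feature vector as
$x = Wz + \mu + \varepsilon$, with $z \sim N(0, I_D)$ and isotropic noise
$\varepsilon \sim N(0, \sigma^2 I_p)$. `fit_ppca()` uses the closed-form
maximum-likelihood solution: $\sigma^2$ is the mean of the $p - D$
smallest eigenvalues of the ML sample covariance (denominator n), and
$W = U_D(\Lambda_D - \sigma^2 I)^{1/2}$. The eigendecomposition route was
chosen over EM because it is exact and deterministic at these problem
sizes; sign convention (the largest-magnitude entry of each eigenvector
is positive) makes projections reproducible across platforms.

The dimension is chosen by AIC over a grid (default $2 \dots
\min(p, n) - 1$; the model is not estimable at $D = p$, where the noise
variance would average an empty eigenvalue set). The free-parameter count
is $m = pD - D(D-1)/2 + p + 1$: the loadings minus their rotational gauge,
the $p$ means, and $\sigma^2$. This count is a declared convention — other
conventions shift all AIC values by a constant in $D$-independent terms
and rarely change the arg-min — and it is isolated in `ppca_n_params()` so
it can be audited or replaced.

Subjects are placed in the latent space by the posterior mean
$E[z \mid x] = (W^\top W + \sigma^2 I)^{-1} W^\top (x - \mu)$.

## Imputation with an error gate

Subjects with missing cells are projected through the conditional
posterior restricted to their observed features,
$E[z \mid x_{obs}] = (W_o^\top W_o + \sigma^2 I)^{-1} W_o^\top
(x_{obs} - \mu_o)$ — the natural model-based imputation given that the
generative model is already fitted.

How wrong is such a projection likely to be? `estimate_error()` replays
the subject's missingness pattern on every complete-case donor, measures
each donor's realized latent error against its complete-data projection,
and averages with Gaussian-kernel weights on the donor–target distance
over the features the target actually observed (bandwidth defaults to the
median donor–target distance, a scale-free choice). Latent axes are first
rescaled so each has s.d. 0.1 over the complete cases; the default
inclusion gate, estimated error strictly below 0.05, is therefore half a
rescaled standard deviation. Both the rescaling convention and the kernel
are declared conventions, configurable in `imputation_config()`.

## Subgrouping: GMM with LOO-CV model selection

Patients' latent scores are clustered with a Gaussian mixture fitted by
EM: full, unshared covariances, a diagonal ridge (`reg`, default 1e-4)
added at every M-step, k-means++-style initialization, and the best of
`n_restarts` runs by training likelihood. The number of components is
selected by leave-one-out cross-validation: for each K and each patient,
the model is fitted on the n−1 others and the held-out negative
log-likelihood recorded; the selected K minimizes the mean curve, ties
going to the smaller K.

Two numerical choices matter at n = 44:

* **Spike rejection.** Picking the best restart by training likelihood
  will otherwise select degenerate solutions in which a near-singular
  component wraps a handful of points — these have arbitrarily high
  training likelihood and disastrous held-out likelihood. A full
  D-dimensional covariance needs at least D+1 points, so restarts in
  which any component's responsibility mass falls below D+1 are discarded
  (`min_mass`).
* **Detection threshold.** With full unshared covariances, a 4-D
  two-component mixture needs roughly 6 standard deviations between the
  component means before LOO-CV prefers K = 2 over K = 1 at n = 44; we
  measured ~6 s.d. on ideal bimodal Gaussians and ~7 s.d. through the
  full generate–standardize–project pipeline. This conservatism is a
  property of the estimator, not a bug: with 29 free parameters for K = 2
  against 14 for K = 1, held-out likelihood demands strong evidence at
  this sample size.

Components are renamed by descending size, so "subgroup 1" is always the
larger.

## External validation

Whether the discovered subgroups predict anything clinical is tested with
a linear soft-margin SVM (C = 100) on the three PANSS subscores (positive,
negative, general) of each block — baseline, follow-up, and change
(baseline − follow-up, the treatment effect) — on that block's
available-case subset. Features are standardized inside every training
fold (C = 100 on raw score scales is scale-sensitive; the behaviour is
switchable). Leave-one-out accuracy is compared with the majority-class
baseline, and significance is assessed by refitting the full LOO loop
under 1000 label permutations with the add-one p-value
$p = (1 + \#\{A_{null} \ge A_{obs}\}) / (1 + B)$, which cannot be zero. A
decision value of exactly zero predicts the first class level —
documented because ties, while measure-zero in theory, can arise from
degenerate inputs.

The univariate characterization table reports, per subgroup: gender and
four substance-use items (2×2 Pearson χ², no continuity correction — the
uncorrected statistic is what matches the motivating study's published
p-values), and age, the nine PANSS cells and drug dose (Welch t-test;
the pooled-variance test is available but Welch is what reproduces the
published age comparison). No multiplicity correction is applied, matching
the descriptive use of such tables.

## The synthetic cohort generator

Because the motivating clinical data are not public, `generate_cohort()`
builds cohorts with the structure the analysis assumes, with ground truth
for every stage:

* 44 patients and 53 controls (defaults), 26 "cognitive" and 19
  "electrophysiological" features;
* a 4-factor latent structure with blocked loadings: factor 1 loads all
  cognitive features (a general-capacity factor), factor 2 primarily the
  electrophysiological ones, and higher factors are mixed-modality signed
  contrasts (Walsh-style alternating patterns — without the sign
  structure, mixed blocks would be nearly collinear with factors 1–2 and
  unrecoverable);
* patients drawn from a two-component latent mixture with mean difference
  `subgroup_mean_shift` (default signs (−,−,−,+), magnitude 1.5 per axis
  ≈ 3 s.d. total — a realistic clinical separation, deliberately below
  the K-detection threshold above; recovery experiments that need a
  "separated" cohort use 3.5 per axis ≈ 7 s.d.), subgroup-1 proportion
  26/44; controls from a single Gaussian offset on factor 1;
* isotropic feature noise (s.d. 0.5), MCAR missingness hitting ~30% of
  subjects with 1–3 cells each (the mechanism is a modelling choice — the
  motivating study does not report which cells were missing);
* PANSS records whose baseline is subgroup-independent and whose change
  scores differ between subgroups mainly on the negative/general
  subscales, at the means and s.d. of the motivating study's clinical
  table; scores are truncated to their legal ranges (positive/negative
  7–49, general 16–112) and blocks can be missing at configurable rates.

One further option, `equalize_feature_variance`, rescales loading rows so
all features share one marginal variance. Per-feature standardization
then preserves noise isotropy exactly, which matters for a subtle reason:
a strong subgroup separation inflates the variance of the features that
load on the shifted axes, standardization then makes the residual noise
anisotropic, and AIC spends extra dimensions on that anisotropy. Even
with equalized variances, a very strong separation biases AIC upward
through eigenvalue repulsion from the spiked directions — which is why
the end-to-end recovery demonstration pins the dimension grid at the
known latent dimension and lets the mixture stage do the work, while
dimension recovery is demonstrated at the default separation.

What the generator does **not** emulate: raw EEG/EMG traces, item-level
test scores, non-Gaussian feature distributions, outliers, and any
non-MCAR missingness. Passing recovery tests therefore show the pipeline
is correct under its own assumptions, not that those assumptions hold for
any particular clinical data set.

## Simulation sizes used by the test suite

The packaged tests exercise the statistical properties at sizes chosen to
make the suite complete in minutes while keeping each experiment
informative:

* AIC dimension recovery: 100 default cohorts, grid 2–10;
* K selection: 50 null and 50 separated cohorts, K grid 1–3, 5 EM
  restarts per fold fit;
* permutation-test validity: 200 null replicates at n = 16, B = 99
  (nominal 0.05; the add-one p-value is slightly conservative by
  construction);
* imputation-error calibration: a 300-subject cohort with 1–15 masked
  cells per affected subject, so imputation difficulty spans a wide
  range.

## Known limitations

* The AIC parameter count and the imputation conventions (estimator,
  kernel, axis rescaling) are reasoned choices, not unique
  reconstructions; alternatives are exposed as parameters.
* LOO-CV selection of K is conservative at n = 44 (see the detection
  threshold above); genuinely present but modest subgroup structure will
  be reported as K = 1.
* Hard subgroup labels discard assignment uncertainty; the responsibility
  matrix is returned for users who need it.
* The SVM validation tests association, not causation, and 6-week symptom
  change under one drug does not generalize to other treatments.
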