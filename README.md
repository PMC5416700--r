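# mixstrat

Unsupervised stratification of clinical cohorts measured on multimodal
continuous feature batteries — the motivating setting is a first-episode
schizophrenia cohort with 26 neurocognitive and 19 electrophysiological
variables per subject, where symptom-based diagnosis may hide biologically
distinct patient subgroups with different treatment responses.

The pipeline, each stage usable on its own:

1. **Standardization** of features to zero mean / unit variance on the
   complete cases (`standardize()`).
2. **Probabilistic PCA**, x = Wz + μ + ε with isotropic noise, fitted by
   the closed-form maximum-likelihood eigendecomposition; the latent
   dimension D is selected by AIC, −2ℓ + 2m with
   m = pD − D(D−1)/2 + p + 1 (`fit_ppca()`, `select_dimension()`).
3. **Model-based imputation** of subjects with missing cells through the
   PPCA conditional posterior E[z | x_obs], gated by a similarity-weighted
   estimate of the latent imputation error: subjects are included only if
   the estimated error is below 0.05 on latent axes rescaled to s.d. 0.1
   (`impute_cohort()`).
4. **Gaussian mixture subgrouping** of the patients' latent scores (EM,
   full covariances, k-means++ restarts), with the number of subgroups K
   chosen by leave-one-out cross-validated held-out negative
   log-likelihood over K = 1…10 (`fit_gmm()`, `loo_select_k()`).
5. **External validation**: linear soft-margin SVM (C = 100) predicting
   subgroup membership from PANSS symptom subscores (baseline, follow-up,
   and change = baseline − follow-up), leave-one-out accuracy vs the
   majority-class baseline, significance by a 1000-permutation test with
   the add-one p-value (`permutation_test()`).
6. **Univariate characterization**: Welch t-tests and uncorrected 2×2 χ²
   across subgroups for demographics, symptom scores, dose and substance
   use, plus exact recombination of group summaries
   (`characterize_subgroups()`, `welch_t()`, `chi2_2x2()`,
   `pool_summaries()`).

Because the motivating study's patient data are not public, the package
ships a synthetic cohort generator (`generate_cohort()`) producing
cohorts with the assumed structure — blocked modality loadings, a
two-component patient mixture in latent space, MCAR missingness, and
PANSS effects concentrated on the negative/general change scores — with
ground truth retained for every stage, so the whole pipeline is testable
by parameter recovery.

## Worked example

A separated synthetic cohort (97 subjects, two patient subgroups 7 s.d.
apart in latent space), analyzed end to end with the dimension grid
pinned at the generating latent dimension:

```r
library(mixstrat)
cfg <- pipeline_config(
  cohort = cohort_config(seed = 1, subgroup_mean_shift = 3.5 * c(-1, -1, -1, 1),
                         equalize_feature_variance = TRUE),
  D_grid = 4L, K_grid = 1:10, B = 1000, cv_restarts = 10, gmm_restarts = 20,
  seed = 1)
report <- run_pipeline(cfg)
print(report)
```

```
Stratification pipeline run
  97 subjects (72 complete), 45 features
  latent dimension D = 4 (AIC); 25 imputed subjects included, 0 excluded
  subgroups K = 2 (LOO-CV), sizes 28 / 16
  baseline: LOO accuracy 62.5% vs baseline 62.5%, p = 0.4376 (n = 40)
  followup: LOO accuracy 57.6% vs baseline 66.7%, p = 0.7922 (n = 33)
  change: LOO accuracy 71.0% vs baseline 64.5%, p = 0.05295 (n = 31)
```

Reading the output: all 25 subjects with missing cells passed the
imputation error gate, so 97 subjects are analyzed; cross-validation
prefers two patient subgroups (sizes 28/16; the generator planted 28/16
on this seed); and of the three clinical blocks only the treatment-effect
scores (change) predict subgroup membership better than always guessing
the majority class. The CV curve and the confusion matrix behind these
lines are in `report$cv_curve` and `report$validation$change`:

```
LOO accuracy 71.0% vs majority baseline 64.5% (n = 31)
permutation p = 0.05295 (B = 1000)
           predicted
actual      subgroup1 subgroup2
  subgroup1        17         3
  subgroup2         6         5
```

With `out_dir` set, every stage writes its artifact (`aic_curve.csv`,
`ppca_model.json`, `scores.csv`, `imputation_report.csv`, `cv_curve.csv`,
`subgroups.csv`, `validation_*.json`, `table1_report.csv`) plus a
`manifest.json`, and `write_cohort()` / `read_cohort()` round-trip
cohorts as plain CSV. The methods vignette
(`vignettes/stratification-methods.Rmd`) documents the model, the
numerical choices, and what the synthetic benchmarks do and do not show.

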