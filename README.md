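# gpmnet

Graph-theoretical predictive modeling (GPM) of functional brain
connectomes: predict dimensional, reward-related symptoms — anhedonia,
impulsivity, (hypo)mania — from weighted graph measures of a subject's
functional connectivity, cross-sectionally and prospectively, in cohorts
where unipolar and bipolar mood pathology are deliberately pooled.

The package is for network-neuroscience and computational-psychiatry
researchers who have per-subject node time series (or connectomes) in one
or more cognitive states, longitudinal symptom scores, and a medication
covariate, and who want covariate-adjusted, cross-validated individual
predictions with honest statistical validation.

## The model

For subject *i* with connectome-derived graph metrics
*x*<sub>*i*1</sub>, …, *x*<sub>*ip*</sub> (five global measures plus
clustering, local efficiency and betweenness of each reward-circuit ROI,
per state) and covariates **c**<sub>*i*</sub> (baseline symptom scales and
medication load), the GPM inside every cross-validation fold:

1. selects the single metric *x*<sub>·*j**</sub> maximizing
   |cor(*x*<sub>·*j*</sub>, *y*)| over the training subjects
   (winner-take-all; covariates excluded from selection);
2. fits *y* = β₀ + β₁ *x*<sub>·*j**</sub> + **γ**ᵀ**c** + ε by OLS;
3. predicts the held-out subjects from their own values.

Metrics are computed on the positive-weighted graph (negative Fisher-z
connections removed) with shortest paths over reciprocal-weight lengths:
global efficiency is the mean inverse shortest-path length
(1/(n(n−1))) Σ<sub>i≠j</sub> 1/d<sub>ij</sub>, characteristic path length
the mean d<sub>ij</sub>, clustering the Onnela triangle form, local
efficiency the efficiency of the neighbor-induced subgraph, betweenness the
normalized Brandes centrality. (Hypo)mania targets are modeled as
log(x+1).

Validation compares the GPM against the covariates-only **null model** via
MSE_diff = (MSE_null − MSE_GPM)/MSE_null, the **Nadeau–Bengio corrected
repeated k-fold CV t-test** (variance factor 1/(k·r) + n_test/n_train),
and **permutation testing** of the predicted-observed correlation. An
**elastic-net** variant (alpha grid 0–1 by 0.05, covariates unpenalized),
the edge-based **CPM comparator** (p < 0.01 edge selection, network
strength), and a unipolar→bipolar **group-transfer** mode are included,
plus a calibrated **synthetic-cohort generator** so everything runs
without clinical data.

## Worked example

```r
library(gpmnet)

cfg <- synthetic_config(n_subjects = 80, effect_size = 0.3)  # planted: rest L_ACC betweenness -> impulsivity
sc   <- simulate_cohort(cfg, seed = 1)
spec <- gpm_spec("impulsivity", "baseline")

gpm <- cross_validate_gpm(sc$features, sc$cohort, spec)   # LOOCV
nul <- null_model_cv(sc$cohort, spec, features = sc$features)
gpm
#> <gpm_cv> gpm model; target impulsivity_baseline
#>   n = 80 | MSE = 42.836 | r = 0.801
#>   selected (folds): rest:L_ACC_betweenness x80
nul
#> <gpm_cv> null model; target impulsivity_baseline
#>   n = 80 | MSE = 73.667 | r = 0.622
100 * mse_relative_difference(nul$mse, gpm$mse)
#> 41.85
```

The planted feature is selected in all 80 folds and the brain term cuts
prediction error by ~42% relative to baseline symptoms + medication alone.
Formal comparison and inference:

```r
compare_models(sc$features, sc$cohort, spec, scheme = cv_kfold(10, 10, seed = 2))
#> <gpm_comparison> gpm vs null on impulsivity_baseline
#>   MSE_gpm = 43.14 | MSE_null = 73.66 | MSE_diff = 41.42%
#>   corrected CV t(99) = -2.354, p = 0.0205 (k = 10, repeats = 10, n = 80)

permutation_test(sc$features, sc$cohort, spec, n_perm = 500, seed = 3)
#> <gpm_permutation> gpm on impulsivity_baseline
#>   r_obs = 0.801, p = 0.001996 (500 permutations)
```

The negative t favors the GPM (lower loss); the permutation p is the
add-one one-sided tail of the shuffled-target null. `tidy()`/`glance()`
return tibbles for any result object and `autoplot()` draws the
predicted-versus-observed scatter. `run_pipeline()` drives the whole
workflow (connectomes → metrics → models → reports → manifest) from a YAML
config; file formats are plain delimited text throughout.

## Layout

- `R/` — connectome construction, graph metrics, GPM/CPM/elastic-net
  models, validation statistics, synthetic generator, IO, pipeline.
- `tests/testthat/` — unit, property and acceptance suites (oracles in
  `helper-oracles.R`).
- `vignettes/gpm-methods.Rmd` — model, assumptions, design decisions and
  limitations.
- `inst/scripts/run_gpmnet.R` — thin command-line wrapper over
  `run_pipeline()`.
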