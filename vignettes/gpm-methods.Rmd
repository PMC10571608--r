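---
title: "Graph-theoretical predictive modeling: model, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-theoretical predictive modeling: model, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpmnet)
```

## The problem

Clinical assessments struggle to separate unipolar from bipolar mood
pathology and to anticipate who will develop (hypo)manic episodes. A
transdiagnostic alternative is to predict dimensional, reward-related
symptoms — anhedonia, impulsivity, (hypo)mania — directly from the
functional organization of the brain. `gpmnet` implements a brain-based
**graph-theoretical predictive model (GPM)** for exactly this setting: a
modest longitudinal patient cohort with per-subject functional connectomes
in one or more cognitive states (a reward-learning task, rest), symptom
scales at baseline and follow-ups, and a psychotropic medication-load
covariate.

The GPM's premise is that graph measures are *theoretically structured
summations of functional connections*: global efficiency, for instance,
aggregates inverse shortest-path lengths over every node pair. Using such
measures as candidate predictors replaces the atheoretical edge-summing of
connectome-based predictive modeling (CPM) with summaries that name a
mechanism (integration, segregation, centrality) when they win.

## From time series to features

1. **Connectome.** Per subject and state, node-by-time BOLD series (runs
   are demeaned per run and concatenated) give Pearson correlations between
   all node pairs; Fisher's `atanh` transform yields a symmetric `z` matrix
   with zero diagonal. Correlations are clipped at `r_clip = 0.999` before
   the transform — perfectly correlated series otherwise map to infinity;
   the clip caps `|z|` at `atanh(0.999) ≈ 3.8`.
2. **Positive graph.** Negative connections are removed (`w = max(z, 0)`):
   most weighted graph measures require nonnegative weights. Shortest
   paths run over reciprocal lengths `1/w`, the convention of the standard
   brain-connectivity toolboxes (strong connection = short path).
3. **Metrics.** Five global measures — characteristic path length, global
   efficiency, mean clustering, mean local efficiency, mean betweenness —
   plus clustering, local efficiency and betweenness for each
   reward-circuit ROI (bilateral ACC, caudate, putamen, NAc, lateral and
   medial OFC; node indices are a config input, **1-based**). Choices where
   the literature offers variants:
   * clustering is the Onnela geometric-mean-of-triangles form with
     max-weight normalization (values in [0, 1]);
   * local efficiency is the global efficiency of the neighbor-induced
     subgraph with original (restricted) weights — the simpler of the
     published variants;
   * betweenness uses full shortest-path multiplicity counting (tied
     geodesics share credit) and is normalized by `(n-1)(n-2)` so feature
     scales are comparable across graph densities;
   * disconnected pairs contribute zero to efficiencies; characteristic
     path length averages finite pairs only and carries a connectedness
     flag. Dense positive connectomes are essentially always connected —
     these rules exist so degenerate synthetic inputs cannot crash a fold.
   * multi-node ROIs are averaged arithmetically (order-independent).

## The predictive model

For a target symptom at a time point, with feature table `X` (metrics of
both candidate states, columns in canonical state-then-metric order) and
covariates `C` (the *other* baseline scales for a baseline target, all
three baseline scales for a follow-up target, plus medication load):

* **Selection (winner-take-all).** Within the training fold only, the
  single feature maximizing `|cor(x, y)|` with the (transformed) target is
  chosen. Covariates play no role in selection. Absolute correlation is
  used (the direction of a brain-symptom association is not assumed);
  ties break by canonical column order, zero-variance features are
  skipped.
* **Model building.** OLS of the target on `[1, x_selected, C]`.
* **Prediction.** Held-out subjects are predicted from their own feature
  and covariate values. Leave-one-out CV is the default (small cohorts);
  repeated k-fold is available and is required for model comparison.
* **Transform.** (Hypo)mania scores are right-skewed; `log(x+1)` is
  applied before selection and fitting, and MSE and r are reported on
  that modeling scale throughout.
* **Missing data.** Pairwise deletion per model: subjects missing the
  target, any covariate, or any candidate feature are excluded — so each
  analysis has its own N, as in real longitudinal cohorts.
* **Minimum fold size.** 10 complete training cases (an OLS-stability
  guard; configurable).

The **null model** is the identical cross-validated regression without the
brain term — baseline symptoms and medication load only. The GPM's added
value is quantified by `MSE_diff = (MSE_null − MSE_GPM)/MSE_null`.

### Statistical validation

* **Corrected repeated k-fold CV t-test.** Per-fold MSE differences
  between two models evaluated on *identical* folds and subjects feed a
  paired t-test with the Nadeau–Bengio variance correction
  `(1/(k·r) + n_test/n_train)`. The naive resampled test ignores the
  positive correlation of fold losses induced by overlapping training
  sets and is grossly anti-conservative — our calibration suite measures
  a ~0.05 rejection rate for the corrected test versus >0.5 for the naive
  one under a no-difference null. Because the correction's variance term
  is undefined for single-subject test folds, model comparison always
  runs on repeated k-fold (default k = 10, 10 repeats) even when
  prediction is reported under LOOCV.
* **Permutation inference.** Targets are shuffled among included subjects
  (features and covariates travel with their subject), the full CV
  pipeline is re-run per permutation, and the one-sided p-value uses the
  add-one rule `(1 + #{r_perm ≥ r_obs})/(1 + n_perm)`; the default is
  10,000 permutations. Note what the test tests: shuffling severs the
  target's association with the covariates too, so it is calibrated under
  the *full* exchangeability null. A cohort whose covariates genuinely
  predict the target is (correctly) rejected even without any brain
  effect.
* **Elastic-net variant.** All features enter a penalized regression;
  within each outer training fold an inner CV searches alpha from 0 to 1
  in steps of 0.05 (21 values) crossed with an automatic lambda path, and
  the error-minimizing pair is refitted. Covariates are unpenalized —
  they are confound adjustments, not selectable predictors.
* **CPM comparator.** Edges correlated with the target at p < 0.01 within
  the training fold form positive- and negative-feature sets (evaluated as
  separate models; a combined two-predictor mode exists but is off by
  default); summed z over the selected edges is the predictor, with the
  same covariates, transform and CV machinery. Edge p-values use the
  t-distribution transform of Pearson r. A fold in which no edge survives
  selection falls back to the covariates-only model rather than failing —
  at p < 0.01 and small training sets this is a real occurrence. Edge
  selection excludes covariates, mirroring the GPM's selection step.
* **Group transfer.** Selection and fitting once on the unipolar group,
  prediction on the bipolar group (with a companion null), probing whether
  the association is transdiagnostic rather than group-driven.

## The synthetic cohort generator

No clinical fMRI data ship with the package; every pipeline stage is
instead exercised on synthetic cohorts with known ground truth.

**Connectomes.** Node time series follow a latent block-factor model:
nodes load on their community's factor plus a weak global factor, with
Gaussian noise. Between-subject variation enters through connectivity
gains at three scales — per-block within-community gains, a between-community
(global-factor) gain, and per-node gains — each mixed from a shared subject
trait and a state-specific part (cross-state correlation 0.4), so task and
rest connectomes of one subject are similar but not identical. This
heterogeneity is what makes the generator a meaningful test bed: with a
single subject-level gain, all graph metrics collapse onto one latent
dimension and no selection experiment can distinguish them.

**Symptoms.** Three correlated scales (shared mood factor, pairwise
r ≈ 0.35) at baseline, 3 and 6 months; follow-ups autocorrelated with
baseline (ρ = 0.6, so baseline scores capture most follow-up variance, as
in real symptom trajectories); anhedonia- and impulsivity-like scales live
on questionnaire-total scales, while the mania-like scale is generated on a
log scale and exponentiated so that `log(x+1)` is its natural transform.
Visit-level missingness defaults mirror typical attrition (2% baseline,
10% at 3 months, 16% at 6 months); the default cohort is 80 subjects with
a 22/80 bipolar fraction.

**Planting.** The target is composed as
`β · standardized(brain score) + Σ γ · covariates + ε`, with `β`
calibrated against the empirical variance of the non-brain part so the
brain term explains exactly `effect_size` of target variance (verified to
converge at large n). The brain score is either a named graph metric
computed from the generated connectomes (metric mode) or a latent written
additively into a fixed random edge set (edge mode — the regime CPM is
built for). The default planted effect is the betweenness centrality of
the left ACC at rest predicting baseline impulsivity with `effect_size
= 0.2`.

Two design notes discovered while building the generator, relevant to
interpreting recovery experiments:

* *Metric twins.* Some metric pairs are near-monotone transforms of one
  another in any realistic connectome population (global efficiency vs
  characteristic path length; clustering vs local efficiency of the same
  node). Exact-name recovery of a planted *integration* metric is
  therefore bounded by intrinsic collinearity, not by the selection
  machinery. Nodal betweenness has node-specific variance (max competitor
  |r| ≈ 0.26 in our population checks), which is why the default planted
  feature is a centrality measure — itself echoing the kind of nodal
  centrality association the method is designed to find.
* *What passing does not show.* The generator has no hemodynamics, motion,
  scanner drift or site effects, its communities are clean blocks, and its
  symptom model is linear-Gaussian by construction. Recovery and
  calibration results validate the *machinery* (no leakage, correct error
  control, identifiable planting), not performance on real fMRI.

## Problem sizes used in the validation suite

The shipped tests and the acceptance script run: oracle equivalence on 200
random graphs (n ≤ 8) against independently coded Floyd–Warshall /
geodesic-counting / triangle-product oracles (agreement within 1e-9);
corrected-test calibration on 500 simulated cohorts (k = 10, 10 repeats);
permutation calibration on 200 null cohorts at 200 permutations each;
recovery on 100 planted cohorts (n = 80, brain R² = 0.3, LOOCV); plus the
leakage canary and the GPM-vs-CPM regime contrast. These sizes were chosen
so the whole suite completes on a single CPU in minutes while keeping
Monte-Carlo error well inside the asserted bounds.

## Known limitations

* Inputs are preprocessed node time series or connectomes; no
  neuroimaging-format ingestion or parcellation.
* Only linear models; no interaction terms, no site harmonization.
* The corrected CV test is approximate (no exact finite-sample null);
  its calibration is demonstrated, not proven.
* Betweenness normalization and the Onnela clustering form are choices
  among published variants; comparisons with toolboxes using other
  conventions require matching the convention first.

## A worked example

```{r example, eval = FALSE}
cfg <- synthetic_config(n_subjects = 80, effect_size = 0.3)
sc <- simulate_cohort(cfg, seed = 1)
spec <- gpm_spec("impulsivity", "baseline")

gpm <- cross_validate_gpm(sc$features, sc$cohort, spec)
nul <- null_model_cv(sc$cohort, spec, features = sc$features)
glance(gpm)
mse_relative_difference(nul$mse, gpm$mse)

cmp <- compare_models(sc$features, sc$cohort, spec,
                      scheme = cv_kfold(10, 10, seed = 2))
perm <- permutation_test(sc$features, sc$cohort, spec, n_perm = 1000,
                         seed = 3)
autoplot(gpm)
```
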