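---
title: "Sex-stratified brain-age modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-stratified brain-age modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroage)
```

## The model

Brain-age estimation treats chronological age as a supervised learning
target: a regressor is trained on regional structural MRI features
(cortical thickness and volume per Desikan-Killiany region, plus
subcortical volumes — 183 features in the default parcellation) of a large
reference cohort of cognitively unimpaired adults, and applied to new
subjects. The residual structure of the prediction is the object of
interest: after correcting the systematic age bias of the prediction, the
**brain-age delta** (corrected predicted age minus chronological age, in
years) summarises whether a brain looks older or younger than its owner's
age, and is validated against biomarkers of Alzheimer's disease (AD) and
neurodegeneration.

The learner is a gradient-boosted ensemble of depth-limited regression
trees with squared-error loss, L1/L2 leaf-weight regularisation, a minimum
split gain, shrinkage, and per-tree row/column subsampling (`gbt_fit()`).
Because no boosted-tree library is available in the supported R stack, the
package carries its own implementation (exact greedy splits, level-wise
growth) in C++. Two consequences matter for users:

* **Determinism.** All subsampling randomness is derived from a single
  `seed` argument through R's RNG; refitting with identical data and seed
  is bit-identical, and fitting never perturbs the caller's RNG stream.
* **Attributions.** Per-region attributions (`gbt_shap()`) use the exact
  path-dependent tree-Shapley recursion with the conditional-expectation
  value function defined by training-sample node covers. The test suite
  verifies the recursion against a brute-force enumeration of all feature
  coalitions, and local accuracy (base value + row sum = prediction) is
  asserted on every use.

Separate models are trained for females and males (`fit_sex_stratified()`),
since regional aging trajectories differ by sex; prediction routes each
subject to their sex's arm and refuses feature tables whose column set or
order differs from training.

### Hyperparameters

`default_hyperparameters()` returns the per-sex optima found by sequential
model-based optimization under 10-fold, 10-repeat cross-validation on the
reference training cohort (depth 4, learning rate 0.03, 800/850 trees,
and sex-specific regularisation). `tune_hyperparameters()` re-runs such a
search: the default "smbo" method spends half its budget on uniform
exploration of the stated ranges and the rest on Gaussian perturbations
around the incumbent (a deliberately simple sequential strategy — the
approach, not a specific optimizer library, is what matters); a "grid"
method is the exhaustive fallback. The CV objective defaults to MAE with
an RMSE option, since the original objective is not stated.
`fast_hyperparameters()` (300 trees, learning rate 0.08) is the profile
used throughout the simulations and tests; it gives up a small amount of
MAE for an order of magnitude of wall-clock.

### Age-bias correction

Predictions regress toward the training mean. With `Y = alpha * age +
beta` fitted by OLS (`fit_age_bias()`), the correction is

    corrected = predicted + (age - (alpha * age + beta))
    delta     = corrected - age

Algebraically `delta` is the residual of the prediction from the bias
line, so fitting the bias model on the sample being corrected makes delta
*exactly* orthogonal to age — this is asserted at `1e-10` in the
acceptance suite. The literature is ambiguous about where `alpha, beta`
should come from; `brain_age_delta()` defaults to fitting within each
evaluation cohort (which also removes cohort-level offsets) and accepts a
frozen reference model via `bias=` for the alternative reading. Neither is
claimed canonical.

## Preprocessing

Volumes are residualized on total intracranial volume (TIV) and
scanning-site indicators, thicknesses on site only, by per-cohort OLS
(`residualize()`); features are then z-scored feature-wise within cohort
with the sample SD, n−1 (`zscore_within_cohort()`); the denominator
convention is ours, the source does not state one. Site is one-hot coded
against the most frequent site; single-subject sites are pooled into the
reference with a warning. Residualization is idempotent and its residuals
orthogonal to the covariates (property-tested). Residualization models can
be frozen and applied to new subjects (`apply_residualization()`), e.g.
for deployment. Residualization is sex-agnostic: sex enters only at model
training, which is one of the genuinely open design points; we chose the
pooled fit because the downstream sex-stratified models consume the same
harmonized table.

## Biomarker staging and transforms

Amyloid status uses per-cohort cut-offs shipped as editable YAML
(`load_cutoffs()`): CSF amyloid-beta42 below 1098 pg/mL (ALFA+/EPAD
assays) or 880 pg/mL (ADNI) is A+; amyloid-PET above 17 Centiloids
(OASIS) is A+; CSF p-tau181 above 24 pg/mL is T+. **Boundary convention:**
abnormality requires strictly passing the cut-off; a value exactly at the
cut-off is normal. The source never states boundary handling; the choice
is documented here and in the micro-example tests. AT stages cross the two
statuses; A−T+ ("non-AD pathologic change") subjects are excluded from the
association analyses (`exclude_non_ad_change()`), with a per-cohort count.

NfL (CSF and plasma) is natural-log transformed and z-scored within
cohort — all subjects of the cohort as reference, since the source does
not say whether the CU-only subset was used. WMH volumes are natural-log
transformed and residualized on TIV. The aging-signature composite is the
surface-area-weighted mean cortical thickness over aging-vulnerable
regions; several of the published labels ("caudal insula", "medial
superior frontal") have no exact Desikan-Killiany equivalent, so
`aging_signature_weights()` documents our label correspondence (insula,
superiorfrontal, pericalcarine for calcarine, fusiform, cuneus,
parsopercularis + parstriangularis for the inferior frontal gyrus,
precentral) with synthetic template areas of realistic relative magnitude.
This mapping is an interpretation and is user-overridable; per-subject
measured areas can be supplied as a weight matrix. Longitudinal change is
`(V2 - V1) / interval`, per year.

## The association battery

Each validation variable is tested by OLS of standardized delta on the
(standardized, if continuous) variable plus chronological age and sex as
covariates (age only within sex strata). The standardization recipe —
z-score the outcome and continuous predictors, leave dummies unscaled so
their coefficients are in outcome-SD units — is our choice, stated here
because "standardized beta" is otherwise underdetermined. Categorical
predictors (amyloid status, AT stage, APOE category with ε33 reference,
ε2 = {ε22, ε23}, ε4 = {ε34, ε44}, ε24 separate) are handled as
ANCOVA-style adjusted contrasts; Cohen's d per contrast divides the
adjusted difference by the model's **residual** SD (the quoted "estimated
standard deviation" reading; a pooled raw SD would give smaller d).
Continuous predictors report Cohen's
f² = (R²_full − R²_reduced)/(1 − R²_full). Interaction tests center
continuous variables before forming products and always keep main
effects. `run_battery()` executes all specs across strata, treats the
whole run as a single Benjamini-Hochberg family (the family size is
emitted so a particular multiplicity context — e.g. the published 125
tests — can be replicated), continues past per-spec failures, and logs
them. Complete-case analysis per test, with per-test N in the output.
Extreme-delta selection uses linear-interpolation percentiles
(`quantile` type 7), another convention the source leaves open.

## The synthetic world

`generate_cohort()` emulates the multi-cohort data structure with known
ground truth; it is first-class, tested code, not a fixture. Its stated
world:

* Age uniform on [44, 81] (the training cohort's range), 52% female,
  3 scanning sites, 183 regions, sex-dependent TIV (females ~1350 cm³,
  males ~1550 cm³).
* A latent per-subject aging acceleration δ ~ N(0, σ_δ²), σ_δ = 5 years
  by default, shifted additively by APOE genotype (frequencies give ~30%
  ε4 carriers). No source states σ_δ; the default was calibrated once so
  that the held-out prediction quality of the default world falls in the
  realistic envelope (Pearson R between prediction and age ≈ 0.85–0.9,
  MAE ≈ 4–5 y — real multi-cohort studies report R ≈ 0.45–0.73 and MAE
  4–7 y) rather than the near-perfect fit a noise-free linear world
  produces, while the acceleration remains recoverable.
* A per-subject shared noise term (default 0.02 mm on the thickness
  scale, volume-scaled for volumes) adds brain-level variability that no
  amount of across-region averaging removes — the crude stand-in for
  spatially correlated measurement and biological noise.
* Every ROI feature is `a_r + b_r(age+δ) + c_r·sex + d_r(age+δ)·sex +
  s_site,r + k_r·TIV [volumes] + shared + noise`: thickness slopes
  −0.003 to −0.012 mm/y, volumes ±0.2–0.6 %/y (ventricles and CSF spaces
  grow), measurement noise 0.10 mm (thickness) and 5% (volumes).
* Biomarkers load on δ/σ_δ and an independent latent pathology score at
  configurable standardized effects, on the log scale for CSF analytes,
  NfL and WMH (all right-skewed; generating them normal at the published
  SDs would produce negative concentrations — a deliberate deviation
  documented here), and on the raw scale for Centiloids. Diagnosis (MCI)
  is a threshold on the pathology score (~15% MCI).
* `generate_followup()` advances each subject by an effective interval
  `interval · (1 + g·δ)` with fresh noise; `interval = 0` is the
  identity (allowed despite the nominal positivity requirement, because
  the identity limit is useful for testing).

What the generator does **not** emulate: realistic spatial covariance
between regions (only a crude shared-noise term), scanner software or
atrophy-pattern nonlinearity, longitudinal attrition, or cohort-specific
assay drift. A green test therefore establishes that the pipeline's
machinery recovers the quantities its own generative model encodes — not
that the same effect sizes would be observed in any real cohort.

## Importance significance: two modes, one default

The stability of a region's importance is assessed by retraining on
resampled data (`stability_significance()`). The published description
mixes "permutations" with subsampling, so both readings are implemented:

* **permutation-null** (default): per replicate, an 80/20 split is drawn,
  the candidate region is permuted across training subjects, the model
  retrained, and the region's mean |attribution| on the holdout recorded;
  the empirical p-value `(1 + #{null ≥ observed})/(1 + B)` (never exactly
  zero) is Bonferroni-corrected over the tested regions. Only this mode
  yields a calibrated p-value, which is why it is the default and the
  mode used in the acceptance calibration (B = 200, scaled down from the
  reference 1,000).
* **subsample-stability**: no permutation; a region is flagged when the
  sign of its replicate mean attribution agrees with the full-data sign
  in ≥95% of replicates. A caveat discovered during validation: when
  evaluation data follow the training distribution, the signed per-region
  mean attribution is close to zero by construction (attributions are
  centered at the model's expected prediction), so this mode has
  essentially no power in the synthetic world; it is retained for
  completeness and tested only for mechanical soundness and
  conservatism.

Whether significance should be assessed on signed or absolute mean
attribution is genuinely undeterminable from the source; magnitude is
used for ranking and the permutation null, signed values for direction.

## Numerical choices and degenerate inputs

* Split finding uses midpoint thresholds between distinct sorted values;
  ties are broken by first-best in feature order (deterministic).
* Constant features z-score to 0 and are flagged; constant age errors.
* Perfect association fits report `effect_size = Inf` rather than a
  division-by-zero error; empty strata and collinear designs
  (condition number > 1e10) are errors, which `run_battery()` converts
  to logged skips.
* Replicate seeds in resampling procedures derive from a master seed via
  a counter; everything is reproducible from one integer.

## Limitations

The learner is intentionally compact (exact greedy, no histogram
binning, no missing-value routing); training cohorts of ~2×10⁴ subjects
and 183 features fit in seconds-to-minutes, but this is not a
general-purpose production booster. Attribution assumes the
path-dependent value function; with strongly correlated regions,
Shapley attributions spread credit in ways that need not reflect
biology; an interventional (background-dataset) value function is a
known alternative but is not implemented — the path-dependent recursion
is the one the attribution literature for tree ensembles established
first, and the one our exhaustive-coalition oracle verifies. The association battery is cross-sectional; the
longitudinal change score enters as an ordinary predictor, not through a
mixed model.
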