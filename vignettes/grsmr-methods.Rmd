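---
title: "Methods: genetic risk score Mendelian randomisation in grsmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetic risk score Mendelian randomisation in grsmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Observational associations between a modifiable exposure (here, an
adiposity-like continuous trait) and a binary disease outcome are vulnerable
to confounding. Mendelian randomisation (MR) uses genetic variants as
instrumental variables: because alleles are assigned at conception, a
genetic risk score (GRS) that predicts the exposure should be independent of
lifestyle confounders, and its association with the outcome isolates the
causal pathway — provided the instrument affects the outcome only through
the exposure (the exclusion restriction).

`grsmr` implements the full analysis chain for this design: phenotype
derivation from ICD-style diagnosis records, allele-harmonised GRS
construction, one-sample two-stage MR, summary-data two-sample MR (IVW,
MR-Egger, multivariable MR), sliding-window non-linear MR, and a stepwise
confounder-attenuation search — together with a synthetic-cohort generator
with known causal structure, so that every estimator can be validated
against ground truth.

## The generative model

The simulator (`sim_config()`, `simulate_cohort()`) draws, for participant
$i$ with dosages $g_{ij} \sim \mathrm{Binomial}(2, \mathrm{maf}_j)$:

$$X_i = \textstyle\sum_j \beta_j g_{ij} + \gamma_x U_i + \varepsilon_i,
\qquad U_i \sim N(0,1),\ \varepsilon_i \sim N(0, \sigma^2)$$

$$Y_i \sim \mathrm{Bernoulli}\!\left(\mathrm{logit}^{-1}\!\big(\alpha_0 +
\theta_{s(i)} X_i + \theta_q X_i^2 + \gamma_y U_i +
\textstyle\sum_j \pi_j g_{ij}\big)\right)$$

where $\theta_{s(i)}$ is the causal log-odds slope (optionally multiplied
per stratum $s(i)$ for effect modification), $\theta_q$ an optional
quadratic term for the non-linear analyses, and $\pi_j$ optional direct
(pleiotropic) SNP effects. Cases receive invasive diagnosis codes with
dates; a configurable fraction is dated before the fixed baseline
(2008-01-01) to exercise prevalent-case filtering, and a sliver of non-cases
receives in-situ-only codes to exercise exclusion. Menopause fields and
seven workplace-chemical questionnaire answers are attached so the
phenotype-derivation rules run on realistic columns.

The latent confounder is stored in the phenotype table as
`.oracle_confounder`, used by tests only; analysis code never reads it. A
measured proxy (`biomarker` = $U$ + noise of SD 0.5, reliability 0.8) is
also stored — it plays the role of a recorded covariate that the confounder
search can legitimately discover.

### The reference world

`sim_config_standard()` fixes the conditions used throughout the validation
suite, chosen once and not revisited:

* n = 100,000, 30 independent SNPs with MAFs evenly spaced in (0.05, 0.45);
* per-allele effects sized so the instrument explains 2% of exposure
  variance (a realistic GRS strength for an anthropometric trait;
  first-stage F ≈ 2,000);
* confounder slopes 0.5 on both exposure (SD units) and outcome (log-odds);
* residual SD chosen to complete a unit exposure variance;
* baseline intercept `qlogis(0.02)` for ~2% outcome prevalence.

The rare-outcome regime matters because the odds ratio is non-collapsible:
only when the outcome is rare does the marginal logistic slope approximate
the conditional causal effect, so recovery tests target ≤5% prevalence; at
common prevalences tests assert only directions and orderings.

## Phenotype rules

Case labelling is by ICD code prefix: an invasive-code record (e.g. C50,
which also matches C509) makes a case; an in-situ-only record (D05/D075)
excludes the participant; anyone else of the right sex is a control. Prefix
matching is the inclusive reading of a bare three-character code. Incident
filtering removes cases whose earliest invasive diagnosis predates
baseline; cases with no date cannot be classified and are removed with a
warning. Menopause strata compare the age at first diagnosis with the
reported menopause age for cases (baseline status for controls);
indeterminate participants become `unknown` and are dropped from stratified
fits but kept in the pooled analysis. The chemical-exposure stratum is
`frequent` iff any of the seven workplace questions was ever answered
"Often" or "Sometimes". Variant QC keeps MAF ≥ 0.01 and, for imputed
variants, INFO ≥ 0.8.

Standardisation to mean 0 / SD 1 is computed per sex on the post-exclusion
analysis sample. The reference text does not state whether standardisation
preceded or followed the exclusions; computing it on the analysis sample is
the choice here because it makes "per SD" refer to the population actually
analysed.

## Instruments and harmonisation

A GRS is the weighted sum of effect-allele dosages. Weights come either
from an external instrument file or, mirroring the body-fat-percentage
case where no sex-stratified external weights exist, from in-sample
per-variant regressions computed in cancer-free participants only
(`estimate_weights_in_sample()`), per sex, to avoid outcome-driven
selection.

Dosage alignment (`align_dosages()`) and summary-statistics harmonisation
(`harmonise()`) share one policy: identical alleles pass through; swapped
alleles reflect the dosage (2 − d) or flip the outcome beta; strand
complements are resolved first; palindromic variants (A/T, C/G) carry no
strand information and are resolved by allele frequency only when both
sides are at least 0.08 from 0.5 (the conventional 0.42/0.58 bounds),
otherwise dropped with a logged reason. The reference analysis does not
state its harmonisation policy; this one is the standard convention in
summary-data MR software, and is labelled as a convention, not a
reproduction. Missing dosages contribute `weight × 2 × eaf` (mean
imputation) to avoid score bias from missingness.

Instrument strength is reported as $R^2$ and $F = (n-2)R^2/(1-R^2)$; $F <
10$ tags a weak-instrument warning in the fit diagnostics but does not
abort.

## One-sample MR

The two-stage estimator regresses the exposure on the GRS (stage 1) and
the outcome on the stage-1 fitted values plus age at baseline (stage 2,
logistic). The stage-2 covariate set is age only, matching the main
analysis being emulated; principal components and array enter only the
non-linear MR's residual model, where they are stated. Confidence
intervals come from a percentile bootstrap (the CI type is not named in
the reference; percentile is the assumption-light default), resampling
participants and refitting both stages per replicate — 10,000 replicates
by default, scaled down in experiments. More than 5% non-converging
replicates is an error. The exclusion-restriction check regresses the
outcome on the GRS adjusting for the exposure and age; a significant GRS
coefficient flags pleiotropy. Stratified fits rerun the two-stage
estimator per stratum and are compared with a fixed-effect Cochran's Q
($I^2 = \max(0, (Q-\mathrm{df})/Q) \times 100$).

## Two-sample MR

IVW is the weighted regression of outcome betas on exposure betas through
the origin with weights $1/\mathrm{se}_y^2$; the multiplicative
random-effects SE scales the fixed-effect SE by $\max(1,
\sqrt{Q/(k-1)})$. The floor at 1 is an explicit choice — underdispersion
never shrinks the SE — because the emulated software names the model but
not the floor convention. MR-Egger adds a free intercept after reorienting
every variant to $b_x \ge 0$ (flipping $(b_x, b_y)$ jointly), which is
what lets the intercept capture directional pleiotropy; its SEs use the
same scaling with $k-2$ df and t-based p-values. MVMR regresses outcome
betas on the matrix of exposure betas (no intercept, same weights) over
the union of instruments; variants missing any exposure beta are dropped,
de-duplication is by variant identity only, and every MVMR result carries
an explicit "no LD pruning" flag because the LD-based pruning of the
emulated workflow requires a reference panel that is out of scope here.

## Non-linear MR

Participants are ordered by instrument-free residuals — the residuals of
exposure on GRS, age, age², optional leading principal components and
array indicator — and a window of fixed size slides along that order
(defaults 50,000 / step 1,000; scaled down in tests). The per-window
localized estimate is the within-window GRS-outcome logistic coefficient
(adjusted for age) divided by the GRS-exposure slope. The emulated
analysis does not print its per-window estimator, so both denominator
scopes are implemented: the whole-sample stage-1 slope is the default
(per-window slopes can approach zero and destabilise the ratio), and
`denominator = "window"` gives the fully local variant. Overlapping
windows share participants, so their estimates are correlated;
`profile_trend()` therefore computes its null-trend z-statistic on the
independent sub-profile (windows spaced ≥ one window apart) while the
full-profile slope is reported for direction only.

## Confounder search

Candidates with more than 1,000 non-missing values that associate with
both exposure (linear, p < 0.05) and outcome (age-adjusted logistic,
p < 0.05) are eligible; categorical candidates are expanded to per-level
indicators first. Greedy forward selection then adds, at each step, the
candidate that minimises the exposure's |ln(OR)|, accepting only
reductions larger than a relative tolerance (default 1%) — the stop
criterion is not stated in the reference and relative-reduction is the
package's choice; ties break lexicographically so traces are
deterministic, and each model is fit on its own complete cases with n
logged. |ln(OR)| (absolute value) is the tracked objective; the signed
value is reported in the trace so the "does not cross zero" behaviour can
be inspected.

## Numerical and reproducibility choices

* Logistic fits in hot paths (bootstrap, per-SNP outcome regressions,
  per-window fits) use a compiled IRLS with the linear predictor clamped
  at ±30 and working weights floored at 1e-10; user-facing single fits
  match `stats::glm` to numerical precision.
* One master seed streams into labelled substreams
  (`substream_seed(seed, label)`), so each stage is independently
  reproducible and full-pipeline reruns are byte-identical (no timestamps
  in result tables).
* Degenerate inputs error early with named causes: zero cases, zero-variance
  GRS, collinear covariates, n smaller than the window, unresolvable
  alleles beyond 50% of an instrument set.

### Validation bands

The recovery checks compare medians of estimates across 20 seeded cohorts
with fixed tolerance bands. In the reference world the per-seed sampling SD
of the two-stage and IVW estimators is about 0.16 (an unavoidable
consequence of a 2%-variance instrument and a 2%-prevalence outcome at
n = 100,000), which puts the SD of a 20-seed median near 0.045. A ±0.05
band around the true effect is therefore tight: a perfectly calibrated
estimator passes it only ~three times in four. The seeds are fixed a
priori and are never adjusted to the outcome, so an occasional red on that
single check reflects the band's tightness, not a defect — the
accompanying bootstrap-coverage and null-calibration checks are the
discriminating ones.

## What a green test does and does not establish

The simulator draws independent SNPs in Hardy-Weinberg equilibrium with a
single Gaussian confounder and no LD, no population structure, no
genotyping error, and no selection into the cohort. Green recovery tests
therefore establish that the estimators are correctly implemented and
calibrated under the stated model — not that the substantive conclusions
of any particular cohort analysis are right, and not that the method is
robust to violations (LD between instruments, selection bias,
non-Gaussian confounding) that the generator deliberately does not
produce. Reported real-data numbers from the emulating literature are
orientation points only and are never test targets.
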