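---
title: "Trabecular bone texture and the prediction of knee osteoarthritis progression: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trabecular bone texture and the prediction of knee osteoarthritis progression: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope

`tbtprog` implements an analysis pipeline for predicting radiographic knee
osteoarthritis (KOA) progression from trabecular bone texture (TBT) on
knee radiographs: directional multi-scale Hurst-exponent descriptors of the
tibial subchondral plateau, longitudinal delta features, scenario-based
joint-space-narrowing (JSN) outcomes, and a grid of 18 logistic-regression
models evaluated by repeated stratified cross-validation with stepwise-AIC
feature selection and paired (DeLong) ROC comparison. Real cohorts of this
kind (e.g. the Osteoarthritis Initiative) are access-restricted, so the
package also ships simulators — exact fractional Brownian motion (fBm) and
fractional Brownian sheet generators, and a longitudinal cohort generator
with calibrated progressor prevalence — that provide known ground truth for
every stage. This vignette documents the models, the tunable parameters,
and the design decisions taken where the procedure left genuine freedom.

## The texture model and estimator

Radiographic trabecular texture is treated as a self-similar random field.
A 1-D intensity profile $X(t)$ with Hurst exponent $H \in (0,1)$ satisfies
$E[(X(t+u) - X(t))^2] \propto u^{2H}$; the fractal dimension of the profile
is $2 - H$. The package estimates $H$ with the quadratic-variations
estimator built on *second-order* increments,

$$V(u) = \frac{1}{M}\sum_t \left(X(t + 2u) - 2X(t + u) + X(t)\right)^2,
\qquad M = n - 2u ,$$

followed by an ordinary least-squares fit of $\log \bar V(u)$ on
$\log u$ across the lag set; $\hat H$ is half the slope. Second-order
increments are used because they annihilate affine trends exactly and keep
the estimator valid over the whole range $H \in (0,1)$, where first-order
increments lose consistency for $H$ near 1. Two consequences are exploited
as exact tests: $V(u) = 0$ on any affine profile, and $\hat H$ is invariant
under affine intensity maps $aX + b$ (the log-variance curve shifts by
$2\log|a|$, leaving the slope unchanged).

Design choices with no canonical answer, and what this package does:

* **Pooling.** $V(u)$ is averaged across all profiles of an ROI *before*
  the log–log fit (default), which stabilises the small-lag variance;
  per-profile estimation with averaging of $\hat H$ is available via
  `per_profile = TRUE`.
* **Fit weights.** The log–log fit is unweighted OLS, matching the plain
  form of the estimator; weighted variants are out of scope.
* **Out-of-range estimates.** $\hat H \notin (0,1)$ is returned as-is and
  flagged (`out_of_range`), never clipped; a zero $\bar V(u)$ (constant or
  affine texture) yields a `degenerate` flag and `NA`. Flags become missing
  values at the modelling stage, where they are mean-imputed within the
  training fold.
* **Lag sets.** The analysis runs at two scales. Defaults: `micro` =
  \{1, 2, 3, 4\} px; `milli` = the pixels nearest to 0.3–1.2 mm given the
  pixel spacing (falling back to \{4, 8, 12, 16\} px when spacing is
  unknown). Both sets are configurable; the maximum lag must not exceed a
  quarter of the ROI side.

## ROI geometry

Sixteen square ROIs cover the tibial subchondral plateau, placed from the
two proximal-tibia extremity landmarks (landmark detection itself is an
input, not part of this package). The published sources fix the count (16)
and the medial/central/lateral compartment structure but not the exact
arrangement; the package uses 8 columns × 2 rows stacked immediately distal
to the inter-landmark baseline, ROI side = ⌊baseline/8⌋ px, with any
leftover width left as a margin on the lateral side (deterministic
rounding). On the canonical orientation, columns 0–2 are lateral, 3–4
central, 5–7 medial (6/4/6 ROIs). All of these are `place_rois()`
parameters.

Left knees are mirrored to a canonical orientation (medial side on the
right) so compartment labels are laterality-independent. When the baseline
is not horizontal the image is rotated about the baseline midpoint with
bilinear resampling before extracting axis-aligned squares — rotation
rather than oblique sampling keeps the row/column directions aligned with
the anatomical horizontal/vertical axes that the directional estimator
needs. Each ROI is analysed in both directions at both scales:
16 × 2 × 2 = 64 descriptors per knee, named
`tbt_roi<00–15>_<h|v>_<micro|milli>`.

## Synthetic textures

`simulate_texture()` generates a *fractional Brownian sheet*: the
increment field has the separable product covariance of two fractional
Gaussian noises and is simulated exactly by two-dimensional circulant
embedding, then integrated along both axes. Every row profile is then an
exact fBm with `h_horizontal` (up to a row-dependent scale factor that the
scale-invariant estimator ignores) and every column profile an exact fBm
with `h_vertical` — which is precisely why this construction was chosen
over spectral-synthesis approximations: it gives exact per-direction
targets for estimator validation. A 32-px buffer is synthesised and
cropped so no degenerate zero boundary profiles survive, and the field is
affinely mapped to the requested mean intensity ± amplitude.

This is a statistical stand-in, not a physical bone model: it reproduces
directional self-similarity, but none of the projection physics, beam
hardening, soft-tissue background or grading noise of real radiographs.
Passing tests on these textures validate the estimator and pipeline
plumbing, not clinical performance.

The 1-D generator (`simulate_fbm_profile()`) uses the Davies–Harte
circulant embedding of fractional Gaussian noise, which is exact in
distribution; an embedding with materially negative eigenvalues raises an
error rather than silently approximating (for fBm the embedding is
non-negative definite, so this guards numerical pathology only).

## Synthetic cohorts

`simulate_cohort()` emulates the longitudinal structure the analysis
assumes: two knees per participant; age/gender/BMI and per-knee WOMAC pain
at baseline (V0) and 24 months (V3); baseline Kellgren–Lawrence (KL)
grades; medial and lateral JSN grades (JSNM/JSNL, 0–3) at V0/V3/48 months
(V6) moving by at most +1 per interval and never decreasing (matching
OARSI granularity and the ">0 increase" outcome logic); and the 64 texture
descriptors at V0 and V3.

A latent progression propensity $\eta = \beta_0 + \sum_j \beta_j z_j$
drives the medial V3→V6 transition via $\Pr = \mathrm{logit}^{-1}(\eta)$
(knees already at the JSNM ceiling cannot progress). The features $z_j$
are standardised against fixed population constants (age: (age−61)/9; BMI:
(BMI−28.5)/4.8; grades centred; gender as a centred female indicator), so
coefficients keep their meaning at any cohort size. Two latent composites,
`tbt_v0_composite` and `delta_tbt_composite`, load on a designated
descriptor subset (default: vertical-direction descriptors of the medial
and lateral compartments, echoing the observation that vertical-direction
texture and non-central ROIs carry the predictive signal) with loadings
equal to the per-descriptor noise (0.04 at baseline, 0.03 for deltas), so
a single descriptor is weakly informative but the subset jointly recovers
the composite.

Default conditions, chosen once as the study conditions: target
prevalence 0.12 (comparable selections observe roughly 9–12% progressors);
effect coefficients `delta_tbt_composite` 1.0 (dominant),
`tbt_v0_composite` 0.4, KL 0.35, baseline JSNM 0.35, BMI 0.15, age 0.1;
background +1 transition rates 0.04 (JSNM) and 0.03 (JSNL) for V0→V3 and
0.01 for lateral V3→V6; baseline KL distribution (0.15, 0.15, 0.35, 0.25,
0.10) over grades 0–4; small completely-at-random missingness (2% in
WOMAC/BMI, 1% in JSN grades) to exercise the exclusion logic without
modelling informative dropout.

The intercept $\beta_0$ is calibrated by bisection (`calibrate_intercept()`,
tolerance 0.005, ≤200 iterations) against the *expected* propensity-driven
prevalence over the simulated covariates, which makes calibration
deterministic given the seed. Because the lateral background rate over
V3→V6 is small, the any-compartment (scenario 1) prevalence stays within
the calibration band of the target. Unattainable targets (e.g. above the
fraction of knees below the JSNM ceiling) raise an error after the bracket
search fails.

## Cohort selection and outcomes

Eligibility requires baseline KL grade 2 or 3 (the radiographic entry
criterion used in structure-modification studies), complete clinical
covariates ("CLIN" = age, gender, BMI), WOMAC pain, KL, JSNM and JSNL at
V0 and V3, JSNM/JSNL present at V6, and a passing image-quality flag (a
boolean input defaulting to pass for synthetic data; real quality control
is visual and out of scope). One knee per participant is kept to avoid
inter-knee correlation: the more painful knee by baseline WOMAC wins; on a
tie the lower-KL knee is excluded; on a further tie the left knee is
excluded. Deltas are arithmetic differences, follow-up minus baseline.
Knees with any V0→V3 JSN increase are excluded in all scenarios, so the
delta features never overlap the outcome window.

Four progression outcomes are supported: scenarios 1/2 evaluate V3→V6,
scenarios 3/4 V0→V6; scenarios 1/3 count JSNM *or* JSNL increase, and
scenarios 2/4 count JSNM-only increase with lateral progressors *excluded*
from the dataset (not labelled non-progressors, to avoid misclassification).
`build_analysis_dataset()` emits stage-by-stage consort counts.

WOMAC pain is taken on the 0–20 pain-subscale range; it enters only one
model (CLINW) and the knee-selection ordering, so the scale choice is
inert. "ΔCLIN" is the BMI delta (age advances deterministically and gender
is constant; WOMAC deltas are dropped with WOMAC itself after the CLINW
model shows no gain). JSNM deltas are never predictors, to avoid built-in
correlation with the JSN-based outcome.

## The model grid and its evaluation

`enumerate_models()` defines the 18 models: models 1–5 from clinical
covariates and grades alone (model 5, CLIN + KL + JSNM, is the reference),
models 6–18 adding the baseline texture block (TBT), the delta block
(ΔTBT) or both, adjusted for combinations of CLIN/ΔCLIN and KL/ΔKL with
JSNM. Texture blocks are *selectable* (subject to stepwise AIC); all other
blocks are forced. Gender is a binary indicator and KL/JSN grades enter as
numeric scores (parsimonious for ordinal grades; factor coding is a
straightforward user-side transformation of the data frame).

**Stepwise AIC.** The search starts from the full model (forced + all
selectable columns) and moves bidirectionally. Candidate moves are ranked
by cheap estimates of the AIC change (Wald statistics for drops, Rao score
statistics for adds) and tried in that order; the first candidate whose
*exact* refit strictly lowers AIC ($-2\ell + 2k$) is accepted. The search
terminates only when an exhaustive scan finds no improving single move, so
the returned model is a genuine local minimum of AIC, with a strictly
decreasing AIC trace. Forced columns are never dropped; the result is
deterministic given the column order. Columns are standardised internally
for the IRLS (the likelihood is invariant); fits whose standardised
coefficients reach implausible magnitude or fail to converge
(quasi-separation) are retried with a light ridge penalty and flagged.
This native implementation exists because selection runs inside every
cross-validation training fold — thousands of searches over up to 128
texture columns per evaluation — where a formula-based stepwise interface
is impractically slow.

**Cross-validation.** `repeated_cv()` runs stratified 10-fold CV repeated
`repeats` times (the study design uses 300; tests and the acceptance
script use 20–50 to keep runs proportionate, which widens Monte-Carlo
noise slightly but changes no conclusions). Two selection modes exist:

* `"fold"` (default): imputation means and the stepwise subset are
  recomputed on every training fold. No information flows from a test fold
  into training — the leak-free design.
* `"pre"`: one stepwise selection on the full dataset before CV, folds
  refitting only the selected columns. This mirrors the published wording
  (selection "before training the prediction models"), but lets selection
  see the test folds; on null data it inflates CV AUC well above chance.

The two modes answer different questions, and the package's own validation
uses both accordingly: null calibration (does the machinery report chance
performance on signal-free data?) must run leak-free, while reproducing
the published model *ordering* is a question about the published
procedure and runs in `"pre"` mode. The comparison is instructive: on
simulated cohorts where the texture-delta composite dominates, the
baseline + delta model beats the delta-only model clearly under pre-CV
selection, but under leak-free per-fold selection the advantage shrinks or
reverses — the 64 extra baseline candidates cost more in selection noise
than their weaker signal returns. Large-model rankings from
selection-before-CV designs should therefore be read as properties of
that procedure, not of the models alone.

Out-of-fold probabilities are pooled per repeat; AUC is the Mann–Whitney
statistic (ties counted ½), BACC the mean of sensitivity and specificity
at threshold 0.5, and PPV/NPV are left missing when undefined (no
positive/negative predictions) — the NaN convention of highly imbalanced
evaluations, where a model that never crosses the 0.5 threshold shows
BACC 0.5 and undefined PPV. Summary metrics are means over repeats; the
95% AUC interval is the 2.5/97.5 percentile of per-repeat AUCs (the
original report does not state its CI construction; percentiles over
repeats are reproducible and make no asymptotic assumption). The
classification threshold stays at 0.5 deliberately, which reproduces the
characteristic BACC ≈ 0.5 / NaN-PPV behaviour on imbalanced cohorts.

**ROC comparison.** `compare_roc()` compares two models' pooled
out-of-fold probabilities on the same knees with the DeLong
placement-value covariance construction for paired curves (via pROC),
reporting ΔAUC, z and a two-sided p. ΔAUC is antisymmetric and p symmetric
under argument swap; identical score vectors return ΔAUC 0, p 1.

**Selection maps.** `selection_frequency_map()` reports the fraction of
training fits retaining each texture feature, renderable as 16-cell grids
per (block, direction, scale) — the package's analogue of showing *which*
ROIs drive the prediction.

## Numerical notes and degenerate inputs

* Candidate ties in the stepwise scan are broken by the ranked estimate,
  then by column index — deterministic.
* `quadratic_variation()` demands `length >= 2u + 1`; `estimate_hurst()`
  with any zero $\bar V(u)$ flags the entry instead of taking `log(0)`.
* Stratified folding requires at least `folds` knees of each class and
  guarantees every training fold contains both classes.
* All simulators are seeded; `run_pipeline()` writes a manifest from which
  byte-identical reruns are possible.
* Problem sizes used by the package's own validation: Hurst recovery on
  100×100-px ROIs (50 seeds per true H); null calibration and coefficient
  recovery on 2000-participant cohorts with 20–50 CV repeats. These sizes
  were chosen to bound Monte-Carlo error well inside the asserted
  tolerances.

## Known limitations

* The texture generator is separable and stationary-increment; real
  trabecular radiographs are neither, and no claim about clinical
  predictive performance follows from synthetic results.
* Cross-validated AUCs on a single finite cohort carry irreducible
  cohort-draw noise: with ~64 candidate texture columns, chance
  cohort-level correlations of order $\sqrt{2\log 64 / n}$ survive any
  leak-free evaluation, so null CV AUCs of texture models hover a few
  hundredths above 0.5 on typical draws of n ≈ 1400 knees.
* Missingness is completely at random; informative dropout is out of
  scope.
* The milli-scale lag set depends on pixel spacing, whose true value in
  the reference cohort is not recoverable; it is carried in the image
  sidecar and configurable.
* Published point results from restricted cohorts (absolute AUCs, consort
  counts) are not reproducible here by construction; the package validates
  structure, estimator exactness, null calibration and qualitative model
  ordering instead.
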