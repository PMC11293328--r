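---
title: "Infrared plasma fingerprinting for multi-phenotype screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Infrared plasma fingerprinting for multi-phenotype screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irpheno)
```

# The problem

A single transmission FTIR measurement of blood plasma yields an absorbance
spectrum — a molecular fingerprint superimposing the vibrational responses of
everything dissolved in the sample: proteins, lipoproteins, metabolites,
carbohydrates. If common metabolic phenotypes (dyslipidemia, hypertension,
prediabetes, type 2 diabetes, and their absence, "healthy") leave detectable
imprints on this fingerprint, one cheap reagent-free measurement can stand in
for a panel of laboratory tests. `irpheno` implements the full analysis stack
for this idea: spectral preprocessing, a chained multilabel classifier,
multilabel evaluation against a stochastic chance benchmark, leakage-safe
validation across two sampling visits, ridge calibration of clinical analytes
from spectra, and metabolic-syndrome (MetS) scoring and incident forecasting —
plus a synthetic cohort generator, because the clinical data the design
mirrors are access-restricted.

# Spectral preprocessing

Three steps map a raw absorbance spectrum to the analysis-ready fingerprint:

1. **Water-background correction.** Absorbance is reconstructed against a
   pure-water reference; a sample containing less water than the reference
   shows negative absorption. `correct_water()` adds a scaled water spectrum,
   `corrected = raw + c·W`, choosing `c` to minimize the L2 norm of the first
   derivative of the corrected spectrum inside 2000–2300 cm⁻¹, a window where
   plasma itself is biologically silent but water still has structure (the
   association band near 2130 cm⁻¹). With first-order finite differences on
   the uniform grid the objective is quadratic and the minimizer is the
   closed form `c = −⟨A′, W′⟩ / ⟨W′, W′⟩`. We chose the L2 norm over an L1
   reading of "minimal first derivative" because it is convex with a unique,
   deterministic solution. The sign convention (the correction *adds* `c·W`)
   makes recovered coefficients positive for water deficit.
2. **Truncation and masking.** Spectra are truncated to 1000–3000 cm⁻¹ and
   the 1800–2800 cm⁻¹ region is removed. Both retained intervals are treated
   as closed — grid points at exactly 1800 and 2800 cm⁻¹ are kept. On the
   default 2 cm⁻¹ grid this leaves 502 channels.
3. **L2 normalization.** Each spectrum is scaled to unit Euclidean norm,
   absorbing multiplicative effects of total molecular concentration, path
   length and handling. Masking is applied *before* normalization (the
   alternative order is defensible; this one is fixed and documented so that
   the removed silent region never influences the norm).

# The chained multilabel classifier

Five binary L2-regularized logistic classifiers are linked in a chain. At
training time the k-th link sees the fingerprint features plus the *true*
labels of all preceding phenotypes; the first link sees only the features. At
prediction time true labels are hidden, so each link consumes its
predecessors' *predictions*, binarized at the 0.5 threshold (probability
propagation is available behind `propagate = "prob"`, hard labels are the
default). The chain lets the model express label correlations and the two
hard exclusivities — a diabetic individual cannot be prediabetic, and any
condition excludes "healthy". Raw chain outputs are reported as-is; an
optional feasibility projection (`project = TRUE`) is off by default because
enforcement at prediction time is a modeling choice, not part of the chain.

Ties at the threshold (`p = 0.5` exactly) classify negative: the decision
rule is a strict inequality.

The default order is dyslipidemia → hypertension → prediabetes → type 2
diabetes → healthy, with the healthy link last so it can integrate the four
condition predictions. `search_chain_order()` evaluates all `k!` orders (120
for five labels) by k-fold cross-validated exact match ratio with a shared
fold split and a deterministic lexicographic tie-break.

## Regularization of the base learner

The base learner standardizes its feature columns with training-set
statistics (population SD) and applies a fixed ridge penalty `λ = 0.1 /
c_reg` on the standardized scale (glmnet's per-observation parameterization,
intercept unpenalized). An unstandardized unit-`C` penalty — the obvious
default — is scale-sensitive: on unit-norm fingerprints (per-channel RMS
≈ 0.045) it over-shrinks weak distributed signals, while on raw analyte
panels the large-unit columns swamp the small ones. Standardization makes
the penalty meaningful for both feature families, and `λ = 0.1` was chosen
as a mild, sample-size-stable shrinkage adequate for ~500 collinear spectral
channels; it is overridable everywhere through `c_reg`. The objective is
strictly convex, so refits on identical inputs are bit-identical.

# Multilabel evaluation and the chance benchmark

Three metrics, all on [0, 1], higher = better:

- **exact match ratio** `(1/n) Σᵢ I(yᵢ = ŷᵢ)` — strict, no partial credit;
- **Hamming score** (Jaccard) `(1/n) Σᵢ |yᵢ ∩ ŷᵢ| / |yᵢ ∪ ŷᵢ|` over
  positive-label sets — partial credit, true negatives earn nothing, false
  positives are penalized. A row empty on both sides scores 1 by convention
  (it cannot occur for feasible truth vectors, which always contain at least
  one positive, but generic inputs need a defined value);
- **1 − Hamming loss**, one minus the fraction of discordant label cells.

`chance_benchmark()` answers "what would these metrics be for a predictor
that knows the label-combination distribution but cannot see the spectra?":
two independent samples of `n_draws` label vectors are drawn from the
empirical distribution over observed feasible combinations and scored
against each other. Drawing two independent samples is distributionally
equivalent to drawing one and shuffling it. Exact expectations are reported
alongside: `E[EMR] = Σₖ pₖ²` over combination probabilities, `E[Hamming
score] = Σₖ Σₗ pₖ pₗ J(k, l)` (a 12 × 12 sum), and `E[1 − HL] = 1 − (1/L)
Σⱼ 2qⱼ(1 − qⱼ)` from the label marginals. The default `n_draws = 1e5` keeps
the Monte-Carlo standard error of the EMR near 1e-3 at desk scale; tests
compare sampled to analytic values at three standard errors.

Feasibility of label vectors is itself a checkable fact: of the 2⁵ = 32
binary vectors, exactly 12 satisfy the two constraints.

ROC curves group tied scores into single operating points and the AUC is the
trapezoid integral, which equals the tie-corrected Mann–Whitney concordance
probability; tests verify this against an O(n²) pairwise oracle and pROC.

# Validation regimes and leakage

Three regimes mirror the two-visit study design:

- `cv_set1`, `cv_set2`: 10-fold cross-validation within one sample set,
  stratified by label combination where strata allow (strata smaller than k
  are pooled). Fold sizes differ by at most one.
- `set_independent`: the individuals present in both visits are partitioned
  into 10 disjoint hold-out groups; iteration i trains on all visit-1
  samples except those of group-i individuals and tests on group i's visit-2
  samples. Training and testing therefore never share an individual, and the
  test samples were collected and measured years "later" under different
  batch conditions. Partitioning (rather than ten independent 10% draws)
  guarantees every overlapping individual is tested exactly once.

Every emitted `fold_plan` is audited at construction: a fold whose train and
test sides share an individual is an error, not a warning.

`pair_match()` builds anthropometrically matched case-control cohorts: exact
match on sex, greedy nearest-neighbor without replacement on standardized
(age, BMI) Euclidean distance, sex strata processed in order of control
scarcity. Greedy matching was preferred to optimal matching as the
within-stratum distances here are one-dimensionalish and the cohorts large;
unmatched cases are reported, and an optional caliper rejects distant pairs.

# Analyte calibration

`quantify_analyte()` regresses one analyte on the pooled fingerprints of
both sample sets with closed-form ridge (penalized normal equations,
intercept unpenalized, features standardized with train-fold statistics
only; default `λ = 1` on the standardized scale). Performance is the
out-of-sample R² (1 − SSE/SST with SST about the *test-fold* mean — the
paper-style variant is not uniquely defined, so this strict one is fixed
here) and RMSE, both averaged over 10 folds. Because the penalty applies to
the summed squared error, duplicating every row while doubling λ leaves the
fit unchanged — a documented identity the tests exercise. `quantify_ratio()`
calibrates elementwise ratios such as triglycerides/HDL.
`wavenumber_correlation()` gives the univariate view (Pearson r per
channel), with zero-variance channels flagged undefined rather than zeroed.

The pooled-set 10-fold calibration intentionally reproduces the original
design, which cross-validates samples, not individuals; an individual
donating at both visits can appear in train and test folds here. The
classification experiments are where subject-level independence is enforced.

# Metabolic syndrome

`count_risk_factors()` scores the five harmonized IDF/AHA-NHLBI factors:
waist ≥ 94 cm (M) / 80 cm (F); SBP ≥ 130 or DBP ≥ 85 mmHg or
antihypertensive treatment; fasting glucose ≥ 100 mg/dL or antidiabetic
medication; HDL < 40 (M) / 50 (F) mg/dL or fibrates; triglycerides ≥ 150
mg/dL or fibrates. MetS is ≥ 3 factors; 1–2 is pre-MetS. Units follow the
criteria as printed: HDL cutoffs in mg/dL (the clinical table stores mmol/L;
`mgdl_per_mmol` documents the conversion constants), triglycerides in mg/dL,
the dyslipidemia non-HDL cutoff in mmol/L. The "drug treatment for reduced
HDL" and "for elevated triglycerides" overrides share the single fibrates
flag. A record missing any determining field is excluded from every MetS
analysis; a medication override can decide its factor even when the
measurement is missing.

`incident_mets_cohort()` keeps individuals MetS-negative at baseline with a
scorable follow-up and splits them into converters and non-converters, so
|cases| + |controls| equals the baseline-negative pool by construction.
`forecast_experiment()` then classifies conversion from baseline
fingerprints only, 10-fold cross-validated (unstratified by default; a
stratify flag exists since the original fold design is unstated).

# The synthetic cohort generator

`simulate_cohort()` emulates the study conditions end to end. Defaults
follow the study design: 3044 visit-1 samples, 2140 visit-2 samples, 2015
individuals donating twice (3169 unique), ages 32–88, ~3% of samples with a
missing phenotype-determining field (the original analysis excluded 91/3044
and 85/2140 samples for unknown values), and a follow-up horizon of 6.5
years. The end-to-end acceptance analyses run on a desk-scale instance of
the same generator (2000 + 1400, overlap 1000), which completes in minutes
on one CPU; the vignette-scale examples are smaller still.

**Physiology.** Each individual carries four correlated latent burdens —
lipid, glycemic, vascular, adiposity — plus stable per-analyte
multipliers. The 12 analytes are log-normal with sex/age/BMI linear
predictors on the log scale (positive, right-skewed, realistically
correlated). Two couplings deserve note:

- *Glycation memory:* HbA1c tracks the glycemic burden with an extra convex
  (hinge) term that rises disproportionately at diabetic-range burdens. This
  reflects the biology (HbA1c integrates chronic exposure and lags acute
  elevations) and is what makes prediabetes — a *band* in glucose —
  distinguishable by a linear classifier: glucose elevated out of proportion
  to HbA1c marks the intermediate state.
- *Treatment suppression:* individuals on glucose-lowering medication have
  their measured fasting/2-h glucose reduced while HbA1c keeps the memory;
  they remain labeled diabetic through the medication override, as in the
  clinical definitions.

Effect sizes were calibrated once, against two anchors, and then frozen: the
printed prevalences of the study population (dyslipidemia ≈ 49%/42%,
hypertension ≈ 38%, prediabetes + diabetes ≈ 28–33%, healthy the largest
single group, conversion fraction ≈ 233/1387) and the stated detectability
of the default conditions (every phenotype one-vs-rest AUC above 0.8,
glucose calibration R² above 0.9, sex AUC above 0.9).

**Spectra.** Beer–Lambert forward model on a 950–3050 cm⁻¹ grid at 2 cm⁻¹
(the instrument's 4 cm⁻¹ figure is optical resolution, not sampling; a
finer uniform grid keeps finite differences simple):
`A = L_visit·(Σₘ cₘ εₘ(ν) + baseline) − d·W(ν) + noise`, with per-analyte
Gaussian-band absorptivities placed at the field's assignments (glucose ring
modes 1000–1180 cm⁻¹, ester C=O 1725–1750, lipid CH 2800–2975, carbohydrate
C–O 1100–1275, amide I/II 1550–1700), a per-sample water-deficit coefficient
`d` recorded as ground truth, and per-channel Gaussian noise (default
5 × 10⁻⁴ AU — small against biological variability, as reported for the
instrument class). Band amplitudes are arbitrary units tuned only for
signal-to-noise; the true dilution/path-length constants are not public.
Visit 2 differs by a 6% path-length factor (cuvette wear), a smooth storage
baseline distortion, and a per-analyte assay drift — so sample-set-independent
validation is genuinely harder than within-set cross-validation, and the
package's experiments reproduce that ordering.

**Incident dynamics.** Visit-2 burdens evolve by a random drift; a
configured fraction of baseline-MetS-negative overlap individuals (those
with the highest noisy mean burden, controlled by `forecast_signal`)
receives a coordinated burden rise that produces incident MetS. Because
converters are selected on baseline burdens, baseline spectra carry genuine
forecasting signal. Note one intrinsic property of threshold-crossing
dynamics: even with `forecast_signal = 0` and zero drift, individuals near
the risk-factor thresholds at baseline convert more often through
measurement noise, so the forecast AUC does not collapse exactly to 0.5; the
exact chance floor is obtained by permuting outcomes, and the test suite
checks both facts.

**What passing tests do and do not show.** The generator produces Gaussian
bands on smooth baselines with Gaussian noise; real plasma spectra have
non-Gaussian line shapes, scattering and atmospheric artifacts, instrument
drift that is autocorrelated in time, and biology whose "effect sizes" are
not knobs. Green tests therefore certify the *pipeline* — the preprocessing
math, the chain mechanics, the metric formulas, the leakage guarantees, the
cohort constructions — under conditions where ground truth is known; they do
not certify clinical performance, and the package makes no claim to
reproduce the original cohort's numbers, which come from access-restricted
data.

# Numerical choices and degenerate inputs

- Water correction errors on a reference with zero derivative energy in the
  window; the correction itself is exact linear algebra, no iteration.
- L2 normalization of an exactly zero spectrum is an error, not a NaN.
- Single-class outcomes are errors for both the logistic learner and the
  AUC.
- Pearson correlations at zero-variance channels are flagged `NA`.
- Ridge standardization uses the population (n-denominator) SD, which keeps
  the duplicate-row/λ-rescaling identity exact.
- All randomness flows through explicit seeds; helper seeds are derived
  deterministically per stage and the caller's RNG state is restored.

# Known limitations

- The chain passes hard labels by default; whether the original passed
  labels or probabilities at prediction time is not fully specified, so both
  modes exist.
- Stratification of the order-search folds and the forecast folds is not
  specified in the source design; both default to the simpler choice with
  flags available.
- Serum-vs-plasma assay noise for albumin is emulated only as a small extra
  target noise; its true magnitude is unknown.
- The generator's anthropometric imprint (age, BMI) is weaker than real
  cohorts exhibit; age/BMI calibration R² values are correspondingly modest
  and are reported, not asserted.
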