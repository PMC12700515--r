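---
title: "Relating smartwatch digital phenotypes to symptom dimensions with mixed-model selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relating smartwatch digital phenotypes to symptom dimensions with mixed-model selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenolmm)
```

## The problem

Patients with psychotic spectrum disorders are rated monthly on the five
PANSS symptom dimensions (positive, negative, cognitive/disorganization,
depression/anxiety, excitement/hostility) while wearing a smartwatch
continuously. The watch yields passive streams — 3-axis accelerometer and
gyroscope, photoplethysmographic interpulse intervals, step counts, and
wake/sleep labels — from which monthly *digital phenotypes* are derived.
`phenolmm` implements the full chain from raw 5-minute windows to
per-(phenotype, dimension) linear mixed-effects (LME) inference, and
includes a seeded synthetic-cohort generator so that every stage can be
validated against known ground truth without access to patient data.

## Digital phenotypes

Per 5-minute window:

* **Motility.** The short-time energy of the Euclidean norm of the 3-axis
  signal, $STE = \sum_j x_j^2$ — an activity-count-like quantity without
  thresholding. Computed separately for accelerometer and gyroscope.
* **Cardiac.** Interpulse intervals are artifact-cleaned (retained inside an
  absolute band of 300–2000 ms *and* within ±20% of the running median of
  the previous 10 retained intervals; both configurable). The retained
  normal-to-normal (NN) intervals give the **NN count** per window (a
  normalized heart-rate / sympathovagal-balance proxy) and the **RMSSD**,
  $\sqrt{\mathrm{mean}(\Delta NN^2)}$ (a parasympathetic proxy, missing when
  fewer than two intervals survive).

Per day: the sleep:wake ratio (sleep hours / wake hours) and mean steps per
minute, computed only for days with at least 18 h of recording.

Per follow-up month (a 30-day block from enrollment, so completeness
thresholds are comparable across months): the mean and SD of the four
window features, separately for wake and sleep, plus mean and SD of the two
daily features — 20 monthly phenotypes. Months with fewer than 720 wake or
480 sleep windows are excluded (thresholds inclusive: 720/480 is kept).
The monthly SD of the window features is taken across 5-minute windows (a
config switch computes it across daily means instead; which convention the
field uses varies and results can differ). Ratings are aligned by default
to the sensor month *preceding* the interview (`alignment = "preceding"`);
the alternative `"same"` pairs a rating with the block that starts at the
visit.

## The model family and the 3-step selection

For each of the 100 (phenotype, dimension) pairs, with $y_{it}$ the
dimension score of patient $i$ at month $t$ and $x_{it}$ the phenotype:

$$y_{it} = \beta_0 + \beta_1 x_{it} + u_{0i} + u_{1i} x_{it} + \varepsilon_{it}$$

* **Step 1 (screen).** Random intercept only ($u_{1i}$ and AR(1) absent),
  fitted by maximum likelihood. A pair is retained when the two-tailed
  phenotype p-value is below .05 *and* Cohen $f^2 = R_m/(1-R_m) \ge 0.01$,
  where $R_m$ is the marginal pseudo-$R^2$,
  $\mathrm{var}(X\hat\beta) / (\mathrm{var}(X\hat\beta) + \hat\sigma^2_{u0}
  + \hat\sigma^2_\varepsilon)$. No multiplicity correction is applied — the
  screen is declaredly exploratory, and the report notes the expected
  number of false positives among the 100 tests. $R_m$ is defined only for
  this structure: once the residual covariance is a matrix, no comparable
  scalar decomposition exists, and the package refuses to compute it.
* **Step 2 (serial correlation).** AR(1) residual correlation
  ($\mathrm{cor}(\varepsilon_{ij},\varepsilon_{ik}) = \rho^{|j-k|}$, indexed
  by visit order; gaps from excluded months count as unit steps — a
  documented sensitivity switch, not calendar time). One extra parameter in
  the interior of its space, so the likelihood-ratio statistic
  $\Lambda = (-2LL_{small}) - (-2LL_{big})$ is referred to $\chi^2_1$.
* **Step 3 (slope heterogeneity).** A random slope with unstructured 2×2
  covariance of $(u_{0i}, u_{1i})$, added to whichever of steps 1–2 won.
  This puts a variance on the boundary plus a free covariance, so the null
  is the equal-weight mixture
  $p = \tfrac12 P(\chi^2_1 > \Lambda) + \tfrac12 P(\chi^2_2 > \Lambda)$.
  When the slope-only model fails to converge it is refitted with AR(1)
  included and flagged. When step 2 won and step 3 therefore adds the slope
  on top of AR(1), the same mixture null is retained (two extra parameters,
  one at the boundary) — an approximation we document rather than hide.
  Whether the original procedure kept AR(1) under step 3 is ambiguous; the
  nested-chain behaviour here is this package's documented choice.

The final fixed effect is reported from the winning model with
Satterthwaite degrees of freedom. ML (never REML) is used throughout so
that $-2LL$ differences are valid for both fixed- and random-part
comparisons.

Covariates (demographics, diagnosis, medication equivalents, follow-up
time) are screened with random-intercept models only — they have little or
no within-patient variation, so richer structures are ill-posed — using the
same p/$f^2$ gate, with Wald F-tests for factors of 3+ levels. A covariate
is an eligible *confounder* for a retained pair only when it passes the
gate for both the phenotype and the dimension; the interaction model then
adds covariate and phenotype × covariate terms to the pair's best
structure, and the pair is labelled *confounded* when the covariate or
interaction is significant while the phenotype effect loses significance.

## Estimation internals

Fitting profiles the fixed effects by generalized least squares and the
residual variance in closed form, leaving 1–4 variance parameters that are
optimized on unconstrained scales (log variance ratios, Fisher-z for the
AR(1) parameter and the intercept–slope correlation) by L-BFGS-B from at
least three dispersed starts (a data-driven start from an ANOVA-style
variance decomposition, plus perturbed copies; selection steps warm-start
from the previous step's estimates). All likelihood evaluations factor the
marginal covariance per patient — never a dense all-observations matrix —
with a closed-form Woodbury path for the random-intercept structure.
Optimizer tolerances are `factr = 1e5` and `pgtol = 1e-8`; convergence
failure or a non-positive-definite observed information is recorded on the
fit (`converged = FALSE`), not raised, which is what the step-3 fallback
logic consumes. Degenerate likelihood-ratio statistics are clamped at zero
(with an error only if the "larger" model is materially worse, which
indicates an optimizer failure); exact interpolation (noise-free data) is
floored rather than failed so the GLS coefficients are still returned.

Satterthwaite df for a contrast $c$ are
$2\,[\widehat{\mathrm{Var}}(c'\hat\beta)]^2 / \widehat{\mathrm{Var}}[\widehat{\mathrm{Var}}(c'\hat\beta)]$,
the denominator by the delta method over the variance parameters with the
observed information of the $\beta$-profiled likelihood (in Gaussian LMMs
the information is block-diagonal between $\beta$ and the variance
parameters, so profiling loses nothing). The df are clamped to
$[1, n-p]$, and a singular information falls back to $n-p$ with a warning.
Note one ML-specific subtlety: in the balanced one-way design the
Satterthwaite df for the intercept approaches the number of groups $k$
(REML would give the classical $k-1$); the two agree as $k$ grows.

## The synthetic cohort

The generator is the analysis model run forward, wrapped in a plausible
sensor layer. Defaults mirror the reference cohort: 38 patients, follow-up
drawn from a discretized normal on 1–26 months whose center was solved once
so the mean is 11.8 (the discretization narrows the SD to ≈5.9; the
target cohort reports 7.2), 16 h wake / 8 h sleep, and covariate marginals
(68% male, 55% schizophrenia vs affective, chlorpromazine equivalents with
mean ≈519 and SD ≈481, fluoxetine equivalents with ≈45% users).

* **Sensor layer** (`level = "windows"`): a full 5-minute grid per 30-day
  month with a circadian sleep block (onset jittered around midnight, daily
  duration SD 0.5 h, month-level log-normal drift of 1%), state-dependent
  gamma-distributed window features around latent patient-month means
  (log-normal patient effects, SD 0.20; month effects, SD 0.10), Poisson
  steps, and three missingness channels (window drop, non-wear days, missed
  visits; defaults 5% each). With `raw_signals = TRUE` it emits 3-axis
  sample blocks, interpulse-interval lists with injected artifacts, and
  step counts instead of precomputed features, for exercising the feature
  extractors on small fixtures; full-cohort raw streams would be ~10⁹
  samples and serve no analytic purpose.
* **Symptom layer**: dimension scores follow
  $y = \beta_0 + u_{0i} + (\beta_1 + u_{1i})(x - x_{ref}) + \varepsilon$
  with bivariate-normal $(u_0, u_1)$ and AR(1) $\varepsilon$. Slopes act on
  deviations from the phenotype's cohort reference level so that $\beta_0$
  is the score at a typical phenotype value; without centering, a planted
  slope times a large phenotype mean drags scores into the dimension floor
  and censoring distorts every downstream property. Scores are clipped at
  the dimension floor (the item count of each dimension) and left
  continuous unless integer rounding is requested — the conditional
  distribution of real ratings is unknown, so floor/rounding behaviour is
  configuration, not assertion. Default planted slopes mirror the
  qualitative reference pattern (e.g. lower sleep RMSSD with positive
  symptoms) at a standardized 0.55 score units per phenotype SD, sized to
  $f^2 \approx 0.02$ under the default variance components
  ($\sigma_{u0} = 3$, $\sigma_\varepsilon = 2.5$, $\rho = 0.2$, no random
  slope).
* **Reproducibility**: random streams are partitioned per patient (derived
  from the cohort seed and patient index), so adding a patient never
  perturbs the others; identical truth + seed gives byte-identical bundles.
* `level = "monthly"` draws the 20 latent monthly phenotypes directly and
  is exactly model-consistent — this is what replicate calibration studies
  use. At window level the analysis consumes realized aggregates, which
  track the latent values closely (r ≈ 0.9997 for monthly means) but add
  a little aggregation attenuation, as real data would.

What the generator does *not* emulate: realistic PPG waveforms, nonlinear
phenotype–symptom links, informative (symptom-driven) missingness, rater
effects, or calendar-time irregularity of visits. Passing tests therefore
establish the correctness and calibration of the *pipeline*, not the
clinical validity of any particular association.

## Validation studies shipped with the package

The test suite fixes seeds and uses these problem sizes, chosen to balance
Monte-Carlo error against a test run of a few minutes:

* Likelihood oracle: 25 random datasets (≤5 patients × ≤6 visits) against a
  dense multivariate-normal evaluation, agreement to 1e-8 across all three
  structures; random-intercept fits also cross-checked against an
  established mixed-model library's ML estimates and against closed-form
  balanced-design estimators.
* Slope recovery: 100 replicate default-size cohorts (38 patients, mean
  11.8 months) from a random-slope truth with the baseline score placed
  well above the dimension floor and a planted slope SD large enough for
  the slope variance to be identifiable (a truth whose slope variance
  pins to the boundary shrinks the SEs and cannot yield nominal
  intervals); 95% Wald intervals on the package's t reference
  (Satterthwaite df) must cover the planted slope in 90–98% of
  replicates. Observed coverage is ≈0.92 across independent seed bases,
  reflecting the mild downward bias of ML variance estimates.
* Null calibration: 200 replicate null cohorts (all slopes zero), 4 pairs
  each; the joint step-1 gate (p < .05 and $f^2 \ge 0.01$) must not
  materially exceed 5% retention (Monte-Carlo error computed across
  replicate cohorts, since gates within a cohort share its data). At the
  default cohort size the observed rate is 5–6%: the $f^2$ gate only
  binds in smaller samples, and Satterthwaite t-tests under ML are known
  to be mildly anti-conservative — one more reason the procedure treats
  step 1 as an exploratory screen and follows it with steps 2–3.
* Selection consistency: 200 replicates each of a planted-random-slope
  truth (20 patients × 8 months, slope SD large enough that per-patient
  slope dispersion is visible over the within-patient phenotype variation)
  and a planted-AR(1) truth ($\rho = 0.6$); the corresponding structure
  must be selected in the majority of replicates. Random-slope detection
  requires within-patient predictor variation — a purely between-patient
  association is absorbed by the random intercept, which is also why a
  between-patient confound cannot masquerade as a within-patient slope.
* Printed-arithmetic checks: the $\chi^2_1$ and mixture p-values and
  estimate/SE → t arithmetic of the inference layer against a reference
  table of published comparisons, at the precision those values were
  printed (a handful of rows whose printed values are inconsistent with
  either null distribution are excluded as typographical).

`scripts/acceptance.R` re-runs scaled versions of these studies plus a full
window-level demo pipeline and writes the headline numbers as JSON.

## Known limitations

* ML variance estimates are biased low in small cohorts, so Wald CIs run
  slightly below nominal coverage (0.92–0.95 observed at 38 patients).
* The AR(1) index treats excluded months as adjacent visits; with heavy
  missingness this understates the true gap.
* The confounder logic follows the eligibility-gated interaction protocol
  exactly; it is a screening heuristic, not a causal analysis.
* Dimension scores are modelled as Gaussian with a floor; heavy floor
  effects (remitted cohorts scoring at the minimum) would call for censored
  or ordinal models outside this package's scope.
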