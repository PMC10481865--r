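---
title: "Assessing resting energy expenditure in severe cerebral palsy: methods behind cpree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing resting energy expenditure in severe cerebral palsy: methods behind cpree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpree)
```

## The clinical problem

Children with spastic quadriplegic cerebral palsy (GMFCS level V) have
altered growth, body composition and muscle tone, so their energy needs are
hard to anticipate. The reference measurement of resting energy expenditure
(REE) is indirect calorimetry, but most nutrition units rely on prediction
equations developed in healthy children — equations that tend to
overestimate REE in this population and risk overfeeding. `cpree`
implements, end to end, the analysis pipeline for this problem: evaluating
the standard pediatric equations against calorimetry, quantifying their
proportional bias and deriving correction ("conversion") equations, fitting
and validating a population-specific weight + triceps-skinfold (TSF) model,
and packaging that model as a clinical nomogram. A synthetic cohort
generator with the statistical structure of the target population makes
every stage runnable and testable without patient data.

## Anthropometry and cohort handling

Subjects are stored in a fixed 13-column table (`cohort()`); heights are
always carried in **cm** internally, and each prediction formula converts
units itself — a single canonical unit avoids silent m/cm mistakes. For
children who cannot stand, stature is estimated from knee height as
`2.69 * KH + 24.2` cm, and `predict_all()` falls back to this estimate
automatically when a measured height is absent.

Nutritional status enters as an externally computed BMI-for-age z-score.
Groups are formed as: group 1, moderate + severe malnutrition (z <= -2);
group 2, mild malnutrition through overweight (z >= -1). Scores in the open
gap (-2, -1) belong to neither published interval; rather than force them
into a group we label them `"unassigned"` and drop them from group
contrasts. Measured REE values below `min_ree = 300` kcal/day (default) are
excluded before method comparison: such extreme values — typically severe
chronic malnutrition — would dominate the difference-on-average regressions
and the model fit.

## Indirect calorimetry processing

A calorimetry session yields breath-by-breath VO2, VCO2 and minute
ventilation. REE is only interpretable once gas exchange is stable, so
`detect_steady_state()` slides a window (default 5 min) breath by breath
and accepts the earliest window in which the **coefficient of variation**
of the respiratory quotient is below 5% and of VO2 and minute ventilation
below 10%. "Variation" is not defined uniquely in the metabolic-cart
literature; CV (SD/mean) is the conventional criterion and is our
documented choice — range/mean or trend-slope definitions would accept
slightly different windows. Ties go to the earliest window, which makes
detection deterministic.

After onset, `measure_ree()` averages VO2 and VCO2 over a measurement
window (default 20 min) and applies the abbreviated Weir equation

```
REE [kcal/day] = 1.44 * (3.941 * VO2 + 1.106 * VCO2),   VO2, VCO2 in ml/min
```

i.e. the canonical Weir caloric equivalents without the urinary-nitrogen
(protein) term, whose omission changes REE by under 2% while sparing a
24-hour urine collection. RQ is reported as the ratio of the window means
(not the mean of per-breath ratios), matching how carts report it.

## Method comparison and conversion equations

For each formula the differences `D = formula - calorimetry` are plotted
against the averages `A = (formula + calorimetry)/2`. Classic Bland-Altman
limits of agreement (`mean(D) +/- 1.96 sd(D)`) assume the bias is constant;
a Pearson correlation between D and A (two-sided test, alpha = 0.05 is our
declaration threshold) flags **proportional bias**, which in this
population is present for every formula — all of them drift towards
underestimation as REE grows.

Under proportional bias we regress the differences on the averages,
`D = a + b A + e`, `var(e) = tau^2` (tau on n - 2 degrees of freedom), and
report the sloped limits `a + b A +/- 2 tau`. The multiplier on this path
is exactly 2, as conventional for the regression-based limits; the classic
path keeps 1.96. Both conventions are deliberate and visible in the API.
The same fit yields bidirectional **conversion equations**

```
y1|2 = a/(1 - b/2) + y2 (1 + b/2)/(1 - b/2) +/- 2 tau/(1 - b/2)
y2|1 = -a/(1 + b/2) + y1 (1 - b/2)/(1 + b/2) +/- 2 tau/(1 + b/2)
```

which translate a formula estimate into the calorimetry scale (and back)
with prediction limits. The two directions compose to the identity in the
point prediction for any |b| < 2; `conversion_equations()` refuses |b| >= 2
where the denominators vanish. As an external anchor, a fit with
(a, b) = (560, -0.5185) reproduces the published Harris-Benedict correction
`-756.11 + 1.70 x`, and applying that correction to an estimate of
956 kcal/day returns ~869 kcal/day.

Concordance with calorimetry is summarised by **Lin's CCC**,
`2 s_xy / (s_x^2 + s_y^2 + (mean x - mean y)^2)` with population (1/n)
moments — with small samples the (n-1)/n convention moves the third
decimal, so the choice is fixed and covered by an independent-oracle test.
The 95% CI uses the Fisher z-transform with Lin's asymptotic standard
error.

## The population-specific model

Model development starts from a pre-specified base (REE on weight) and
proceeds with:

* **Nonlinearity testing.** Weight is expanded in a restricted cubic
  spline with 3 knots at the 0.10/0.50/0.90 quantiles (Harrell's default
  for 3 knots; only "three fixed knots" is prescribed by the design). The
  spline term is compared to the linear fit with a Gaussian likelihood
  ratio test, `n log(SSE_lin/SSE_spline) ~ chi^2(1)`. Under the null this
  test holds its 5% size (verified by simulation); on the cohorts this
  package targets the nonlinear term is not significant, and the final
  model stays linear.
* **Limited backward selection.** Candidates height, age, sex and TSF are
  eliminated by largest partial-F p-value above 0.05 (the criterion is our
  choice; AIC elimination is available behind a flag), with weight forced.
  On data with the target structure this retains exactly weight and TSF.
* **The final formula.** `REE = 28.43 * weight - 17 * TSF + 398.2`
  (kcal/day, weight in kg, TSF in mm). The negative TSF coefficient
  captures the lean-mass signal: at equal weight, more peripheral fat
  means less metabolically active tissue.

Fit quality is reported as adjusted R^2 and MSE. MSE uses the `SSE/n`
convention ("mean squared error of the estimate"); the residual SD is kept
separately on `n - p - 1` degrees of freedom, so both conventions are
available unambiguously.

**Validation** is Harrell's optimism bootstrap (default 3000 resamples of
size n): `training` is the mean apparent index across resample fits,
`test` the mean index of those fits on the original data,
`optimism = training - test`, `corrected = original - optimism`. These are
exact arithmetic identities of every run, and they are applied with the
same sign convention to both indices — for MSE the optimism comes out
negative, so the corrected error is *larger* than the apparent one, which
is the honest direction for an overfit model. A historical train/test
split (first 54 subjects train, remainder test, mirroring an earlier
preliminary sample rather than a random partition) feeds the CCC
comparison against all standard formulas; on generated cohorts the
weight + TSF model attains the highest concordance by construction.

## Prediction equations and unit conventions

All printed pediatric equations are implemented with half-open age bands
[0,3), [3,10), [10,18), [18,30) — a 10-year-old uses the 10-18 equation,
which is the standard Schofield convention, and dispatch raises at 30
years. Schofield weight & height takes height in **metres** (its height
coefficients ~100-1500 only make sense there); Harris-Benedict and Mifflin
take cm. One reprinted coefficient deserves a note: the Schofield
weight-and-height male <3-year weight coefficient circulates as 1.67,
which yields absurd REE at infant weights; the original value 0.167 is the
default, with `as_printed = TRUE` restoring the reprinted figure for
comparability.

## The nomogram

`build_nomogram()` converts the final linear model into point scales:
predictor j at value x scores `|beta_j| (x - ref_j) / max_k(|beta_k|
range_k) * 100` points, with `ref_j` the range end contributing least to
REE — for the negative TSF coefficient, points are maximal at the TSF
*minimum*, so points always add towards higher REE. The dominant predictor
spans exactly 0-100 points; with the default ranges (weight 5-60 kg, TSF
2-20 mm, chosen to span the population quartiles with clinical margin) the
TSF axis tops out at `306/1563.65*100 = 19.57` points. The total-points
axis is the exact linear inverse including the intercept, so reading the
nomogram equals evaluating the model to floating-point accuracy — the
plain-text tick table is the canonical surface and the drawn figure is a
thin layer over it.

## The synthetic cohort generator

The generator (`generator_config()`, `generate_cohort()`) emulates the
target population: n = 100, 65% male, median (IQR) age 9 (6, 14) years,
weight 19.45 (14.43, 26.05) kg, height 118 (107.55, 135.25) cm, TSF 7.7
(5.4, 9.2) mm, median RQ 0.7144, median intake 1146 kcal/day. Choices worth
recording:

* **Marginals.** Log-normal, with the location solved from the median and
  the spread from the quartile *ratio* `q3/q1`. Only medians and IQRs of
  skewed positive quantities are available, and a two-parameter family can
  match a median and one spread measure; asymmetric printed quartiles are
  therefore matched in ratio, not elementwise.
* **Dependence.** A Gaussian copula with weight-TSF Spearman correlation
  0.3 (a config knob, not a claim about any real sample — no correlation
  structure is published) plus fixed latent correlations age-height 0.8,
  age-weight 0.6, height-weight 0.7 that merely keep generated children
  anthropometrically plausible.
* **REE.** `398.2 + 28.43 weight - 17 TSF` plus Gaussian noise with SD 200
  kcal/day (the square root of the validated model's test MSE, ~40,000),
  floored at 250 kcal/day. The floor is a `pmax` clamp: resampling the
  residual instead would lift the conditional mean of low-weight/high-TSF
  subjects by up to ~60 kcal/day and visibly bias coefficient recovery,
  while the clamp distorts about 3.5 times less and touches well under 1%
  of subjects at defaults. An `inject_outlier` flag plants one
  209 kcal/day severe-malnutrition subject to exercise the exclusion rule.
* **Intake.** Solved by inverting the target multivariable relation — REE
  rises 163 kcal/day per +388 kcal/day intake and 102 kcal/day per +4.75
  years of age — anchored at the median subject, plus independent noise
  (SD 150 kcal/day). The intake noise attenuates the recovered
  coefficients by ~3%, well inside the stochastic tolerances used in
  testing.
* **z-scores.** Generated from the weight latent normal (mean -2.05, SD
  1.3), so ~52% of subjects fall in the moderate+severe group — matching
  the undernutrition burden of the target population — and the
  better-nourished group has higher REE, reproducing the direction of the
  published group contrast.

The breath-series generator constructs traces whose stationary segment
returns the requested REE and RQ under the Weir equation exactly in
expectation, with breath-level CVs (~2% VO2/VE, ~1.2% RQ) comfortably
under the steady-state tolerances, and an optional unsteady lead carrying
a +/-50% slow VO2 oscillation that no qualifying window can overlap by
more than a fraction of a minute.

**What the generator does not emulate:** feeding-mode-specific REE
differences, WHO growth-standard z-score computation, true measurement
error in anthropometry, or any correlation between RQ and the other
variables. Tests passing on generated cohorts therefore demonstrate the
*statistical machinery* — recovery, calibration, identities — not the
clinical accuracy of any equation in real children.

## Numerical choices and degenerate inputs

* Steady-state CVs are computed from cumulative sums with a non-negativity
  guard; an exhaustive per-window scan is kept as the test oracle.
* `bland_altman()` short-circuits zero-variance differences (identical
  methods) to r = 0, p = 1 instead of an undefined correlation; zero
  variance in the averages is an error.
* `lin_ccc()` collapses its CI to a point at |CCC| = 1, where the
  asymptotic SE degenerates.
* A constant response in `fit_linear()` is treated as R^2 = 0 (nothing to
  explain), making the adjusted value properly negative.
* Bootstrap resamples with rank-deficient designs are skipped and counted,
  never silently imputed.
* Quantiles are type-7 throughout (R's default interpolation).
* Seeds: every stochastic routine takes an explicit seed and restores the
  caller's RNG state; the pipeline derives per-stage substreams from one
  master seed so stages can be re-run in isolation.

## Problem sizes used by the test suite

The suite exercises distributional calibration at n = 10,000, coefficient
recovery at n = 5,000, selection behaviour at n = 1,000, the optimism
bootstrap at its default 3,000 resamples on n = 54, and the
likelihood-ratio test's size with 1,000 null simulations of n = 500 —
sizes chosen so Monte-Carlo error is small relative to the tolerances
asserted while the whole suite stays quick to run.

## Known limitations

The conversion equations and the final model are only as good as the
population they describe: severe (GMFCS V) spastic quadriplegic cerebral
palsy. Peripheral skinfolds under-represent centrally stored fat in this
group, which bounds how much concordance any TSF-based model can achieve;
the published concordance of the weight + TSF model is moderate
(CCC ~0.64), and nothing in this package should be read as making
calorimetry unnecessary where it is available.
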