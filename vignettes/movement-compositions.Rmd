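---
title: "Movement-behaviour compositions and cardiometabolic risk: methods"
author: "movecoda"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement-behaviour compositions and cardiometabolic risk: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(movecoda)
```

## The model

A monitored day is a five-part composition
$x = (\mathrm{SED}, \mathrm{LPA}, \mathrm{MPA}, \mathrm{VPA}, \mathrm{Sleep})$
of strictly positive minutes closed to 1440. Compositions live in the
simplex, where only ratios carry information; `movecoda` works in
Aitchison geometry throughout. The centred log-ratio is
$\mathrm{clr}(x)_i = \ln x_i - \tfrac1D\sum_j \ln x_j$, and an isometric
log-ratio (ilr) basis is any orthonormal set of $D-1$ contrasts of the
clr. We use *pivot* bases: for pivot part $x_1$ and $D = 5$,

$$z_1 = \sqrt{\tfrac{4}{5}}\,
  \ln\frac{x_1}{(x_2 x_3 x_4 x_5)^{1/4}},$$

with $z_2 \dots z_4$ completing the basis over the remaining parts in
their canonical order (SED, LPA, MPA, VPA, Sleep). The five pivot
rotations of one fitted model are reparameterisations of each other:
fitted values, the joint F test and $R^2$ are identical across them,
which the test suite checks to $10^{-10}$.

Each cardiometabolic outcome is regressed on the four ilr coordinates
plus covariates (age, sex, ethnicity, monitoring month, dummy-coded with
male / White / January references). Right-skewed outcomes (BMI, glucose,
insulin, lipids, waist circumference) are modelled on the natural-log
scale; z-scores and blood pressures are left untransformed. Natural logs
are used everywhere; the choice affects coefficient scale only, never p
values.

Two headline statistics come from comparing against the covariate-only
model: the **model p value** is the joint F test of the four
coordinates, and the reported **R²** is by default the *increment* in
R² attributable to the composition. The phrase "variance explained by
the composition after covarying" denotes the composition's share, not
the full model's; a config switch (`r_squared = "total"`) reports the
total instead, and both are stored on every fit.

Per behaviour, the model is refit in that behaviour's pivot basis and
the first coordinate's coefficient, two-sided t-test p value and 95% CI
are reported. No multiplicity adjustment is applied to these twenty
tests per outcome panel; that mirrors standard practice in this
literature and is deliberate — consumers who need familywise control
should apply it downstream.

## Isotemporal substitution

A reallocation moves $\delta$ minutes (default 10) from a donor
behaviour to a receiver at a reference composition, leaving the other
parts untouched; the reference is the group's geometric-mean composition
(its compositional centre). Covariate terms cancel in the model-space
difference, so the predicted change is
$\Delta\hat y = \beta^\top\{\mathrm{ilr}(x_{\mathrm{new}}) -
\mathrm{ilr}(x_{\mathrm{ref}})\}$, verified in the tests by predicting at
two covariate profiles. Percentage changes use the exact back-transform
$(e^{\Delta\hat y}-1)\times 100$ for log outcomes (a switch gives the
first-order $\Delta\hat y \times 100$ approximation, to probe what a
published table used) and $\Delta\hat y/\bar y\times 100$ for identity
outcomes.

Three behaviours of these matrices deserve emphasis:

- **They are asymmetric.** $\Delta\hat y(A\!\to\!B) \ne
  -\Delta\hat y(B\!\to\!A)$ in general, because $\ln(a-\delta)/a$ and
  $\ln(a+\delta)/a$ differ in magnitude — materially so when $\delta$ is
  large relative to the donor (10 min against a ~12-min VPA mean). The
  signs do flip, and the first-order (linearised) prediction is exactly
  antisymmetric; the tests assert the sign flip, not magnitude equality.
- **Infeasible cells stay missing.** If the donor holds fewer than
  $\delta$ minutes, the cell raises an `infeasible_reallocation`
  condition and is reported as missing, never extrapolated.
- **Near-zero outcome means destabilise percentages.** For BMI z-scores
  the group mean is close to 0, so percent-of-mean changes are enormous
  while absolute changes are modest. The matrix carries a
  `near_zero_mean` flag and an absolute-units companion rather than
  suppressing the pathology.

Cells are flagged when the absolute predicted change exceeds the
smallest worthwhile change, $\mathrm{SWC} = 0.2\times$ group SD of the
raw outcome, computed sex-specifically. Sex-specific matrices are built
from sex-stratified fits at the sex's own centre by default (a pooled
fit with sex covariate is available via config); stratification lets the
two sexes differ in their compositional effects, which is the scientific
question these matrices usually address.

## Ingestion choices

Wear-time criteria for this kind of cohort are rarely portable between
studies, so they are explicit configuration with conventional defaults,
offered as substitutes for any particular study's (often unpublished)
criteria: a valid day wears the monitor ≥ 600 min (10 h) with
self-reported sleep within 240–960 min, and a participant needs ≥ 3
valid days. Waking behaviours are averaged over valid days and rescaled
proportionally to fill $1440 - \overline{\mathrm{sleep}}$: mean wear
plus sleep rarely tiles the day, some reconciliation is unavoidable, and
proportional scaling is the least-informative option. Averaging is
defined on raw minutes *before* closure (averaging ilr coordinates
instead would give the compositional mean; the two differ slightly, and
the raw-minutes definition is the one tested). Zero parts — certain for
VPA in real paediatric data — are floored at 0.5 min before closure
(configurable; a total-preserving multiplicative variant is provided).
The monitoring-month covariate is the modal month over valid days, ties
to the earliest. Missing outcomes are handled by listwise deletion per
outcome model, never imputed across outcomes.

One deliberate non-goal: the pairwise log-ratio **variation matrix** is
implemented with its standard definition
$t_{ij} = \mathrm{var}\{\ln(x_i/x_j)\}$ (n−1 denominator), which is
symmetric with non-negative off-diagonals by construction. Published
tables occasionally print negative "variation" entries; those must be
some other statistic (e.g. a covariance), and this package does not try
to reproduce them.

## What the generator emulates — and what it does not

The synthetic cohort is logistic-normal: participant compositions are
Gaussian in ilr space around sex-specific centres and mapped back to the
simplex. The default centres are typical boys'/girls' geometric-mean
24-hour compositions for 10–13-year-olds (boys ≈ 342/351/40.5/14/693
min for SED/LPA/MPA/VPA/Sleep; girls ≈ 366/348.5/30/11.5/681). The
default ilr spread (diagonal, SDs 0.18, 0.18, 0.40, 0.55 on the
canonical pivot coordinates) was chosen once so that marginal minute
spreads look like a plausible cohort — VPA roughly 16 ± 14 min/day in
boys — and is documented rather than fitted to any dataset. Days are
carved from the participant composition with multiplicative jitter
(log-SD 0.08) of the waking parts inside a drawn wear time
(normal, 792 ± 102 min) and Gaussian sleep jitter (SD 20 min), so
valid-day filtering has realistic work to do; invalid days and whole
failing participants can be planted exactly, with every plant recorded
in a ground-truth object the pipeline under test never reads.

Outcomes are linear in the ilr coordinates of the participant's
*analysis* composition (the one ingestion recovers from the valid days)
plus additive sex and age effects and Gaussian noise. That makes the
regression exactly correctly specified under the generator — which is
the point: parameter-recovery and CI-coverage tests are then sharp tests
of the estimation machinery, with no attenuation from
errors-in-variables. The flip side is the limitation: passing recovery
tests says the pipeline estimates what it claims to estimate *when the
model holds*; it says nothing about day-level measurement error in real
accelerometry, inter-cohort heterogeneity, non-linear dose–response, or
confounding — none of which the generator emulates.

The recovery benchmark plants strong coefficients
($\beta = (0.6, -0.4, 0.5, -0.5)$, noise SD 0.95) on an identity-scale
outcome: an a-priori power choice, made so that a 2%-of-coefficient-scale
bias bound at 200 replicates tests correctness rather than Monte-Carlo
luck ("coefficient scale" is the Euclidean norm of the five true pivot
coefficients, since individual rotated coefficients can be legitimately
near zero). Coverage of nominal 95% CIs is reported pooled across the
five behaviours. Default cohort sizes in the validation suite (2000 per
sex, 200 replicates; consistency grid 500→8000 per sex) keep the whole
suite comfortably within a coffee break on one core while leaving
binomial error well inside the acceptance bands.

## Numerical conventions

- Closure tolerance $10^{-6}$ relative; ilr round trips are tested to
  $10^{-9}$ relative error (they achieve ~$10^{-15}$).
- Sample variances and SDs use the n−1 denominator throughout.
- Cohen's d uses the pooled n−1-weighted SD and the standard
  normal-approximation CI; the conventional band thresholds 0.20 / 0.60
  / 0.80 are printed with gaps in many papers (0.20 vs 0.21), closed
  here as half-open intervals split at the midpoints (0.205, 0.605,
  0.805) so every value that rounds to a printed threshold lands in the
  intended band. The default d is computed from raw group data; a
  covariate-adjusted variant (adjusted mean difference over pooled
  residual SD) is available and labelled, because adjusted and raw d can
  differ visibly when covariates correlate with group.
- The ANCOVA F for sex is the nested-model F, identical to the squared
  t of the sex coefficient; adjusted means are least-squares means via
  `emmeans`.
- All randomness flows from a single integer seed per entry point; the
  same seed reproduces every table byte-for-byte.

## Known limitations

Pooled (non-hierarchical) models only: multi-cohort data are treated as
one sample, as is common when harmonised cohorts are analysed jointly.
Only pairwise 1:1 reallocations are implemented, not
one-vs-all-remaining redistribution. The generator's missingness is
MCAR; informative missingness would bias real analyses in ways the
validation suite cannot detect. And compositional regression, however
carefully done, remains observational association — no causal reading is
implied by a change matrix.
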