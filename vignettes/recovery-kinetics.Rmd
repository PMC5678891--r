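---
title: "Modelling V̇O2 recovery kinetics after 6-minute walk tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling V̇O2 recovery kinetics after 6-minute walk tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vo2kinetics)
```

## The problem

A 6-minute walk test produces a breath-by-breath oxygen-uptake trace with
three phases: a resting plateau, a mono-exponential rise toward a walking
steady state, and — once the patient stops — a sigmoid decline back toward
a recovery plateau. In COPD, the *speed* of that post-exercise decline
(summarized by the recovery half-time T₁/₂V̇O₂) carries information about
disease severity. Estimating stage-level half-times from a cohort of such
traces raises two methodological questions this package addresses jointly:
which recovery curve to use (no single sigmoid is biologically privileged),
and how to pool dozens of individually fitted curves into stage-level
estimates.

## The curve model

`vo2_curve(t, p, family)` evaluates

$$
\dot V O_2(t) = \dot VO_{2rest}
 + (\dot VO_{2ss} - \dot VO_{2rest})\bigl(1 - e^{-(t-\lambda)/\tau_1}\bigr)\,[t > \lambda]
 + (\dot VO_{2rec} - \dot VO_{2ss})\, g\!\left(\tfrac{t - t_0}{T_{1/2}}\right)[t > t_0],
$$

with $t_0 = \lambda_{max} + 360$ s and $g(x) = 1/(1+x^{\tau_2})$
(log-logistic), $e^{-x^{\tau_2}}$ (Weibull 1) or $1 - e^{-x^{\tau_2}}$
(Weibull 2).

Two conventions make these formulas total functions of time:

* **Piecewise activation.** The exercise and recovery terms involve
  $\log(t - \text{onset})$-type expressions that are undefined before their
  onsets, so each term is gated to zero for $t \le \lambda$ and
  $t \le t_0$ respectively. This reproduces the rest → exercise → recovery
  phase structure and keeps the curve continuous at both boundaries (the
  unit tests assert continuity numerically).
* **Sign of τ₂.** The direction of each sigmoid is set by the sign of τ₂.
  For the decline to run from the exercise plateau to the recovery plateau,
  τ₂ must be negative for the log-logistic and Weibull-1 families and
  positive for Weibull 2. These signs are used for initialization only,
  never as hard constraints, since nothing in the model itself forbids the
  mirrored curves.

The recovery onset uses the *cohort* constant $\lambda_{max}$, not the
individual $\lambda_i$: `align_to_lam_max()` first translates every
patient's clock by $\lambda_{max} - \lambda_i$, so that exercise starts at
$\lambda_{max}$ and recovery at $\lambda_{max} + 360$ for everyone. λ is
experimental metadata (the technician starts the walk), so it is never
estimated.

Parameters, units and typical magnitudes for a COPD walking cohort:

| parameter | meaning | units | typical |
|---|---|---|---|
| V̇O₂rest | resting plateau | mL/min | ~300 |
| V̇O₂ss | walking steady state | mL/min | 1000–1300 |
| V̇O₂rec | recovery plateau | mL/min | ~400 |
| τ₁ | exercise rise time constant (= mean response time) | s | ~30 |
| τ₂ | recovery steepness | — | ±2 |
| T₁/₂V̇O₂ | recovery half-time scale | s | 100–200 |

For the log-logistic family T₁/₂V̇O₂ is *exactly* the time after $t_0$ at
which half the decline is achieved, whatever τ₂; the asymmetric families
reach $e^{-1}$ (Weibull 1) or $1-e^{-1}$ (Weibull 2) of the decline there,
which is why, refitted to the same data, Weibull 1 reports smaller and
Weibull 2 larger half-times than the log-logistic.

## Preprocessing

Raw breaths are averaged over consecutive 20-s windows (`bin_breaths()`),
the convention of cardiopulmonary exercise testing; 5/10/15-s windows are
exposed for sensitivity analyses (`run_pipeline(sensitivity = ...)`). Bin
timestamps are window midpoints — unbiased when the trace is locally
linear; empty windows are dropped rather than interpolated because the
fitting step accepts irregular grids, and partial first/last windows are
kept if nonempty.

## Per-patient fitting

`fit_patient()` minimizes the residual sum of squares over the six curve
parameters with a Levenberg–Marquardt search driven by the analytic
Jacobian (`vo2_gradient()`, verified against central finite differences at
1e-6 relative tolerance). Numerical choices:

* starting values from `auto_init()` (phase means for the three plateaus;
  τ₁ = 30 s; half-level crossing of a 3-bin moving average for T₁/₂, with a
  120-s fallback; τ₂ = ±2 per family);
* relative tolerance 1e-8 on the RSS; up to three restarts from jittered
  starts (±20%) when the first search fails; convergence judged from the
  optimizer's return code and reported honestly — a non-converged fit is a
  result, never silently dropped;
* $\hat\sigma^2 = RSS/n$ for the Gaussian log-likelihood, and the
  covariance $(J^\top J)^{-1} RSS/(n-6)$ with the $n/(n-6)$ small-sample
  correction, since per-patient series have only a few dozen bins;
* AIC $= -2\ell + 2K$ with $K = 7$ (six curve parameters plus the residual
  variance), applied uniformly so that between-family comparisons are
  unaffected by the convention.

Residuals are treated as i.i.d. Gaussian; no autocorrelation or
heteroscedasticity model is offered, matching the identity within-patient
covariance assumed throughout.

## Cohort summarization

**Mixed effects.** `fit_nlme()` fits stage-specific fixed effects for all
six parameters (dummy coding without intercept: 18 fixed effects for three
stages) and patient random effects on the four recovery-phase parameters,
via the alternating-linearization scheme of `nlme` (maximum likelihood,
outer tolerance 1e-6, up to 200 iterations, random-effect modes started at
zero and fixed effects at per-stage medians of the individual fits). The
random-effect covariance **G is diagonal by default**: four correlated
random effects on a 61-patient cohort are fragile, and the unstructured
option (`g_structure = "full"`) is available when the data can support it.
With `random_params = character(0)` the model degenerates to pooled
per-stage nonlinear least squares; a test verifies this reduction against
an independent pooled-NLS oracle at 1e-4. Convergence failures — routine
when single-stage subgroups are fitted — are first-class results carried
with their error message. The marginal-likelihood ascent itself is
delegated to `nlme` and is not re-instrumented; the package checks the
fit's correctness through its reductions and parameter-recovery behaviour
rather than its iteration path. Only the Lindstrom–Bates route is
provided; a Laplace-approximation alternative is not, as no installed
backend supports it for user-defined nonlinear mean functions of this
form.

**Two-step meta-analysis.** `fit_meta()` pools the per-patient half-time
estimates $\hat\phi_i$ under
$\hat\phi_i = \theta_{stage(i)} + A_i + \epsilon_i$, with
$A_i \sim N(0, \tau^2)$ and $\epsilon_i \sim N(0, \sigma_i^2)$, the
first-step standard errors entering as *known* variances (no residual
scale is estimated). τ² is estimated by REML (ML and DerSimonian–Laird are
available; DL doubles as a closed-form oracle in the tests). Inference
uses the normal reference.

**Two-step weighted regression.** `fit_weighted()` replaces the known-
variance assumption with $\epsilon_i \sim N(0, \sigma^2\sigma_i^2)$:
weighted least squares with weights $1/\sigma_i^2$ and an estimated
multiplicative residual scale, with t inference on $m - q$ degrees of
freedom. With equal $\sigma_i$ it reduces exactly to per-stage means, and
its point estimates are invariant to rescaling all $\sigma_i$ — two
properties the test suite asserts, alongside the τ² → ∞ limit of the meta
step (unweighted means).

The reference distributions (z for mixed effects and meta-analysis, t for
weighted regression) are defaults chosen because they reproduce the
published p-value conventions for this design; both are configurable in
`stage_estimates()`.

## Model averaging and subgroup selection

`akaike_weights()` implements $w_p \propto e^{-\Delta_p/2}$;
`model_average()` combines the per-family focal estimates with the
conservative standard error
$\sum_p w_p \sqrt{\widehat{var}(\hat\theta_p) + (\hat\theta_p - \hat\theta_{MA})^2}$
(sum-of-square-roots form), which charges the between-model spread in full
and therefore over- rather than under-covers. The averaged row of the
pipeline's multimodel table is always recomputed from that table's own
per-family rows, so the report is self-consistent by construction.

`subgroup_aic()` compares the families within each disease stage. A
subtlety worth recording: for the two-step strategies the subgroup AIC is
that of the *second-step* pooling model — a likelihood of the extracted
estimates, not of the raw traces — and simulation shows it carries little
information about which family generated the data. The mixed-effects
subgroup AIC is a raw-data likelihood and discriminates strongly (a
Weibull-1-generated stage-sized cohort selects Weibull 1 in ~90% of
seeds), at the cost of occasional non-convergence at subgroup sample
sizes, which the table carries as missing cells with the reason. The
package's self-consistency test therefore uses the mixed-effects subgroup
AIC.

Stage contrasts (4−2, 3−2, 4−3) are reported with raw p-values by default
(`all_contrasts()`), matching the convention of reporting unadjusted
pairwise comparisons; Holm adjustment is available.

## The synthetic cohort generator

`generate_cohort()` emulates the structure the analysis assumes, so every
stage of the pipeline can be validated against a known truth:

* 21/30/10 patients in GOLD stages 2/3/4, the severity mix typical of a
  referred walking-test cohort;
* stage-mean curves with recovery half-times 128/133/168 s, V̇O₂rest
  300 mL/min, V̇O₂ss 1300/1150/1000 mL/min (exercise capacity decreasing
  with severity), V̇O₂rec 400 mL/min, τ₁ 30 s, log-logistic truth with
  τ₂ = −2 — plausible magnitudes for this population, not ground truth;
* Gaussian patient random effects on the four recovery parameters with
  SDs 100 (V̇O₂ss), 50 (V̇O₂rec), 0.3 (τ₂) and 25 s (T₁/₂V̇O₂), diagonal
  covariance in truth to match the default fitted structure (a correlated
  option exists for robustness work); draws violating the parameter-space
  constraints are redrawn, at most 100 times;
* resting lengths λᵢ uniform on 30–90 s, breath intervals jittered uniform
  on 2–4 s (realistic breath density feeding the 20-s binning), recovery
  recorded for 300 s after the walk, and i.i.d. Gaussian breath noise with
  SD 50 mL/min (5% of the 1000 mL/min exercise span).

It does **not** emulate device artifacts, outlier breaths, dropout,
autocorrelated noise, or the SpO₂/heart-rate/V̇CO₂ channels. Passing
recovery tests on these cohorts therefore demonstrates correctness of the
estimation machinery under the model's own assumptions — not robustness to
the ways real breath-by-breath data violate them.

## Problem sizes used by the test suite

Unit tests run on 12–24-patient cohorts where the property under test is
algebraic, and on full 61-patient cohorts where Wald intervals matter (at
smaller sizes the random-effect variance is estimated too poorly for
"within 3 SE" checks to be meaningful). The coverage check uses 15
replicates at full size, the contrast-power check 20 replicates, and the
subgroup-selection check 20 seeds of a 21-patient single-stage cohort.

## Known limitations

* **Truncated recovery limits identifiability.** With 300 s of recorded
  recovery and half-times up to ~170 s, the recovery plateau is partly
  extrapolated; per-patient half-time estimates are roughly median-unbiased
  but their standard errors grow with the estimate (slow recoverers are
  less identified; correlation between estimate and SE reaches ~0.9 in the
  most affected stage).
* **Weighted regression is biased under estimate-dependent weights.** The
  correlation above means inverse-variance weighting systematically
  down-weights large half-times, biasing the weighted-regression stage
  means low — several of its own (small) standard errors below the
  generating values on synthetic cohorts, and an extreme form of the
  shrink-toward-the-mean behaviour this strategy is known for. The
  mixed-effects and meta-analytic strategies recover the generating
  stage means within Wald uncertainty under the same conditions. Users
  should treat the weighted route as a fast descriptive cross-check, not
  as the primary estimator, whenever per-patient precision varies with the
  parameter value.
* **Second-step AICs are not family-selection tools** (see above); use the
  mixed-effects subgroup AIC for that question.
* The exact numerical output of any nonlinear mixed-effects fit depends on
  optimizer settings; reproduction of third-party results is statistical,
  not bit-exact.

```{r example}
cohort <- generate_cohort(default_truth(seed = 42))
pl <- run_pipeline(data = cohort$breaths, families = "log_logistic")
pl$table2
```
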