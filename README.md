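# vo2kinetics

Modelling of post-exercise oxygen-uptake recovery after 6-minute walk tests
(6MWT) in chronic obstructive pulmonary disease (COPD), with multimodel
inference across curve families and across cohort-summarization strategies.

The package is aimed at exercise physiologists and biostatisticians who
collect breath-by-breath V̇O₂ traces around a submaximal walking test and
want stage-level (GOLD 2/3/4) estimates of recovery speed — in particular
the recovery half-time T₁/₂V̇O₂ — together with honest uncertainty about
both the curve model and the pooling strategy.

## The model

Each patient's trace is described by a six-parameter curve combining a
mono-exponential exercise rise with a sigmoid recovery decline. With
resting phase of length λ (aligned to the cohort maximum λ_max) and a
360-s walk,

    V̇O₂(t) = V̇O₂rest
            + (V̇O₂ss − V̇O₂rest) · (1 − exp(−(t − λ)/τ₁))          (t > λ)
            + (V̇O₂rec − V̇O₂ss) · g((t − t₀)/T₁/₂V̇O₂; τ₂)          (t > t₀)

where t₀ = λ_max + 360 is the recovery onset and the recovery fraction `g`
defines the family (x = elapsed recovery time over T₁/₂V̇O₂, z = x^τ₂):

| family       | g(x)           | shape                                  |
|--------------|----------------|----------------------------------------|
| log-logistic | 1/(1 + z)      | symmetric; g = 1/2 exactly at x = 1    |
| Weibull 1    | exp(−z)        | steep early decline; g(1) = e⁻¹        |
| Weibull 2    | 1 − exp(−z)    | late decline; g(1) = 1 − e⁻¹           |

Three strategies summarize a cohort of such curves:

1. **Nonlinear mixed effects** (`fit_nlme()`): stage-specific fixed effects
   for all six parameters, Gaussian patient random effects on the four
   recovery parameters (V̇O₂ss, V̇O₂rec, τ₂, T₁/₂V̇O₂), fitted by the
   Lindstrom–Bates algorithm.
2. **Two-step meta-analysis** (`fit_patient()`/`fit_cohort()` then
   `fit_meta()`): per-patient least squares, then a random-effects
   meta-regression of the extracted T₁/₂V̇O₂ estimates on stage, with the
   first-step standard errors as known within-patient variances and REML
   heterogeneity τ².
3. **Two-step weighted regression** (`fit_weighted()`): the same extracted
   estimates pooled by weighted least squares with weights 1/σᵢ² and a
   multiplicative residual scale; inference on t with m − q df.

Within each strategy the three families are combined by Akaike weights
w_p ∝ exp(−Δ_p/2) (`akaike_weights()`) into a model-averaged estimate
θ̂_MA = Σ w_p θ̂_p with the conservative unconditional standard error
Σ w_p √(var(θ̂_p) + (θ̂_p − θ̂_MA)²) (`model_average()`). Stage contrasts
(4−2, 3−2, 4−3) with Wald p-values come from `all_contrasts()`, and
`subgroup_aic()` compares the families' goodness of fit within each stage.

Because the underlying clinical dataset is not shipped, `generate_cohort()`
simulates cohorts with the same statistical structure (21/30/10 patients in
stages 2/3/4, patient heterogeneity on the recovery parameters, i.i.d.
Gaussian breath noise) and returns the generating truth for validation.

## Worked example

```r
library(vo2kinetics)

cohort <- generate_cohort(default_truth(seed = 42))
pl <- run_pipeline(data = cohort$breaths, families = "log_logistic")
dplyr::filter(pl$table2, grepl("4-2", label))
#> # A tibble: 3 × 6
#>   method   family       label      estimate std.error   p.value
#>   <chr>    <chr>        <chr>         <dbl>     <dbl>     <dbl>
#> 1 mixed    log_logistic COPD (4-2)     63.7      15.3 0.0000329
#> 2 meta     log_logistic COPD (4-2)     43.2      13.0 0.000907
#> 3 weighted log_logistic COPD (4-2)     50.4      22.3 0.0277
```

Each row is one strategy's estimate of the difference in recovery half-time
(seconds) between very severe (GOLD 4) and moderate (GOLD 2) COPD on this
simulated cohort, whose generating difference is 40 s: all three strategies
detect a slower recovery in the more severe stage, with the two-step
strategies attenuated relative to the mixed-effects fit. Running all three
families and averaging (`run_pipeline(data = cohort$breaths)`) adds the
per-family AICs, Akaike weights and the model-averaged row in `pl$table3`;
`autoplot(pl)` draws the per-stage estimates.

The averaging algebra itself is exact: applied to the reported AIC triple
of the mixed-effects fits,

```r
round(akaike_weights(c(36556, 36578, 36567)), 3)
#> [1] 0.996 0.000 0.004
```

virtually all support goes to the log-logistic family.

## Vignette

`vignettes/recovery-kinetics.Rmd` documents the model, the estimation
choices (initialization, tolerances, reference distributions), what the
synthetic cohorts do and do not emulate, and known limitations.
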