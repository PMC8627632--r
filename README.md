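# hazext

Survival extrapolation with flexible and dynamic hazard models.

Health-technology assessments routinely need survival estimates far
beyond the follow-up of the pivotal trial: a model is fitted to two or
three years of right-censored data and its hazard is extrapolated over a
decade or more. `hazext` is a simulation and evaluation toolkit for
studying how well different hazard-model classes do this. It provides

- a fully specified **two-component mixture-Weibull data-generating
  mechanism** with closed-form survival and hazard functions,

  S(t) = ρ·exp(−Λ₁ t^γ₁) + (1 − ρ)·exp(−Λ₂ t^γ₂),

  λ(t) = [ρ Λ₁γ₁ t^{γ₁−1} e^{−Λ₁ t^{γ₁}} + (1−ρ) Λ₂γ₂ t^{γ₂−1} e^{−Λ₂ t^{γ₂}}] / S(t),

  with defaults (γ₁, Λ₁, γ₂, Λ₂, ρ) = (1.8, 0.02, 1.4, 2.3, 0.5): a
  short-survival and a long-survival sub-population whose mixture hazard
  rises, falls, and rises again (two turning points), with true survival
  46.8% / 43.3% / 39.2% at 2 / 3 / 4 years;
- cohort simulation under administrative censoring for nine scenarios
  (n = 100/300/600 × follow-up 2/3/4 years);
- five classes of hazard model fitted to right-censored data behind one
  interface: **standard parametric families** (exponential, Weibull,
  Gompertz, log-logistic, lognormal, gamma, generalised gamma),
  **Royston–Parmar** restricted cubic spline models on the hazard or
  odds scale, **fractional-polynomial** log-hazard regressions (8 FP(1)
  and 36 FP(2) specifications), a **penalised-spline (GAM)** hazard in
  log-time, and Bayesian **dynamic survival models** whose level and
  trend states evolve as random walks, with optionally damped trend
  (φ ∈ (0,1), estimated) so extrapolations level off;
- a **simulation-study engine** scoring time-varying MSE and bias of
  estimated log-hazards against the known truth, within sample, out of
  sample, and overall;
- an adapter for user-supplied individual patient data and a
  case-study workflow (fit to an early data cut, compare extrapolations
  against a later cut).

The estimand throughout is the natural logarithm of the time-varying
hazard, predicted over any positive time grid including extrapolation
times.

## Worked example

```r
library(hazext)

# one cohort from the default mechanism: n = 300, censored at 3 years
d <- simulate_cohort(scenario(300, 3), seed = 7)
sum(d$event)
#> [1] 183

# current practice: fit all parametric families, select by AIC
f <- fit_hazard(d, "current_practice")
f
#> Hazard model fit: generalised_gamma
#>   log-likelihood -335.2761 on 3 parameter(s), n = 300
#>   AIC 676.5522, BIC 687.6636

# dynamic survival model with damped trend and local level
ds <- fit_dsm(d, trend = "damped", level = "local", seed = 7)
round(mean(ds$phi_draws), 3)   # posterior mean damping factor
#> [1] 0.897
predict(ds, c(1, 3, 5, 10))
#>   time log_hazard     lower      upper
#> 1    1 -0.8905604 -1.262217 -0.5731235
#> 2    3 -2.0553521 -2.781340 -1.3480652
#> 3    5 -2.0562917 -2.780821 -1.3809121
#> 4   10 -2.0530812 -2.783247 -1.3655628
```

The AIC-selected generalised gamma's log-hazard declines over the whole
horizon, while the damped-trend dynamic model's extrapolated log-hazard
flattens beyond follow-up (the trend state decays geometrically at rate
φ ≈ 0.9 per 0.1-year interval), with a 90% posterior band.

A small simulation experiment — replicate cohorts are simulated, each
model class is fitted and selected within class by AIC, and predicted
log-hazards are scored against the closed-form truth on a 0.05-year
grid to a 10-year horizon:

```r
run_scenario(scenario(100, 2, id = 1),
             classes = c("current_practice", "gam"),
             n_replicates = 5, base_seed = 1)
#> Scenario: n=100, follow-up 2 years (5 replicates)
#>             class mse_within mse_out mse_overall bias_overall n_effective failures
#>  current_practice     0.4482  0.9640      0.8608      -0.2781           5        0
#>               gam     0.1812  8.1840      6.5837      -1.8225           5        0
```

Read: the penalised spline fits the observed two years much better
(within-sample MSE 0.18 vs 0.45) but extrapolates far worse (out-of-sample
MSE 8.2 vs 0.96) — the central trade-off the package is built to expose.

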