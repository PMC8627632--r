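---
title: "Extrapolating hazards: models, simulation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extrapolating hazards: models, simulation design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hazext)
```

## The problem

Reimbursement decisions for new treatments hinge on expected survival
over a lifetime horizon, but trial data typically end after two to four
years. Whatever model is fitted to the observed window must then be
extrapolated, and different model classes that fit the observed data
almost equally well can imply wildly different long-term hazards. This
package implements a controlled laboratory for that problem: a known
data-generating mechanism, five model classes, and an engine that scores
estimated log-hazards against the truth both within and beyond the
observed window.

## The data-generating mechanism

Cohorts are drawn from a two-component mixture-Weibull,

$$S(t) = \rho\, e^{-\Lambda_1 t^{\gamma_1}} + (1-\rho)\, e^{-\Lambda_2 t^{\gamma_2}},$$

interpretable as a high-hazard (short survival) and a low-hazard (long
survival) sub-population. The default parameters are
$(\gamma_1, \Lambda_1, \gamma_2, \Lambda_2, \rho) =
(1.8, 0.02, 1.4, 2.3, 0.5)$. The short-survival component dominates
early, so the mixture hazard first rises and then falls as that
component is depleted; the surviving population is increasingly drawn
from the second component, whose shape parameter exceeds one, so the
hazard eventually rises again — an ageing-like long-term increase. The
hazard's two stationary points under these defaults are at 0.327 and
2.134 years:

```{r}
hazard_turning_points(mixture_weibull())
```

Each subject's event time is drawn by inverse transform within their
latent component, $t = (-\log U / \Lambda)^{1/\gamma}$, and observation
is administratively censored at the follow-up limit — censoring is
deterministic given survival to that time, with no random dropout, so
every censored time equals the follow-up limit. The nine study scenarios
cross $n \in \{100, 300, 600\}$ with follow-up $\in \{2, 3, 4\}$ years
(true survival 46.8%, 43.3%, 39.2% at those times). Replicate $r$ of
scenario $s$ uses seed $\texttt{base\_seed} + 1000s + r$, making every
cell of the experiment independently reproducible and extensible.

What the generator deliberately omits: covariates, competing risks,
informative censoring, cure fractions, and staggered accrual. Passing
performance here therefore says nothing about, for example, dropout
that is correlated with risk; it isolates pure extrapolation behaviour
under a hazard with two turning points.

## The model classes

All fitted models expose one contract: pointwise log-hazard over any
positive grid, including extrapolation times. The estimand summarised
and scored is always the natural log of the hazard.

**Standard parametric families** ("current practice") are fitted by
right-censored maximum likelihood via `flexsurv`. Seven families are
offered (exponential through generalised gamma); the generalised F is
not offered. The Gompertz is fitted but excluded from AIC selection by
default: its exponential-in-time hazard makes it an extreme
extrapolator, and the headline comparisons are run without it (a flag
restores it). Selection within the class is by AIC.

**Royston–Parmar models** place a restricted cubic spline in log-time on
the log cumulative-hazard scale (a Weibull extension) or log
cumulative-odds scale (a log-logistic extension), with 0–5 internal
knots at centiles of the uncensored log event times and boundary knots
at their extremes. Beyond the boundary knots the spline is linear in
log-time, so the extrapolated log-hazard trend is Weibull-like with the
locally estimated slope. With zero internal knots the two scales
reproduce the Weibull and log-logistic exactly; this nesting is verified
to 1e-4 in the tests. Note that fits with different numbers of internal
knots are *not* nested in one another (the knot locations move), so the
log-likelihood need not increase with every added knot; what is
guaranteed — and tested — is that every spline basis dominates the
0-knot linear fit it contains.

**Fractional polynomials** model
$\log \lambda(t) = \beta_0 + \beta_1 g_1(t) + \beta_2 g_2(t)$ with
powers from $\{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}$ (0 denoting $\log t$; a
repeated power $p$ contributes $t^p$ and $t^p \log t$), giving 8 FP(1)
and 36 FP(2) specifications, kept as separate classes and each selected
by AIC within class. Being global polynomials, their extrapolations
follow the fitted polynomial trend and readily diverge to very small or
very large hazards — that behaviour is part of what the simulation
study measures, not a defect of the implementation. Specifications
whose likelihood degenerates (hazard driven to zero in-region,
divergent coefficients) are flagged and excluded from selection.

**Penalised splines (GAM)** fit the log-hazard as a cubic regression
spline in log-time (basis dimension 10) with a curvature penalty whose
null space is exactly the linear-in-log-time functions — i.e. the
Weibull form. The smoothing parameter is estimated by REML, with GCV as
fallback when the REML optimisation fails. As the smoothing parameter
grows the fit collapses onto the Weibull (verified to 0.01 uniformly),
and effective degrees of freedom decrease monotonically. Spline knots
span the event-time range; beyond them the basis continues linearly, and
prediction beyond the data continues the boundary value and slope
linearly in log-time.

**Dynamic survival models** discretise follow-up into equal 0.1-year
intervals and model interval event counts as
$y_k \sim \text{Poisson}(E_k \exp(\alpha_k + \beta_k \log t_k))$ with
exposure $E_k$. The static limit $\alpha_k \equiv \alpha,
\beta_k \equiv \beta$ is exactly a linear Weibull log-hazard; flexibility
comes from letting the trend evolve,
$\beta_k = \phi\,\beta_{k-1} + \epsilon_k$, and optionally the level,
$\alpha_k = \alpha_{k-1} + \eta_k$. The local-trend variant fixes
$\phi = 1$; the damped variant estimates $\phi \in (0,1)$, and damping
acts on the trend state both in-sample and in forecast. Forecasts hold
the level at its final value and damp the trend geometrically,
$\beta_{K+h} = \phi^h \beta_K$, so extrapolated log-hazards flatten to a
constant; with $\phi = 1$ they continue linearly in log-time at the
final trend. The point summary is the posterior mean of the log-hazard
(matching the estimand — not the log of the posterior-mean hazard),
with a central 90% band. Priors are weakly informative and
configurable: half-normal(0.2) on the innovation standard deviations, a
Beta(18, 2) prior on $\phi$ (centred near 0.9, the usual forecasting
default for damping), and N(0, 10²) on the initial states. Posterior
sampling uses JAGS with a fixed seed; innovation scales fixed below
1e-6 are treated as exactly zero, collapsing the state to static — this
both defines the degenerate Weibull limit cleanly and avoids asking the
sampler to traverse a near-degenerate random walk, which mixes
arbitrarily badly.

## The piecewise-exponential device and its grid

The FP and GAM classes (and the DSM's observation layer) are fitted as
Poisson regressions of interval event counts with a log-exposure
offset. The accuracy of this device depends on how interval times enter
the covariate. Because every one of these models is a function of
$\log t$, an equal-width grid is a poor choice: $\log t$ has unbounded
variation near the origin, and the earliest interval — which holds the
whole cohort's exposure — misattributes it badly enough to bias the
fitted log-time slope by about 0.05 on realistic cohorts. The device
therefore uses a *log-uniform* grid: 100 intervals equal in width in
log-time, running from three decades below the first observed time up
to the end of follow-up, with geometric-midpoint representative times
(and $t_{\text{hi}}/e$, the exponential of the mean log-time, for the
initial interval touching zero). Under this grid the device reproduces
the exact censored-data Weibull MLE to ~1e-4, which is the accuracy the
nesting checks rely on. The DSM keeps its equal-width 0.1-year *state*
grid — forecast steps and damping are defined per interval — but each
state interval's observation is split over the finer log-uniform
sub-grid, every sub-row sharing its parent interval's states.

All fitted log-hazards are clamped to ±700 before exponentiation-free
reporting, purely to keep curves finite when a polynomial extrapolation
underflows; the clamp is far outside any scientifically meaningful
range.

## Scoring

For each replicate, each class's selected model predicts log-hazard on
a grid from 0.05 to the 10-year horizon in steps of 0.05 years ($t = 0$
is excluded because the true log-hazard diverges there). At each grid
time, bias is the mean error and MSE the mean squared error across
replicates; fits flagged as failed are excluded from their class's
average and tallied. Window aggregates are unweighted means over grid
points at or before the follow-up limit (within sample), beyond it
(out of sample), and overall. The identity
$\text{MSE} \ge \text{bias}^2$ holds cell-wise and is asserted in the
tests. The 10-year horizon and the unweighted grid aggregation are
package choices exposed as configuration — ordinal comparisons between
classes were stable across the horizons tried, but absolute MSE values
scale with both choices and should not be compared against other
implementations' tables.

The headline simulation finding this package reproduces at reduced
scale (25 replicates, data-rich scenario: n = 600, 4-year follow-up) is
ordinal: the damped-trend, local-level DSM attains lower overall MSE
than current practice, and the two FP classes attain the highest
overall MSE of all classes run. Replicate counts are kept modest so the
whole suite runs on one CPU in minutes; the orderings were already
unambiguous at this scale.

## Degenerate inputs, ties and failure handling

Datasets must have positive times and at least one event; rows with
non-positive times in imported IPD are rejected and counted rather than
silently dropped. Model selection breaks AIC ties by fewest parameters,
then by the fixed candidate ordering in which fitters emit their
specifications. Optimiser non-convergence, non-monotone fitted
cumulative hazards (RPM), divergent coefficients (FP), smoothing
failures (GAM) and sampler errors (DSM) all yield flagged failure
objects that selection and scoring skip and count — a run never dies on
a single bad fit.

## Known limitations

Only one mechanism shape is built in (two turning points, long-term
rise); conclusions do not transfer to cure-fraction or
proportional-hazards-with-covariates settings, which are out of scope.
DSM chains are run single-chain with modest lengths by default —
adequate for point summaries of log-hazard at the tested sizes, but
anyone using the posterior bands for inference should lengthen them and
check effective sample sizes (stored in the fit). The case-study
workflow's smoothed nonparametric hazard is a kernel-smoothed
occurrence/exposure estimate intended for visual comparison only.
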