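---
title: "Models, priors and Monte-Carlo evaluation in bsced"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, priors and Monte-Carlo evaluation in bsced}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsced)
```

## The problem

A single-case experimental design (SCED) measures one subject repeatedly
through a baseline phase and a treatment phase. Trend in such a series can
come from two sources that are nearly confounded on 10–30 observations: a
genuine phase *slope*, and lag-1 *autocorrelated* errors. A model that
estimates both can attribute the same visible trend to either source, so the
credible intervals of both the slope and the autocorrelation may cover 0 even
when neither true value is 0 — an *indeterminacy* that inflates type II
errors. `bsced` exists to fit the four models that bracket this choice and to
measure, by simulation, what each one does to parameter recovery.

## The models

Let phase 1 occupy times $1,\dots,t_b$ and phase 2 the following $t_i$
points. The mean structure is piecewise linear,

$$\hat y_t = \begin{cases}
\beta_{11} + \beta_{21}\,t, & t \le t_b\\
\beta_{12} + \beta_{22}\,(t - t_b), & t > t_b,
\end{cases}$$

with first index 1 = intercept, 2 = slope and second index = phase (the
package labels every output by role — `intercept_p1`, `slope_p2` — precisely
because bare double subscripts are ambiguous). Residuals
$e_t = y_t - \hat y_t$ follow a first-order autoregression
$e_t = \rho\,e_{t-1} + \varepsilon_t$, $\varepsilon_t \sim N(0,
\sigma^2_\varepsilon)$. The first point of each phase is drawn around its
regression mean with SD $\sigma_\varepsilon$ and the recursion restarts at
the phase boundary; a single process across the boundary ("carry-over") and a
stationary initialization with the marginal SD
$\sigma_e = \sigma_\varepsilon/\sqrt{1-\rho^2}$ are available behind
`sced_gen_config()` flags. The likelihood factorizes conditionally: every
point after a phase's first is Gaussian around
(regression mean $+\,\rho \times$ previous residual) with innovation SD
$\sigma_\varepsilon$. A unit test verifies this factorization against a
joint multivariate-normal density whose covariance is built directly from the
recursion; note that with the first residual drawn at SD
$\sigma_\varepsilon$ the error process is *not* stationary, so the
stationary AR(1) covariance would be the wrong oracle.

The four fitted structures are `IO` (intercepts only), `NS` (intercepts +
$\rho$, no slopes), `SI` (intercepts + slopes, no $\rho$) and `SA` (all of
the above). Components a model omits are pinned at 0 and never sampled, which
makes the nesting lattice an exact likelihood identity (tested at 1e-12).

## Priors

The hierarchy is weakly informative:
$\beta_{1p} \sim N(\mu_{1p}, \sigma^2_{int})$,
$\beta_{2p} \sim N(\mu_{2p}, \sigma^2_{slope})$ with
$\mu_{1p} \sim \mathrm{unif}(0, 50)$, $\mu_{2p} \sim N(0, 1)$,
$\sigma_\varepsilon \sim \mathrm{unif}(0.1, 5)$,
$\rho \sim \mathrm{unif}(-1, 1)$. The intercept and slope variances are
drawn from gamma distributions whose *mode* and *SD* are themselves uniform
on $(0.01, 1)$; `gamma_from_mode_sd()` converts that parameterization to
shape/rate (always with shape $> 1$, so the density vanishes at 0). Whether
the gamma governs the variance or the SD of the coefficient distributions is
genuinely open; the package defaults to the variance scale and exposes
`hyper_scale = "sd"` as the alternative — both normalize correctly (tested
by quadrature). Any parameter can be pinned by a degenerate prior through
`sced_prior(fixed = ...)`, which is also how the conjugate unit tests reduce
the model to a closed-form normal–normal problem.

## Effect sizes

Per retained draw, the intercept effect size is the standardized mean
difference $ES_1 = (\beta_{12} - \beta_{11})/\sigma_\varepsilon$, using each
draw's own $\sigma_\varepsilon$ in the denominator (the fully Bayesian
reading; a posterior summary of $\sigma_\varepsilon$ would be the
alternative). The slope effect size is the difference between the predicted
value at the midpoint of the intervention phase with and without an
intervention effect,
$ES_2 = (\beta_{12} + M\beta_{22}) - (\beta_{11} + M\beta_{21})$ with
$M = t_b + t_i/2$. Two remarks. First, $M$ uses *absolute* time even though
phase-2 time is coded $t - t_b$; this is internally tense but is implemented
as stated because the same formula is applied to the true parameters and to
every draw, so recovery comparisons are coherent. Second, for models without
slopes $ES_2$ reduces exactly to the intercept difference.

Point estimates are pooled-chain posterior means; intervals are 95%
equal-tailed sample quantiles (the field default — highest-density intervals
are out of scope), with containment inclusive at the endpoints (a
measure-zero convention that only matters for degenerate draws).

## The synthetic-data generator

`sced_conditions()` enumerates the fully crossed design — phase length
$\{5, 8, 10, 15\}$, $\sigma_\varepsilon \in \{1, 2, 5\}$,
$ES_1 \in \{0.5, 1, 2, 5\}$, $ES_2 \in \{0, 0.3, 0.5, 1\}$,
$\rho \in \{0, 0.2, 0.5, 0.8\}$ — 768 conditions, ordered with phase length
varying slowest and $\rho$ fastest. `true_params()` inverts the effect-size
definitions into generative coefficients. Two inversions are defensible and
both ship:

* `pure_slope` (default): $\beta_{22} = ES_2 / M$, assigning the whole slope
  effect to the slope-difference term. This keeps $ES_1$ and $ES_2$
  orthogonal as crossed factors, at the price that the *total*
  mid-intervention contrast equals $ES_1\sigma_\varepsilon + ES_2$.
* `literal`: $\beta_{22} = \beta_{21} + (ES_2 - ES_1\sigma_\varepsilon)/M$,
  making the full contrast equal $ES_2$ exactly — which turns $\beta_{22}$
  negative whenever $ES_1\sigma_\varepsilon > ES_2$.

Under either mapping the *stored* true effect sizes are recomputed from the
betas with the same formulas the estimator uses, so coverage and bias are
measured against internally consistent targets. The baseline intercept is
not pinned down by the design factors; the default is 20, the centre of the
0–50 range the intercept prior means live on, and the baseline slope
defaults to 0 (no pre-intervention trend). Per-dataset seeds are derived by
an integer hash of (root seed, condition index, replication index), so any
single dataset is reproducible in isolation and results are independent of
execution order.

What the generator emulates is exactly the models' own stochastic structure:
Gaussian innovations, a single lag-1 coefficient common to both phases,
equal phase lengths. Real SCED data bring non-Gaussian outcomes (counts,
bounded scales), unequal and multiple phases, session-level
non-stationarity, and measurement artefacts, none of which are generated
here — so passing tests certify the estimation machinery, not robustness to
those features.

## The sampler

The posterior is explored by adaptive random-walk Metropolis-within-Gibbs on
transformed coordinates: $\rho$ on the logit of $(\rho+1)/2$, variances on
the log scale, bounded-uniform parameters ($\mu_{1p}$,
$\sigma_\varepsilon$, the gamma hyperparameters) on the logit of their
support, everything else untransformed. Step sizes adapt toward 44%
acceptance in batches of 50 during burn-in only, so the post-burn-in kernel
is fixed and valid. Chains start from independent prior draws; a start with
non-finite posterior is redrawn (up to 100 times, then the fit aborts with
"posterior unevaluable").

Convergence is certified per fit by the Brooks–Gelman multivariate potential
scale reduction factor on the free parameters
($(n-1)/n + \frac{m+1}{m}\lambda_{\max}(W^{-1}B/n)$, threshold 1.1 — the
common practice value, configurable) together with per-parameter, per-chain
Heidelberger–Welch stationarity tests (Cramér–von Mises on the Brownian
bridge of cumulative sums, spectral density at zero from an AIC-selected AR
fit, front-discarding 0–40% in 10% steps; default $\alpha$ = 0.01 because
the test runs once per parameter per chain). A failed check extends every
chain by another block of draws, up to `max_rounds`; a fit that still fails
is returned with `converged = FALSE` and *kept* — diagnostics count it in
`n_converged`, and a strict-exclusion switch exists. With ~14 free
parameters and 4 chains some fraction of stationarity tests fail by chance
alone, so a `FALSE` flag is a caution marker, not a verdict.

Sampler correctness is certified internally, not against another sampler: a
conjugate normal–normal case with degenerate hyper-priors must match the
closed-form posterior within Monte-Carlo error, and simulation-based
calibration (rank of the true parameter among thinned posterior draws over
200 prior-predictive replicates) must be uniform. Defaults are desk-scale —
burn-in 2,000 and 4,000 retained draws per chain; a `"paper"` profile raises
burn-in to 100,000 for full-scale runs.

## Recovery diagnostics and the study harness

For each (condition, model, parameter): RMSE of posterior means, mean bias,
relative bias (undefined when the true value is 0, and flagged "substantial"
above |0.05|), coverage and 0-coverage of the credible intervals, and mean
posterior SD. The indeterminacy cross-tab classifies each dataset by whether
the $\rho$ and phase-2-slope intervals cover 0 (both / $\rho$ only / slope
only / neither), restricted by default to conditions where neither true
value is 0. `replication_adequacy()` reports where the cumulative RMSE trace
settles (successive changes below 0.03 by default); note that estimates
alternating symmetrically around the truth give a *constant* cumulative
RMSE, so "settled" does not imply "precise" — the threshold measures
stability of the Monte-Carlo summary, nothing more.

`eta_squared()` decomposes each diagnostic over the design factors with a
fixed-effects ANOVA containing all main effects and two-way interactions,
reporting $SS_{term}/SS_{total}$ in percent. The unit of analysis is one row
per condition (per-condition aggregates such as RMSE), with `model` entering
as an extra crossed factor when models are compared — the reading that
reproduces a per-diagnostic, per-parameter table structure. Shares are
invariant to affine rescaling of the response, which is also why the
corrected (mean-centred) total is the right denominator; a constant response
is reported as all-zero shares by convention.

## Problem sizes used by the tests

The package's own test suite runs everything at desk scale, chosen so the
full pipeline is exercised end to end on one CPU: simulation-based
calibration and the correct-specification coverage check use 200 replicates
each; the qualitative indeterminacy study uses 16 conditions (phase lengths
{5, 10}, $\sigma_\varepsilon = 1$, $ES_1 \in \{1, 2\}$,
$ES_2 \in \{0.3, 1\}$, $\rho \in \{0.5, 0.8\}$) with 25 replications and the
NS/SA pair, i.e. 800 fits with 4 chains of 800 retained draws. The full
768-condition, 100-replication, 4-model design (76,800 datasets) is what
`sced_study_config()` describes by default and is intended for long
unattended runs with the `"paper"` sampler profile; the reduced runs
reproduce directions and rough magnitudes, not the full design's percentages
to the decimal.

## Known limitations

Two equal-length phases only (no ABAB, multiple-baseline or alternating
treatments); Gaussian outcomes; one subject (no multilevel pooling); a
single common $\rho$ (no higher-order AR or MA terms); random-walk MCMC
rather than gradient-based sampling, which is ample at these dimensions but
would not scale to long series; and credible intervals are equal-tailed
quantiles only.
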