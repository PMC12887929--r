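---
title: "Simulation-based power analysis for interrupted time series: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation-based power analysis for interrupted time series: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itspower)
```

## Why simulate

Interrupted time-series (ITS) designs estimate the effect of an
intervention from a single outcome series observed before and after it.
The standard analysis is ARIMA regression with an exogenous intervention
regressor. Analytic power formulas exist only for the simplest versions
of this problem; once the generating process involves autocorrelated
errors, a confounding covariate, a baseline trend, or a temporary
(pulse) effect, the honest way to compute power is to simulate the whole
pipeline: draw a series from a known data-generating process (DGP), fit
the intended analysis model, test the intervention coefficient, and
repeat. Power is the rejection proportion; every quantity this package
reports is produced by exactly that loop.

## The data-generating process

One replicate of length $t$ with the intervention after timepoint $k$ is

$$y_\tau = \beta_0 + \beta_1 x_\tau + \beta_2 c_\tau + g_\tau +
  \varepsilon_\tau, \qquad \tau = 1, \dots, t,$$

assembled by `simulate_its()` from four components, each drawn fresh in
every Monte Carlo replicate:

**Intervention regressor** $x_\tau$ (`build_intervention_regressor()`).
A *step* is 0 up to $k$ and 1 from $k+1$; a *pulse* is 1 for
`pulse_duration` timepoints from $k+1$ and 0 elsewhere; a *change in
trend* is $\max(0, \tau - k)$, so $\beta_1$ is the slope change per
timepoint and the post-intervention slope is the baseline slope plus
$\beta_1$.

**ARMA errors** $\varepsilon_\tau$ (`simulate_arma_errors()`). A
stationary, invertible ARMA($p$, $q$) process with independent Gaussian
innovations of standard deviation `noise_sd` (the *innovation* SD, not
the marginal SD of the errors: for an AR(1) with coefficient $\phi$ the
marginal error variance is $\sigma^2/(1-\phi^2)$). Validation
(`validate_error_model()`) checks each coefficient lies strictly in
$(-1, 1)$ and, because the box constraint is not sufficient beyond order
one, that all characteristic-polynomial roots lie outside the unit
circle. Simulation generates $\max(200,\ 10(p+q+1))$ extra points and
discards them, so the retained segment is a draw from the (approximate)
stationary distribution rather than reflecting arbitrary start-up
values.

**Covariate** $c_\tau$ (`simulate_covariate()`). An AR(1) process with
lag-1 coefficient fixed at 0.5 — a deliberately simple stand-in for
"typical" smoothly varying real-world confounders — parameterised by its
*marginal* mean and SD (so the innovation SD is
$\mathrm{sd}\sqrt{1-0.25}$; users specify moments they can estimate from
data), plus an optional level shift from $k+1$ that makes the covariate
intervention-correlated, i.e. a genuine confounder.

**Baseline trend** $g_\tau$ (`build_baseline_trend()`). Deterministic:
$\text{magnitude} \cdot (0, 1, \dots, t-1)$, anchored at zero so
$\beta_0$ keeps its meaning as the expected outcome at the first
timepoint. Stochastic: magnitude times the cumulative sum of independent
$N(0, \text{sd}^2)$ innovations — a scaled random walk whose shocks
permanently move the level. The two strength parameters (scaling factor
and innovation SD) are kept separate; the scaling factor multiplies the
raw walk, with 1 adding it unchanged and 0 removing it.

On the log scale (`log_transform_outcome = TRUE`) the same arithmetic
applies with every coefficient interpreted as a log-scale quantity: the
simulated series is the log-outcome and a coefficient $\beta$
corresponds to a multiplicative effect $e^\beta$ on the original scale.
No transformation is applied by the package — the flag is a unit
declaration, which is why it changes no simulation code path.

Differencing never enters the DGP: the error-model $d$ (and the
trend-by-differencing option) applies only to the *fitted* model.
Integrated behaviour on the data side enters solely through the
stochastic trend. Periodicity is carried as metadata (axis labels); no
seasonal structure is simulated or fitted.

## The analysis model

`build_design()` translates the scenario into the fitted model: the
intervention regressor always; the covariate column iff
`model_covariate`; a linear time column iff the trend is handled as an
exogenous regressor. For a change-in-trend intervention the time column
is the baseline slope and the slope-change regressor is the tested
column. Handling the trend by differencing sets $d = 1$ and adds no time
column (no direct time coefficient exists in that parameterisation).
Because DGP inclusion and model inclusion are independent switches,
omitted-variable and ignored-trend analyses are first-class scenarios.

`fit_its_model()` fits Gaussian maximum-likelihood ARIMA regression via
`stats::arima` (CSS starting values, ML final estimates; intercept
included when $d = 0$) and computes a two-sided Wald $z$ p-value for the
target coefficient from the asymptotic covariance. The normal reference
was chosen over a $t$ approximation because the decision rule being
emulated is the plain "$P < 0.05$" of applied ITS practice; at the
series lengths where the two differ materially (near the $t = 20$ lower
bound) simulation-based power is approximate anyway. With no ARMA terms
and $d = 0$ the estimator coincides with ordinary least squares, which
the test suite exploits as an independent oracle.

Optimiser failures are flagged, not raised. The power estimator excludes
failed replicates from the denominator — treating them as automatic
non-rejections would bias power downward — and raises an error if more
than 20% of replicates fail, on the view that a scenario the fitter
cannot handle one time in five needs redesign, not a power number.

## Power, inversion, tables

`estimate_power()` runs `n_sims` replicates and reports the rejection
proportion with its binomial standard error
$\sqrt{\hat\pi(1-\hat\pi)/n_\text{eff}}$. Each replicate runs on its own
substream seed derived from the master seed, so estimates are
bit-reproducible and order-invariant (parallel execution would not
change results). The default `n_sims = 1000` (mc se $\approx 0.013$ at
power 0.8) matches common reporting practice; `alpha` defaults to 0.05
two-sided.

`minimal_detectable_effect()` inverts the power function over the effect
magnitude: the bracket upper end starts at the configured effect (or 1)
and doubles until its power reaches the target, then bisection shrinks
the bracket below `tol` (default 0.05 effect units) or stops early when
an evaluation lands within `power_tol` (default 0.01) of the target. All
evaluations reuse the same replicate substreams — common random numbers
— so the estimated power is monotone in the effect along the search and
the bisection cannot oscillate on Monte Carlo noise. The returned effect
is the final bracket midpoint with its power measured once more; its
accuracy is limited by both `tol` and the Monte Carlo error of each
evaluation (roughly mc se divided by the local slope of the power
curve). Monotonicity of true power in $|\beta_1|$ is assumed, which
holds for these Wald tests.

`generate_lookup_table()` batch-produces power over a
(series length × effect size) grid under the conventions used for
quick-reference ITS tables: intercept 0, intervention at the midpoint
$k = \lfloor t/2 \rfloor$, no covariate or baseline trend, pulse
duration 1, and — for change-in-trend tables — a zero-slope baseline
deterministic trend *modelled* as a time regressor (so the analysis
matches what a practitioner expecting a trend would fit). Cells are
independent simulations seeded by a hash of (master seed, $t$, effect),
making the table regenerable cell-by-cell in any order. A minimum length
of 20 timepoints is enforced throughout: below that, autocorrelation
estimates are routinely non-stationary and fits unstable.
`flag_nonmonotone_cells()` screens a table for cells that violate the
expected monotonicity beyond Monte Carlo error — useful when vetting a
regenerated table against a printed one, whose layout may carry
typesetting artifacts that a correct simulator should *not* reproduce.

## Numerical and design choices

- **Seeds.** One master seed drives everything; substreams are drawn by
  `sample.int` under the master seed. Identical (scenario, seed) gives
  bit-identical output, tested as such. Helper code restores the
  caller's RNG state.
- **Degenerate inputs.** `noise_sd` must be strictly positive (the
  analysis model is meaningless for a deterministic outcome); covariate
  `sd = 0` is allowed and yields a constant covariate; stochastic-trend
  magnitude 0 removes the trend exactly. Collinear design matrices raise
  a descriptive error rather than reaching the optimiser.
- **Validation is structural, not statistical**: stationarity and
  invertibility are root conditions checked exactly; `k` must leave at
  least two post-intervention points; a pulse must end within the
  series.
- **CSV round trips.** Lookup tables serialise losslessly (numerics at
  17 significant digits under a version-stamped metadata header); the
  two-decimal wide layout of printed tables is a separate export, so
  presentation never limits precision.

## What the simulations do and do not show

The generator emulates the stylised conditions under which ITS power is
conventionally studied: Gaussian innovations, complete equally spaced
observations, a single continuous AR(1) covariate, linear trends, and
abrupt intervention onset. Real data violate these in familiar ways —
seasonality, outliers, missing values, gradual (transfer-function)
onsets, multiple or categorical confounders, non-linear trends — and the
package deliberately does not model them. A passing test suite therefore
demonstrates that the simulator and its inversion are correct *under the
stated DGP*, not that a real study with messier data will achieve the
computed power; users should treat results as best-case planning numbers
and stress-test assumptions (especially `noise_sd` and the AR
coefficient, to which power is very sensitive) over plausible ranges.

Problem sizes used by the test suite reflect this purpose: structural
checks run on short series (t = 40–100) at a few hundred replicates,
while the reproduction checks of published quantities use the original
scale (t up to 400, 1000–2000 replicates), where a power estimate
carries mc se ≈ 0.013 — agreement is asserted within that Monte Carlo
tolerance, never exactly.

## Known limitations

Seasonal ARIMA, transfer functions (gradual effects), three-phase
designs, multiple covariates, non-Gaussian innovations and irregular
sampling are out of scope by design. The Wald z-test is asymptotic: near
the 20-timepoint lower bound, rejection rates under the null run above
the nominal level (visible as inflated power at tiny effects in short
series), which is a property of the analysis being emulated rather than
of the simulator. The minimal-detectable-effect search assumes power is
monotone in the effect magnitude and that the target power is reachable;
scenarios where 80% power requires implausibly large effects fail with a
bracket-expansion error rather than extrapolating.
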