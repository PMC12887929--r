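# itspower

Monte Carlo power analysis for interrupted time-series (ITS) studies
analysed with ARIMA intervention models.

Interrupted time series is the workhorse quasi-experimental design for
evaluating policies and population-level interventions — a tobacco
packaging law, a minimum unit price for alcohol, a one-day drug take-back
event — where an outcome is observed repeatedly before and after the
intervention but randomisation is impossible. Formal power calculations
are rare in this literature because closed-form formulas break down once
the data-generating process involves autocorrelated errors, confounders
and trends. `itspower` closes that gap by simulation: it generates
outcome series under a fully specified data-generating process, fits the
analysis model to each replicate, and estimates power as the proportion
of replicates in which the intervention effect is detected.

The package is aimed at epidemiologists, addiction and health-policy
researchers, and applied statisticians planning (or retrospectively
assessing) ITS studies.

## The model

One simulated outcome series of length *t* with the intervention after
timepoint *k* is

```
y_τ = b0 + b1 · x_τ + b2 · c_τ + g_τ + e_τ ,          τ = 1, …, t
```

where

- `x_τ` encodes the intervention: a **step** (0 before, 1 from k+1 on), a
  **pulse** (1 for `pulse_duration` timepoints from k+1, then 0), or a
  **change in trend** (0, …, 0, 1, 2, 3, … from k+1, so `b1` is the
  change in slope per timepoint);
- `c_τ` is an optional time-varying covariate, an AR(1) process with
  lag-1 coefficient 0.5, given marginal mean and SD, and an optional
  level shift after k (an intervention-correlated confounder);
- `g_τ` is an optional baseline trend, either deterministic
  (`magnitude · (0, 1, …, t−1)`) or stochastic (a scaled random walk);
- `e_τ` is a stationary, invertible ARMA(p, q) error process with
  Gaussian innovations of standard deviation `noise_sd`.

Each replicate is analysed by Gaussian maximum-likelihood ARIMA(p, d, q)
regression with exogenous regressors (`stats::arima`): always the
intervention regressor, plus the covariate and/or a linear time term
according to the model specification (trends can instead be handled by
first differencing, d = 1). The intervention coefficient is tested
two-sidedly with an asymptotic Wald z-test; power is the rejection
proportion at level alpha, reported with its binomial Monte Carlo
standard error. The power function can be inverted by bracketing and
bisection (with common random numbers) to the **minimal detectable
effect** at a target power, and batch-generated over
(series length × effect size) grids as lookup tables.

Deliberately misspecified analyses — omitting a real confounder or
ignoring a real trend — are one flag away, so the cost of model
misspecification can be quantified in power terms.

## Worked example

Power of a single-day collection event (a 1-day pulse) on the daily
volume of prescription opioids collected: 200 daily observations, event
after day 100, baseline 5 kg/day, AR(1) = 0.3 errors with innovation
SD 2 kg.

```r
library(itspower)

sc <- its_scenario(t = 200, k = 100, period = 7, b0 = 5,
                   b1_effect = 5.4, intervention_type = "pulse",
                   pulse_duration = 1,
                   errormodel = error_model(ar = 0.3, noise_sd = 2),
                   n_sims = 1000, seed = 123)

estimate_power(sc)
#> Monte Carlo power: 0.814 (mc se 0.0123) at alpha = 0.05
#>   1000 effective replicates (1000 requested, 0 failed), seed 123

minimal_detectable_effect(sc, target_power = 0.80)
#> Minimal detectable effect at 80% power: 5.231 (pulse intervention)
#>   achieved power 0.794 (mc se 0.0128) in 6 power evaluations
```

So a spike of about 5.4 kg on the event day is detectable with roughly
80% power (the Monte Carlo estimate at exactly 5.4 is 0.814 ± 0.012),
and inverting the power function puts the 80%-power minimal detectable
pulse near 5.2–5.5 kg — anything smaller risks an underpowered study.
`power_curve()` traces the whole power function over an effect grid, and
`plot()` methods draw the power curve and the simulated-series
decomposition.

Lookup tables over a (length × effect) grid:

```r
tab <- generate_lookup_table(
  lookup_grid(times = seq(40, 200, by = 40), effects = seq(0.5, 2, by = 0.5)))
write_lookup_csv(tab, "step_power.csv")        # lossless, metadata header
write_lookup_wide_csv(tab, "step_power_wide.csv")  # printed 2-decimal layout
```

## Command-line interface

A thin Rscript front end exposes the same functionality as `power`,
`curve`, `mde` and `table` subcommands, with flags mirroring the
`its_scenario()` arguments and an optional flat `key = value` config
file. Every run writes `results.json`, a `manifest.json` sufficient to
reproduce it bit-for-bit, and a timing log.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/itspower.R", package="itspower"))')" \
  power --t 200 --k 100 --b0 5 --b1-effect 5.4 --intervention-type pulse \
  --pulse-duration 1 --ar 0.3 --noise-sd 2 --n-sims 1000 --seed 123 --out run1
```

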