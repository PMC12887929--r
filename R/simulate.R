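#' Build the intervention regressor
#'
#' Encodes the intervention as an exogenous regressor over timepoints
#' `1..t`, with the intervention starting at timepoint k+1:
#' \describe{
#'   \item{step}{0 for timepoints 1..k, 1 thereafter.}
#'   \item{pulse}{1 exactly for timepoints k+1 .. k+pulse_duration, else 0.}
#'   \item{trend_change}{0 for 1..k, then 1, 2, 3, ... increasing by one
#'     per timepoint, so its coefficient is the change in slope.}
#' }
#'
#' @param kind `"step"`, `"pulse"` or `"trend_change"`.
#' @param t Series length.
#' @param k Pre-intervention timepoints.
#' @param pulse_duration Pulse length (pulse only); requires
#'   `k + pulse_duration <= t`.
#' @return Numeric vector of length `t`.
#' @examples
#' build_intervention_regressor("step", t = 6, k = 3)
#' build_intervention_regressor("pulse", t = 6, k = 3, pulse_duration = 2)
#' build_intervention_regressor("trend_change", t = 6, k = 3)
#' @export
build_intervention_regressor <- function(kind, t, k, pulse_duration = 1L) {
  stopifnot(t >= 1, k >= 0, k <= t)
  tau <- seq_len(t)
  switch(kind,
    step = as.numeric(tau > k),
    pulse = {
      stopifnot(pulse_duration >= 1, k + pulse_duration <= t)
      as.numeric(tau > k & tau <= k + pulse_duration)
    },
    trend_change = pmax(0, tau - k),
    stop(sprintf("unknown intervention kind '%s'", kind), call. = FALSE))
}

#' Simulate the AR(1) covariate
#'
#' Draws the time-varying covariate as an AR(1) process with lag-1
#' coefficient 0.5, marginal mean `spec$mean` and marginal standard
#' deviation `spec$sd` (the innovation SD is therefore
#' `sd * sqrt(1 - 0.5^2)`), then adds `spec$shift_after_k` to every
#' timepoint after `k`.  With `sd = 0` the covariate is the constant mean
#' (plus the shift).
#'
#' @param spec A [covariate_spec()] with `include_in_dgp = TRUE`.
#' @param t Series length.
#' @param k Pre-intervention timepoints.
#' @return Numeric vector of length `t`.
#' @export
simulate_covariate <- function(spec, t, k) {
  stopifnot(inherits(spec, "its_covariate"), spec$include_in_dgp)
  rho <- 0.5
  x <- if (spec$sd == 0) rep(0, t) else
    as.numeric(stats::arima.sim(list(ar = rho), n = t,
                                sd = spec$sd * sqrt(1 - rho^2),
                                n.start = 200L))
  spec$mean + x + spec$shift_after_k * (seq_len(t) > k)
}

#' Build the baseline trend component
#'
#' A deterministic trend is `magnitude * (0, 1, ..., t-1)`, anchored at
#' zero so the scenario intercept stays the level at timepoint 1.  A
#' stochastic trend is `magnitude` times the cumulative sum of
#' independent Gaussian innovations with SD `stochastic_innov_sd` (a
#' scaled random walk).
#'
#' @param spec A [trend_spec()] with `include_in_dgp = TRUE`.
#' @param t Series length.
#' @return Numeric vector of length `t`.
#' @export
build_baseline_trend <- function(spec, t) {
  stopifnot(inherits(spec, "its_trend"), spec$include_in_dgp)
  if (spec$kind == "deterministic")
    spec$magnitude * (seq_len(t) - 1)
  else
    spec$magnitude * cumsum(stats::rnorm(t, 0, spec$stochastic_innov_sd))
}

#' Simulate one interrupted time-series realisation
#'
#' Assembles a single outcome series from the scenario's components:
#' `y = b0 + b1 * intervention + beta2 * covariate + trend + e`,
#' with `e` a stationary ARMA realisation.  The additive decomposition is
#' exact by construction and is returned alongside the outcome.  When the
#' scenario is on the log scale, `y` is the log-outcome and all
#' coefficients are log-scale quantities.
#'
#' Components are drawn from R's random number stream in a fixed order
#' (errors, covariate, stochastic trend), so results are bit-reproducible
#' given `set.seed()`.
#'
#' @param scenario An [its_scenario()].
#' @return An object of class `"its_series"`: list with elements `y`,
#'   `intervention_regressor`, `covariate_values` (or `NULL`),
#'   `trend_values` (or `NULL`), `errors`, `t`, `k`, and the generating
#'   `scenario`.
#' @examples
#' sc <- its_scenario(t = 40, k = 20, b0 = 10, b1_effect = 2,
#'                    intervention_type = "step", seed = 1)
#' set.seed(sc$seed)
#' s <- simulate_its(sc)
#' head(as.data.frame(s))
#' @export
simulate_its <- function(scenario) {
  stopifnot(inherits(scenario, "its_scenario"))
  t <- scenario$t; k <- scenario$k
  iv <- scenario$intervention
  errors <- simulate_arma_errors(scenario$error_model, t)
  x_iv <- build_intervention_regressor(iv$kind, t, k, iv$pulse_duration)
  covariate <- if (scenario$covariate$include_in_dgp)
    simulate_covariate(scenario$covariate, t, k) else NULL
  trend <- if (scenario$trend$include_in_dgp)
    build_baseline_trend(scenario$trend, t) else NULL
  # single left-to-right sum so the additive decomposition reconstructs
  # bit-identically from the returned components
  y <- scenario$b0 + iv$effect_size * x_iv +
    (if (is.null(covariate)) 0 else scenario$covariate$beta * covariate) +
    (if (is.null(trend)) 0 else trend) +
    errors
  structure(
    list(y = y, intervention_regressor = x_iv, covariate_values = covariate,
         trend_values = trend, errors = errors, t = t, k = k,
         scenario = scenario),
    class = "its_series")
}

#' Simulate replicate series from a scenario
#'
#' `simulate()` method drawing `nsim` independent realisations, each from
#' its own reproducible substream derived from `seed`.
#'
#' @param object An [its_scenario()].
#' @param nsim Number of replicate series.
#' @param seed Master seed; defaults to the scenario's seed.
#' @param ... Unused.
#' @return A list of `nsim` [simulate_its()] results.
#' @export
simulate.its_scenario <- function(object, nsim = 1, seed = object$seed, ...) {
  seeds <- derive_seeds(seed, nsim)
  lapply(seeds, function(s) {
    set.seed(s)
    simulate_its(object)
  })
}

#' @export
print.its_series <- function(x, ...) {
  cat(sprintf("Simulated ITS series: t = %d, intervention after k = %d (%s)\n",
              x$t, x$k, x$scenario$intervention$kind))
  cat(sprintf("  components: intervention%s%s + ARMA errors\n",
              if (!is.null(x$covariate_values)) " + covariate" else "",
              if (!is.null(x$trend_values)) " + trend" else ""))
  cat(sprintf("  pre-intervention mean %.4g, post-intervention mean %.4g\n",
              mean(x$y[seq_len(x$k)]), mean(x$y[-seq_len(x$k)])))
  invisible(x)
}

#' Tidy one simulated series
#'
#' @param x An `"its_series"` object.
#' @param ... Unused.
#' @return A data frame with columns `time`, `y`, `intervention`,
#'   `covariate`, `trend` (the last two `NA` when absent from the DGP)
#'   and `error`.
#' @export
as.data.frame.its_series <- function(x, ...) {
  data.frame(time = seq_len(x$t), y = x$y,
             intervention = x$intervention_regressor,
             covariate = x$covariate_values %||% rep(NA_real_, x$t),
             trend = x$trend_values %||% rep(NA_real_, x$t),
             error = x$errors)
}

#' Plot the decomposition of a simulated series
#'
#' Draws the outcome with the intervention point marked, plus one panel
#' per stochastic input component (covariate, trend), mirroring the usual
#' "simulated data" diagnostic for ITS power studies.
#'
#' @param x An `"its_series"` object.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.its_series <- function(x, ...) {
  panels <- 1L + !is.null(x$covariate_values) + !is.null(x$trend_values)
  old <- graphics::par(mfrow = c(panels, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  tm <- seq_len(x$t)
  graphics::plot(tm, x$y, type = "l", xlab = "time", ylab = "outcome",
                 main = "Simulated outcome", ...)
  graphics::abline(v = x$k + 0.5, lty = 2, col = "red")
  if (!is.null(x$covariate_values)) {
    graphics::plot(tm, x$covariate_values, type = "l", xlab = "time",
                   ylab = "covariate", main = "Covariate")
    graphics::abline(v = x$k + 0.5, lty = 2, col = "red")
  }
  if (!is.null(x$trend_values)) {
    graphics::plot(tm, x$trend_values, type = "l", xlab = "time",
                   ylab = "trend", main = "Baseline trend")
    graphics::abline(v = x$k + 0.5, lty = 2, col = "red")
  }
  invisible(x)
}

# n reproducible substream seeds from one master seed, preserving the
# caller's RNG state
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
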