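#' Intervention specification
#'
#' Describes the simulated intervention effect.  Three forms are
#' supported: a `step` change (immediate, sustained shift in the outcome
#' level from timepoint k+1 onward), a `pulse` (temporary shift lasting
#' `pulse_duration` timepoints, then reverting to baseline) and a
#' `trend_change` (alteration of the per-timepoint slope from k+1
#' onward, so `effect_size` is in outcome units per timepoint).
#'
#' @param kind One of `"step"`, `"pulse"`, `"trend_change"`.
#' @param effect_size Intervention effect size (b1), in outcome units
#'   (per-timepoint slope units for `trend_change`).
#' @param pulse_duration Number of timepoints a pulse lasts, starting at
#'   k+1; must be >= 1 when `kind = "pulse"` and is ignored otherwise.
#' @return An object of class `"its_intervention"`.
#' @examples
#' intervention_spec("step", 1.4)
#' intervention_spec("pulse", 5.4, pulse_duration = 1)
#' @export
intervention_spec <- function(kind = c("step", "pulse", "trend_change"),
                              effect_size = 0, pulse_duration = 1L) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(effect_size), length(effect_size) == 1L,
            is.finite(effect_size))
  if (kind == "pulse") {
    if (!is.numeric(pulse_duration) || length(pulse_duration) != 1L ||
        pulse_duration < 1 || pulse_duration != round(pulse_duration))
      stop("`pulse_duration` must be a positive integer for pulse interventions",
           call. = FALSE)
    pulse_duration <- as.integer(pulse_duration)
  } else {
    pulse_duration <- NA_integer_
  }
  structure(list(kind = kind, effect_size = effect_size,
                 pulse_duration = pulse_duration),
            class = "its_intervention")
}

#' Time-varying covariate specification
#'
#' An optional confounder generated as an AR(1) process with lag-1
#' coefficient 0.5, marginal mean `mean` and marginal standard deviation
#' `sd`, plus an additive level shift `shift_after_k` applied from
#' timepoint k+1 onward (an intervention-correlated confounder).  The
#' covariate can be included in the data-generating process and,
#' independently, in the fitted analysis model, which allows
#' omitted-variable scenarios to be simulated.
#'
#' @param beta Effect of the covariate on the outcome (outcome units per
#'   covariate unit).
#' @param mean Marginal mean of the covariate.
#' @param sd Marginal standard deviation of the covariate (>= 0).
#' @param shift_after_k Additive shift in the covariate level from
#'   timepoint k+1 onward.
#' @param include_in_dgp Does the covariate enter the simulated outcome?
#' @param include_in_model Is the covariate a regressor in the fitted
#'   model?  Requires `include_in_dgp = TRUE`.
#' @return An object of class `"its_covariate"`.
#' @examples
#' covariate_spec(beta = 0.098, mean = 10, sd = 3, shift_after_k = 1,
#'                include_in_dgp = TRUE, include_in_model = TRUE)
#' @export
covariate_spec <- function(beta = 0, mean = 0, sd = 0, shift_after_k = 0,
                           include_in_dgp = FALSE,
                           include_in_model = include_in_dgp) {
  stopifnot(is.numeric(beta), is.numeric(mean), is.numeric(sd),
            is.numeric(shift_after_k),
            is.logical(include_in_dgp), is.logical(include_in_model))
  if (sd < 0) stop("covariate `sd` must be >= 0", call. = FALSE)
  if (include_in_model && !include_in_dgp)
    stop("a covariate cannot be modelled (`include_in_model = TRUE`) unless ",
         "it is part of the data-generating process (`include_in_dgp = TRUE`)",
         call. = FALSE)
  structure(list(beta = beta, mean = mean, sd = sd,
                 shift_after_k = shift_after_k,
                 include_in_dgp = include_in_dgp,
                 include_in_model = include_in_model),
            class = "its_covariate")
}

#' Baseline trend specification
#'
#' An optional underlying trend in the outcome.  A `deterministic` trend
#' is a straight line with slope `magnitude` per timepoint (zero at the
#' first timepoint, so the intercept retains its meaning as the baseline
#' level at timepoint 1).  A `stochastic` trend is `magnitude` times the
#' cumulative sum of independent Gaussian innovations with standard
#' deviation `stochastic_innov_sd` — a scaled random walk, in which past
#' shocks permanently move the series level.
#'
#' The analysis model can handle the trend in three ways
#' (`model_method`): ignore it (`"none"`), include a linear time
#' regressor (`"xreg"`), or difference the outcome once (`"diff"`, which
#' forces the fitted ARIMA d to 1 and produces no direct time
#' coefficient).
#'
#' @param kind `"deterministic"` or `"stochastic"`.
#' @param magnitude Slope per timepoint (deterministic) or scaling factor
#'   applied to the random walk (stochastic; 1 adds the raw walk, 0
#'   removes it).
#' @param stochastic_innov_sd Innovation SD of the random walk; used only
#'   when `kind = "stochastic"`.
#' @param include_in_dgp Does the trend enter the simulated outcome?
#' @param model_method One of `"none"`, `"xreg"`, `"diff"`.
#' @return An object of class `"its_trend"`.
#' @examples
#' trend_spec("deterministic", magnitude = -0.13, include_in_dgp = TRUE,
#'            model_method = "xreg")
#' @export
trend_spec <- function(kind = c("deterministic", "stochastic"),
                       magnitude = 0, stochastic_innov_sd = 0,
                       include_in_dgp = FALSE,
                       model_method = c("none", "xreg", "diff")) {
  kind <- match.arg(kind)
  model_method <- match.arg(model_method)
  stopifnot(is.numeric(magnitude), length(magnitude) == 1L,
            is.numeric(stochastic_innov_sd),
            length(stochastic_innov_sd) == 1L,
            is.logical(include_in_dgp))
  if (stochastic_innov_sd < 0)
    stop("`stochastic_innov_sd` must be >= 0", call. = FALSE)
  structure(list(kind = kind, magnitude = magnitude,
                 stochastic_innov_sd = stochastic_innov_sd,
                 include_in_dgp = include_in_dgp,
                 model_method = model_method),
            class = "its_trend")
}

#' Define an interrupted time-series power-simulation scenario
#'
#' Bundles every ingredient of one simulate-fit-test experiment: the
#' study design (series length `t`, intervention after timepoint `k`,
#' baseline intercept `b0`), the intervention, the optional covariate and
#' baseline trend, the ARMA error model shared by the data-generating
#' process and the analysis model, and the Monte Carlo settings.
#'
#' The flat arguments mirror the conventional simulator interface for
#' ITS power analysis: `b1_effect` + `intervention_type` +
#' `pulse_duration` populate the intervention, the `b2_*` arguments the
#' covariate, and `b3_trend` + `trend_type` + `trend_model_method` +
#' `stochastic_trend_sd` the baseline trend.  Structured specs built with
#' [intervention_spec()], [covariate_spec()] and [trend_spec()] can be
#' supplied instead through `intervention`, `covariate` and `trend`.
#'
#' When `log_transform_outcome` is `TRUE` all coefficients (`b0`,
#' `b1_effect`, covariate and trend terms, `noise_sd`) are interpreted on
#' the log scale and the simulated outcome is the log-outcome; a
#' coefficient beta then corresponds to a multiplicative effect
#' `exp(beta)` on the original scale.
#'
#' @param t Total number of timepoints (>= 20; very short series give
#'   unstable autocorrelation estimates).
#' @param k Number of pre-intervention timepoints; the intervention
#'   occurs at timepoint k+1.  Requires `1 <= k <= t - 2`.
#' @param period Periodicity of the series (e.g. 12 for monthly data).
#'   Metadata used for axis labelling only; no seasonal structure is
#'   simulated or fitted.
#' @param b0 Baseline intercept: the average outcome level at the first
#'   timepoint, before trend, covariate and intervention contributions.
#' @param b1_effect Intervention effect size (see [intervention_spec()]).
#' @param intervention_type `"step"`, `"pulse"` or `"trend_change"`.
#' @param pulse_duration Pulse length in timepoints (pulse only).
#' @param b2_covariate,b2_mean,b2_sd,b2_shift_after_k Covariate effect,
#'   marginal mean, marginal SD and post-intervention shift (see
#'   [covariate_spec()]).
#' @param noise_sd Innovation standard deviation of the ARMA error
#'   process.
#' @param b3_trend Baseline trend magnitude (see [trend_spec()]).
#' @param include_covariate,model_covariate Covariate in the DGP / in the
#'   fitted model.
#' @param include_trend Baseline trend in the DGP.
#' @param trend_model_method How the analysis model accounts for the
#'   baseline trend: `"none"` (ignore it), `"xreg"` (linear time
#'   regressor) or `"diff"` (difference once, forcing the fitted d to 1).
#'   Consulted only when `include_trend = TRUE`; supply a [trend_spec()]
#'   via `trend` to model a time term without a trend in the DGP.
#' @param trend_type `"deterministic"` or `"stochastic"`.
#' @param stochastic_trend_sd Innovation SD of a stochastic trend.
#' @param log_transform_outcome Interpret all coefficients on the log
#'   scale (the simulated series is then the log-outcome).
#' @param alpha Two-sided significance level for the intervention test.
#' @param n_sims Number of Monte Carlo replicates.
#' @param seed Integer seed; fixes the whole simulation reproducibly.
#' @param errormodel An [error_model()] object (takes precedence over
#'   `noise_sd` if both are given with conflicting values; by default an
#'   AR(1) = 0.5 model with the given `noise_sd`).
#' @param intervention,covariate,trend Optional structured specs
#'   overriding the flat arguments.
#'
#' @return An object of class `"its_scenario"`.
#' @examples
#' sc <- its_scenario(t = 200, k = 100, b0 = 36, b1_effect = 1.4,
#'                    intervention_type = "step",
#'                    errormodel = error_model(ar = 0.5, noise_sd = 1),
#'                    n_sims = 1000, seed = 123)
#' sc
#' @seealso [simulate_its()], [estimate_power()],
#'   [minimal_detectable_effect()]
#' @export
its_scenario <- function(t, k = floor(t / 2), period = 1L, b0 = 0,
                         b1_effect = 0,
                         intervention_type = c("step", "pulse", "trend_change"),
                         pulse_duration = 1L,
                         b2_covariate = 0, b2_mean = 0, b2_sd = 0,
                         b2_shift_after_k = 0, noise_sd = 1, b3_trend = 0,
                         include_covariate = FALSE,
                         model_covariate = include_covariate,
                         include_trend = FALSE,
                         trend_model_method = c("xreg", "none", "diff"),
                         trend_type = c("deterministic", "stochastic"),
                         stochastic_trend_sd = 0,
                         log_transform_outcome = FALSE,
                         alpha = 0.05, n_sims = 1000L, seed = 123L,
                         errormodel = error_model(ar = 0.5, noise_sd = noise_sd),
                         intervention = NULL, covariate = NULL, trend = NULL) {
  if (missing(t)) stop("`t` (total timepoints) is required", call. = FALSE)
  stopifnot(is.numeric(t), length(t) == 1L, t == round(t),
            is.numeric(k), length(k) == 1L, k == round(k),
            is.numeric(period), length(period) == 1L, period >= 1,
            is.numeric(b0), length(b0) == 1L,
            is.numeric(alpha), length(alpha) == 1L,
            is.numeric(n_sims), length(n_sims) == 1L,
            n_sims == round(n_sims), n_sims >= 1,
            is.numeric(seed), length(seed) == 1L, seed == round(seed),
            is.logical(log_transform_outcome))
  if (t < 20)
    stop("`t` must be at least 20: shorter series give unstable ",
         "autocorrelation estimates", call. = FALSE)
  if (k < 1 || k > t - 2)
    stop(sprintf("`k` must satisfy 1 <= k <= t - 2 (got k = %d, t = %d)",
                 as.integer(k), as.integer(t)), call. = FALSE)
  if (alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie in (0, 1)", call. = FALSE)

  intervention <- intervention %||% intervention_spec(
    kind = match.arg(intervention_type), effect_size = b1_effect,
    pulse_duration = if (match.arg(intervention_type) == "pulse")
      max(1L, pulse_duration) else 1L)
  covariate <- covariate %||% covariate_spec(
    beta = b2_covariate, mean = b2_mean, sd = b2_sd,
    shift_after_k = b2_shift_after_k, include_in_dgp = include_covariate,
    include_in_model = model_covariate)
  # the trend-handling method is only consulted when a baseline trend is
  # part of the scenario; pass a structured `trend` spec to model a time
  # regressor without a DGP trend
  trend <- trend %||% trend_spec(
    kind = match.arg(trend_type), magnitude = b3_trend,
    stochastic_innov_sd = stochastic_trend_sd,
    include_in_dgp = include_trend,
    model_method = if (include_trend) match.arg(trend_model_method) else "none")
  errormodel <- validate_error_model(errormodel)

  if (intervention$kind == "pulse" &&
      k + intervention$pulse_duration > t)
    stop(sprintf(
      "pulse extends past the series end: k + pulse_duration = %d > t = %d",
      as.integer(k + intervention$pulse_duration), as.integer(t)),
      call. = FALSE)

  structure(
    list(t = as.integer(t), k = as.integer(k), period = as.integer(period),
         b0 = b0, intervention = intervention, covariate = covariate,
         trend = trend, error_model = errormodel,
         log_scale = log_transform_outcome, alpha = alpha,
         n_sims = as.integer(n_sims), seed = as.integer(seed)),
    class = "its_scenario")
}

#' @export
print.its_scenario <- function(x, ...) {
  em <- x$error_model
  cat("Interrupted time-series power scenario\n")
  cat(sprintf("  design: t = %d, intervention after k = %d (at %d), b0 = %g%s\n",
              x$t, x$k, x$k + 1L, x$b0,
              if (x$log_scale) " [log scale]" else ""))
  iv <- x$intervention
  cat(sprintf("  intervention: %s, effect = %g%s\n", iv$kind, iv$effect_size,
              if (iv$kind == "pulse")
                sprintf(", duration = %d", iv$pulse_duration) else ""))
  cat(sprintf("  errors: ARMA(p=%d, q=%d)%s, innovation sd = %g; fitted d = %d\n",
              em$p, em$q,
              if (em$p + em$q > 0)
                sprintf(" [ar: %s%s]", paste(format(em$ar), collapse = " "),
                        if (em$q > 0)
                          paste0("; ma: ", paste(format(em$ma), collapse = " "))
                        else "")
              else "", em$noise_sd, fitted_d(x)))
  if (x$covariate$include_in_dgp)
    cat(sprintf("  covariate: beta = %g, mean = %g, sd = %g, shift after k = %g, modelled = %s\n",
                x$covariate$beta, x$covariate$mean, x$covariate$sd,
                x$covariate$shift_after_k, x$covariate$include_in_model))
  if (x$trend$include_in_dgp || x$trend$model_method != "none")
    cat(sprintf("  trend: %s, magnitude = %g, in DGP = %s, model method = %s\n",
                x$trend$kind, x$trend$magnitude, x$trend$include_in_dgp,
                x$trend$model_method))
  cat(sprintf("  simulation: n_sims = %d, alpha = %g, seed = %d\n",
              x$n_sims, x$alpha, x$seed))
  invisible(x)
}

# differencing order of the analysis model: trend handling by differencing
# overrides the error model's d
fitted_d <- function(scenario) {
  if (scenario$trend$model_method == "diff") 1L else scenario$error_model$d
}

# replace the intervention effect size, keeping everything else fixed
set_effect <- function(scenario, effect) {
  scenario$intervention$effect_size <- effect
  scenario
}
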