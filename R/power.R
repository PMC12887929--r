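#' Estimate statistical power by Monte Carlo simulation
#'
#' Runs `n_sims` independent replicates of the scenario — fresh ARMA
#' errors, fresh covariate and fresh stochastic trend per replicate —
#' fitting the analysis ARIMA model to each and testing the intervention
#' coefficient two-sidedly at level `alpha`.  Power is the proportion of
#' converged replicates with p < alpha; its binomial Monte Carlo standard
#' error `sqrt(power * (1 - power) / n_effective)` is reported alongside.
#'
#' Each replicate runs on its own substream derived from the scenario
#' seed, so the estimate is bit-reproducible and invariant to execution
#' order.  Replicates on which the optimiser fails are excluded from the
#' denominator (counting them as non-rejections would bias power
#' downward); if more than 20% fail the scenario is considered
#' pathological and an error is raised with diagnostics.
#'
#' @param scenario An [its_scenario()].
#' @param n_sims Number of replicates; defaults to the scenario's.
#' @param seed Master seed; defaults to the scenario's.
#' @return An object of class `"its_power"`: list with `power`,
#'   `mc_se`, `n_effective`, `n_requested`, `n_failed`, `alpha`, `seed`,
#'   `estimates` (the replicate intervention-coefficient estimates) and
#'   `scenario`.
#' @examples
#' sc <- its_scenario(t = 40, k = 20, b1_effect = 1.5,
#'                    intervention_type = "step", n_sims = 200, seed = 7)
#' estimate_power(sc)
#' @seealso [power_curve()], [minimal_detectable_effect()]
#' @export
estimate_power <- function(scenario, n_sims = scenario$n_sims,
                           seed = scenario$seed) {
  stopifnot(inherits(scenario, "its_scenario"))
  seeds <- derive_seeds(seed, n_sims)
  pvals <- numeric(n_sims)
  est <- numeric(n_sims)
  failures <- character(0)
  for (i in seq_len(n_sims)) {
    set.seed(seeds[i])
    fit <- simulate_and_fit(scenario)
    pvals[i] <- fit$intervention_pvalue
    est[i] <- fit$intervention_estimate
    if (!fit$converged) failures <- c(failures, fit$failure)
  }
  ok <- !is.na(pvals)
  n_eff <- sum(ok)
  n_failed <- n_sims - n_eff
  if (n_failed / n_sims > 0.2) {
    tab <- sort(table(failures), decreasing = TRUE)
    stop(sprintf(
      paste0("pathological scenario: %d of %d replicates failed to ",
             "converge (> 20%%); most common failure: %s"),
      n_failed, n_sims, names(tab)[1]), call. = FALSE)
  }
  power <- mean(pvals[ok] < scenario$alpha)
  structure(
    list(power = power,
         mc_se = sqrt(power * (1 - power) / n_eff),
         n_effective = n_eff, n_requested = as.integer(n_sims),
         n_failed = as.integer(n_failed), alpha = scenario$alpha,
         seed = as.integer(seed), estimates = est[ok],
         scenario = scenario),
    class = "its_power")
}

#' @export
print.its_power <- function(x, ...) {
  cat(sprintf(
    "Monte Carlo power: %.3f (mc se %.4f) at alpha = %g\n",
    x$power, x$mc_se, x$alpha))
  cat(sprintf("  %d effective replicates (%d requested, %d failed), seed %d\n",
              x$n_effective, x$n_requested, x$n_failed, x$seed))
  invisible(x)
}

#' @export
summary.its_power <- function(object, ...) {
  iv <- object$scenario$intervention
  cat(sprintf("Scenario: %s intervention, effect %g, t = %d, k = %d\n",
              iv$kind, iv$effect_size, object$scenario$t, object$scenario$k))
  print(object)
  cat(sprintf("  intervention estimates: mean %.4g, sd %.4g (true %g)\n",
              mean(object$estimates), stats::sd(object$estimates),
              iv$effect_size))
  invisible(object)
}

#' Power as a function of the intervention effect size
#'
#' Re-estimates power over a grid of effect sizes, holding every other
#' scenario parameter constant.  Each grid point uses its own substream
#' derived from the master seed, so the curve is reproducible and
#' order-invariant.
#'
#' @param scenario An [its_scenario()].
#' @param effect_grid Strictly increasing vector of effect sizes.
#' @param n_sims Replicates per grid point; defaults to the scenario's.
#' @return An object of class `"its_power_curve"`: list with
#'   `effect_grid`, `powers` (list of [estimate_power()] results) and
#'   `scenario`.
#' @examples
#' sc <- its_scenario(t = 40, k = 20, intervention_type = "step",
#'                    n_sims = 100, seed = 7)
#' pc <- power_curve(sc, c(0.5, 1, 2))
#' as.data.frame(pc)
#' @export
power_curve <- function(scenario, effect_grid, n_sims = scenario$n_sims) {
  stopifnot(inherits(scenario, "its_scenario"),
            is.numeric(effect_grid), length(effect_grid) >= 1)
  if (is.unsorted(effect_grid, strictly = TRUE))
    stop("`effect_grid` must be strictly increasing", call. = FALSE)
  seeds <- derive_seeds(scenario$seed, length(effect_grid))
  powers <- vector("list", length(effect_grid))
  for (i in seq_along(effect_grid)) {
    powers[[i]] <- estimate_power(set_effect(scenario, effect_grid[i]),
                                  n_sims = n_sims, seed = seeds[i])
  }
  structure(list(effect_grid = effect_grid, powers = powers,
                 scenario = scenario),
            class = "its_power_curve")
}

#' @export
print.its_power_curve <- function(x, ...) {
  cat("ITS power curve\n")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.its_power_curve <- function(x, ...) {
  data.frame(effect = x$effect_grid,
             power = vapply(x$powers, `[[`, 0, "power"),
             mc_se = vapply(x$powers, `[[`, 0, "mc_se"),
             n_effective = vapply(x$powers, `[[`, 0L, "n_effective"))
}

#' Plot a power curve
#'
#' Power against effect size with pointwise +/- 2 Monte Carlo standard
#' error bands and the conventional 80% power reference line.
#'
#' @param x An `"its_power_curve"` object.
#' @param target Reference power level drawn as a horizontal line.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.its_power_curve <- function(x, target = 0.8, ...) {
  df <- as.data.frame(x)
  graphics::plot(df$effect, df$power, type = "b", pch = 16,
                 ylim = c(0, 1), xlab = "intervention effect size",
                 ylab = "power", ...)
  graphics::arrows(df$effect, pmax(0, df$power - 2 * df$mc_se),
                   df$effect, pmin(1, df$power + 2 * df$mc_se),
                   angle = 90, code = 3, length = 0.03, col = "grey40")
  graphics::abline(h = target, lty = 2, col = "red")
  invisible(x)
}

#' Minimal detectable effect at a target power
#'
#' Inverts the Monte Carlo power function over the intervention effect
#' magnitude: starting from a unit bracket, the upper end is doubled
#' until its estimated power reaches `target_power` (bracket expansion),
#' then the bracket is bisected until its width falls below `tol` effect
#' units or an evaluation lands within `power_tol` of the target.  All
#' evaluations reuse the same replicate substreams (common random
#' numbers), which makes the estimated power monotone in the effect
#' magnitude along the search and stabilises the bisection.  The sign of
#' the returned effect follows the sign of the scenario's configured
#' effect (negative effects are searched by magnitude).
#'
#' @param scenario An [its_scenario()].  Its configured `b1_effect`, if
#'   nonzero, seeds the initial bracket guess.
#' @param target_power Target power in (alpha, 1); conventionally 0.80.
#' @param tol Bracket-width stopping tolerance, in effect units.
#' @param power_tol Early stop when an evaluated power is within this of
#'   the target.
#' @param n_sims Replicates per power evaluation.
#' @param max_doublings Bound on bracket expansion before giving up.
#' @return An object of class `"its_mde"`: list with `effect`,
#'   `achieved_power` (an [estimate_power()] result at that effect),
#'   `target_power`, `tol`, `iterations` and the evaluation `trace`.
#' @examples
#' \donttest{
#' sc <- its_scenario(t = 60, k = 30, intervention_type = "step",
#'                    n_sims = 200, seed = 42)
#' minimal_detectable_effect(sc, target_power = 0.8, tol = 0.1)
#' }
#' @export
minimal_detectable_effect <- function(scenario, target_power = 0.80,
                                      tol = 0.05, power_tol = 0.01,
                                      n_sims = scenario$n_sims,
                                      max_doublings = 20L) {
  stopifnot(inherits(scenario, "its_scenario"))
  if (target_power <= scenario$alpha || target_power >= 1)
    stop("`target_power` must lie in (alpha, 1)", call. = FALSE)
  sign <- if (scenario$intervention$effect_size < 0) -1 else 1
  trace <- data.frame(effect = numeric(0), power = numeric(0))
  iterations <- 0L
  # every evaluation uses the scenario seed: common random numbers
  eval_power <- function(magnitude) {
    p <- estimate_power(set_effect(scenario, sign * magnitude),
                        n_sims = n_sims, seed = scenario$seed)
    iterations <<- iterations + 1L
    trace <<- rbind(trace, data.frame(effect = sign * magnitude,
                                      power = p$power))
    p
  }
  guess <- abs(scenario$intervention$effect_size)
  hi <- if (guess > 0) guess else 1
  lo <- 0
  p_hi <- eval_power(hi)
  doublings <- 0L
  while (p_hi$power < target_power) {
    if (doublings >= max_doublings)
      stop(sprintf(
        "no bracket found: power is still %.3f at effect magnitude %g after %d doublings",
        p_hi$power, hi, doublings), call. = FALSE)
    lo <- hi
    hi <- hi * 2
    p_hi <- eval_power(hi)
    doublings <- doublings + 1L
  }
  achieved <- p_hi
  effect <- hi
  early <- FALSE
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    p_mid <- eval_power(mid)
    if (abs(p_mid$power - target_power) <= power_tol) {
      achieved <- p_mid
      effect <- mid
      early <- TRUE
      break
    }
    if (p_mid$power >= target_power) hi <- mid else lo <- mid
  }
  if (!early) {
    # report the bracket midpoint, with its power measured once more
    effect <- (lo + hi) / 2
    achieved <- eval_power(effect)
  }
  structure(
    list(effect = sign * effect, achieved_power = achieved,
         target_power = target_power, tol = tol,
         iterations = iterations, trace = trace, scenario = scenario),
    class = "its_mde")
}

#' @export
print.its_mde <- function(x, ...) {
  cat(sprintf(
    "Minimal detectable effect at %g%% power: %.4g (%s intervention)\n",
    100 * x$target_power, x$effect, x$scenario$intervention$kind))
  cat(sprintf("  achieved power %.3f (mc se %.4f) in %d power evaluations\n",
              x$achieved_power$power, x$achieved_power$mc_se, x$iterations))
  invisible(x)
}
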