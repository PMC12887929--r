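#' Build the analysis design for one simulated series
#'
#' Constructs the response and exogenous regressor matrix for the ARIMA
#' analysis model implied by the scenario.  The matrix always contains
#' the intervention regressor; it contains the covariate column iff the
#' covariate is modelled, and a linear time column (1..t) iff the trend
#' is modelled as an exogenous regressor.  For a change-in-trend
#' intervention the time column is the baseline slope and the
#' slope-change regressor is the tested column.  When the trend is
#' handled by differencing no time column is added (the trend is removed
#' implicitly and no time coefficient is produced); the fitted d becomes
#' 1.
#'
#' @param scenario The generating [its_scenario()].
#' @param series The matching [simulate_its()] result.
#' @return A list with `y` (response), `X` (regressor matrix), `target`
#'   (name of the tested column) and `order` (the (p, d, q) of the
#'   analysis model).
#' @export
build_design <- function(scenario, series) {
  stopifnot(inherits(scenario, "its_scenario"), inherits(series, "its_series"))
  t <- scenario$t
  cols <- list(intervention = series$intervention_regressor)
  if (scenario$covariate$include_in_model)
    cols$covariate <- series$covariate_values
  if (scenario$trend$model_method == "xreg")
    cols$time <- as.numeric(seq_len(t))
  X <- do.call(cbind, cols)
  if (qr(X)$rank < ncol(X))
    stop("singular design: the analysis regressors are collinear (",
         paste(colnames(X), collapse = ", "), ")", call. = FALSE)
  em <- scenario$error_model
  list(y = series$y, X = X, target = "intervention",
       order = c(em$p, fitted_d(scenario), em$q))
}

#' Fit the ARIMA intervention model and test the intervention coefficient
#'
#' Fits a Gaussian maximum-likelihood ARIMA(p, d, q) regression with
#' exogenous regressors (an intercept is included whenever d = 0) and
#' computes the two-sided asymptotic-normal (Wald z) p-value of the
#' target coefficient against zero.  Optimiser failure or a degenerate
#' coefficient covariance is reported through `converged = FALSE`, not
#' raised: the non-convergence policy belongs to the power estimator.
#'
#' @param y Response vector.
#' @param X Regressor matrix with named columns, containing `target`.
#' @param order ARIMA order `c(p, d, q)` of the analysis model.
#' @param target Name of the tested column (default `"intervention"`).
#' @return An object of class `"its_fit"`: list with `coefficients`,
#'   `standard_errors`, `intervention_estimate`, `intervention_pvalue`,
#'   `converged`, `order_used` and the underlying `arima` fit (or `NULL`).
#' @examples
#' set.seed(1)
#' x <- c(rep(0, 30), rep(1, 30))
#' y <- 2 * x + as.numeric(arima.sim(list(ar = 0.5), 60))
#' fit_its_model(y, cbind(intervention = x), order = c(1, 0, 0))
#' @export
fit_its_model <- function(y, X, order, target = "intervention") {
  stopifnot(is.numeric(y), is.matrix(X), nrow(X) == length(y),
            length(order) == 3L, target %in% colnames(X))
  n_par <- ncol(X) + sum(order[c(1, 3)]) + (order[2] == 0)
  if (length(y) < n_par + 2L)
    stop("series too short: need more observations than model parameters",
         call. = FALSE)
  if (qr(X)$rank < ncol(X))
    stop("singular design: the analysis regressors are collinear (",
         paste(colnames(X), collapse = ", "), ")", call. = FALSE)
  fit <- tryCatch(
    suppressWarnings(stats::arima(y, order = order, xreg = X,
                                  method = "CSS-ML")),
    error = function(e) e)
  failed <- inherits(fit, "error") || fit$code != 0L
  if (!failed) {
    co <- stats::coef(fit)
    vc <- diag(fit$var.coef)
    se <- ifelse(vc > 0 & is.finite(vc), sqrt(vc), NA_real_)
    names(se) <- names(co)
    z <- co[[target]] / se[[target]]
    failed <- !is.finite(z)
  }
  if (failed) {
    return(structure(
      list(coefficients = NULL, standard_errors = NULL,
           intervention_estimate = NA_real_,
           intervention_pvalue = NA_real_, converged = FALSE,
           order_used = order, target = target,
           fit = if (inherits(fit, "error")) NULL else fit,
           failure = if (inherits(fit, "error"))
             conditionMessage(fit) else "optimiser did not converge"),
      class = "its_fit"))
  }
  structure(
    list(coefficients = co, standard_errors = se,
         intervention_estimate = co[[target]],
         intervention_pvalue = 2 * stats::pnorm(-abs(z)),
         converged = TRUE, order_used = order, target = target,
         fit = fit, failure = NULL),
    class = "its_fit")
}

#' @export
print.its_fit <- function(x, ...) {
  cat(sprintf("ITS ARIMA(%d,%d,%d) fit [%s]\n", x$order_used[1],
              x$order_used[2], x$order_used[3],
              if (x$converged) "converged" else
                paste("failed:", x$failure)))
  if (x$converged) {
    tab <- cbind(estimate = x$coefficients, se = x$standard_errors)
    print(round(tab, 4))
    cat(sprintf("intervention ('%s'): estimate %.4g, two-sided p = %.4g\n",
                x$target, x$intervention_estimate, x$intervention_pvalue))
  }
  invisible(x)
}

#' @export
coef.its_fit <- function(object, ...) object$coefficients

#' @export
residuals.its_fit <- function(object, ...) {
  if (!object$converged) return(NULL)
  as.numeric(stats::residuals(object$fit))
}

# one replicate: simulate under the scenario, fit, test
simulate_and_fit <- function(scenario) {
  series <- simulate_its(scenario)
  d <- build_design(scenario, series)
  fit_its_model(d$y, d$X, d$order, d$target)
}
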