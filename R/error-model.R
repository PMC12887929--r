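#' Specify the ARIMA error model of an ITS data-generating process
#'
#' Describes the stochastic error process added to the deterministic
#' components of a simulated interrupted time-series outcome, and the
#' (p, d, q) order of the ARIMA model fitted at analysis time.  Errors are
#' generated as a stationary, invertible ARMA(p, q) process with Gaussian
#' innovations; the differencing order `d` applies only to the fitted
#' analysis model, never to data generation.
#'
#' @param ar Numeric vector of autoregressive coefficients (possibly
#'   empty/`NULL`).  The AR polynomial must be stationary: every
#'   coefficient in (-1, 1) and all roots of `1 - ar[1] z - ...` outside
#'   the unit circle.
#' @param ma Numeric vector of moving-average coefficients (possibly
#'   empty/`NULL`), subject to the analogous invertibility condition.
#' @param d Differencing order of the fitted model, 0 or 1.
#' @param noise_sd Positive innovation standard deviation, in outcome
#'   units.
#'
#' @return An object of class `"its_error_model"`: a list with elements
#'   `ar`, `ma`, `d`, `noise_sd` and the implied orders `p` and `q`.
#' @examples
#' error_model(ar = 0.5)              # the AR(1) = 0.5 default error model
#' error_model(ar = 0.3, noise_sd = 2)
#' error_model(ma = c(0.4, 0.2), d = 1)
#' @seealso [validate_error_model()], [simulate_arma_errors()]
#' @export
error_model <- function(ar = NULL, ma = NULL, d = 0, noise_sd = 1) {
  ar <- as.numeric(ar %||% numeric(0))
  ma <- as.numeric(ma %||% numeric(0))
  if (!is.numeric(d) || length(d) != 1L || !(d %in% c(0, 1)))
    stop("`d` must be 0 or 1", call. = FALSE)
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L ||
      !is.finite(noise_sd) || noise_sd <= 0)
    stop("`noise_sd` must be a positive number", call. = FALSE)
  spec <- structure(
    list(ar = ar, ma = ma, p = length(ar), d = as.integer(d),
         q = length(ma), noise_sd = noise_sd),
    class = "its_error_model")
  validate_error_model(spec)
}

#' Validate stationarity and invertibility of an error model
#'
#' Checks that every AR and MA coefficient lies strictly in (-1, 1) and —
#' the binding condition for orders above one — that all roots of the AR
#' characteristic polynomial lie outside the unit circle (stationarity)
#' and likewise for the MA polynomial (invertibility).
#'
#' @param spec An [error_model()] object.
#' @return `spec`, unchanged, if valid; otherwise an error naming the
#'   offending polynomial and its root moduli.
#' @examples
#' validate_error_model(error_model(ar = 0.5))
#' \dontrun{
#' error_model(ar = c(0.6, 0.5))  # root inside the unit circle: rejected
#' }
#' @export
validate_error_model <- function(spec) {
  stopifnot(inherits(spec, "its_error_model"))
  check_poly <- function(coefs, what, condition) {
    if (length(coefs) == 0L) return(invisible(NULL))
    if (any(!is.finite(coefs)))
      stop(sprintf("%s coefficients must be finite", what), call. = FALSE)
    if (any(abs(coefs) >= 1))
      stop(sprintf(
        "%s coefficients must lie strictly between -1 and 1 (got %s)",
        what, paste(format(coefs), collapse = ", ")), call. = FALSE)
    # characteristic polynomial 1 - c1 z - c2 z^2 - ... (AR) or
    # 1 + c1 z + ... (MA); both reduce to a root-modulus check
    sign <- if (what == "AR") -1 else 1
    roots <- polyroot(c(1, sign * coefs))
    if (any(Mod(roots) <= 1 + 1e-8))
      stop(sprintf(
        "%s polynomial is not %s: root moduli %s (all must exceed 1)",
        what, condition,
        paste(format(Mod(roots), digits = 4), collapse = ", ")),
        call. = FALSE)
    invisible(NULL)
  }
  check_poly(spec$ar, "AR", "stationary")
  check_poly(spec$ma, "MA", "invertible")
  spec
}

#' Simulate a stationary ARMA error series
#'
#' Draws one length-`t` realisation of the stationary ARMA(p, q) process
#' described by `spec`, with independent Gaussian innovations of standard
#' deviation `noise_sd`.  A burn-in segment of
#' `max(200, 10 * (p + q + 1))` points is generated and discarded so that
#' the returned segment is (to close approximation) a draw from the
#' stationary distribution.  The result is deterministic given the state
#' of R's random number generator.
#'
#' @param spec An [error_model()] object.
#' @param t Series length, a positive integer.
#' @return Numeric vector of length `t`.
#' @examples
#' set.seed(1)
#' e <- simulate_arma_errors(error_model(ar = 0.5), t = 500)
#' stats::acf(e, lag.max = 1, plot = FALSE)
#' @export
simulate_arma_errors <- function(spec, t) {
  spec <- validate_error_model(spec)
  stopifnot(is.numeric(t), length(t) == 1L, t >= 1, t == round(t))
  model <- list()
  if (spec$p > 0L) model$ar <- spec$ar
  if (spec$q > 0L) model$ma <- spec$ma
  burn <- max(200L, 10L * (spec$p + spec$q + 1L))
  as.numeric(stats::arima.sim(model, n = t, sd = spec$noise_sd,
                              n.start = burn + spec$p + spec$q))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
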