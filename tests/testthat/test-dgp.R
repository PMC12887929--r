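test_that("intervention regressors encode step, pulse and slope change", {
  expect_equal(build_intervention_regressor("step", 6, 3),
               c(0, 0, 0, 1, 1, 1))
  expect_equal(build_intervention_regressor("pulse", 6, 3, 2),
               c(0, 0, 0, 1, 1, 0))
  expect_equal(build_intervention_regressor("trend_change", 6, 3),
               c(0, 0, 0, 1, 2, 3))
  expect_error(build_intervention_regressor("pulse", 6, 5, 2))
  expect_error(build_intervention_regressor("ramp", 6, 3), "unknown")
})

test_that("regressor mass invariants hold across random designs", {
  set.seed(99)
  for (i in 1:25) {
    t <- sample(20:300, 1)
    k <- sample(seq_len(t - 2), 1)
    expect_equal(sum(build_intervention_regressor("step", t, k)), t - k)
    dur <- sample(seq_len(t - k), 1)
    expect_equal(sum(build_intervention_regressor("pulse", t, k, dur)), dur)
    tc <- build_intervention_regressor("trend_change", t, k)
    expect_equal(tc[t], t - k)
    expect_equal(diff(tc[(k + 1):t]), rep(1, t - k - 1))
  }
})

test_that("covariate is AR(1) with the requested marginal moments and shift", {
  cs <- covariate_spec(beta = 1, mean = 7, sd = 0, shift_after_k = 2,
                       include_in_dgp = TRUE)
  expect_equal(simulate_covariate(cs, 6, 3), c(7, 7, 7, 9, 9, 9))

  # marginal mean 10 / sd 3, one-point shift after k
  n <- 1e5; k <- n / 2
  cs <- covariate_spec(beta = 1, mean = 10, sd = 3, shift_after_k = 1,
                       include_in_dgp = TRUE)
  set.seed(4)
  x <- simulate_covariate(cs, n, k)
  expect_equal(mean(x[1:k]), 10, tolerance = 0.05)
  expect_equal(mean(x[(k + 1):n]), 11, tolerance = 0.05)
  expect_equal(sd(x[1:k]), 3, tolerance = 0.05)

  # lag-1 autocorrelation is the fixed rho = 0.5
  set.seed(5)
  z <- simulate_covariate(covariate_spec(mean = 0, sd = 1,
                                         include_in_dgp = TRUE), n, n - 1)
  expect_equal(acf(z[1:(n - 1)], lag.max = 1, plot = FALSE)$acf[2], 0.5,
               tolerance = 0.02)

  expect_error(covariate_spec(include_in_dgp = FALSE, include_in_model = TRUE),
               "include_in_dgp")
  expect_error(covariate_spec(sd = -1), ">= 0")
})

test_that("baseline trends: deterministic slope and scaled random walk", {
  tr <- trend_spec("deterministic", magnitude = -0.13, include_in_dgp = TRUE)
  expect_equal(build_baseline_trend(tr, 4), c(0, -0.13, -0.26, -0.39))

  tr0 <- trend_spec("stochastic", magnitude = 0, stochastic_innov_sd = 1,
                    include_in_dgp = TRUE)
  expect_equal(build_baseline_trend(tr0, 10), rep(0, 10))

  # random-walk variance grows linearly: Var(trend_T) ~ T
  T <- 1e4; reps <- 400
  tr1 <- trend_spec("stochastic", magnitude = 1, stochastic_innov_sd = 1,
                    include_in_dgp = TRUE)
  set.seed(6)
  finals <- vapply(seq_len(reps),
                   function(i) build_baseline_trend(tr1, T)[T], 0)
  expect_equal(var(finals), T, tolerance = 0.2 * T)

  # magnitude is a scaling factor on the walk
  set.seed(7); a <- build_baseline_trend(tr1, 100)
  tr2 <- trend_spec("stochastic", magnitude = 2, stochastic_innov_sd = 1,
                    include_in_dgp = TRUE)
  set.seed(7); b <- build_baseline_trend(tr2, 100)
  expect_equal(b, 2 * a)
})

test_that("assembled series satisfies the additive decomposition exactly", {
  sc <- its_scenario(t = 60, k = 25, b0 = 36, b1_effect = 1.4,
                     intervention_type = "step",
                     b2_covariate = 0.098, b2_mean = 10, b2_sd = 3,
                     b2_shift_after_k = 1, include_covariate = TRUE,
                     b3_trend = -0.13, include_trend = TRUE,
                     trend_model_method = "xreg", seed = 11)
  set.seed(sc$seed)
  s <- simulate_its(sc)
  rebuilt <- sc$b0 + 1.4 * s$intervention_regressor +
    0.098 * s$covariate_values + s$trend_values + s$errors
  expect_identical(s$y, rebuilt)
  df <- as.data.frame(s)
  expect_named(df, c("time", "y", "intervention", "covariate", "trend",
                     "error"))
  expect_equal(nrow(df), 60)
})

test_that("degenerate noise recovers the deterministic skeleton", {
  # intercept only
  sc <- its_scenario(t = 20, k = 10, b0 = 36,
                     errormodel = error_model(ar = 0.5, noise_sd = 1e-10),
                     seed = 8)
  set.seed(sc$seed)
  expect_equal(simulate_its(sc)$y, rep(36, 20), tolerance = 1e-7)

  # pure step of size 2
  sc <- its_scenario(t = 20, k = 10, b0 = 0, b1_effect = 2,
                     intervention_type = "step",
                     errormodel = error_model(noise_sd = 1e-10), seed = 8)
  set.seed(sc$seed)
  expect_equal(simulate_its(sc)$y, rep(c(0, 2), each = 10),
               tolerance = 1e-7)

  # log scale: coefficients are multiplicative on the original scale
  sc <- its_scenario(t = 20, k = 10, b0 = log(100), b1_effect = log(1.10),
                     intervention_type = "step",
                     log_transform_outcome = TRUE,
                     errormodel = error_model(noise_sd = 1e-10), seed = 8)
  set.seed(sc$seed)
  y <- simulate_its(sc)$y
  expect_equal(exp(mean(y[11:20])) / exp(mean(y[1:10])), 1.10,
               tolerance = 1e-6)
})

test_that("outcome is invariant to covariate settings kept out of the DGP", {
  base <- its_scenario(t = 40, k = 20, b1_effect = 1, seed = 21)
  loud <- its_scenario(t = 40, k = 20, b1_effect = 1, seed = 21,
                       b2_covariate = 99, b2_mean = -5, b2_sd = 17,
                       b2_shift_after_k = 3, include_covariate = FALSE,
                       model_covariate = FALSE)
  set.seed(21); y1 <- simulate_its(base)$y
  set.seed(21); y2 <- simulate_its(loud)$y
  expect_identical(y1, y2)
})

test_that("identical scenario and seed give bit-identical replicates", {
  sc <- example1_scenario(n_sims = 3, seed = 77)
  a <- simulate(sc, nsim = 3)
  b <- simulate(sc, nsim = 3)
  expect_identical(lapply(a, `[[`, "y"), lapply(b, `[[`, "y"))
  # distinct replicates are genuinely distinct draws
  expect_false(identical(a[[1]]$y, a[[2]]$y))
})

test_that("scenario validation enforces the design invariants", {
  expect_error(its_scenario(t = 19), "at least 20")
  expect_error(its_scenario(t = 30, k = 29), "k")
  expect_error(its_scenario(t = 30, k = 0), "k")
  expect_error(its_scenario(t = 30, k = 25, intervention_type = "pulse",
                            pulse_duration = 10), "past the series end")
  expect_error(its_scenario(t = 30, alpha = 1), "alpha")
  expect_error(its_scenario(), "required")
})
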