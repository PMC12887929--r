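test_that("design matrix follows the scenario's model specification", {
  # fully adjusted step model: intervention + covariate + time
  sc <- example1_scenario(n_sims = 1)
  set.seed(1); s <- simulate_its(sc)
  d <- build_design(sc, s)
  expect_identical(colnames(d$X), c("intervention", "covariate", "time"))
  expect_identical(d$target, "intervention")
  expect_identical(d$order, c(1L, 0L, 0L))

  # omitted-variable scenario: covariate in the DGP, not in the model
  sc2 <- its_scenario(t = 40, k = 20, b1_effect = 1,
                      b2_covariate = 0.5, b2_mean = 2, b2_sd = 1,
                      include_covariate = TRUE, model_covariate = FALSE,
                      seed = 2)
  set.seed(2); s2 <- simulate_its(sc2)
  expect_identical(colnames(build_design(sc2, s2)$X), "intervention")

  # unadjusted pulse model: single intervention column
  sc3 <- example3_scenario(n_sims = 1)
  set.seed(3); s3 <- simulate_its(sc3)
  expect_identical(colnames(build_design(sc3, s3)$X), "intervention")

  # trend handled by differencing: no time column, fitted d = 1
  sc4 <- its_scenario(t = 40, k = 20, b1_effect = 1, b3_trend = 0.2,
                      include_trend = TRUE, trend_model_method = "diff",
                      seed = 4)
  set.seed(4); s4 <- simulate_its(sc4)
  d4 <- build_design(sc4, s4)
  expect_false("time" %in% colnames(d4$X))
  expect_identical(d4$order[2], 1L)

  # change in trend: baseline time column plus the tested slope-change
  sc5 <- example2_scenario(n_sims = 1)
  set.seed(5); s5 <- simulate_its(sc5)
  d5 <- build_design(sc5, s5)
  expect_true(all(c("time", "intervention", "covariate") %in%
                    colnames(d5$X)))
  expect_identical(d5$target, "intervention")
})

test_that("order (0,0,0) coefficients match the least-squares oracle", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(25:60, 1)
    X <- cbind(intervention = as.numeric(seq_len(n) > n / 2),
               covariate = rnorm(n))
    y <- 2 + X %*% c(1.5, -0.7) + rnorm(n)
    fit <- fit_its_model(as.numeric(y), X, order = c(0, 0, 0))
    ols <- lm(y ~ X)
    expect_true(fit$converged)
    expect_equal(unname(fit$coefficients[c("intercept", "intervention",
                                           "covariate")]),
                 unname(coef(ols)), tolerance = 1e-8)
  }
})

test_that("overwhelming signal yields a vanishing p-value", {
  sc <- its_scenario(t = 200, k = 100, b1_effect = 50, seed = 12)
  set.seed(12)
  fit <- with(build_design(sc, simulate_its(sc)),
              fit_its_model(y, X, order, target))
  expect_true(fit$converged)
  expect_lt(fit$intervention_pvalue, 1e-6)
  expect_equal(fit$intervention_estimate, 50, tolerance = 0.1)
})

test_that("null p-values are approximately uniform", {
  sc <- its_scenario(t = 100, k = 50, b1_effect = 0, seed = 13)
  set.seed(13)
  seeds <- sample.int(1e6, 1000)
  pvals <- vapply(seeds, function(s) {
    set.seed(s)
    d <- build_design(sc, simulate_its(sc))
    fit_its_model(d$y, d$X, d$order)$intervention_pvalue
  }, 0)
  pvals <- pvals[!is.na(pvals)]
  expect_gt(length(pvals), 950)
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("estimation is deterministic given the data and degenerate designs error", {
  set.seed(14)
  x <- as.numeric(seq_len(60) > 30)
  y <- x + as.numeric(arima.sim(list(ar = 0.5), 60))
  set.seed(1); f1 <- fit_its_model(y, cbind(intervention = x), c(1, 0, 0))
  set.seed(999); f2 <- fit_its_model(y, cbind(intervention = x), c(1, 0, 0))
  expect_identical(f1$intervention_pvalue, f2$intervention_pvalue)

  expect_error(
    fit_its_model(y, cbind(intervention = x, copy = x), c(1, 0, 0)),
    "singular design")
  expect_error(
    fit_its_model(y[1:4], cbind(intervention = c(0, 1, 0, 1)), c(1, 0, 0)),
    "too short")
})
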