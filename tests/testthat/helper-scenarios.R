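# scenario builders shared across tests

# lookup-table style scenario: intercept 0, midpoint intervention, AR(1)
# errors, no covariate; change-in-trend cells model a zero-slope baseline
# time trend
table_scenario <- function(t, effect, kind = "step", ar1 = 0.5,
                           noise_sd = 1, n_sims = 1000L, seed = 123L,
                           alpha = 0.05) {
  its_scenario(
    t = t, k = floor(t / 2), b0 = 0, b1_effect = effect,
    intervention_type = kind, pulse_duration = 1L,
    include_trend = kind == "trend_change", b3_trend = 0,
    trend_model_method = if (kind == "trend_change") "xreg" else "none",
    errormodel = error_model(ar = ar1, noise_sd = noise_sd),
    alpha = alpha, n_sims = n_sims, seed = seed)
}

# the three worked-example scenarios (plain packaging, minimum unit
# pricing, drug take-back day)
example1_scenario <- function(effect = 1.40, n_sims = 1000L, seed = 123L) {
  its_scenario(
    t = 200, k = 100, period = 12, b0 = 36, b1_effect = effect,
    intervention_type = "step",
    b2_covariate = 0.098, b2_mean = 10, b2_sd = 3, b2_shift_after_k = 1,
    include_covariate = TRUE, model_covariate = TRUE,
    b3_trend = -0.13, include_trend = TRUE,
    trend_model_method = "xreg", trend_type = "deterministic",
    errormodel = error_model(ar = 0.5, noise_sd = 1),
    n_sims = n_sims, seed = seed)
}

example2_scenario <- function(effect = -2.3, n_sims = 1000L, seed = 123L) {
  its_scenario(
    t = 180, k = 160, period = 12, b0 = 650, b1_effect = effect,
    intervention_type = "trend_change",
    b2_covariate = 5, b2_mean = 5, b2_sd = 1, b2_shift_after_k = 0,
    include_covariate = TRUE, model_covariate = TRUE,
    b3_trend = -0.5, include_trend = TRUE,
    trend_model_method = "xreg", trend_type = "deterministic",
    errormodel = error_model(ar = 0.5, noise_sd = 20),
    n_sims = n_sims, seed = seed)
}

example3_scenario <- function(effect = 5.4, n_sims = 1000L, seed = 123L) {
  its_scenario(
    t = 200, k = 100, period = 7, b0 = 5, b1_effect = effect,
    intervention_type = "pulse", pulse_duration = 1,
    errormodel = error_model(ar = 0.3, noise_sd = 2),
    n_sims = n_sims, seed = seed)
}
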