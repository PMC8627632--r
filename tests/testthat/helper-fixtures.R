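# Shared fixtures: moderate-size cohorts simulated from the default
# mixture-Weibull mechanism, built once per test file.
fix_cohort <- function(n = 300, follow_up = 3, seed = 42) {
  simulate_cohort(scenario(n, follow_up, id = 1), seed = seed)
}

# Uncensored single-Weibull sample (shape/scale on the R parameterisation).
fix_weibull_sample <- function(n, shape = 1.4, scale = 2.3, seed = 5,
                               censor_at = Inf) {
  set.seed(seed)
  tt <- rweibull(n, shape, scale)
  survival_data(pmin(tt, censor_at), as.integer(tt <= censor_at),
                follow_up = if (is.finite(censor_at)) censor_at else NULL)
}
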