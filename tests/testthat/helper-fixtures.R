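# shared fixtures: parameter grids and reduced-cost settings used across tests

grid_params <- function() {
  # theta capped at 150 so every combination keeps its mass inside the
  # default [0, 1000] support (alpha = 1, theta = 250, gamma = 0.8 has mean
  # above 1000 and legitimately triggers the truncation error)
  g <- expand.grid(alpha = c(1, 2, 3), theta = c(5, 50, 150),
                   gamma = c(0.3, 0.5, 0.8))
  lapply(seq_len(nrow(g)),
         function(i) degradation_params(g$alpha[i], g$theta[i], g$gamma[i]))
}

# short-chain settings for tests that only need rough posterior spread
fast_mcmc <- function(seed = 1L) {
  mcmc_settings(steps = 12000L, burn_in = 6000L, thin = 10L, seed = seed)
}

# small synthetic study: same passage structure as the default design,
# scaled down for unit tests
small_design <- function(seed = 1L, n = 120L) {
  study_design(n_per_passage = rep(n, 6L), seed = seed)
}

expect_params_equal <- function(p, q, tol = 1e-8) {
  expect_equal(p$alpha, q$alpha, tolerance = tol)
  expect_equal(p$theta, q$theta, tolerance = tol)
  expect_equal(p$gamma, q$gamma, tolerance = tol)
}
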