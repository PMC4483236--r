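# Log-odds transform, weighted trend tests, centrality trajectories and the
# four-parameter logistic fit.

test_that("log-odds transform, its inverse and delta-method sd", {
  expect_equal(log_odds_gamma(0.5), 0)
  expect_equal(log_odds_gamma(0.75), log(1 / 3))
  g <- seq(0.05, 0.95, by = 0.05)
  expect_equal(inv_log_odds_gamma(log_odds_gamma(g)), g, tolerance = 1e-12)
  # strictly decreasing: a decreasing log-odds means gamma increases
  expect_true(all(diff(log_odds_gamma(g)) < 0))
  tr <- log_odds_gamma(0.8, sd = 0.02)
  expect_equal(tr$sd, 0.02 / (0.8 * 0.2))
  expect_error(log_odds_gamma(1), class = "nucdeg_invalid_params")
  expect_error(log_odds_gamma(0), class = "nucdeg_invalid_params")
})

test_that("weighted slope test recovers exact lines and reduces to OLS", {
  x <- 1:6
  tr <- param_trajectory(x, 2.5 * x + 1, rep(0.3, 6))
  fit <- suppressWarnings(wls_slope_test(tr))  # lm warns on a perfect fit
  expect_equal(fit$slope, 2.5, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_lt(fit$p_value, 1e-8)

  # equal weights = ordinary least squares
  set.seed(3)
  y <- 0.4 * x + rnorm(6)
  wfit <- wls_slope_test(param_trajectory(x, y, rep(2, 6)))
  ols <- summary(lm(y ~ x))$coefficients
  expect_equal(wfit$slope, ols["x", "Estimate"], tolerance = 1e-10)
  expect_equal(wfit$slope_se, ols["x", "Std. Error"], tolerance = 1e-10)
  expect_equal(wfit$p_value, ols["x", "Pr(>|t|)"], tolerance = 1e-10)

  expect_error(wls_slope_test(param_trajectory(1:2, 1:2, c(1, 1))),
               class = "nucdeg_insufficient_data")
})

test_that("null slope p-values are approximately uniform", {
  set.seed(71)
  n_rep <- 200
  pv <- vapply(seq_len(n_rep), function(i) {
    sds <- runif(6, 0.2, 0.5)
    y <- rnorm(6, mean = 5, sd = sds)
    wls_slope_test(param_trajectory(1:6, y, sds))$p_value
  }, 0)
  rej <- mean(pv < 0.05)
  expect_gte(rej, 0.02)
  expect_lte(rej, 0.08)
})

test_that("centrality trajectories track the model mean as gamma ramps", {
  # posterior chains for three passages with increasing gamma
  gammas <- c(0.3, 0.5, 0.7)
  chains <- lapply(seq_along(gammas), function(i) {
    x <- sample_counts(degradation_params(2, 80, gammas[i]), 250,
                       seed = 40 + i)
    run_adaptive_metropolis(x, fast_mcmc(seed = 50 + i))
  })
  traj <- centrality_trajectory(c(3, 6, 9), chains, n_max = 1000)
  expect_identical(traj$passage, c(3, 6, 9))
  expect_true(all(diff(traj$mean) > 0))
  expect_true(all(traj$mean_lo <= traj$mean & traj$mean <= traj$mean_hi))
  expect_error(centrality_trajectory(3, chains[1]),
               class = "nucdeg_insufficient_data")
})

test_that("logistic fit recovers noiseless parameters and nests its bands", {
  x <- 3:13
  truth <- c(ymin = 150, ymax = 600, k = 1.4, m = 11.5)
  y <- truth["ymin"] + (truth["ymax"] - truth["ymin"]) /
    (1 + exp(-truth["k"] * (x - truth["m"])))
  fit <- logistic4_fit(x, y, y_sd = rep(1e-3, length(x)), n_boot = 50, seed = 2)
  expect_equal(fit$y_min, unname(truth["ymin"]), tolerance = 1e-3)
  expect_equal(fit$y_max, unname(truth["ymax"]), tolerance = 1e-3)
  expect_equal(fit$steepness, unname(truth["k"]), tolerance = 1e-3)
  expect_equal(fit$midpoint, unname(truth["m"]), tolerance = 1e-3)

  # noisy recovery of the transition passage
  set.seed(9)
  mids <- vapply(1:10, function(i) {
    yn <- y + rnorm(length(y), 0, 15)
    logistic4_fit(x, yn, y_sd = rep(15, length(x)), n_boot = 20,
                  seed = i)$midpoint
  }, 0)
  expect_lt(abs(mean(mids) - 11.5), 0.5)

  # band nesting at every passage
  yn <- y + rnorm(length(y), 0, 10)
  fb <- logistic4_fit(x, yn, y_sd = rep(10, length(x)), n_boot = 200, seed = 4)
  expect_true(all(fb$band_50$lo >= fb$band_95$lo - 1e-9))
  expect_true(all(fb$band_50$hi <= fb$band_95$hi + 1e-9))

  expect_error(logistic4_fit(1:4, (1:4)^2), class = "nucdeg_insufficient_data")
})
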