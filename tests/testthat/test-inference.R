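# Likelihood, ML fitting, information criteria and the posterior sampler.

test_that("log-likelihood sums per-observation log masses and is additive", {
  p <- degradation_params(2, 50, 0.5)
  pmf <- stationary_pmf(p, 400)
  expect_equal(log_likelihood(17L, p, 400), pmf$log_probs[18])

  set.seed(21)
  x <- sample_counts(p, 50, n_max = 400)
  y <- sample_counts(p, 30, n_max = 400)
  expect_equal(log_likelihood(c(x, y), p, 400),
               log_likelihood(x, p, 400) + log_likelihood(y, p, 400),
               tolerance = 1e-12)

  # matches a naive per-observation recomputation
  naive <- sum(vapply(x, function(n) pmf$log_probs[n + 1], 0))
  expect_equal(log_likelihood(x, p, 400), naive, tolerance = 1e-10)

  expect_error(log_likelihood(401L, p, 400), class = "nucdeg_support_error")
  expect_error(log_likelihood(-1L, p, 400), class = "nucdeg_invalid_counts")
})

test_that("the C++ likelihood fast path agrees with the R recurrence", {
  set.seed(4)
  x <- sample_counts(degradation_params(2, 250, 0.8), 300, seed = 4)
  tab <- tabulate(x + 1L, nbins = 1001L)
  for (p in grid_params()) {
    expect_equal(nucdeg:::gnb_loglik_cpp(tab, p$alpha, p$theta, p$gamma),
                 log_likelihood(x, p, 1000), tolerance = 1e-9)
  }
})

test_that("ML fitting maximizes the likelihood and nests nb inside gnb", {
  p_true <- degradation_params(2, 100, 0.5)
  x <- sample_counts(p_true, 500, seed = 9)
  fit_g <- fit_ml(x, "gnb")
  fit_n <- fit_ml(x, "nb")

  # MLE beats the generating parameters on the same sample
  expect_gte(fit_g$log_likelihood, log_likelihood(x, p_true))
  # nesting: gnb maximum cannot fall below the nb maximum
  expect_gte(fit_g$log_likelihood, fit_n$log_likelihood - 1e-6)
  expect_identical(fit_n$params_hat$alpha, 1)
  expect_identical(fit_n$k, 2L)
  expect_identical(fit_g$k, 3L)

  # a gnb fit started exactly at the nb solution with alpha = 1 can only
  # improve; the nb maximum is attainable inside the gnb family
  ll_nb_in_gnb <- log_likelihood(x, degradation_params(
    1, fit_n$params_hat$theta, fit_n$params_hat$gamma))
  expect_equal(ll_nb_in_gnb, fit_n$log_likelihood, tolerance = 1e-8)

  expect_error(fit_ml(x[1:5], "nb"), class = "nucdeg_invalid_counts")
})

test_that("information criteria follow their defining formulas", {
  fake <- structure(list(family = "gnb", k = 3L, n = 100L,
                         log_likelihood = -100),
                    class = "fit_result")
  ic <- information_criteria(fake)
  expect_equal(ic$aic, 206)
  expect_equal(ic$bic, 3 * log(100) + 200)
  expect_equal(ic$aicc, 206 + 2 * 3 * 4 / (100 - 4))
  fake$n <- 4L
  expect_error(information_criteria(fake), class = "nucdeg_invalid_params")
})

test_that("gamma is recovered with small bias at the reference design", {
  # moderate replication; the acceptance suite runs the full harness
  gh <- vapply(1:8, function(r) {
    x <- sample_counts(degradation_params(2, 250, 0.8), 700, seed = 1000 + r)
    fit_ml(x, "gnb")$params_hat$gamma
  }, 0)
  expect_lt(abs(mean(gh) - 0.8), 0.05)
})

test_that("the adaptive chain is reproducible, sized correctly and in-bounds", {
  x <- sample_counts(degradation_params(2, 80, 0.5), 250, seed = 14)
  st <- fast_mcmc(seed = 7)
  ch1 <- run_adaptive_metropolis(x, st)
  ch2 <- run_adaptive_metropolis(x, st)
  expect_identical(ch1$samples, ch2$samples)          # determinism
  expect_identical(nrow(ch1$samples),
                   (st$steps - st$burn_in) %/% st$thin)
  expect_true(all(ch1$samples[, "gamma"] > 0 & ch1$samples[, "gamma"] < 1))
  expect_true(all(ch1$samples[, "alpha"] > 0 & ch1$samples[, "alpha"] <= 10))
  expect_true(all(ch1$samples[, "theta"] > 0 & ch1$samples[, "theta"] <= 2000))
  expect_gt(ch1$acceptance_rate, 0.01)
})

test_that("posterior summaries expose the max-likelihood point and spread", {
  x <- sample_counts(degradation_params(2, 80, 0.5), 250, seed = 14)
  ch <- run_adaptive_metropolis(x, fast_mcmc(seed = 8))
  s <- posterior_summary(ch)
  # argmax property: the point estimate dominates the posterior-mean point
  pm <- colMeans(ch$samples)
  ll_point <- log_likelihood(x, s$point)
  ll_mean <- log_likelihood(x, degradation_params(pm[1], pm[2], pm[3]))
  expect_gte(ll_point, ll_mean - 1e-9)
  expect_true(all(s$sd > 0))
  expect_true(all(s$ci[1, ] <= s$ci[2, ]))

  # a constant chain collapses to zero spread
  const <- ch
  const$samples <- ch$samples[rep(1L, 50), ]
  const$log_likelihoods <- ch$log_likelihoods[rep(1L, 50)]
  sc <- posterior_summary(const)
  expect_equal(unname(sc$sd), c(0, 0, 0))
  expect_params_equal(sc$point, degradation_params(
    ch$samples[1, 1], ch$samples[1, 2], ch$samples[1, 3]))

  # ML point and posterior point agree within posterior spread
  fit <- fit_ml(x, "gnb")
  expect_lt(abs(fit$params_hat$gamma - s$point$gamma), 2 * s$sd[["gamma"]] + 1e-6)
})

test_that("posterior spread shrinks with sample size", {
  p <- degradation_params(2, 80, 0.5)
  sd_small <- posterior_summary(run_adaptive_metropolis(
    sample_counts(p, 200, seed = 31), fast_mcmc(seed = 1)))$sd
  sd_big <- posterior_summary(run_adaptive_metropolis(
    sample_counts(p, 800, seed = 32), fast_mcmc(seed = 2)))$sd
  # roughly 1/sqrt(n): a factor-4 sample increase should halve the sd;
  # allow generous slack for Monte-Carlo error
  expect_lt(sd_big[["gamma"]], sd_small[["gamma"]])
  expect_lt(sd_big[["theta"]], sd_small[["theta"]])
})

test_that("chains serialize to CSV", {
  x <- sample_counts(degradation_params(1, 30, 0.4), 100, seed = 2)
  ch <- run_adaptive_metropolis(x, fast_mcmc(seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_chain_csv(ch, path)
  tab <- read.csv(path)
  expect_identical(names(tab), c("step", "alpha", "theta", "gamma", "loglik"))
  expect_identical(nrow(tab), nrow(ch$samples))
})
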