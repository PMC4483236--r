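# Stationary law of the active-degradation chain: recurrence weights,
# normalization, detailed balance, closed-form alpha = 1 case, centralities
# and the Gamma burst null density.

test_that("log weights match direct products and the alpha=1 closed form", {
  # empty product at n = 0
  expect_identical(log_weight_sequence(degradation_params(2, 100, 0.9), 0), 0)

  # single-term product: gamma * (theta^2 + 1)/1
  lw <- log_weight_sequence(degradation_params(2, 100, 0.9), 1)
  expect_equal(lw[2], log(0.9) + log(100^2 + 1), tolerance = 1e-12)

  # alpha = 1, integer theta: weight_n = choose(theta + n, n) gamma^n
  lw <- log_weight_sequence(degradation_params(1, 2, 0.5), 5)
  expect_equal(lw[3], log(choose(4, 2) * 0.5^2), tolerance = 1e-12)
  expect_equal(lw[6], log(choose(7, 5) * 0.5^5), tolerance = 1e-12)

  expect_error(degradation_params(1, 2, 1.2), class = "nucdeg_invalid_params")
  expect_error(degradation_params(-1, 2, 0.5), class = "nucdeg_invalid_params")
})

test_that("pmf is normalized and satisfies detailed balance on a grid", {
  for (p in grid_params()) {
    pmf <- stationary_pmf(p, 1000)
    expect_equal(sum(pmf$probs), 1, tolerance = 1e-9)
    expect_true(all(pmf$probs >= 0))
    # P_n * r_n = P_{n-1} * gamma, checked in log space where mass is finite
    n <- 1:pmf$n_max
    log_r <- p$alpha * log(n) - log(p$theta^p$alpha + n^p$alpha)
    lhs <- pmf$log_probs[-1] + log_r
    rhs <- pmf$log_probs[-(pmf$n_max + 1)] + log(p$gamma)
    keep <- is.finite(lhs) & is.finite(rhs)
    expect_true(any(keep))
    expect_lt(max(abs(exp(lhs[keep] - rhs[keep]) - 1)), 1e-9)
  }
})

test_that("alpha=1 pmf agrees with the negative-binomial closed form", {
  for (theta in c(1, 2, 5)) {
    for (gamma in c(0.3, 0.5, 0.8)) {
      pmf <- stationary_pmf(degradation_params(1, theta, gamma), 2000)
      # closed-form normalization P0 = (1 - gamma)^(theta + 1)
      expect_equal(pmf$probs[1], (1 - gamma)^(theta + 1),
                   tolerance = max(1e-9, pmf$truncation_tail_mass))
      # elementwise agreement with gamma-function generalization of the
      # binomial-coefficient weights
      n <- 0:50
      closed <- lgamma(theta + n + 1) - lgamma(n + 1) - lgamma(theta + 1) +
        n * log(gamma) + (theta + 1) * log(1 - gamma)
      expect_equal(pmf$log_probs[1:51], closed, tolerance = 1e-9)
    }
  }
})

test_that("truncation tail mass is reported and triggers an error when large", {
  pmf <- stationary_pmf(degradation_params(1, 5, 0.5), 1000)
  expect_lt(pmf$truncation_tail_mass, 1e-6)
  expect_error(stationary_pmf(degradation_params(1, 500, 0.99), 1000),
               class = "nucdeg_truncation_error")
})

test_that("deterministic mode matches closed forms and the pmf argmax", {
  expect_equal(deterministic_mode(degradation_params(1, 200, 0.6)), 300)
  expect_equal(deterministic_mode(degradation_params(2, 200, 0.9)), 600)
  # gamma = 0.5 balances production and half-saturated degradation at theta
  for (a in c(0.7, 1, 3)) {
    expect_equal(deterministic_mode(degradation_params(a, 123, 0.5)), 123)
  }
  for (p in list(degradation_params(2, 200, 0.9),
                 degradation_params(3, 150, 0.6),
                 degradation_params(1, 100, 0.7))) {
    pmf <- stationary_pmf(p, 1500)
    argmax <- which.max(pmf$probs) - 1
    expect_lte(abs(argmax - deterministic_mode(p)), 1 + 1e-9)
  }
})

test_that("centralities are exact on a degenerate pmf and match nb moments", {
  pmf <- stationary_pmf(degradation_params(1, 5, 0.5), 200)
  degenerate <- pmf
  degenerate$probs <- c(rep(0, 5), 1, rep(0, 195))
  degenerate$log_probs <- log(degenerate$probs)
  cm <- centralities(degenerate)
  expect_identical(cm$median, 5L)
  expect_identical(cm$mode, 5L)
  expect_equal(cm$mean, 5)
  expect_equal(cm$fano, 0)

  # alpha = 1: Fano factor of the untruncated negative binomial is 1/(1-gamma)
  for (gamma in c(0.3, 0.6, 0.8)) {
    pmf <- stationary_pmf(degradation_params(1, 10, gamma), 2000)
    expect_equal(centralities(pmf)$fano, 1 / (1 - gamma), tolerance = 1e-6)
  }
})

test_that("mean of the stationary law increases strictly with gamma", {
  for (alpha in c(1, 2)) {
    means <- vapply(c(0.3, 0.45, 0.6, 0.75), function(g) {
      centralities(stationary_pmf(degradation_params(alpha, 80, g), 1000))$mean
    }, 0)
    expect_true(all(diff(means) > 0))
  }
})

test_that("Gamma burst density is the Gamma law with the burst parameters", {
  gp <- gamma_burst_params(1, 1)
  expect_equal(gamma_burst_density(gp, 1e-12), 1, tolerance = 1e-9)
  gp <- gamma_burst_params(2.5, 30)
  f <- function(x) gamma_burst_density(gp, x)
  expect_equal(integrate(f, 0, Inf)$value, 1, tolerance = 1e-6)
  # sum of independent Gamma(a_i, b) variates is Gamma(sum a_i, b):
  # Monte-Carlo check against the closed-form density via a KS statistic
  set.seed(11)
  sums <- rgamma(4000, 1.2, scale = 20) + rgamma(4000, 2.3, scale = 20)
  ks <- suppressWarnings(ks.test(sums, function(q) pgamma(q, 3.5, scale = 20)))
  expect_gt(ks$p.value, 0.01)
  expect_error(gamma_burst_density(gp, -1), class = "nucdeg_invalid_params")
})

test_that("pmf CSV export round-trips", {
  pmf <- stationary_pmf(degradation_params(2, 50, 0.5), 400)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pmf_csv(pmf, path)
  tab <- read.csv(path)
  expect_equal(tab$probability, pmf$probs)
  expect_equal(tab$n, 0:400)
})
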