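# Replicative-passage trend analysis: weighted regression on parameter
# trajectories (with a log-odds transform of gamma) and four-parameter
# logistic fits of the distribution centralities.

#' Log-odds transform of the production/degradation ratio
#'
#' Returns \eqn{\log((1-\gamma)/\gamma)}, which linearizes and symmetrizes
#' the (0,1)-bounded ratio; the transform is strictly decreasing, so a
#' decreasing log-odds trend over passages means \eqn{\gamma} increases.
#' Uncertainty is propagated by the delta method:
#' \eqn{sd_{out} = sd_{in} / (\gamma(1-\gamma))}.
#'
#' @param gamma Value(s) in (0, 1).
#' @param sd Optional standard deviation(s) of `gamma`.
#' @return If `sd` is NULL, the log-odds value(s); otherwise a list with
#'   `value` and `sd`.
#' @export
log_odds_gamma <- function(gamma, sd = NULL) {
  if (any(!is.finite(gamma)) || any(gamma <= 0) || any(gamma >= 1))
    stop_nucdeg("'gamma' must lie strictly inside (0, 1)", "nucdeg_invalid_params")
  value <- log((1 - gamma) / gamma)
  if (is.null(sd)) return(value)
  list(value = value, sd = sd / (gamma * (1 - gamma)))
}

#' Inverse of the log-odds transform
#'
#' @param x Log-odds value(s).
#' @return `gamma` in (0, 1) with `log_odds_gamma(gamma) == x`.
#' @export
inv_log_odds_gamma <- function(x) {
  1 / (1 + exp(x))
}

#' Build a parameter trajectory across passages
#'
#' @param passages Integer passage vector.
#' @param estimates Parameter estimates, one per passage.
#' @param sds Positive uncertainties (posterior standard deviations).
#' @return Object of class `param_trajectory`.
#' @export
param_trajectory <- function(passages, estimates, sds) {
  if (length(passages) != length(estimates) || length(estimates) != length(sds))
    stop_nucdeg("'passages', 'estimates' and 'sds' must have equal length",
                "nucdeg_invalid_params")
  if (any(!is.finite(sds)) || any(sds <= 0))
    stop_nucdeg("'sds' must be positive", "nucdeg_invalid_params")
  structure(list(passages = as.numeric(passages),
                 estimates = as.numeric(estimates), sds = as.numeric(sds)),
            class = "param_trajectory")
}

#' Weighted least-squares test for a linear passage trend
#'
#' Regresses the per-passage estimates on passage number with
#' inverse-variance weights \eqn{1/sd^2} and tests the null hypothesis of
#' no variation during passages with a two-sided t test on the slope
#' (`length - 2` degrees of freedom).
#'
#' @param trajectory A [param_trajectory()] (>= 3 passages).
#' @return Object of class `trend_fit`: list with `slope`, `intercept`,
#'   `slope_se`, `p_value`, and the underlying `lm` fit.
#' @export
wls_slope_test <- function(trajectory) {
  stopifnot(inherits(trajectory, "param_trajectory"))
  if (length(trajectory$passages) < 3L)
    stop_nucdeg("need at least 3 passages for a trend test",
                "nucdeg_insufficient_data")
  d <- data.frame(x = trajectory$passages, y = trajectory$estimates,
                  w = 1 / trajectory$sds^2)
  fit <- stats::lm(y ~ x, data = d, weights = w)
  sm <- summary(fit)$coefficients
  structure(list(slope = unname(sm["x", "Estimate"]),
                 intercept = unname(sm["(Intercept)", "Estimate"]),
                 slope_se = unname(sm["x", "Std. Error"]),
                 p_value = unname(sm["x", "Pr(>|t|)"]),
                 lm_fit = fit),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("Weighted linear trend: slope %.4g (se %.4g), p = %.4g\n",
              x$slope, x$slope_se, x$p_value))
  invisible(x)
}

#' Centrality trajectories across passages
#'
#' For each passage, evaluates mean, median and mode of the stationary pmf
#' at the posterior point estimate, with uncertainty obtained by pushing a
#' subsample of the posterior through the centrality computation (central
#' 95% of the induced distribution).  Posterior propagation is used rather
#' than the delta method because mode and median are discrete,
#' non-smooth functionals.
#'
#' @param passages Integer passage vector.
#' @param chains List of [run_adaptive_metropolis()] chains, one per passage.
#' @param n_max Truncation bound; default 1000.
#' @param n_draws Posterior draws propagated per passage; default 200.
#' @return A data.frame with one row per passage and columns
#'   `passage, mean, median, mode, mean_lo, mean_hi, mean_sd, median_lo,
#'   median_hi, mode_lo, mode_hi`.
#' @export
centrality_trajectory <- function(passages, chains, n_max = 1000L,
                                  n_draws = 200L) {
  if (length(passages) < 2L)
    stop_nucdeg("need at least 2 passages", "nucdeg_insufficient_data")
  stopifnot(length(passages) == length(chains))
  rows <- lapply(seq_along(passages), function(i) {
    chain <- chains[[i]]
    stopifnot(inherits(chain, "posterior_chain"))
    pt <- posterior_summary(chain)$point
    cm <- centralities(stationary_pmf(pt, n_max))
    m <- nrow(chain$samples)
    idx <- unique(round(seq(1L, m, length.out = min(n_draws, m))))
    prop <- t(vapply(idx, function(j) {
      s <- chain$samples[j, ]
      p <- tryCatch(
        stationary_pmf(degradation_params(s[["alpha"]], s[["theta"]],
                                          s[["gamma"]]), n_max),
        error = function(e) NULL)
      if (is.null(p)) return(c(NA_real_, NA_real_, NA_real_))
      cc <- centralities(p)
      c(cc$mean, cc$median, cc$mode)
    }, numeric(3L)))
    q <- function(v, p) stats::quantile(v, p, na.rm = TRUE, names = FALSE)
    data.frame(passage = passages[i],
               mean = cm$mean, median = cm$median, mode = cm$mode,
               mean_lo = q(prop[, 1L], 0.025), mean_hi = q(prop[, 1L], 0.975),
               mean_sd = stats::sd(prop[, 1L], na.rm = TRUE),
               median_lo = q(prop[, 2L], 0.025), median_hi = q(prop[, 2L], 0.975),
               mode_lo = q(prop[, 3L], 0.025), mode_hi = q(prop[, 3L], 0.975))
  })
  do.call(rbind, rows)
}

#' Four-parameter logistic fit of a passage trajectory
#'
#' Weighted nonlinear least squares of
#' \deqn{y = y_{min} + \frac{y_{max} - y_{min}}{1 + e^{-k (x - m)}}}
#' with parameters minimum, maximum, steepness `k` and transition passage
#' `m`.  Pointwise 50% and 95% uncertainty bands are computed by a
#' parametric bootstrap: the observations are resampled from
#' `Normal(y, y_sd)`, the curve refitted, and per-passage quantiles of the
#' refitted curves taken (central quantiles, so the 50% band is nested
#' inside the 95% band by construction).
#'
#' @param x Passage vector (>= 5 points).
#' @param y Centrality values.
#' @param y_sd Positive uncertainties on `y`.
#' @param n_boot Bootstrap resamples for the bands; default 500.
#' @param seed RNG seed for the band bootstrap.
#' @return Object of class `logistic_fit`: list with `y_min`, `y_max`,
#'   `steepness`, `midpoint`, `fitted` (values at `x`), `band_50` and
#'   `band_95` (data.frames with `lo`/`hi` per passage), `x`.
#' @export
logistic4_fit <- function(x, y, y_sd = NULL, n_boot = 500L, seed = 1L) {
  if (length(x) < 5L)
    stop_nucdeg("need at least 5 points for a 4-parameter logistic fit",
                "nucdeg_insufficient_data")
  if (is.null(y_sd)) y_sd <- rep(max(stats::sd(y) * 0.05, 1e-6), length(x))
  if (any(y_sd <= 0))
    stop_nucdeg("'y_sd' must be positive", "nucdeg_invalid_params")
  w <- 1 / y_sd^2

  fit_once <- function(yy, weights) {
    rng <- range(yy)
    span <- max(diff(rng), 1e-8)
    start <- list(ymin = rng[1L], ymax = rng[2L],
                  k = 4 / max(diff(range(x)), 1), m = stats::median(x))
    minpack.lm::nlsLM(
      yy ~ ymin + (ymax - ymin) / (1 + exp(-k * (xx - m))),
      data = data.frame(xx = x, yy = yy),
      start = start, weights = weights,
      lower = c(rng[1L] - 2 * span, rng[1L] - 2 * span, -50, min(x) - 20),
      upper = c(rng[2L] + 2 * span, rng[2L] + 2 * span, 50, max(x) + 20),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  }

  fit <- tryCatch(fit_once(y, w), error = function(e) NULL)
  if (is.null(fit))
    stop_nucdeg("logistic fit failed to converge; consider a linear trend fit instead",
                "nucdeg_degenerate_fit")
  cf <- stats::coef(fit)

  set.seed(seed)
  curves <- matrix(NA_real_, nrow = n_boot, ncol = length(x))
  for (b in seq_len(n_boot)) {
    yb <- stats::rnorm(length(y), y, y_sd)
    fb <- tryCatch(fit_once(yb, w), error = function(e) NULL)
    if (!is.null(fb)) curves[b, ] <- stats::predict(fb)
  }
  band <- function(p) {
    lo <- apply(curves, 2L, stats::quantile, probs = (1 - p) / 2, na.rm = TRUE)
    hi <- apply(curves, 2L, stats::quantile, probs = 1 - (1 - p) / 2, na.rm = TRUE)
    data.frame(passage = x, lo = lo, hi = hi)
  }

  structure(list(y_min = min(cf[["ymin"]], cf[["ymax"]]),
                 y_max = max(cf[["ymin"]], cf[["ymax"]]),
                 steepness = cf[["k"]], midpoint = cf[["m"]],
                 fitted = stats::predict(fit),
                 band_50 = band(0.50), band_95 = band(0.95), x = x),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "4-parameter logistic fit: range [%.3g, %.3g], steepness %.3g, transition at passage %.2f\n",
    x$y_min, x$y_max, x$steepness, x$midpoint))
  invisible(x)
}

#' Parameter trajectories from per-passage posterior chains
#'
#' Builds the three trend-test inputs from posterior samples: posterior
#' means and standard deviations of alpha and theta, and of the log-odds
#' of gamma (transformed sample-by-sample, which respects the skew of the
#' posterior better than transforming a summary).  Posterior means are
#' used rather than the maximum-likelihood sample because the likelihood
#' ridge makes the argmax of a finite chain an unstable order statistic,
#' whereas the posterior mean is the quantity whose uncertainty the
#' attached sd actually describes.
#'
#' @param passages Integer passage vector.
#' @param chains List of [run_adaptive_metropolis()] chains, one per
#'   passage.
#' @return Named list of [param_trajectory()] objects: `alpha`, `theta`,
#'   `gamma_log_odds`.
#' @export
chain_trajectories <- function(passages, chains) {
  stopifnot(length(passages) == length(chains))
  stat <- function(f) {
    vals <- lapply(chains, function(ch) f(ch$samples))
    list(mean = vapply(vals, mean, 0),
         sd = pmax(vapply(vals, stats::sd, 0), 1e-12))
  }
  a <- stat(function(s) s[, "alpha"])
  th <- stat(function(s) s[, "theta"])
  lo <- stat(function(s) log((1 - s[, "gamma"]) / s[, "gamma"]))
  list(alpha = param_trajectory(passages, a$mean, a$sd),
       theta = param_trajectory(passages, th$mean, th$sd),
       gamma_log_odds = param_trajectory(passages, lo$mean, lo$sd))
}
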