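# Likelihood, maximum-likelihood fitting and information criteria for the
# negative binomial (alpha = 1, Michaelis-Menten degradation) and the
# generalized negative binomial (free alpha, Hill degradation) families.

# tiny memo of recently used pmfs, keyed by parameters quantized at 1e-12
.pmf_cache <- new.env(parent = emptyenv())

cached_pmf <- function(params, n_max) {
  key <- paste(sprintf("%.12e", c(params$alpha, params$theta, params$gamma)),
               n_max, collapse = "|")
  hit <- .pmf_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- stationary_pmf(params, n_max)
  keys <- ls(.pmf_cache)
  if (length(keys) > 32L) rm(list = keys[seq_len(16L)], envir = .pmf_cache)
  assign(key, val, envir = .pmf_cache)
  val
}

validate_counts <- function(counts, n_max) {
  if (length(counts) == 0L || any(!is.finite(counts)))
    stop_nucdeg("'counts' must be a non-empty finite integer vector",
                "nucdeg_invalid_counts")
  if (any(counts < 0) || any(counts != floor(counts)))
    stop_nucdeg("'counts' must be non-negative integers", "nucdeg_invalid_counts")
  if (any(counts > n_max))
    stop_nucdeg(sprintf("counts exceed the pmf support [0, %d]", n_max),
                "nucdeg_support_error")
  as.integer(counts)
}

#' Log-likelihood of count data under the active-degradation model
#'
#' Evaluates the stationary pmf once and sums its log mass over the
#' observations, so the cost is independent of the sample size beyond a
#' single tabulation.
#'
#' @param counts Integer vector of scaled protein counts in `[0, n_max]`.
#' @param params A [degradation_params()] object.
#' @param n_max Truncation bound of the stationary pmf; default 1000.
#' @return The log-likelihood (a single real).
#' @export
log_likelihood <- function(counts, params, n_max = 1000L) {
  counts <- validate_counts(counts, n_max)
  pmf <- cached_pmf(as_degradation_params(params), as.integer(n_max))
  tab <- tabulate(counts + 1L, nbins = n_max + 1L)
  sum(tab * pmf$log_probs)
}

# negative log-likelihood on the optimizer scale
# x = (log alpha, log theta, logit gamma) for gnb; (log theta, logit gamma) for nb
nll_factory <- function(counts, family, n_max,
                        bounds = list(alpha = c(0, 10), theta = c(0, 2000))) {
  tab <- tabulate(validate_counts(counts, n_max) + 1L, nbins = n_max + 1L)
  function(x) {
    if (any(!is.finite(x)) || any(abs(x) > 50)) return(1e10)
    if (family == "gnb") {
      alpha <- exp(x[1L]); theta <- exp(x[2L]); gamma <- stats::plogis(x[3L])
    } else {
      alpha <- 1; theta <- exp(x[1L]); gamma <- stats::plogis(x[2L])
    }
    if (alpha > bounds$alpha[2L] || theta > bounds$theta[2L]) return(1e10)
    ll <- gnb_loglik_cpp(tab, alpha, theta, gamma)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
}

# method-of-moments initialization from the alpha = 1 (negative binomial) law:
# mean = gamma (theta + 1) / (1 - gamma), var = mean / (1 - gamma)
moments_init <- function(counts) {
  m <- mean(counts); v <- stats::var(counts)
  gamma0 <- 1 - m / max(v, m * 1.0001)
  gamma0 <- min(max(gamma0, 0.05), 0.95)
  theta0 <- min(max(m * (1 - gamma0) / gamma0 - 1, 0.5), 1500)
  c(theta = theta0, gamma = gamma0)
}

# mean-matched fallback starts spanning the gamma range; used when the
# moments start alone cannot bracket under-dispersed samples
fallback_starts <- function(counts, family) {
  m <- max(mean(counts), 1)
  lapply(c(0.3, 0.7), function(g) {
    th <- min(max(m * (1 - g) / g, 0.5), 1500)
    if (family == "gnb") c(log(1.5), log(th), stats::qlogis(g))
    else c(log(th), stats::qlogis(g))
  })
}

#' Maximum-likelihood fit of the count distribution
#'
#' Fits the stationary law to scaled single-cell counts by direct
#' maximization of the log-likelihood with derivative-free local search
#' (Nelder-Mead on log/logit-transformed parameters) from several starting
#' points: a method-of-moments negative-binomial initialization for
#' \eqn{(\theta, \gamma)} combined with cooperativity starts
#' \eqn{\alpha \in \{1, 2, 3\}} (the `nb` family pins \eqn{\alpha = 1}).
#'
#' @param counts Integer vector of scaled counts (>= 10 observations).
#' @param family `"nb"` (negative binomial, 2 free parameters) or `"gnb"`
#'   (generalized negative binomial, 3 free parameters).
#' @param n_max Truncation bound; default 1000.
#' @param start Optional [degradation_params()] used as the single start
#'   (used by the bootstrap refits for speed).
#' @return Object of class `fit_result`: list with `family`, `params_hat`,
#'   `log_likelihood`, `k` (free parameters), `n`, and `aic`, `bic`, `aicc`.
#' @export
fit_ml <- function(counts, family = c("gnb", "nb"), n_max = 1000L,
                   start = NULL) {
  family <- match.arg(family)
  counts <- validate_counts(counts, n_max)
  if (length(counts) < 10L)
    stop_nucdeg("need at least 10 observations to fit", "nucdeg_invalid_counts")
  nll <- nll_factory(counts, family, n_max)

  if (is.null(start)) {
    mm <- moments_init(counts)
    mode_obs <- max(as.numeric(names(which.max(table(counts)))), 1)
    starts <- if (family == "gnb") {
      lapply(c(1, 2, 3), function(a) {
        th <- if (a == 1) mm[["theta"]] else
          max(mode_obs * ((1 - mm[["gamma"]]) / mm[["gamma"]])^(1 / a), 0.5)
        c(log(a), log(th), stats::qlogis(mm[["gamma"]]))
      })
    } else {
      c(list(c(log(mm[["theta"]]), stats::qlogis(mm[["gamma"]]))),
        fallback_starts(counts, "nb"))
    }
  } else {
    start <- as_degradation_params(start)
    starts <- if (family == "gnb") {
      list(c(log(start$alpha), log(start$theta), stats::qlogis(start$gamma)))
    } else {
      list(c(log(start$theta), stats::qlogis(start$gamma)))
    }
  }

  best <- NULL
  for (x0 in starts) {
    opt <- tryCatch(
      stats::optim(x0, nll, method = "Nelder-Mead",
                   control = list(maxit = 1000, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e10) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop_nucdeg("maximum-likelihood fit failed to converge from all starts",
                "nucdeg_fit_failure")

  x <- best$par
  params_hat <- if (family == "gnb") {
    degradation_params(exp(x[1L]), exp(x[2L]), stats::plogis(x[3L]))
  } else {
    degradation_params(1, exp(x[1L]), stats::plogis(x[2L]))
  }
  ll <- -best$value
  k <- if (family == "gnb") 3L else 2L
  n <- length(counts)
  fit <- structure(list(family = family, params_hat = params_hat,
                        log_likelihood = ll, k = k, n = n, n_max = n_max,
                        convergence = best$convergence),
                   class = "fit_result")
  fit[c("aic", "bic", "aicc")] <- information_criteria(fit)
  fit
}

#' @export
print.fit_result <- function(x, ...) {
  p <- x$params_hat
  cat(sprintf("%s maximum-likelihood fit (n = %d)\n",
              toupper(x$family), x$n))
  cat(sprintf("  alpha = %.4g%s, theta = %.4g, gamma = %.4g\n",
              p$alpha, if (x$family == "nb") " (fixed)" else "",
              p$theta, p$gamma))
  cat(sprintf("  logLik = %.3f, AIC = %.2f, BIC = %.2f, AICc = %.2f\n",
              x$log_likelihood, x$aic, x$bic, x$aicc))
  invisible(x)
}

#' Information criteria of a fit
#'
#' AIC, BIC and the small-sample-corrected AICc:
#' `aic = 2k - 2 logL`, `bic = k log(n) - 2 logL`,
#' `aicc = aic + 2k(k+1)/(n-k-1)`.
#'
#' @param fit A [fit_ml()] result.
#' @return List with `aic`, `bic`, `aicc`.
#' @export
information_criteria <- function(fit) {
  stopifnot(inherits(fit, "fit_result"))
  k <- fit$k; n <- fit$n; ll <- fit$log_likelihood
  if (n <= k + 1L)
    stop_nucdeg("AICc undefined: sample size must exceed k + 1",
                "nucdeg_invalid_params")
  aic <- 2 * k - 2 * ll
  list(aic = aic, bic = k * log(n) - 2 * ll,
       aicc = aic + 2 * k * (k + 1) / (n - k - 1))
}

#' Compare the nb and gnb families on one count sample
#'
#' Fits both families by maximum likelihood and reports the information
#' criterion differences `delta = criterion(gnb) - criterion(nb)`; negative
#' values favour the generalized (cooperative) model.
#'
#' @param counts Integer count vector.
#' @param n_max Truncation bound; default 1000.
#' @return List with `fit_nb`, `fit_gnb`, `delta_aic`, `delta_bic`,
#'   `delta_aicc`, `n`.
#' @export
compare_families <- function(counts, n_max = 1000L) {
  fit_nb <- fit_ml(counts, "nb", n_max)
  fit_gnb <- fit_ml(counts, "gnb", n_max)
  list(fit_nb = fit_nb, fit_gnb = fit_gnb,
       delta_aic = fit_gnb$aic - fit_nb$aic,
       delta_bic = fit_gnb$bic - fit_nb$bic,
       delta_aicc = fit_gnb$aicc - fit_nb$aicc,
       n = length(counts))
}

#' Profile-likelihood confidence intervals for an ML fit
#'
#' For each free parameter, profiles the log-likelihood (re-maximizing over
#' the remaining parameters) outward from the MLE until it drops by
#' `qchisq(level, 1) / 2`, the likelihood-ratio cutoff.  On weakly
#' identified data the profiles follow the likelihood ridge, so the
#' intervals widen honestly instead of relying on curvature at the maximum.
#' Intervals are truncated at the parameter domain bounds
#' (`alpha <= 10`, `theta <= 2000`, `gamma` in (0,1)).
#'
#' @param counts The counts the fit was computed from.
#' @param fit A [fit_ml()] result.
#' @param level Confidence level; default 0.95.
#' @param n_grid Profile evaluations per direction; default 25.
#' @return Matrix with rows `lower`/`upper` and one column per free
#'   parameter.
#' @export
profile_intervals <- function(counts, fit, level = 0.95, n_grid = 25L) {
  stopifnot(inherits(fit, "fit_result"))
  counts <- validate_counts(counts, fit$n_max)
  tab <- tabulate(counts + 1L, nbins = fit$n_max + 1L)
  cutoff <- stats::qchisq(level, 1) / 2
  ll_max <- fit$log_likelihood
  ph <- fit$params_hat
  free <- if (fit$family == "gnb") c("alpha", "theta", "gamma") else
    c("theta", "gamma")

  # u-scale bounds: log alpha in (-inf, log 10], log theta in (-inf, log 2000],
  # logit gamma unbounded
  u_hat <- c(alpha = log(ph$alpha), theta = log(ph$theta),
             gamma = stats::qlogis(ph$gamma))
  u_cap <- c(alpha = log(10), theta = log(2000), gamma = Inf)

  prof_ll <- function(name, u_val, warm = NULL) {
    others <- setdiff(free, name)
    assemble <- function(uo) {
      u <- u_hat
      u[name] <- u_val
      u[others] <- uo
      a <- if (fit$family == "nb") 1 else exp(u[["alpha"]])
      c(a, exp(u[["theta"]]), stats::plogis(u[["gamma"]]))
    }
    nll <- function(uo) {
      p <- assemble(uo)
      if (p[1L] > 10 || p[2L] > 2000) return(1e10)
      ll <- gnb_loglik_cpp(tab, p[1L], p[2L], p[3L])
      if (!is.finite(ll)) return(1e10)
      -ll
    }
    start <- if (is.null(warm)) u_hat[others] else warm
    o <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(maxit = 600, reltol = 1e-9))
    list(ll = -o$value, par = o$par)
  }

  scan_dir <- function(name, direction) {
    # walk outward on the u scale, warm-starting each profile optimization
    # from the previous point so the maximization tracks the ridge, then
    # bisect across the cutoff
    u0 <- u_hat[[name]]
    step <- 0.08
    prev <- u0; warm <- NULL
    hi <- u0; crossed <- FALSE
    for (i in seq_len(n_grid)) {
      cand <- u0 + direction * step * i * (1 + 0.12 * i)
      capped <- direction > 0 && cand > u_cap[[name]]
      if (capped) cand <- u_cap[[name]]
      pr <- prof_ll(name, cand, warm)
      warm <- pr$par
      if (ll_max - pr$ll > cutoff) { hi <- cand; crossed <- TRUE; break }
      prev <- cand
      hi <- cand
      if (capped) break
    }
    if (!crossed) return(hi)
    lo <- prev
    for (i in seq_len(12L)) {
      mid <- (lo + hi) / 2
      pr <- prof_ll(name, mid, warm)
      warm <- pr$par
      if (ll_max - pr$ll > cutoff) hi <- mid else lo <- mid
      if (abs(hi - lo) < 1e-3) break
    }
    (lo + hi) / 2
  }

  out <- vapply(free, function(name) {
    lo_u <- scan_dir(name, -1)
    hi_u <- scan_dir(name, +1)
    back <- function(u) switch(name, alpha = exp(u), theta = exp(u),
                               gamma = stats::plogis(u))
    c(lower = back(lo_u), upper = back(hi_u))
  }, numeric(2L))
  out
}

# u-space local optima of the gnb likelihood from the standard multi-start
# scheme, deduplicated; used by the sampler to build mode-jump proposals
gnb_mode_candidates <- function(counts, n_max = 1000L) {
  counts <- validate_counts(counts, n_max)
  nll <- nll_factory(counts, "gnb", n_max)
  mm <- moments_init(counts)
  mode_obs <- max(as.numeric(names(which.max(table(counts)))), 1)
  starts <- lapply(c(1, 2, 3), function(a) {
    th <- if (a == 1) mm[["theta"]] else
      max(mode_obs * ((1 - mm[["gamma"]]) / mm[["gamma"]])^(1 / a), 0.5)
    c(log(a), log(th), stats::qlogis(mm[["gamma"]]))
  })
  sols <- list()
  for (x0 in starts) {
    opt <- tryCatch(
      stats::optim(x0, nll, method = "Nelder-Mead",
                   control = list(maxit = 1000, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e10) next
    dup <- any(vapply(sols, function(s) sqrt(sum((s - opt$par)^2)) < 0.4,
                      TRUE))
    if (!dup) sols[[length(sols) + 1L]] <- opt$par
  }
  if (length(sols) == 0L) return(matrix(numeric(0), 0L, 3L))
  do.call(rbind, sols)
}
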