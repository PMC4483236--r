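# Adaptive-Metropolis posterior sampling of (alpha, theta, gamma).
#
# The posterior is the likelihood under a flat prior truncated to practical
# bounds (gamma in (0,1) by construction; theta in (0, 2000); alpha in
# (0, 10]); the bounds make the otherwise improper flat prior proper without
# constraining realistic fits on the [0, 1000] count scale.

#' Settings for the adaptive Metropolis sampler
#'
#' Defaults follow the estimation protocol used for the fluorescence data:
#' 2e5 steps, 1e5 burn-in, thinning factor 10 (9 of every 10 post-burn-in
#' steps discarded to reduce sampling correlation).
#'
#' @param steps Total chain length.
#' @param burn_in Steps discarded before retention; must be < `steps`.
#' @param thin Thinning factor (>= 1).
#' @param seed RNG seed; the chain is bit-reproducible given the seed.
#' @param adapt_interval Proposal-covariance refresh interval during
#'   burn-in (steps).
#' @param scale Proposal covariance scaling; default `2.38^2 / 3`, the
#'   standard optimal random-walk scaling in 3 dimensions.
#' @param n_temps Number of parallel-tempering levels (1 disables
#'   tempering); default 3.
#' @param temp_max Hottest temperature of the geometric ladder; default 10.
#' @param swap_interval Steps between replica-exchange attempts; default 10.
#' @return Object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(steps = 200000L, burn_in = 100000L, thin = 10L,
                          seed = 1L, adapt_interval = 100L,
                          scale = 2.38^2 / 3, n_temps = 3L, temp_max = 10,
                          swap_interval = 10L) {
  steps <- as.integer(steps); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (burn_in >= steps)
    stop_nucdeg("'burn_in' must be smaller than 'steps'", "nucdeg_invalid_params")
  if (thin < 1L)
    stop_nucdeg("'thin' must be >= 1", "nucdeg_invalid_params")
  if (n_temps < 1L || temp_max <= 1)
    stop_nucdeg("'n_temps' must be >= 1 and 'temp_max' > 1",
                "nucdeg_invalid_params")
  structure(list(steps = steps, burn_in = burn_in, thin = thin,
                 seed = as.integer(seed),
                 adapt_interval = as.integer(adapt_interval),
                 scale = scale, n_temps = as.integer(n_temps),
                 temp_max = temp_max,
                 swap_interval = as.integer(swap_interval)),
            class = "mcmc_settings")
}

#' Adaptive Metropolis sampling of the degradation-model posterior
#'
#' Random-walk Metropolis targeting the posterior of
#' \eqn{(\alpha, \theta, \gamma)} under a flat prior truncated to the
#' practical bounds above.  The walk itself takes place on
#' \eqn{(\log\alpha, \log\theta, \mathrm{logit}\,\gamma)} with the Jacobian
#' correction, because the likelihood ridge coupling the three parameters
#' is nearly straight on that scale and a Gaussian random walk can traverse
#' it; the target remains the flat-prior posterior on the natural scale.
#' The proposal covariance is learned from the chain's own history
#' (refreshed every `adapt_interval` steps during burn-in, scaled by
#' \eqn{2.38^2/3} times a step-size multiplier tuned to the optimal
#' acceptance rate, then frozen so the post-burn-in chain is a genuine
#' Markov chain).  Proposals outside the truncated prior's support are
#' rejected.
#'
#' Because the three parameters trade off along a long, curved likelihood
#' ridge, a single locally adapted walk can fail to explore the full
#' posterior; the sampler therefore runs a small parallel-tempering ladder
#' (`n_temps` levels with replica exchange) plus symmetric mode-jump
#' proposals between the distinct optima found by the multi-start ML fit.
#' Only the cold level is retained, so the returned chain targets the
#' exact flat-prior posterior.
#'
#' @param counts Integer vector of scaled counts.
#' @param settings An [mcmc_settings()] object.
#' @param init Optional [degradation_params()] starting point; defaults to
#'   the gnb maximum-likelihood fit.
#' @param n_max Truncation bound of the pmf; default 1000.
#' @return Object of class `posterior_chain`: list with matrix `samples`
#'   (columns alpha, theta, gamma), `log_likelihoods`, `acceptance_rate`,
#'   `settings`.
#' @export
run_adaptive_metropolis <- function(counts, settings = mcmc_settings(),
                                    init = NULL, n_max = 1000L) {
  stopifnot(inherits(settings, "mcmc_settings"))
  counts <- validate_counts(counts, n_max)
  tab <- tabulate(counts + 1L, nbins = n_max + 1L)

  set.seed(settings$seed)
  if (is.null(init)) init <- fit_ml(counts, "gnb", n_max)$params_hat
  init <- as_degradation_params(init)
  init_u <- c(log(init$alpha), log(init$theta), stats::qlogis(init$gamma))

  # displacement vectors between distinct likelihood modes found by the
  # multi-start fit; the sampler uses them as symmetric mode-jump proposals
  # so the chain can cross the probability barrier between modes
  modes <- gnb_mode_candidates(counts, n_max)
  jumps <- if (nrow(modes) >= 2L) {
    pairs <- utils::combn(nrow(modes), 2L)
    t(apply(pairs, 2L, function(ij) modes[ij[2L], ] - modes[ij[1L], ]))
  } else {
    matrix(numeric(0), 0L, 3L)
  }

  res <- am_chain_cpp(tab, init_u, settings$steps, settings$burn_in,
                      settings$thin, settings$adapt_interval, settings$scale,
                      10, 2000, jumps, settings$n_temps, settings$temp_max,
                      settings$swap_interval)
  samples <- res$samples
  colnames(samples) <- c("alpha", "theta", "gamma")

  if (res$acceptance_rate < 0.01)
    warning(sprintf("post-burn-in acceptance rate %.3f%% indicates mixing failure",
                    100 * res$acceptance_rate), call. = FALSE)

  structure(list(samples = samples,
                 log_likelihoods = as.numeric(res$log_likelihoods),
                 acceptance_rate = res$acceptance_rate,
                 settings = settings, n_max = n_max),
            class = "posterior_chain")
}

#' @export
print.posterior_chain <- function(x, ...) {
  cat(sprintf("Posterior chain: %d retained samples (acceptance %.1f%%)\n",
              nrow(x$samples), 100 * x$acceptance_rate))
  s <- posterior_summary(x)
  p <- s$point
  cat(sprintf("  point (max logLik): alpha = %.4g, theta = %.4g, gamma = %.4g\n",
              p$alpha, p$theta, p$gamma))
  invisible(x)
}

#' Summarize a posterior chain
#'
#' The point estimate is the retained sample with the highest
#' log-likelihood (the local maximum taken as the maximum-likelihood
#' value); spread is reported as per-parameter standard deviations and
#' central 95% credible intervals, plus the pairwise correlation matrix.
#'
#' @param chain A [run_adaptive_metropolis()] result.
#' @return List with `point` ([degradation_params()]), `sd` (named vector),
#'   `ci` (2 x 3 matrix of 2.5% and 97.5% quantiles), `correlation`
#'   (3 x 3 matrix).
#' @export
posterior_summary <- function(chain) {
  stopifnot(inherits(chain, "posterior_chain"))
  if (nrow(chain$samples) == 0L)
    stop_nucdeg("empty chain", "nucdeg_invalid_params")
  best <- which.max(chain$log_likelihoods)
  pt <- chain$samples[best, ]
  sds <- apply(chain$samples, 2L, stats::sd)
  ci <- apply(chain$samples, 2L, stats::quantile, probs = c(0.025, 0.975))
  corr <- if (all(sds > 0)) stats::cor(chain$samples) else
    diag(3L)
  dimnames(corr) <- list(colnames(chain$samples), colnames(chain$samples))
  list(point = degradation_params(pt[["alpha"]], pt[["theta"]], pt[["gamma"]]),
       sd = sds, ci = ci, correlation = corr)
}

#' Write a posterior chain to a flat CSV
#'
#' @param chain A `posterior_chain`.
#' @param path Output path (columns step, alpha, theta, gamma, loglik).
#' @return `path`, invisibly.
#' @export
write_chain_csv <- function(chain, path) {
  stopifnot(inherits(chain, "posterior_chain"))
  utils::write.csv(
    data.frame(step = seq_len(nrow(chain$samples)), chain$samples,
               loglik = chain$log_likelihoods),
    path, row.names = FALSE)
  invisible(path)
}
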