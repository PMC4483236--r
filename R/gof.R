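# Parametric-bootstrap r-squared goodness of fit.
#
# The Kolmogorov-Smirnov test is biased when the tested distribution's
# parameters are estimated from the same data, so the fit quality is
# assessed instead by comparing the observed histogram-level r-squared with
# its null distribution under data resampled from the fitted model.

#' Histogram r-squared between counts and a stationary pmf
#'
#' Bins the support `[0, n_max]` into fixed-width bins and computes
#' \eqn{r^2 = 1 - SS_{res}/SS_{tot}} between the observed bin relative
#' frequencies and the model bin probabilities, with the total sum of
#' squares taken around the mean observed bin frequency.  Fixed-width bins
#' keep the statistic well defined for sparse counts; the width is
#' configurable.
#'
#' @param counts Integer count vector within the pmf support.
#' @param pmf A [stationary_pmf()] object.
#' @param bin_width Bin width on the count axis; default 20.
#' @return The r-squared statistic (<= 1; can be negative for fits worse
#'   than a flat histogram).
#' @export
r2_statistic <- function(counts, pmf, bin_width = 20L) {
  stopifnot(inherits(pmf, "stationary_pmf"))
  counts <- validate_counts(counts, pmf$n_max)
  breaks <- seq(0L, pmf$n_max + bin_width, by = bin_width)
  bin_of <- findInterval(counts, breaks, rightmost.closed = FALSE)
  n_bins <- length(breaks) - 1L
  obs <- tabulate(bin_of, nbins = n_bins) / length(counts)
  if (sum(obs > 0) < 3L)
    stop_nucdeg("fewer than 3 non-empty bins: r-squared undefined",
                "nucdeg_undefined_statistic")
  bin_of_support <- findInterval(0:pmf$n_max, breaks, rightmost.closed = FALSE)
  model <- as.numeric(rowsum(pmf$probs, bin_of_support)[, 1L])
  model <- model[seq_len(n_bins)]
  model[is.na(model)] <- 0
  ss_res <- sum((obs - model)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  1 - ss_res / ss_tot
}

#' Parametric-bootstrap goodness-of-fit p-value
#'
#' Fits the chosen family by maximum likelihood, computes the observed
#' histogram r-squared against the fitted pmf, then repeatedly (B times)
#' draws a sample of the same size from the fitted distribution, refits the
#' same family (starting the optimizer from the original fit) and records
#' the r-squared of the refit.  The one-sided lower-tail p-value
#' \deqn{p = \frac{1 + \#\{b : r^2_b \le r^2_{obs}\}}{B + 1}}
#' is the probability of a fit at least as poor as the observed one when
#' the family is true; low p indicates the family cannot describe the data.
#'
#' @param counts Integer count vector.
#' @param family `"nb"` or `"gnb"`.
#' @param B Number of bootstrap replicates; default 1000.
#' @param seed RNG seed (result is deterministic given the seed).
#' @param n_max Truncation bound; default 1000.
#' @param bin_width Histogram bin width for the statistic; default 20.
#' @return Object of class `gof_result`: list with `family`, `r2_observed`,
#'   `r2_null` (length B), `p_value`, `B`, `seed`, `fit`.
#' @export
bootstrap_gof <- function(counts, family = c("gnb", "nb"), B = 1000L,
                          seed = 1L, n_max = 1000L, bin_width = 20L) {
  family <- match.arg(family)
  counts <- validate_counts(counts, n_max)
  fit <- fit_ml(counts, family, n_max)
  pmf_hat <- stationary_pmf(fit$params_hat, n_max)
  r2_obs <- r2_statistic(counts, pmf_hat, bin_width)

  set.seed(seed)
  n <- length(counts)
  r2_null <- numeric(B)
  failures <- 0L
  for (b in seq_len(B)) {
    boot_counts <- sample_counts_from_pmf(pmf_hat, n)
    rb <- tryCatch({
      fit_b <- fit_ml(boot_counts, family, n_max, start = fit$params_hat)
      r2_statistic(boot_counts, stationary_pmf(fit_b$params_hat, n_max),
                   bin_width)
    }, error = function(e) NA_real_)
    if (is.na(rb)) failures <- failures + 1L
    r2_null[b] <- rb
  }
  if (failures > 0.05 * B)
    stop_nucdeg(sprintf("%d of %d bootstrap refits failed; result unreliable",
                        failures, B), "nucdeg_unreliable_result")
  ok <- !is.na(r2_null)
  p_value <- (1 + sum(r2_null[ok] <= r2_obs)) / (sum(ok) + 1)

  structure(list(family = family, r2_observed = r2_obs,
                 r2_null = r2_null[ok], p_value = p_value,
                 B = as.integer(B), seed = as.integer(seed), fit = fit),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf(
    "Parametric-bootstrap GoF (%s): r2 = %.4f, p = %.3f (B = %d)\n",
    toupper(x$family), x$r2_observed, x$p_value, x$B))
  invisible(x)
}

#' Goodness-of-fit p-value matrix across passages and experiments
#'
#' Builds the familiar report shape: one row per experiment plus a pooled
#' `"combined"` row, one column per passage, each cell the bootstrap GoF
#' p-value for the requested family (cells with fewer than `min_n` cells
#' are left NA).
#'
#' @param dataset A [scale_to_counts()] result.
#' @param family `"nb"` or `"gnb"`.
#' @param B Bootstrap replicates per cell.
#' @param seed Master seed; each cell uses a derived child seed.
#' @param min_n Minimum cells required to test a cell; default 50.
#' @param n_max Truncation bound.
#' @return A data.frame with rownames = experiments + "combined" and one
#'   column per passage.
#' @export
gof_matrix <- function(dataset, family = c("gnb", "nb"), B = 199L,
                       seed = 1L, min_n = 50L, n_max = 1000L) {
  family <- match.arg(family)
  stopifnot(inherits(dataset, "scaled_dataset"))
  passages <- sort(unique(dataset$passage))
  experiments <- sort(unique(dataset$experiment))
  rows <- c(experiments, "combined")
  out <- matrix(NA_real_, nrow = length(rows), ncol = length(passages),
                dimnames = list(rows, paste0("p", passages)))
  seeds <- fanout_seeds(seed, length(rows) * length(passages))
  k <- 0L
  for (i in seq_along(rows)) {
    for (j in seq_along(passages)) {
      k <- k + 1L
      counts <- tryCatch(
        select_passage(dataset, passages[j],
                       if (rows[i] == "combined") "all" else rows[i]),
        error = function(e) NULL)
      if (is.null(counts) || length(counts) < min_n) next
      res <- tryCatch(
        bootstrap_gof(counts, family, B = B, seed = seeds[k], n_max = n_max),
        error = function(e) NULL)
      if (!is.null(res)) out[i, j] <- res$p_value
    }
  }
  as.data.frame(out)
}
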