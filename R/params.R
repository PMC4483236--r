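#' Parameters of the cooperative active-degradation model
#'
#' Constructs and validates the parameter triple of the birth-death model of
#' nuclear protein abundance: constant production at normalized rate
#' \eqn{\gamma} and Hill-kinetics degradation at rate
#' \eqn{r_n = n^\alpha / (\theta^\alpha + n^\alpha)}.  All kinetic
#' coefficients are normalized to the maximal degradation rate, so
#' \eqn{\gamma} is the ratio of the constant production rate to the maximal
#' degradation velocity and a stationary distribution exists only for
#' \eqn{\gamma \in (0, 1)}.
#'
#' @param alpha Hill cooperativity coefficient; any positive real.
#'   `alpha = 1` gives uncooperative Michaelis-Menten degradation and the
#'   stationary law reduces to a negative binomial distribution.
#' @param theta Half-saturation threshold of the degradation machinery, in
#'   scaled-count units; any positive real.
#' @param gamma Production/maximal-degradation rate ratio, in (0, 1).
#' @return An object of class `degradation_params` (a named list with
#'   elements `alpha`, `theta`, `gamma`).
#' @examples
#' degradation_params(alpha = 2, theta = 250, gamma = 0.8)
#' @export
degradation_params <- function(alpha, theta, gamma) {
  for (nm in c("alpha", "theta", "gamma")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop_nucdeg(sprintf("'%s' must be a single finite numeric value", nm),
                  "nucdeg_invalid_params")
  }
  if (alpha <= 0)
    stop_nucdeg("'alpha' must be > 0", "nucdeg_invalid_params")
  if (theta <= 0)
    stop_nucdeg("'theta' must be > 0", "nucdeg_invalid_params")
  if (gamma <= 0 || gamma >= 1)
    stop_nucdeg("'gamma' must lie in the open interval (0, 1)",
                "nucdeg_invalid_params")
  structure(list(alpha = as.double(alpha), theta = as.double(theta),
                 gamma = as.double(gamma)),
            class = "degradation_params")
}

#' @export
print.degradation_params <- function(x, ...) {
  cat(sprintf(
    "Cooperative degradation parameters: alpha = %g, theta = %g, gamma = %g\n",
    x$alpha, x$theta, x$gamma))
  invisible(x)
}

as_degradation_params <- function(x) {
  if (inherits(x, "degradation_params")) return(x)
  if (is.numeric(x) && length(x) == 3L)
    return(degradation_params(x[[1L]], x[[2L]], x[[3L]]))
  if (is.list(x) && all(c("alpha", "theta", "gamma") %in% names(x)))
    return(degradation_params(x$alpha, x$theta, x$gamma))
  stop_nucdeg("cannot interpret object as degradation parameters",
              "nucdeg_invalid_params")
}

#' Parameters of the Gamma burst-production null model
#'
#' The continuous null model for protein abundance under bursty production:
#' proteins are produced in exponentially distributed translational bursts
#' from short-lived transcripts and degraded linearly, giving a Gamma
#' stationary density.  `a` is the mean number of bursts per protein
#' lifetime and `b` the mean number of proteins per burst, so the summed
#' abundance of many protein species with a shared burst size is again
#' Gamma with the shape parameters added.
#'
#' @param a Mean bursts per degradation cycle; positive real.
#' @param b Mean proteins per burst (scale); positive real.
#' @return An object of class `gamma_burst_params`.
#' @export
gamma_burst_params <- function(a, b) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop_nucdeg("'a' must be a single positive number", "nucdeg_invalid_params")
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0)
    stop_nucdeg("'b' must be a single positive number", "nucdeg_invalid_params")
  structure(list(a = as.double(a), b = as.double(b)),
            class = "gamma_burst_params")
}
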