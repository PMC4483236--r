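# internal numerical helpers

# log(sum(exp(x))) without overflow; -Inf-safe
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# round half away from zero (base round() rounds half to even)
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Derive reproducible child seeds from a master seed
#'
#' Deterministically expands one master seed into named per-stage seeds so
#' that pipeline stages can be rerun independently with identical randomness.
#' Kept strictly below 2^31 so the result is always a valid R integer seed.
#'
#' @param master_seed Integer master seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`.
#' @export
fanout_seeds <- function(master_seed, n) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L, n >= 1)
  # linear congruential expansion, values in [1, 2^31 - 2]
  m <- 2147483647
  s <- (as.double(master_seed) %% m)
  out <- integer(n)
  for (i in seq_len(n)) {
    s <- (s * 48271) %% m
    if (s == 0) s <- 1
    out[i] <- as.integer(s)
  }
  out
}

stop_nucdeg <- function(msg, class) {
  stop(structure(
    class = c(class, "nucdeg_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
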