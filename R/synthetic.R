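# Synthetic data: model-exact count samples, Gillespie trajectories as an
# independent oracle, and full synthetic single-cell studies.

#' Draw i.i.d. counts from a pre-computed stationary pmf
#'
#' Inverse-CDF lookup on the truncated pmf.  Used internally by the
#' bootstrap and by [sample_counts()].
#'
#' @param pmf A [stationary_pmf()] object.
#' @param n Sample size.
#' @param seed Optional RNG seed; if `NULL`, the ambient RNG state is used.
#' @return Integer vector of length `n`.
#' @export
sample_counts_from_pmf <- function(pmf, n, seed = NULL) {
  stopifnot(inherits(pmf, "stationary_pmf"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  cdf <- cumsum(pmf$probs)
  u <- stats::runif(n)
  pmin(findInterval(u, cdf), pmf$n_max)
}

#' Draw i.i.d. counts from the stationary law
#'
#' @param params A [degradation_params()] object.
#' @param n Sample size (>= 1).
#' @param seed RNG seed for reproducibility.
#' @param n_max Truncation bound; default 1000.
#' @return Integer vector of length `n`.
#' @export
sample_counts <- function(params, n, seed = NULL, n_max = 1000L) {
  sample_counts_from_pmf(stationary_pmf(params, n_max), n, seed)
}

#' Stationary distribution by exact stochastic simulation
#'
#' Independent oracle for the analytic pmf: Gillespie simulation of the
#' birth-death chain with birth rate `rate_scale * gamma` and death rate
#' `rate_scale * n^alpha / (theta^alpha + n^alpha)`, summarized as the
#' time-weighted occupancy of each state over the window
#' `(t_burn, t_total]`.  Time-weighting (rather than event sampling)
#' avoids holding-time bias; in distribution the estimate is invariant to
#' `rate_scale`, which only rescales time.
#'
#' @param params A [degradation_params()] object.
#' @param rate_scale Overall kinetic rate scale; default 1.
#' @param t_burn Equilibration time discarded before observation.
#' @param t_total Total simulated time (> `t_burn`).
#' @param seed RNG seed.
#' @param n0 Initial state; defaults to the deterministic mode (rounded),
#'   which shortens equilibration.
#' @param n_cap Hard cap on the simulated state space.
#' @return List with `probs` (empirical stationary distribution over
#'   `0:n_cap`), `n_cap`, and the call parameters.
#' @export
ssa_stationary_sample <- function(params, rate_scale = 1, t_burn, t_total,
                                  seed = NULL, n0 = NULL, n_cap = 4000L) {
  params <- as_degradation_params(params)
  if (t_burn >= t_total)
    stop_nucdeg("'t_burn' must be smaller than 't_total'", "nucdeg_invalid_params")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n0)) n0 <- as.integer(round(deterministic_mode(params)))
  occ <- ssa_occupancy_cpp(params$alpha, params$theta, params$gamma,
                           rate_scale, t_burn, t_total,
                           as.integer(n0), as.integer(n_cap))
  list(probs = as.numeric(occ), n_cap = as.integer(n_cap), params = params,
       rate_scale = rate_scale, t_burn = t_burn, t_total = t_total)
}

#' Total-variation distance between an analytic pmf and an SSA estimate
#'
#' @param pmf A [stationary_pmf()] object.
#' @param ssa An [ssa_stationary_sample()] result.
#' @return Total-variation distance in `[0, 1]`.
#' @export
tv_distance <- function(pmf, ssa) {
  stopifnot(inherits(pmf, "stationary_pmf"))
  len <- max(pmf$n_max, ssa$n_cap) + 1L
  p <- c(pmf$probs, numeric(len - pmf$n_max - 1L))
  q <- c(ssa$probs, numeric(len - ssa$n_cap - 1L))
  sum(abs(p - q)) / 2
}

#' Design of a synthetic single-cell fluorescence study
#'
#' Defaults emulate the structure of the senescence experiment: six
#' passages with the observed per-passage cell numbers
#' (744, 255, 195, 103, 182, 684 at passages 3, 9-13), constant
#' cooperativity and threshold, and a production/degradation ratio gamma
#' drifting linearly on the log-odds scale across passages from 0.30 to
#' 0.85 (the generating values themselves are package choices, not
#' measured quantities; the ramp spans the regime where the cooperative
#' and uncooperative families are clearly distinguishable through the
#' near-saturated regime where they are not, and moves the distribution
#' mode several-fold, matching the qualitative behaviour of senescing
#' cultures).  Experiments mirror the replicate layout: the first and last
#' passages are pooled from several replicates, intermediate passages come
#' from one.
#'
#' @param passages Passage numbers.
#' @param n_per_passage Cells per passage.
#' @param alpha,theta Constant model parameters across passages.  The
#'   default threshold (320) is chosen so the last passage's distribution
#'   reaches close to 1000: generated counts then live natively on the
#'   analysis scale and the fluorescence rescaling is near the identity.
#'   This matters because the count statistics are not scale-invariant —
#'   stretching counts by a factor s multiplies the Fano factor by s, and
#'   the sub-Poissonian dispersion that distinguishes cooperative from
#'   uncooperative degradation is destroyed if generation happens far
#'   below the analysis scale.
#' @param gamma_by_passage Gamma per passage, in (0,1); default a linear
#'   log-odds ramp from 0.30 to 0.85.
#' @param experiments_by_passage List of experiment labels active at each
#'   passage (cells split evenly among them).
#' @param fluorescence_unit Raw fluorescence units per protein count.
#' @param nucleus_meanlog,nucleus_sdlog Log-normal nucleus-area parameters.
#' @param seed RNG seed.
#' @return Object of class `study_design`.
#' @export
study_design <- function(passages = c(3L, 9L, 10L, 11L, 12L, 13L),
                         n_per_passage = c(744L, 255L, 195L, 103L, 182L, 684L),
                         alpha = 2, theta = 320,
                         gamma_by_passage = inv_log_odds_gamma(
                           seq(log(0.7 / 0.3), log(0.15 / 0.85),
                               length.out = length(passages))),
                         experiments_by_passage = NULL,
                         fluorescence_unit = 100,
                         nucleus_meanlog = log(150), nucleus_sdlog = 0.25,
                         seed = 1L) {
  if (length(passages) != length(n_per_passage) ||
      length(passages) != length(gamma_by_passage))
    stop_nucdeg("'passages', 'n_per_passage' and 'gamma_by_passage' must have equal length",
                "nucdeg_invalid_params")
  if (any(gamma_by_passage <= 0) || any(gamma_by_passage >= 1))
    stop_nucdeg("all gammas must lie in (0, 1)", "nucdeg_invalid_params")
  if (is.null(experiments_by_passage)) {
    experiments_by_passage <- lapply(passages, function(p) {
      if (p == min(passages)) paste0("exp", 1:3)
      else if (p == max(passages)) paste0("exp", 1:4)
      else "exp4"
    })
  }
  stopifnot(length(experiments_by_passage) == length(passages))
  structure(list(passages = as.integer(passages),
                 n_per_passage = as.integer(n_per_passage),
                 alpha = alpha, theta = theta,
                 gamma_by_passage = as.numeric(gamma_by_passage),
                 experiments_by_passage = experiments_by_passage,
                 fluorescence_unit = fluorescence_unit,
                 nucleus_meanlog = nucleus_meanlog,
                 nucleus_sdlog = nucleus_sdlog,
                 seed = as.integer(seed)),
            class = "study_design")
}

#' Generate a synthetic single-cell study
#'
#' Per passage, draws counts from the generalized-negative-binomial
#' stationary law at the design parameters and maps them to continuous
#' fluorescence as `count * fluorescence_unit + Uniform(0, unit)` jitter
#' (mimicking a continuous microscope readout while keeping count recovery
#' near-exact); nucleus areas are log-normal and cells are allocated
#' round-robin to the passage's experiments.
#'
#' @param design A [study_design()] object.
#' @return A list with `records` (a `cell_records` data.frame emulating the
#'   single-cell table schema) and `truth` (ground-truth ledger: the design,
#'   the generating counts and per-passage parameters).
#' @export
generate_study <- function(design = study_design()) {
  stopifnot(inherits(design, "study_design"))
  set.seed(design$seed)
  recs <- list(); truths <- list()
  for (i in seq_along(design$passages)) {
    p <- design$passages[i]
    n <- design$n_per_passage[i]
    params <- degradation_params(design$alpha, design$theta,
                                 design$gamma_by_passage[i])
    counts <- sample_counts(params, n)
    fl <- counts * design$fluorescence_unit +
      stats::runif(n, 0, design$fluorescence_unit)
    exps <- design$experiments_by_passage[[i]]
    recs[[i]] <- data.frame(
      nucleus_size = stats::rlnorm(n, design$nucleus_meanlog,
                                   design$nucleus_sdlog),
      fluorescence = fl,
      passage = rep(p, n),
      experiment = rep_len(exps, n),
      stringsAsFactors = FALSE)
    truths[[i]] <- data.frame(passage = rep(p, n), count = counts)
  }
  records <- do.call(rbind, recs)
  class(records) <- c("cell_records", "data.frame")
  truth_counts <- do.call(rbind, truths)
  list(records = records,
       truth = list(design = design, counts = truth_counts,
                    max_count = max(truth_counts$count)))
}

#' Write a synthetic study to disk
#'
#' Writes the single-cell table (CSV or TSV, four-column schema) and, if
#' `truth_path` is given, the ground-truth ledger as JSON.
#'
#' @param study A [generate_study()] result.
#' @param path Output path for the cell table.
#' @param dialect `"csv"` or `"tsv"`.
#' @param truth_path Optional path for the ground-truth JSON.
#' @return `path`, invisibly.
#' @export
write_study <- function(study, path, dialect = c("csv", "tsv"),
                        truth_path = NULL) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  utils::write.table(as.data.frame(study$records), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  if (!is.null(truth_path)) {
    d <- study$truth$design
    jsonlite::write_json(
      list(alpha = d$alpha, theta = d$theta,
           passages = d$passages,
           gamma_by_passage = d$gamma_by_passage,
           n_per_passage = d$n_per_passage,
           fluorescence_unit = d$fluorescence_unit,
           seed = d$seed,
           max_count = study$truth$max_count,
           counts = study$truth$counts),
      truth_path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  invisible(path)
}
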