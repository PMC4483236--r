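# nucdeg

Stochastic modelling of nuclear protein content under cooperative active
degradation, with a full inference pipeline for passage-resolved
single-cell fluorescence data.

## The problem

Cultured fibroblasts accumulate nuclear protein as they approach
replicative senescence.  `nucdeg` asks *why* the single-cell distribution
of nuclear protein changes shape across passages, by modelling the
per-cell protein count as a birth–death Markov chain: constant production
(rate `γ`, normalized to the maximal degradation velocity) balanced
against active, enzyme-mediated degradation with Hill kinetics
(rate `n^α / (θ^α + n^α)` for a cell holding `n` units).  The stationary
law follows from detailed balance,

    P(n) = P(0) · Π_{i=1..n} γ (θ^α + i^α) / i^α ,

a **generalized negative binomial** (gnb): at `α = 1`
(Michaelis–Menten degradation) it reduces to the classic negative
binomial with `P(0) = (1 − γ)^(θ+1)`; for real `α` it is evaluated by a
log-space recurrence on the truncated support `[0, 1000]`.  Three
interpretable parameters result: the cooperativity `α`, the
half-saturation threshold `θ`, and the production/degradation balance
`γ ∈ (0,1)` — the quantity whose drift toward 1 reproduces the abrupt
rise in protein content seen in senescing cultures even though every
parameter moves smoothly.

The package is aimed at quantitative cell biologists and modellers who
have per-cell integrated fluorescence tables (cell × {nucleus size,
fluorescence, passage, replicate}) and want distribution-level inference
rather than mean comparisons.

## What it provides

* `stationary_pmf()`, `deterministic_mode()`, `centralities()` — the
  stationary law, its balance point `θ(γ/(1−γ))^(1/α)`, and
  mean/median/mode/Fano summaries; `gamma_burst_density()` is the Gamma
  burst-production null.
* `read_records()`, `scale_to_counts()`, `select_passage()` — the
  single-cell table schema and the global rescaling of fluorescence to
  integer counts on `[0, 1000]`.
* `fit_ml()`, `profile_intervals()`, `compare_families()` — maximum
  likelihood for the nb and gnb families, profile-likelihood intervals,
  and AIC/BIC/AICc differences (negative Δ favours cooperativity).
* `run_adaptive_metropolis()`, `posterior_summary()` — flat-prior
  Bayesian inference via parallel-tempered adaptive Metropolis (the
  defaults follow the 2·10⁵-step / 10⁵ burn-in / thin-10 protocol).
* `r2_statistic()`, `bootstrap_gof()`, `gof_matrix()` — parametric
  bootstrap goodness of fit (the KS test is biased when parameters are
  estimated from the tested data).
* `wls_slope_test()`, `log_odds_gamma()`, `centrality_trajectory()`,
  `logistic4_fit()` — passage-trend analysis with inverse-variance
  weighting and 4-parameter logistic fits of the centrality transition.
* `generate_study()`, `ssa_stationary_sample()` — a synthetic-study
  generator emulating the single-cell table schema, and an exact
  Gillespie simulator used as an independent oracle for the analytic law.
* `run_full_analysis()` — the whole pipeline behind one seed, plus
  `scripts/run_analysis.R` as a command-line wrapper.

## Worked example

```r
library(nucdeg)

p <- degradation_params(alpha = 2, theta = 250, gamma = 0.8)
stationary_pmf(p, n_max = 1000)
#> Stationary protein-count pmf (alpha = 2, theta = 250, gamma = 0.8)
#>   support 0..1000, truncation tail mass 4.7e-25
#>   mean 502.75, median 502, mode 500, Fano factor 2.516

counts <- sample_counts(p, n = 700, seed = 7)
fit_ml(counts, "gnb")
#> GNB maximum-likelihood fit (n = 700)
#>   alpha = 2.794, theta = 271.1, gamma = 0.8469
#>   logLik = -3470.068, AIC = 6946.14, BIC = 6959.79, AICc = 6946.17
```

The fitted triple differs from the generating one — the three parameters
trade off along a likelihood ridge — but the implied distribution is
nearly identical and the profile/credible intervals cover the truth;
see the vignette for why interval estimates, not point estimates, are
the meaningful output at this sample size.

A full synthetic study (six passages with the realistic per-passage cell
numbers, constant `α`, `θ`, and `γ` ramping in log-odds) runs end to end
as:

```r
study  <- generate_study(study_design(seed = 1))
report <- run_full_analysis(study$records, seed = 1, profile = "fast")
report
```

The printed report contains the per-passage ΔAIC/ΔBIC table (strongly
negative at the large low-`γ` passages, where cooperativity is
identifiable), the GoF p-value matrix, and the weighted trend tests —
flagging only `γ`'s log-odds trajectory as significantly drifting, the
model's signature of senescence-associated degradation decline.

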