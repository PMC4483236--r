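#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Exact Gillespie simulation of the birth-death chain with constant
// production (rate gamma * rate_scale) and Hill degradation
// (rate rate_scale * n^alpha / (theta^alpha + n^alpha)).  Returns the
// time-weighted occupancy of each state over (t_burn, t_total], which
// estimates the stationary distribution without holding-time bias.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector ssa_occupancy_cpp(double alpha, double theta, double gamma,
                                double rate_scale, double t_burn,
                                double t_total, int n0, int n_cap) {
  if (t_burn >= t_total) stop("t_burn must be smaller than t_total");
  if (n_cap < 1) stop("n_cap must be positive");

  // precomputed degradation rates for states 0..n_cap
  std::vector<double> death(n_cap + 1);
  const double th_a = std::pow(theta, alpha);
  death[0] = 0.0;
  for (int n = 1; n <= n_cap; ++n) {
    const double na = std::pow((double)n, alpha);
    death[n] = rate_scale * na / (th_a + na);
  }
  const double birth = rate_scale * gamma;

  NumericVector occ(n_cap + 1);
  double t = 0.0;
  int n = n0 < 0 ? 0 : (n0 > n_cap ? n_cap : n0);

  RNGScope scope;
  while (t < t_total) {
    const double total = birth + death[n];
    const double dt = R::exp_rand() / total;
    double t_next = t + dt;
    if (t_next > t_total) t_next = t_total;
    // accumulate occupancy only inside the observation window
    const double a = t > t_burn ? t : t_burn;
    if (t_next > a) occ[n] += t_next - a;
    t += dt;
    if (t >= t_total) break;
    if (unif_rand() * total < birth) {
      if (n < n_cap) ++n;  // reflecting cap, far above any mass in practice
    } else {
      if (n > 0) --n;
    }
  }

  const double window = t_total - t_burn;
  for (int i = 0; i <= n_cap; ++i) occ[i] /= window;
  return occ;
}

// Log-likelihood of tabulated counts under the stationary law, computed by
// the same log-space recurrence as stationary_pmf() but without building
// the R-side object; hot path for the MCMC sampler and bootstrap refits.
// Returns -Inf when parameters are invalid or the truncation tail mass
// exceeds 1e-3 (mirroring the R-side truncation error).
// [[Rcpp::export]]
double gnb_loglik_cpp(const IntegerVector& tab, double alpha, double theta,
                      double gamma) {
  const int n_max = tab.size() - 1;
  if (alpha <= 0 || theta <= 0 || gamma <= 0 || gamma >= 1 || n_max < 1)
    return R_NegInf;

  std::vector<double> lw(n_max + 1);
  lw[0] = 0.0;
  const double lg = std::log(gamma), lth = std::log(theta);
  double acc = 0.0, m = 0.0;
  for (int i = 1; i <= n_max; ++i) {
    acc += std::log1p(std::exp(alpha * (lth - std::log((double)i))));
    lw[i] = i * lg + acc;
    if (lw[i] > m) m = lw[i];
  }
  double z = 0.0;
  for (int i = 0; i <= n_max; ++i) z += std::exp(lw[i] - m);
  const double lz = m + std::log(z);

  const double rho = gamma *
    (1.0 + std::exp(alpha * (lth - std::log((double)(n_max + 1)))));
  if (rho >= 1.0) return R_NegInf;
  const double tail = std::exp(lw[n_max] - lz) * rho / (1.0 - rho);
  if (tail > 1e-3) return R_NegInf;

  double ll = 0.0;
  for (int i = 0; i <= n_max; ++i)
    if (tab[i] > 0) ll += tab[i] * (lw[i] - lz);
  return ll;
}

// Parallel-tempered adaptive Metropolis on u = (log alpha, log theta,
// logit gamma) with the Jacobian correction.  Each temperature level runs
// the same adaptive kernel (covariance from the recent half of its burn-in
// history, scalar step-size tuned toward 23.4% acceptance, both frozen
// after burn-in); adjacent levels attempt state swaps every swap_interval
// steps.  Tempering flattens the curved likelihood ridge that traps a
// single locally adapted random walk, while the retained cold chain still
// targets the exact flat-prior posterior.  `jumps` holds optional
// mode-displacement rows in u space proposed symmetrically (u +/- jump_k).
// Uses R's RNG so chains are reproducible under set.seed().
// [[Rcpp::export]]
List am_chain_cpp(const IntegerVector& tab, NumericVector init_u, int steps,
                  int burn_in, int thin, int adapt_interval, double scale,
                  double alpha_max, double theta_max, NumericMatrix jumps,
                  int n_temps, double temp_max, int swap_interval) {
  const int d = 3;
  const int K = n_temps < 1 ? 1 : n_temps;
  const int n_jumps = jumps.nrow();

  std::vector<double> beta(K);      // inverse temperatures, beta[0] = 1
  for (int k = 0; k < K; ++k)
    beta[k] = K == 1 ? 1.0 : std::pow(temp_max, -(double)k / (K - 1));

  auto loglik = [&](const double* par) {
    if (par[0] > alpha_max || par[1] > theta_max) return R_NegInf;
    return gnb_loglik_cpp(tab, par[0], par[1], par[2]);
  };
  auto natural = [&](const std::vector<double>& u, double* par) {
    par[0] = std::exp(u[0]);
    par[1] = std::exp(u[1]);
    par[2] = 1.0 / (1.0 + std::exp(-u[2]));
  };

  // per-level state
  std::vector<std::vector<double>> cur_u(K,
      std::vector<double>(init_u.begin(), init_u.end()));
  std::vector<double> lp(K), ll(K);
  std::vector<std::vector<double>> L(K, std::vector<double>(d * d, 0.0));
  std::vector<double> log_lambda(K, 0.0);
  std::vector<int> acc_window(K, 0), loc_window(K, 0);
  std::vector<std::vector<double>> history(K,
      std::vector<double>((size_t)burn_in * d));
  int n_adapt = 0, accepted_post = 0;

  {
    double par[3];
    natural(cur_u[0], par);
    const double l0 = loglik(par);
    if (!R_finite(l0)) stop("initial point has zero posterior density");
    const double lp0 = l0 + cur_u[0][0] + cur_u[0][1] +
      std::log(par[2] * (1.0 - par[2]));
    for (int k = 0; k < K; ++k) {
      ll[k] = l0; lp[k] = lp0;
      L[k][0] = L[k][4] = L[k][8] = 0.1;
    }
  }

  const int n_keep = (steps - burn_in) / thin;
  NumericMatrix samples(n_keep, d);
  NumericVector lls(n_keep);
  int kept = 0;

  RNGScope scope;
  std::vector<double> prop_u(d);
  for (int s = 1; s <= steps; ++s) {
    for (int k = 0; k < K; ++k) {
      const bool jump = n_jumps > 0 && unif_rand() < 0.05;
      if (jump) {
        const int j = std::min((int)(unif_rand() * n_jumps), n_jumps - 1);
        const double sign = unif_rand() < 0.5 ? 1.0 : -1.0;
        for (int c = 0; c < d; ++c) prop_u[c] = cur_u[k][c] + sign * jumps(j, c);
      } else {
        double z[3] = {norm_rand(), norm_rand(), norm_rand()};
        // small-world mixture: occasional 10x-amplified step along the
        // adapted directions widens each level's reach on the ridge
        const bool wide = unif_rand() < 0.10;
        const double lam = std::exp(log_lambda[k]) * (wide ? 10.0 : 1.0);
        const std::vector<double>& Lk = L[k];
        prop_u[0] = cur_u[k][0] + lam * (Lk[0] * z[0]);
        prop_u[1] = cur_u[k][1] + lam * (Lk[1] * z[0] + Lk[4] * z[1]);
        prop_u[2] = cur_u[k][2] + lam * (Lk[2] * z[0] + Lk[5] * z[1] + Lk[8] * z[2]);
        if (s <= burn_in) ++loc_window[k];
      }

      double prop_par[3];
      natural(prop_u, prop_par);
      const double ll_prop = loglik(prop_par);
      const double u_mh = unif_rand();
      if (R_finite(ll_prop)) {
        const double lp_prop = ll_prop + prop_u[0] + prop_u[1] +
          std::log(prop_par[2] * (1.0 - prop_par[2]));
        if (std::log(u_mh) < beta[k] * (lp_prop - lp[k])) {
          cur_u[k] = prop_u;
          ll[k] = ll_prop; lp[k] = lp_prop;
          if (k == 0) {
            if (s > burn_in) ++accepted_post;
            else if (!jump) ++acc_window[0];
          } else if (s <= burn_in && !jump) {
            ++acc_window[k];
          }
        }
      }
    }

    // replica exchange between a random adjacent pair
    if (K > 1 && s % swap_interval == 0) {
      const int i = std::min((int)(unif_rand() * (K - 1)), K - 2);
      const double u_sw = unif_rand();
      const double log_acc = (beta[i] - beta[i + 1]) * (lp[i + 1] - lp[i]);
      if (std::log(u_sw) < log_acc) {
        std::swap(cur_u[i], cur_u[i + 1]);
        std::swap(lp[i], lp[i + 1]);
        std::swap(ll[i], ll[i + 1]);
      }
    }

    if (s <= burn_in) {
      for (int k = 0; k < K; ++k)
        for (int j = 0; j < d; ++j)
          history[k][(size_t)(s - 1) * d + j] = cur_u[k][j];
      if (s % adapt_interval == 0) {
        ++n_adapt;
        for (int k = 0; k < K; ++k) {
          if (s >= 200) {
            const int lo = s / 2 - 1, n = s - lo;
            double mean[3] = {0, 0, 0};
            for (int i = lo; i < s; ++i)
              for (int j = 0; j < d; ++j)
                mean[j] += history[k][(size_t)i * d + j];
            for (int j = 0; j < d; ++j) mean[j] /= n;
            double C[9] = {0};
            for (int i = lo; i < s; ++i)
              for (int j = 0; j < d; ++j)
                for (int c = j; c < d; ++c)
                  C[j * d + c] += (history[k][(size_t)i * d + j] - mean[j]) *
                                  (history[k][(size_t)i * d + c] - mean[c]);
            for (int j = 0; j < d; ++j)
              for (int c = j; c < d; ++c) {
                C[j * d + c] = scale * C[j * d + c] / (n - 1);
                C[c * d + j] = C[j * d + c];
              }
            for (int j = 0; j < d; ++j) C[j * d + j] += 1e-10;
            double U[9] = {0};
            bool ok = true;
            for (int j = 0; j < d && ok; ++j) {
              double sum = C[j * d + j];
              for (int i = 0; i < j; ++i) sum -= U[i * d + j] * U[i * d + j];
              if (sum <= 0) { ok = false; break; }
              U[j * d + j] = std::sqrt(sum);
              for (int c = j + 1; c < d; ++c) {
                double s2 = C[j * d + c];
                for (int i = 0; i < j; ++i) s2 -= U[i * d + j] * U[i * d + c];
                U[j * d + c] = s2 / U[j * d + j];
              }
            }
            if (ok) std::copy(U, U + 9, L[k].begin());
          }
          if (loc_window[k] > 0)
            log_lambda[k] += ((double)acc_window[k] / loc_window[k] - 0.234) /
              std::sqrt((double)n_adapt);
          acc_window[k] = 0; loc_window[k] = 0;
        }
      }
    } else if ((s - burn_in) % thin == 0) {
      double par[3];
      natural(cur_u[0], par);
      samples(kept, 0) = par[0];
      samples(kept, 1) = par[1];
      samples(kept, 2) = par[2];
      lls[kept] = ll[0];
      ++kept;
    }
  }

  return List::create(
    _["samples"] = samples, _["log_likelihoods"] = lls,
    _["acceptance_rate"] = (double)accepted_post / (steps - burn_in));
}
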