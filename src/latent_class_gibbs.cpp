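#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Collapsed Gibbs sampler for a finite mixture of per-locus Bernoulli
// components over binary band profiles. Beta(a, b) priors on the per-locus
// presence probabilities, symmetric Dirichlet(conc) on the mixture weights.
// Uses R's RNG so set.seed() on the R side makes runs reproducible.
//
// Returned Q accumulates posterior assignment frequencies after burn-in,
// with label switching handled by greedily matching each recorded
// iteration's component frequency vectors (posterior means) to those of the
// first recorded iteration. The returned loglik is the mean post-burn-in
// log-likelihood of the data under component frequencies *sampled* from
// their Beta full conditionals — the Structure-style model log-likelihood
// whose run-to-run dispersion the Evanno delta-K statistic divides by.

// Greedy one-to-one matching of current theta rows to reference rows by
// squared distance; perm[current label] = reference label.
static void greedy_match(const std::vector<double> &theta,
                         const std::vector<double> &ref,
                         int K, int L, std::vector<int> &perm) {
  std::vector<bool> used_cur(K, false), used_ref(K, false);
  for (int step = 0; step < K; ++step) {
    double best = R_PosInf;
    int bi = -1, bj = -1;
    for (int i = 0; i < K; ++i) {
      if (used_cur[i]) continue;
      for (int j = 0; j < K; ++j) {
        if (used_ref[j]) continue;
        double s = 0.0;
        for (int l = 0; l < L; ++l) {
          double dd = theta[i * L + l] - ref[j * L + l];
          s += dd * dd;
        }
        if (s < best) { best = s; bi = i; bj = j; }
      }
    }
    used_cur[bi] = true;
    used_ref[bj] = true;
    perm[bi] = bj;
  }
}

struct GibbsState {
  std::vector<int> z, nk;
  std::vector<double> C;
};

// One full sweep of single-site assignment updates at inverse temperature
// beta (beta < 1 flattens the conditional during burn-in annealing).
static void gibbs_sweep(const IntegerMatrix &x, int K, GibbsState &st,
                        double prior_a, double prior_b, double prior_conc,
                        double beta, std::vector<double> &logp) {
  const int N = x.nrow(), L = x.ncol();
  for (int i = 0; i < N; ++i) {
    int k0 = st.z[i];
    st.nk[k0]--;
    for (int l = 0; l < L; ++l) st.C[k0 * L + l] -= x(i, l);
    double mx = R_NegInf;
    for (int k = 0; k < K; ++k) {
      double lp = std::log(st.nk[k] + prior_conc) -
                  L * std::log(prior_a + prior_b + st.nk[k]);
      const double *Ck = &st.C[k * L];
      for (int l = 0; l < L; ++l) {
        lp += x(i, l) ? std::log(prior_a + Ck[l])
                      : std::log(prior_b + st.nk[k] - Ck[l]);
      }
      lp *= beta;
      logp[k] = lp;
      if (lp > mx) mx = lp;
    }
    double tot = 0.0;
    for (int k = 0; k < K; ++k) {
      logp[k] = std::exp(logp[k] - mx);
      tot += logp[k];
    }
    double u = unif_rand() * tot, cum = 0.0;
    int knew = K - 1;
    for (int k = 0; k < K; ++k) {
      cum += logp[k];
      if (u <= cum) { knew = k; break; }
    }
    st.z[i] = knew;
    st.nk[knew]++;
    for (int l = 0; l < L; ++l) st.C[knew * L + l] += x(i, l);
  }
}

static GibbsState random_init(const IntegerMatrix &x, int K) {
  const int N = x.nrow(), L = x.ncol();
  GibbsState st;
  st.z.resize(N);
  st.nk.assign(K, 0);
  st.C.assign(K * L, 0.0);
  for (int i = 0; i < N; ++i) {
    int k = (int)(unif_rand() * K);
    if (k >= K) k = K - 1;
    st.z[i] = k;
    st.nk[k]++;
    for (int l = 0; l < L; ++l) st.C[k * L + l] += x(i, l);
  }
  return st;
}

// Data log-likelihood under the posterior-mean component frequencies given
// the current assignment; used to pick the best burn-in restart.
static double state_loglik(const IntegerMatrix &x, int K, const GibbsState &st,
                           double prior_a, double prior_b) {
  const int N = x.nrow(), L = x.ncol();
  double ll = 0.0;
  for (int i = 0; i < N; ++i) {
    int k = st.z[i];
    for (int l = 0; l < L; ++l) {
      double t = (st.C[k * L + l] + prior_a) / (st.nk[k] + prior_a + prior_b);
      ll += x(i, l) ? std::log(t) : std::log(1.0 - t);
    }
  }
  return ll;
}

// [[Rcpp::export]]
List gibbs_latent_class(IntegerMatrix x, int K, int n_iter, int burn_in,
                        double prior_a, double prior_b, double prior_conc,
                        int n_restarts, double anneal_start) {
  const int N = x.nrow(), L = x.ncol();
  if (K < 1) stop("K must be >= 1");
  if (K > N) stop("K exceeds the number of samples");
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter");
  if (n_restarts < 1) stop("n_restarts must be >= 1");

  std::vector<double> logp(K);

  // Burn-in with restart selection: each restart runs its own annealed
  // burn-in (inverse temperature ramped from anneal_start to 1); the
  // restart ending with the highest posterior-mean log-likelihood is
  // continued through the recording phase.
  GibbsState best;
  double best_ll = R_NegInf;
  for (int r = 0; r < n_restarts; ++r) {
    GibbsState st = random_init(x, K);
    for (int it = 0; it < burn_in; ++it) {
      double beta = anneal_start +
        (1.0 - anneal_start) * (burn_in > 1 ? (double)it / (burn_in - 1) : 1.0);
      gibbs_sweep(x, K, st, prior_a, prior_b, prior_conc, beta, logp);
    }
    double ll = state_loglik(x, K, st, prior_a, prior_b);
    if (ll > best_ll) { best_ll = ll; best = st; }
  }
  GibbsState st = best;

  NumericMatrix Q(N, K);
  std::vector<double> theta(K * L), theta_ref(K * L);
  std::vector<int> perm(K);
  bool have_ref = false;
  double loglik_sum = 0.0;
  int n_rec = 0;

  for (int it = burn_in; it < n_iter; ++it) {
    gibbs_sweep(x, K, st, prior_a, prior_b, prior_conc, 1.0, logp);
    {
      std::vector<int> &z = st.z;
      std::vector<int> &nk = st.nk;
      std::vector<double> &C = st.C;
      for (int k = 0; k < K; ++k)
        for (int l = 0; l < L; ++l)
          theta[k * L + l] = (C[k * L + l] + prior_a) /
                             (nk[k] + prior_a + prior_b);
      if (!have_ref) {
        theta_ref = theta;
        have_ref = true;
        for (int k = 0; k < K; ++k) perm[k] = k;
      } else {
        greedy_match(theta, theta_ref, K, L, perm);
      }
      for (int i = 0; i < N; ++i) Q(i, perm[z[i]]) += 1.0;
      // sample component frequencies from their Beta full conditionals and
      // score the data under them
      std::vector<double> theta_s(K * L);
      for (int k = 0; k < K; ++k)
        for (int l = 0; l < L; ++l)
          theta_s[k * L + l] = R::rbeta(prior_a + C[k * L + l],
                                        prior_b + nk[k] - C[k * L + l]);
      double ll = 0.0;
      for (int i = 0; i < N; ++i) {
        const double *tz = &theta_s[z[i] * L];
        for (int l = 0; l < L; ++l) {
          ll += x(i, l) ? std::log(tz[l]) : std::log(1.0 - tz[l]);
        }
      }
      loglik_sum += ll;
      n_rec++;
    }
  }

  for (int i = 0; i < N; ++i)
    for (int k = 0; k < K; ++k) Q(i, k) /= n_rec;

  return List::create(_["Q"] = Q,
                      _["loglik"] = loglik_sum / n_rec,
                      _["z_last"] = wrap(st.z),
                      _["n_recorded"] = n_rec);
}
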