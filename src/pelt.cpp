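#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Bernoulli maximum-log-likelihood cost of a segment with n sites of which
// s1 carry code 1: -(s1*log(p) + s0*log(1-p)) at p = s1/n, with 0*log(0) = 0.
static inline double seg_cost(int n, int s1) {
  if (n <= 0) return 0.0;
  int s0 = n - s1;
  double c = 0.0;
  if (s1 > 0) c -= s1 * std::log((double)s1 / n);
  if (s0 > 0) c -= s0 * std::log((double)s0 / n);
  return c;
}

// Exact optimal partitioning of a binary series under penalized Bernoulli
// likelihood (PELT pruning; exact because adding a changepoint never
// increases the unpenalized cost). Returns 1-based indices i such that a
// changepoint lies between positions i and i+1.
// [[Rcpp::export(name = ".pelt_binary")]]
IntegerVector pelt_binary(IntegerVector x, double penalty) {
  int n = x.size();
  if (n < 2) return IntegerVector(0);

  std::vector<int> cs(n + 1, 0);
  for (int i = 0; i < n; ++i) cs[i + 1] = cs[i] + (x[i] ? 1 : 0);

  std::vector<double> F(n + 1);
  std::vector<int> last(n + 1, 0);
  F[0] = -penalty;
  std::vector<int> cand;
  cand.push_back(0);

  for (int t = 1; t <= n; ++t) {
    double best = R_PosInf;
    int best_tau = 0;
    std::vector<double> val(cand.size());
    for (size_t j = 0; j < cand.size(); ++j) {
      int tau = cand[j];
      double v = F[tau] + seg_cost(t - tau, cs[t] - cs[tau]) + penalty;
      val[j] = v;
      if (v < best) { best = v; best_tau = tau; }
    }
    F[t] = best;
    last[t] = best_tau;
    // prune: tau stays a candidate if F(tau) + C(tau..t) <= F(t)
    std::vector<int> keep;
    for (size_t j = 0; j < cand.size(); ++j) {
      int tau = cand[j];
      if (F[tau] + seg_cost(t - tau, cs[t] - cs[tau]) <= F[t]) keep.push_back(tau);
    }
    keep.push_back(t);
    cand = keep;
  }

  std::vector<int> cps;
  int t = n;
  while (t > 0) {
    int tau = last[t];
    if (tau > 0) cps.push_back(tau);
    t = tau;
  }
  IntegerVector out(cps.rbegin(), cps.rend());
  return out;
}
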