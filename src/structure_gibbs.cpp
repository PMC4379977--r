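// Gibbs sampler for the no-admixture clustering model on dominant
// (presence/absence) loci.
//
// Model: each individual i carries one latent cluster z_i (uniform prior);
// band frequency p[k][l] ~ Beta(lambda, lambda).  Sweep:
//   (a) p[k][l] | z  ~ Beta(lambda + n1, lambda + n0)
//   (b) z_i | p      ~ Categorical( prod_l p^x (1-p)^(1-x) ), missing skipped
// Ln P(D) is estimated downstream as mean(lnL) - var(lnL)/2 over
// post-burn-in sweeps (the STRUCTURE approximation).  Label switching is
// resolved per sweep by canonical relabelling (clusters ordered by the
// index of their first member) before accumulating membership counts.
//
// All randomness is drawn from R's RNG stream (unif_rand/norm_rand), so
// results are reproducible under set.seed().  Beta variates come from two
// Marsaglia-Tsang gamma draws, which is considerably faster than the
// generic beta generator for the shapes arising here.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Rng {
  // Marsaglia polar normal with spare caching, on top of unif_rand()
  bool has_spare = false;
  double spare = 0.0;
  double normal() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, s;
    do {
      u = 2.0 * unif_rand() - 1.0;
      v = 2.0 * unif_rand() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    const double f = std::sqrt(-2.0 * std::log(s) / s);
    spare = v * f; has_spare = true;
    return u * f;
  }
  // Marsaglia-Tsang, shape >= 1 fast path; shape < 1 via boosting
  double gamma(double shape) {
    if (shape < 1.0) {
      const double u = unif_rand();
      return gamma(shape + 1.0) * std::pow(u, 1.0 / shape);
    }
    const double d = shape - 1.0 / 3.0;
    const double c = 1.0 / std::sqrt(9.0 * d);
    for (;;) {
      double x, v;
      do { x = normal(); v = 1.0 + c * x; } while (v <= 0.0);
      v = v * v * v;
      const double u = unif_rand();
      const double x2 = x * x;
      if (u < 1.0 - 0.0331 * x2 * x2) return d * v;
      if (std::log(u) < 0.5 * x2 + d * (1.0 - v + std::log(v))) return d * v;
    }
  }
  double beta(double a, double b) {
    const double g1 = gamma(a);
    const double g2 = gamma(b);
    return g1 / (g1 + g2);
  }
};

}  // namespace

// [[Rcpp::export]]
List structure_gibbs_cpp(IntegerMatrix X, int K, int burnin, int reps,
                         double lambda, IntegerVector z_init) {
  const int n = X.nrow(), L = X.ncol();
  Rng rng;

  // sparse representation: indices of 1-loci and missing loci per individual
  std::vector<std::vector<int>> ones(n), nas(n);
  for (int i = 0; i < n; ++i)
    for (int l = 0; l < L; ++l) {
      const int v = X(i, l);
      if (v == NA_INTEGER) nas[i].push_back(l);
      else if (v == 1) ones[i].push_back(l);
    }

  std::vector<int> z(n);
  for (int i = 0; i < n; ++i)
    z[i] = (z_init[i] - 1) % K;  // 1-based cluster labels from R

  std::vector<double> lp(K * L), l1p(K * L), dl(K * L), rowsum(K);
  std::vector<int> n1(K * L), n0(K * L);
  std::vector<double> qcount(n * K, 0.0);
  std::vector<int> first_seen(K);
  NumericVector trace(reps);
  std::vector<double> logq(K);

  const int total = burnin + reps;
  for (int sweep = 0; sweep < total; ++sweep) {
    // (a) p | z, with log / log1m / difference tables for the z step
    std::fill(n1.begin(), n1.end(), 0);
    std::fill(n0.begin(), n0.end(), 0);
    for (int i = 0; i < n; ++i) {
      const int base = z[i] * L;
      for (int l : ones[i]) ++n1[base + l];
    }
    // n0 = members(k) - n1 - missing(k)
    std::vector<int> members(K, 0);
    for (int i = 0; i < n; ++i) ++members[z[i]];
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l) n0[k * L + l] = members[k];
    for (int i = 0; i < n; ++i) {
      const int base = z[i] * L;
      for (int l : ones[i]) --n0[base + l];
      for (int l : nas[i]) --n0[base + l];
    }
    for (int k = 0; k < K; ++k) {
      double rs = 0.0;
      for (int l = 0; l < L; ++l) {
        double pv = rng.beta(lambda + n1[k * L + l], lambda + n0[k * L + l]);
        if (pv < 1e-12) pv = 1e-12;
        if (pv > 1.0 - 1e-12) pv = 1.0 - 1e-12;
        const double a = std::log(pv), b = std::log(1.0 - pv);
        lp[k * L + l] = a;
        l1p[k * L + l] = b;
        dl[k * L + l] = a - b;
        rs += b;
      }
      rowsum[k] = rs;
    }

    // (b) z | p, accumulating the data log-likelihood of the drawn z
    double lnl = 0.0;
    std::vector<double> logs(K);
    for (int i = 0; i < n; ++i) {
      double mx = -1e300;
      for (int k = 0; k < K; ++k) {
        const int base = k * L;
        double s = rowsum[k];
        for (int l : ones[i]) s += dl[base + l];
        for (int l : nas[i]) s -= l1p[base + l];
        logs[k] = s;
        if (s > mx) mx = s;
      }
      int zi = 0;
      if (K > 1) {
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          logq[k] = std::exp(logs[k] - mx);
          tot += logq[k];
        }
        const double u = unif_rand() * tot;
        double c = 0.0;
        zi = K - 1;
        for (int k = 0; k < K; ++k) {
          c += logq[k];
          if (u <= c) { zi = k; break; }
        }
        z[i] = zi;
      }
      lnl += logs[zi];
    }

    if (sweep >= burnin) {
      std::fill(first_seen.begin(), first_seen.end(), -1);
      int next = 0;
      for (int i = 0; i < n && next < K; ++i)
        if (first_seen[z[i]] < 0) first_seen[z[i]] = next++;
      for (int k = 0; k < K; ++k)
        if (first_seen[k] < 0) first_seen[k] = next++;
      for (int i = 0; i < n; ++i)
        qcount[i * K + first_seen[z[i]]] += 1.0;
      trace[sweep - burnin] = lnl;
    }
  }

  NumericMatrix q(n, K);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k)
      q(i, k) = qcount[i * K + k] / reps;
  return List::create(_["q"] = q, _["trace"] = trace);
}
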