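#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Best circular split of z into an arc [i, j) and its complement,
// maximizing the absolute pooled-variance two-sample t statistic.
// Every circular two-arc partition is represented by a contiguous arc,
// so scanning 0 <= i < j <= n covers the circle. Both parts must hold at
// least min_seg bins when n >= 2*min_seg (else at least 1).
// Degenerate pooled variance (all values equal within a part split that
// leaves zero within-variance): statistic is 0 if the means agree,
// +Inf otherwise.
static void best_split_core(const double *z, int n, int min_seg,
                            int &bi, int &bj, double &bstat) {
  bi = -1; bj = -1; bstat = 0.0;
  if (n < 2) return;
  std::vector<double> S(n + 1), Q(n + 1);
  S[0] = 0.0; Q[0] = 0.0;
  for (int t = 0; t < n; ++t) {
    S[t + 1] = S[t] + z[t];
    Q[t + 1] = Q[t] + z[t] * z[t];
  }
  const double St = S[n], Qt = Q[n];
  int m = (n >= 2 * min_seg) ? min_seg : 1;
  if (m < 1) m = 1;
  const double tiny = 1e-12;
  for (int i = 0; i <= n - m; ++i) {
    int jlo = i + m;                       // arc holds at least m bins
    int jhi = std::min(n, i + (n - m));    // complement holds at least m
    for (int j = jlo; j <= jhi; ++j) {
      int na = j - i, nb = n - na;
      double Sa = S[j] - S[i], Qa = Q[j] - Q[i];
      double Sb = St - Sa, Qb = Qt - Qa;
      double diff = Sa / na - Sb / nb;
      double ssw = (Qa - Sa * Sa / na) + (Qb - Sb * Sb / nb);
      if (ssw < 0) ssw = 0;
      double stat;
      if (n - 2 <= 0 || ssw <= tiny * (std::abs(Qt) + 1.0)) {
        stat = (std::abs(diff) <= 1e-12) ? 0.0
             : std::numeric_limits<double>::infinity();
      } else {
        double sp2 = ssw / (n - 2);
        stat = std::abs(diff) / std::sqrt(sp2 * (1.0 / na + 1.0 / nb));
      }
      if (stat > bstat) { bstat = stat; bi = i; bj = j; }
    }
  }
}

// [[Rcpp::export]]
List cbs_best_split_cpp(NumericVector z, int min_seg) {
  int bi, bj; double bstat;
  best_split_core(REAL(z), z.size(), min_seg, bi, bj, bstat);
  return List::create(_["i"] = bi, _["j"] = bj, _["statistic"] = bstat);
}

// Permutation reference distribution for the best-split statistic.
// Counts whole-vector shuffles whose best statistic reaches the observed
// one; p = (1 + count) / (1 + n_perm). With early_stop, permutation stops
// as soon as the count already forces p >= alpha at the configured
// n_perm (the accept/reject decision is then identical to the full run);
// the returned p is (1 + count) / (1 + n_done), a lower bound on the
// full-run p that is itself >= alpha at the stopping point.
// [[Rcpp::export]]
List cbs_perm_pvalue_cpp(NumericVector z, double observed, int n_perm,
                         int min_seg, int seed, double alpha,
                         bool early_stop) {
  int n = z.size();
  std::vector<double> w(REAL(z), REAL(z) + n);
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  int count = 0, done = 0;
  // acceptance needs (1 + count) < alpha * (1 + n_perm)
  double accept_bound = alpha * (1.0 + n_perm);
  for (int p = 0; p < n_perm; ++p) {
    for (int t = n - 1; t > 0; --t) {
      std::uniform_int_distribution<int> d(0, t);
      int u = d(rng);
      std::swap(w[t], w[u]);
    }
    int bi, bj; double bstat;
    best_split_core(w.data(), n, min_seg, bi, bj, bstat);
    if (bstat >= observed) ++count;
    ++done;
    if (early_stop && (1.0 + count) >= accept_bound) break;
  }
  double pval = (1.0 + count) / (1.0 + (early_stop ? done : n_perm));
  return List::create(_["p"] = pval, _["count"] = count,
                      _["n_done"] = done);
}
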