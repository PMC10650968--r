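// Exact permutation distribution of the Spearman statistic for small n.
// With the rank vectors fixed, rho is a monotone function of
// S = sum_i rx[i] * ry[perm[i]], so the two-sided p-value is the fraction of
// the n! permutations with |S - c| >= |S_obs - c|, where c = n * mean(rx) *
// mean(ry) centers the statistic.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
double spearman_exact_p_cpp(NumericVector rx, NumericVector ry) {
  const int n = rx.size();
  if (n != ry.size()) stop("length mismatch");
  if (n < 2 || n > 10) stop("exact permutation p only for 2 <= n <= 10");
  double sx = 0, sy = 0;
  for (int i = 0; i < n; ++i) { sx += rx[i]; sy += ry[i]; }
  const double c = sx * sy / n;
  double s_obs = 0;
  for (int i = 0; i < n; ++i) s_obs += rx[i] * ry[i];
  const double thr = std::fabs(s_obs - c) - 1e-9;

  std::vector<double> y(ry.begin(), ry.end());
  std::vector<int> ctr(n, 0);
  long long hits = 0, total = 0;
  auto tally = [&]() {
    double s = 0;
    for (int i = 0; i < n; ++i) s += rx[i] * y[i];
    if (std::fabs(s - c) >= thr) ++hits;
    ++total;
  };
  tally();
  int i = 0;
  while (i < n) {  // Heap's algorithm, iterative form
    if (ctr[i] < i) {
      if (i % 2 == 0) std::swap(y[0], y[i]);
      else std::swap(y[ctr[i]], y[i]);
      tally();
      ++ctr[i];
      i = 0;
    } else {
      ctr[i] = 0;
      ++i;
    }
  }
  return (double)hits / (double)total;
}
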