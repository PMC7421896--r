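#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Exact two-sided permutation p-value for the Spearman correlation.
// rx, ry are (mid)rank vectors; enumerates every distinct arrangement of ry
// (next_permutation over the sorted multiset, so tied ranks are handled
// correctly with uniform weight) and counts arrangements whose |rho| is at
// least the observed |rho|. rho is monotone in S = sum(rx * ry) around its
// permutation mean, so the comparison is done on |S - E[S]|.
// [[Rcpp::export]]
double spearman_exact_p(NumericVector rx, NumericVector ry) {
  int n = rx.size();
  if (n != ry.size()) stop("rank vectors differ in length");
  if (n > 10) stop("exact permutation p only supported for n <= 10");
  double mx = mean(rx), my = mean(ry);
  double s_obs = 0.0;
  for (int i = 0; i < n; ++i) s_obs += rx[i] * ry[i];
  double center = n * mx * my;
  double t_obs = std::abs(s_obs - center) - 1e-9;

  std::vector<double> perm(ry.begin(), ry.end());
  std::sort(perm.begin(), perm.end());
  long long total = 0, hits = 0;
  do {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += rx[i] * perm[i];
    ++total;
    if (std::abs(s - center) >= t_obs) ++hits;
  } while (std::next_permutation(perm.begin(), perm.end()));
  return static_cast<double>(hits) / static_cast<double>(total);
}
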