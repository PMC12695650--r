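#include <Rcpp.h>
using namespace Rcpp;

// PELT (pruned exact linear time) multiple change-point detection for a
// multivariate mean-change model with unit-variance Gaussian cost on each
// (pre-standardized) dimension. Cost of a segment is the summed residual
// sum of squares around the segment mean, over all dimensions. The penalty
// is added once per change-point, so the number of change-points is
// non-increasing in the penalty.
//
// x: n x d matrix (columns are signal dimensions, already standardized)
// penalty: per-change-point penalty (> 0)
// returns: 1-based end indices of all segments except the last (i.e. the
// change-point positions); empty vector means a single segment.

// [[Rcpp::export(name = ".pelt_cpp")]]
IntegerVector pelt_cpp(NumericMatrix x, double penalty) {
  const int n = x.nrow();
  const int d = x.ncol();
  if (n == 0) return IntegerVector(0);

  // cumulative sums and sums of squares per dimension
  std::vector<std::vector<double> > cs(d, std::vector<double>(n + 1, 0.0));
  std::vector<std::vector<double> > css(d, std::vector<double>(n + 1, 0.0));
  for (int j = 0; j < d; ++j) {
    for (int i = 0; i < n; ++i) {
      double v = x(i, j);
      cs[j][i + 1] = cs[j][i] + v;
      css[j][i + 1] = css[j][i] + v * v;
    }
  }

  std::vector<double> F(n + 1);
  std::vector<int> prev(n + 1, 0);
  F[0] = -penalty;
  std::vector<int> cand;
  cand.push_back(0);

  for (int t = 1; t <= n; ++t) {
    double best = R_PosInf;
    int best_s = 0;
    std::vector<double> segcost(cand.size());
    for (size_t k = 0; k < cand.size(); ++k) {
      int s = cand[k];
      double cost = 0.0;
      double len = (double)(t - s);
      for (int j = 0; j < d; ++j) {
        double sum = cs[j][t] - cs[j][s];
        double ssq = css[j][t] - css[j][s];
        cost += ssq - sum * sum / len;
      }
      segcost[k] = cost;
      double tot = F[s] + cost + penalty;
      if (tot < best) { best = tot; best_s = s; }
    }
    F[t] = best;
    prev[t] = best_s;
    // prune candidates that can never be optimal again
    std::vector<int> keep;
    for (size_t k = 0; k < cand.size(); ++k) {
      if (F[cand[k]] + segcost[k] <= F[t]) keep.push_back(cand[k]);
    }
    keep.push_back(t);
    cand.swap(keep);
  }

  std::vector<int> cps;
  int t = n;
  while (t > 0) {
    int s = prev[t];
    if (s > 0) cps.push_back(s);
    t = s;
  }
  std::sort(cps.begin(), cps.end());
  return wrap(cps);
}
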