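#include <Rcpp.h>
using namespace Rcpp;

// Exact piecewise-constant-fitting segmentation by dynamic programming.
// Minimizes sum over segments of within-segment SSE plus gamma per segment,
// each segment holding at least kmin points. Tie-break: fewest segments,
// then lexicographically earliest boundaries (suffix DP keeps, per start
// index, the smallest feasible segment end among optima; reconstruction
// from the left then yields the lexicographically smallest boundary vector).
// [[Rcpp::export(name = ".pcf_dp")]]
List pcf_dp(NumericVector x, double gamma, int kmin) {
  int n = x.size();
  if (n < 1) stop("empty series");
  if (kmin < 2) stop("kmin must be >= 2");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> G(n + 1, INF);
  std::vector<int> Gn(n + 1, INT_MAX), choice(n + 1, -1);
  G[n] = 0.0; Gn[n] = 0;
  const double *xd = REAL(x);
  for (int i = n - 1; i >= 0; --i) {
    if (n - i < kmin) continue; // infeasible start
    double s = 0.0, s2 = 0.0;
    double bc = INF, tol = 0.0;
    int bn = INT_MAX, be = -1;
    for (int e = i; e < n; ++e) {
      double v = xd[e];
      s += v; s2 += v * v;
      int m = e - i + 1;
      if (m < kmin) continue;
      int tail = n - (e + 1);
      if (tail != 0 && tail < kmin) continue;
      double g1 = G[e + 1];
      if (!std::isfinite(g1)) continue;
      double c = s2 - s * s / m + gamma + g1;
      if (c < bc - tol) {
        bc = c; bn = 1 + Gn[e + 1]; be = e;
        tol = 1e-9 * (1.0 + std::fabs(bc));
      } else if (c <= bc + tol) {
        int mm = 1 + Gn[e + 1];
        if (mm < bn) { bn = mm; be = e; }
        // equal cost and equal segment count: first (earliest) e stays
      }
    }
    G[i] = bc; Gn[i] = bn; choice[i] = be;
  }
  if (!std::isfinite(G[0])) stop("series shorter than kmin");
  std::vector<int> starts, ends;
  std::vector<double> means;
  int i = 0;
  while (i < n) {
    int e = choice[i];
    double s = 0.0;
    for (int k = i; k <= e; ++k) s += xd[k];
    starts.push_back(i + 1);
    ends.push_back(e + 1);
    means.push_back(s / (e - i + 1));
    i = e + 1;
  }
  return List::create(_["start"] = wrap(starts), _["end"] = wrap(ends),
                      _["mean"] = wrap(means), _["cost"] = G[0],
                      _["n_segments"] = (int)starts.size());
}
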