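#include <Rcpp.h>
using namespace Rcpp;

// Hartigan's dip statistic: D = min over unimodal CDFs G of sup_x |F_n(x) - G(x)|.
//
// Computed by bisection on eps = sup-distance. For a candidate eps, a unimodal
// G within eps of the ECDF exists iff for some atom index k (the mode, where G
// may jump):
//   left:  a nondecreasing convex C with C(x_i) in [lo_i, hi_i] for i < k and
//          left limit at x_k not above hi_k, where hi_i = c_{i-1}/n + eps and
//          lo_i = c_i/n - eps (c_i = cumulative counts at the unique values);
//   right: mirrored with a nondecreasing concave piece.
// A convex function through vertical bands exists iff the lower convex hull of
// the upper band points stays above the lower band points (chord argument);
// monotonicity is free because the band limits are nondecreasing. Violations
// only accumulate as the prefix grows, so left-feasibility holds for all
// k <= K1 and right-feasibility for all k >= K2; eps is feasible iff K2 <= K1.

static int left_max_mode(const std::vector<double>& x,
                         const std::vector<double>& lo,
                         const std::vector<double>& hi) {
  // Largest k such that the lower hull of (x_i, hi_i), i = 0..k, lies above
  // lo_i for all i < k. Returns -1 if even k = 0 fails (cannot happen: empty).
  int m = x.size();
  std::vector<int> hull;
  for (int k = 0; k < m; ++k) {
    // incremental lower hull on the upper points
    while (hull.size() >= 2) {
      int i1 = hull[hull.size() - 2], i2 = hull[hull.size() - 1];
      if ((hi[k] - hi[i1]) * (x[i2] - x[i1]) <= (hi[i2] - hi[i1]) * (x[k] - x[i1]))
        hull.pop_back();
      else break;
    }
    hull.push_back(k);
    // prefix-hull(0..k) must be >= lo at all j < k; check every segment
    for (size_t s = 0; s + 1 < hull.size(); ++s) {
      int a = hull[s], b = hull[s + 1];
      double dx = x[b] - x[a];
      // vertex a itself
      if (a < k && lo[a] > hi[a] + 1e-14) return k - 1;
      for (int j = a + 1; j < b; ++j) {
        double hv = hi[a] + (hi[b] - hi[a]) * (x[j] - x[a]) / dx;
        if (lo[j] > hv + 1e-14) return k - 1;
      }
    }
    int last = hull[hull.size() - 1]; // == k, vertex value check when k not mode
    (void)last;
  }
  return m - 1;
}

static bool eps_feasible(const std::vector<double>& x,
                         const std::vector<double>& cprev,
                         const std::vector<double>& ccur,
                         double n, double eps) {
  int m = x.size();
  std::vector<double> lo(m), hi(m);
  for (int i = 0; i < m; ++i) {
    hi[i] = cprev[i] / n + eps;
    lo[i] = ccur[i] / n - eps;
  }
  int K1 = left_max_mode(x, lo, hi);
  if (K1 < 0) return false;
  // mirrored right pass: reverse and negate x, swap roles of the band limits
  // (upper hull of lower points vs. upper caps == lower hull after reflection).
  std::vector<double> rx(m), rlo(m), rhi(m);
  for (int i = 0; i < m; ++i) {
    rx[i] = -x[m - 1 - i];
    // reflect G -> 1 - G(-x): lower caps become upper caps
    rhi[i] = 1.0 - lo[m - 1 - i];
    rlo[i] = 1.0 - hi[m - 1 - i];
  }
  int K1r = left_max_mode(rx, rlo, rhi);
  if (K1r < 0) return false;
  int K2 = m - 1 - K1r; // smallest feasible mode index for the right piece
  return K2 <= K1;
}

// [[Rcpp::export(name = ".dip_cpp")]]
double dip_cpp(NumericVector xs, double tol = 1e-10) {
  std::vector<double> x0(xs.begin(), xs.end());
  std::sort(x0.begin(), x0.end());
  int n = x0.size();
  if (n < 2) return 0.0;
  // unique values + cumulative counts
  std::vector<double> x, cprev, ccur;
  double cum = 0;
  for (int i = 0; i < n; ) {
    int j = i;
    while (j < n && x0[j] == x0[i]) ++j;
    x.push_back(x0[i]);
    cprev.push_back(cum);
    cum += (j - i);
    ccur.push_back(cum);
    i = j;
  }
  if (x.size() == 1) return 0.0; // point mass: a degenerate unimodal CDF fits exactly
  double lo = 0.0, hi = 0.2500000001;
  for (int it = 0; it < 60 && (hi - lo) > tol; ++it) {
    double mid = 0.5 * (lo + hi);
    if (eps_feasible(x, cprev, ccur, (double)n, mid)) hi = mid; else lo = mid;
  }
  return hi;
}
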