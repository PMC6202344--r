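#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Hartigan & Hartigan's dip statistic: the maximum distance between the
// empirical CDF and the closest unimodal CDF.
//
// The computation works in "count" units.  For a sorted sample x[0..n-1]
// the empirical CDF rises from i to i+1 (times 1/n) at x[i].  Any convex
// minorant of the ecdf must pass through or below the points (x[i], i)
// (pre-jump counts); any concave majorant through or above (x[i], i+1)
// (post-jump counts).  A unimodal CDF is convex left of its mode and
// concave right of it, with a free jump at the mode, so the deviation any
// unimodal fit must make from the ecdf decomposes into: the deviation of
// the ecdf above the greatest convex minorant (gcm) left of the modal
// interval, the deviation below the least concave majorant (lcm) right of
// it, and the residual gap between the two hulls inside it.  The modal
// interval [low, high] is shrunk iteratively to where the hull gap is
// widest, accumulating the one-sided deviations, until the interior gap no
// longer exceeds what has been accumulated.  The dip is half the final
// maximum deviation, in ecdf units, floored at 1/(2n).

namespace {

// lower convex hull of the points (x[i], i), i in [low, high] (0-based);
// returns vertex indices in increasing order
void gcm_hull(const std::vector<double>& x, int low, int high,
              std::vector<int>& vert) {
  vert.clear();
  for (int i = low; i <= high; ++i) {
    while (vert.size() >= 2) {
      int j = vert[vert.size() - 1];
      int k = vert[vert.size() - 2];
      // pop j unless it lies strictly below the chord k -> i
      double c = (double)(j - k) * (x[i] - x[k]) -
                 (double)(i - k) * (x[j] - x[k]);
      if (c < 0.0) break;
      vert.pop_back();
    }
    vert.push_back(i);
  }
}

// upper concave hull of the points (x[i], i + 1), i in [low, high]
void lcm_hull(const std::vector<double>& x, int low, int high,
              std::vector<int>& vert) {
  vert.clear();
  for (int i = low; i <= high; ++i) {
    while (vert.size() >= 2) {
      int j = vert[vert.size() - 1];
      int k = vert[vert.size() - 2];
      // pop j unless it lies strictly above the chord k -> i
      double c = (double)(j - k) * (x[i] - x[k]) -
                 (double)(i - k) * (x[j] - x[k]);
      if (c > 0.0) break;
      vert.pop_back();
    }
    vert.push_back(i);
  }
}

// piecewise-linear evaluation of a hull at abscissa t; vertices are sample
// indices, heights y(i) = i + off.  seg is advanced so that consecutive
// queries with non-decreasing t stay O(1).  A tied-abscissa (vertical)
// segment can only occur at the right edge of a gcm or the left edge of an
// lcm; there the hull curve takes the lower (gcm) resp. upper (lcm) value.
double hull_eval(const std::vector<double>& x, const std::vector<int>& vert,
                 double off, double t, int& seg, bool upper) {
  int m = (int)vert.size();
  while (seg < m - 2 && x[vert[seg + 1]] < t) ++seg;
  int aidx = vert[seg], bidx = vert[seg + 1];
  double xa = x[aidx], xb = x[bidx];
  double ya = aidx + off, yb = bidx + off;
  if (xb <= xa) return upper ? yb : ya;
  if (t <= xa) return ya;
  if (t >= xb) return yb;
  return ya + (yb - ya) * (t - xa) / (xb - xa);
}

}  // namespace

// core: x must be sorted ascending; returns the dip in ecdf units
static double dip_sorted(const std::vector<double>& x) {
  const int n = (int)x.size();
  if (n < 2) return n == 1 ? 0.5 / n : NA_REAL;
  if (x.back() == x.front()) return 0.5 / n;

  int low = 0, high = n - 1;
  double D = 0.0;  // accumulated max deviation, count units
  std::vector<int> gcm, lcm;

  for (int iter = 0; iter < 2 * n + 10; ++iter) {
    if (low >= high || x[high] == x[low]) break;
    gcm_hull(x, low, high, gcm);
    lcm_hull(x, low, high, lcm);

    // widest gap between the two hull curves, attained at a vertex of one
    // of them; remember the bracketing vertices as the next modal interval
    double d = 0.0;
    int ig = low, ih = high;
    {
      int seg = 0;
      for (size_t a = 0; a < gcm.size(); ++a) {
        int j = gcm[a];
        double gap = hull_eval(x, lcm, 1.0, x[j], seg, true) - (double)j;
        if (gap > d) {
          d = gap;
          ig = j;
          // right end of the lcm segment covering x[j]
          ih = lcm[std::min((size_t)seg + 1, lcm.size() - 1)];
        }
      }
    }
    {
      int seg = 0;
      for (size_t a = 0; a < lcm.size(); ++a) {
        int j = lcm[a];
        double gap = (double)(j + 1) - hull_eval(x, gcm, 0.0, x[j], seg, false);
        if (gap > d) {
          d = gap;
          ih = j;
          // left end of the gcm segment covering x[j]
          ig = gcm[seg];
        }
      }
    }
    if (ih < ig) std::swap(ig, ih);

    if (d <= D) break;

    // deviation of the ecdf above the gcm on [low, ig]:
    // post-jump count (i + 1) against the minorant
    double dl = 0.0;
    {
      int seg = 0;
      for (int i = low; i <= ig; ++i) {
        double dev = (double)(i + 1) - hull_eval(x, gcm, 0.0, x[i], seg, false);
        if (dev > dl) dl = dev;
      }
    }
    // deviation of the ecdf below the lcm on [ih, high]:
    // pre-jump count i against the majorant
    double du = 0.0;
    {
      int seg = 0;
      for (int i = ih; i <= high; ++i) {
        double dev = hull_eval(x, lcm, 1.0, x[i], seg, true) - (double)i;
        if (dev > du) du = dev;
      }
    }
    if (dl > D) D = dl;
    if (du > D) D = du;

    if (ig == low && ih == high) break;
    low = ig;
    high = ih;
  }

  if (D < 1.0) D = 1.0;  // conventional lower bound 1/(2n)
  return D / (2.0 * n);
}

// dip of one sorted sample (ascending order is the caller's contract)
// [[Rcpp::export(name = ".dip_sorted_cpp")]]
double dip_sorted_cpp(NumericVector x_sorted) {
  std::vector<double> x(x_sorted.begin(), x_sorted.end());
  return dip_sorted(x);
}

// dip statistics of n_boot sorted uniform(0,1) samples of size n, drawn
// from R's RNG stream (so results are governed by set.seed)
// [[Rcpp::export(name = ".dip_null_boot_cpp")]]
NumericVector dip_null_boot_cpp(int n, int n_boot) {
  NumericVector out(n_boot);
  std::vector<double> x(n);
  for (int b = 0; b < n_boot; ++b) {
    for (int i = 0; i < n; ++i) x[i] = unif_rand();
    std::sort(x.begin(), x.end());
    out[b] = dip_sorted(x);
  }
  return out;
}
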