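#include <Rcpp.h>
using namespace Rcpp;

// Hartigan dip statistic of a sorted sample.
//
// Uses the band characterisation of unimodal cdf fits: a unimodal cdf G
// within sup-distance d of the empirical cdf F_n exists iff the sample
// splits at some index m such that a convex cdf piece fits the bands
// [i/n - d, (i-1)/n + d] at x_1..x_m and a concave piece fits them at
// x_{m+1}..x_n (a mode atom may sit between the pieces). Because the
// bands shift uniformly with d, convex feasibility over a prefix reduces
// to c(m) <= 2d, where c(m) is the largest gap i/n minus the greatest
// convex minorant of the points (x_i, (i-1)/n) over the prefix; the
// suffix condition s(m) is the mirror image with the least concave
// majorant of (x_i, i/n). The dip is half the minimum over splits of
// max(c(m), s(m+1)). Prefix values are accumulated in one left-to-right
// hull sweep (amortised rescans only under replaced hull segments),
// suffix values in the mirrored sweep.
// [[Rcpp::export(rng = false)]]
double dip_stat_sorted(NumericVector x) {
  const int n = x.size();
  if (n < 2) return 0.0;
  const double invn = 1.0 / n;

  // prefix sweep: greatest convex minorant of (x_i, (i-1)/n)
  std::vector<double> cvec(n + 1, 0.0);
  {
    std::vector<int> hull;
    hull.reserve(64);
    double run = invn; // deviation at the first point: 1/n - 0
    hull.push_back(0);
    cvec[1] = run;
    for (int i = 1; i < n; ++i) {
      const double yi = i * invn; // (i+1-1)/n with 0-based i
      // pop while the last hull vertex lies on/above the segment
      // from the second-to-last vertex to the new point
      while (hull.size() >= 2) {
        int h1 = hull.back(), h2 = hull[hull.size() - 2];
        double cross = (x[i] - x[h2]) * (h1 * invn - h2 * invn) -
                       (x[h1] - x[h2]) * (yi - h2 * invn);
        if (cross >= 0) hull.pop_back(); else break;
      }
      const int v = hull.back();
      const double xv = x[v], yv = v * invn;
      const double dx = x[i] - xv;
      // rescan points under the new segment (v, i]
      for (int j = v + 1; j <= i; ++j) {
        double hy = (dx > 0) ? yv + (yi - yv) * (x[j] - xv) / dx : yv;
        double dev = (j + 1) * invn - hy;
        if (dev > run) run = dev;
      }
      hull.push_back(i);
      cvec[i + 1] = run;
    }
  }

  // suffix sweep: least concave majorant of (x_i, i/n), right to left
  std::vector<double> svec(n + 2, 0.0);
  {
    std::vector<int> hull;
    hull.reserve(64);
    double run = invn; // deviation at the last point: n/n - (n-1)/n
    hull.push_back(n - 1);
    svec[n] = run;
    for (int i = n - 2; i >= 0; --i) {
      const double yi = (i + 1) * invn;
      while (hull.size() >= 2) {
        int h1 = hull.back(), h2 = hull[hull.size() - 2];
        // keep the majorant concave viewed left-to-right
        double cross = (x[i] - x[h2]) * ((h1 + 1) * invn - (h2 + 1) * invn) -
                       (x[h1] - x[h2]) * (yi - (h2 + 1) * invn);
        if (cross >= 0) hull.pop_back(); else break;
      }
      const int v = hull.back();
      const double xv = x[v], yv = (v + 1) * invn;
      const double dx = xv - x[i];
      for (int j = i; j < v; ++j) {
        double hy = (dx > 0) ? yi + (yv - yi) * (x[j] - x[i]) / dx : yv;
        double dev = hy - j * invn; // lcm minus (j+1-1)/n
        if (dev > run) run = dev;
      }
      hull.push_back(i);
      svec[i + 1] = run;
    }
  }

  double best = std::numeric_limits<double>::infinity();
  for (int m = 0; m <= n; ++m) {
    double v = std::max(cvec[m], svec[m + 1]);
    if (v < best) best = v;
  }
  return 0.5 * best;
}
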