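#include <Rcpp.h>
using namespace Rcpp;

// shoelace area (absolute) of a closed polygon
static double shoelace(const std::vector<double> &x,
                       const std::vector<double> &y) {
  const int n = x.size();
  if (n < 3) return 0.0;
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    const int j = (i + 1 == n) ? 0 : i + 1;
    s += x[i] * y[j] - x[j] * y[i];
  }
  return std::fabs(s) / 2.0;
}

// Sutherland-Hodgman clip against half-plane ax*px + ay*py >= 0,
// then shoelace area of the clipped polygon
static double clip_area(const std::vector<double> &px,
                        const std::vector<double> &py,
                        double ax, double ay) {
  const int n = px.size();
  std::vector<double> qx, qy;
  qx.reserve(2 * n);
  qy.reserve(2 * n);
  for (int i = 0; i < n; ++i) {
    const int j = (i + 1 == n) ? 0 : i + 1;
    const double di = ax * px[i] + ay * py[i];
    const double dj = ax * px[j] + ay * py[j];
    if (di >= 0) { qx.push_back(px[i]); qy.push_back(py[i]); }
    if ((di >= 0) != (dj >= 0)) {
      const double t = di / (di - dj);
      qx.push_back(px[i] + t * (px[j] - px[i]));
      qy.push_back(py[i] + t * (py[j] - py[i]));
    }
  }
  return shoelace(qx, qy);
}

// Per-stride phase-plot orbit geometry: area by the shoelace formula,
// half-orbit area asymmetries about the principal axes, and orbit
// centroid.  `a` and `j` are the (z-normalized) acceleration and jerk
// of the whole bout; starts/ends are 0-based half-open sample bounds.
// [[Rcpp::export(name = ".orbit_stats")]]
DataFrame orbit_stats(NumericVector a, NumericVector jrk,
                      IntegerVector starts, IntegerVector ends) {
  const int ns = starts.size();
  NumericVector area(ns, NA_REAL), long_asym(ns, NA_REAL),
      short_asym(ns, NA_REAL), cx(ns, NA_REAL), cy(ns, NA_REAL);
  for (int s = 0; s < ns; ++s) {
    const int lo = starts[s], hi = ends[s];
    const int n = hi - lo;
    if (n < 5 || lo < 0 || hi > a.size()) continue;
    std::vector<double> px(n), py(n);
    double mx = 0, my = 0;
    for (int i = 0; i < n; ++i) {
      px[i] = a[lo + i];
      py[i] = jrk[lo + i];
      mx += px[i]; my += py[i];
    }
    mx /= n; my /= n;
    double sxx = 0, syy = 0, sxy = 0;
    for (int i = 0; i < n; ++i) {
      px[i] -= mx; py[i] -= my;
      sxx += px[i] * px[i];
      syy += py[i] * py[i];
      sxy += px[i] * py[i];
    }
    const double ar = shoelace(px, py);
    if (ar < 1e-12) continue;
    const double ang = 0.5 * std::atan2(2 * sxy, sxx - syy);
    const double c = std::cos(ang), sn = std::sin(ang);
    // long axis = PC1 (c, sn); its sides are along PC2 (-sn, c)
    const double lp = clip_area(px, py, -sn, c);
    const double lm = clip_area(px, py, sn, -c);
    const double sp = clip_area(px, py, c, sn);
    const double sm = clip_area(px, py, -c, -sn);
    area[s] = ar;
    if (lp + lm > 0) long_asym[s] = std::fabs(lp - lm) / (lp + lm);
    if (sp + sm > 0) short_asym[s] = std::fabs(sp - sm) / (sp + sm);
    cx[s] = mx; cy[s] = my;
  }
  return DataFrame::create(_["area"] = area, _["long_asym"] = long_asym,
                           _["short_asym"] = short_asym, _["cx"] = cx,
                           _["cy"] = cy);
}
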