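// Hartigan & Hartigan dip statistic.
//
// The dip of an empirical CDF F_n is min_G sup_x |F_n(x) - G(x)| over the
// class of unimodal CDFs G (convex below the mode, concave above it).  A
// unimodal G lies within a band of half-width delta around F_n iff there is
// a knot p (the mode) and values G_i with
//   G_i in [l_i - delta, u_i + delta],  u_i = (i-1)/n, l_i = i/n,
//   (G_1..G_p) discretely convex and (G_p..G_n) discretely concave.
// Feasibility of each side alone reduces to chord conditions (lower convex
// hull of the upper band must dominate the lower band, and mirrored), and
// the two sides must additionally agree on a common value at the mode knot,
// which is checked through pairwise line-extrapolation bounds on G_p.  The
// dip is located by bisection on delta.  Tied observations are treated as
// infinitesimally separated, matching the reference implementation's
// behaviour (a point mass scores the minimal dip 1/(2n), not 0).
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct DipWork {
  int n;
  std::vector<double> x, u, l;   // sorted values, ECDF left/right limits
};

// Left sweep: largest p (0-based) such that a convex chain within the band
// exists on points 0..p, i.e. lowerhull(u)(x_i) >= l_i - dd for all i <= p.
// Incremental lower hull with lazy re-evaluation of deviations on popped
// ranges; the running max deviation is monotone in p.
int pmax_left(const DipWork& w, double dd) {
  const int n = w.n;
  std::vector<int> hull;
  double maxdev = 0.0;
  const double tol = 1e-12;
  for (int p = 0; p < n; ++p) {
    int lowest_pop = -1;
    while ((int)hull.size() >= 2) {
      int a = hull[hull.size() - 2], b = hull[hull.size() - 1];
      if ((w.u[b] - w.u[a]) * (w.x[p] - w.x[a]) >=
          (w.u[p] - w.u[a]) * (w.x[b] - w.x[a])) {
        lowest_pop = b;
        hull.pop_back();
      } else break;
    }
    if (lowest_pop >= 0) {
      // hull segment from hull.back() to p replaces segments covering
      // indices (hull.back(), p); re-evaluate their deviations
      int a = hull.back();
      for (int i = a + 1; i < p; ++i) {
        double hv = (w.x[p] == w.x[a]) ? w.u[a]
          : w.u[a] + (w.u[p] - w.u[a]) * (w.x[i] - w.x[a]) / (w.x[p] - w.x[a]);
        double dev = w.l[i] - hv;
        if (dev > maxdev) maxdev = dev;
      }
    }
    hull.push_back(p);
    double devp = w.l[p] - w.u[p];        // hull touches (x_p, u_p)
    if (devp > maxdev) maxdev = devp;
    if (maxdev > dd + tol) return p - 1;
  }
  return n - 1;
}

// Mirrored right sweep: smallest p such that a concave chain within the band
// exists on points p..n-1.
int pmin_right(const DipWork& w, double dd) {
  const int n = w.n;
  std::vector<int> hull;   // upper hull of (x_j, l_j), built right-to-left
  double maxdev = 0.0;
  const double tol = 1e-12;
  for (int p = n - 1; p >= 0; --p) {
    int popped = 0;
    while ((int)hull.size() >= 2) {
      int a = hull[hull.size() - 2], b = hull[hull.size() - 1];
      // moving leftwards: pop b if it lies on/below chord (a, p)
      if ((w.l[b] - w.l[a]) * (w.x[p] - w.x[a]) >=
          (w.l[p] - w.l[a]) * (w.x[b] - w.x[a])) {
        popped = 1;
        hull.pop_back();
      } else break;
    }
    if (popped) {
      int a = hull.back();
      for (int i = a - 1; i > p; --i) {
        double hv = (w.x[p] == w.x[a]) ? w.l[a]
          : w.l[a] + (w.l[p] - w.l[a]) * (w.x[i] - w.x[a]) / (w.x[p] - w.x[a]);
        double dev = hv - w.u[i];
        if (dev > maxdev) maxdev = dev;
      }
    }
    hull.push_back(p);
    double devp = w.l[p] - w.u[p];
    if (devp > maxdev) maxdev = devp;
    if (maxdev > dd + tol) return p + 1;
  }
  return 0;
}

// A unimodal chain with mode knot p exists at half-width delta iff the
// minimal admissible G_p from the convex side does not exceed the maximal
// admissible G_p from the concave side.  The bounds are line extrapolations
// through (x_a, u_a + delta) -> (x_i, l_i - delta) -> x_p (left) and the
// mirror image (right).
bool coupling_ok(const DipWork& w, double delta, int plo, int phi) {
  const int n = w.n;
  const double dd = 2.0 * delta, tol = 1e-12;
  if (plo > phi) return false;
  // steepest slope from any earlier (x_a, u_a) up to (x_i, l_i), minus band
  std::vector<double> sstar(n, -HUGE_VAL);
  {
    std::vector<int> hull;  // lower hull of (x_a, u_a)
    for (int i = 0; i <= phi; ++i) {
      if (i > 0) {
        // ternary search for the tangent point on the hull
        int lo = 0, hi = (int)hull.size() - 1;
        while (hi - lo > 2) {
          int m1 = lo + (hi - lo) / 3, m2 = hi - (hi - lo) / 3;
          double s1 = (w.x[i] > w.x[hull[m1]])
            ? (w.l[i] - w.u[hull[m1]] - dd) / (w.x[i] - w.x[hull[m1]]) : HUGE_VAL;
          double s2 = (w.x[i] > w.x[hull[m2]])
            ? (w.l[i] - w.u[hull[m2]] - dd) / (w.x[i] - w.x[hull[m2]]) : HUGE_VAL;
          if (s1 < s2) lo = m1 + 1; else hi = m2;
        }
        for (int k = lo; k <= hi; ++k) {
          int a = hull[k];
          if (w.x[i] > w.x[a]) {
            double s = (w.l[i] - w.u[a] - dd) / (w.x[i] - w.x[a]);
            if (s > sstar[i]) sstar[i] = s;
          }
        }
      }
      while ((int)hull.size() >= 2) {
        int a = hull[hull.size() - 2], b = hull[hull.size() - 1];
        if ((w.u[b] - w.u[a]) * (w.x[i] - w.x[a]) >=
            (w.u[i] - w.u[a]) * (w.x[b] - w.x[a])) hull.pop_back();
        else break;
      }
      hull.push_back(i);
    }
  }
  // steepest slope from (x_j, u_j) up to any later (x_b, l_b), minus band
  std::vector<double> tstar(n, -HUGE_VAL);
  {
    std::vector<int> hull;  // upper-right hull of (x_b, l_b), right-to-left
    for (int j = n - 1; j >= plo; --j) {
      if (j < n - 1) {
        int lo = 0, hi = (int)hull.size() - 1;
        while (hi - lo > 2) {
          int m1 = lo + (hi - lo) / 3, m2 = hi - (hi - lo) / 3;
          double s1 = (w.x[hull[m1]] > w.x[j])
            ? (w.l[hull[m1]] - w.u[j] - dd) / (w.x[hull[m1]] - w.x[j]) : HUGE_VAL;
          double s2 = (w.x[hull[m2]] > w.x[j])
            ? (w.l[hull[m2]] - w.u[j] - dd) / (w.x[hull[m2]] - w.x[j]) : HUGE_VAL;
          if (s1 < s2) lo = m1 + 1; else hi = m2;
        }
        for (int k = lo; k <= hi; ++k) {
          int b = hull[k];
          if (w.x[b] > w.x[j]) {
            double s = (w.l[b] - w.u[j] - dd) / (w.x[b] - w.x[j]);
            if (s > tstar[j]) tstar[j] = s;
          }
        }
      }
      while ((int)hull.size() >= 2) {
        int a = hull[hull.size() - 2], b = hull[hull.size() - 1];
        if ((w.l[b] - w.l[a]) * (w.x[j] - w.x[a]) >=
            (w.l[j] - w.l[a]) * (w.x[b] - w.x[a])) hull.pop_back();
        else break;
      }
      hull.push_back(j);
    }
  }
  for (int p = plo; p <= phi; ++p) {
    double gLmin = w.l[p] - delta;
    for (int i = 0; i < p; ++i) {
      if (sstar[i] == -HUGE_VAL) continue;
      double v = (w.l[i] - delta) + sstar[i] * (w.x[p] - w.x[i]);
      if (v > gLmin) gLmin = v;
    }
    double gRmax = w.u[p] + delta;
    for (int j = p + 1; j < n; ++j) {
      if (tstar[j] == -HUGE_VAL) continue;
      double v = (w.u[j] + delta) - tstar[j] * (w.x[j] - w.x[p]);
      if (v < gRmax) gRmax = v;
    }
    if (gLmin <= gRmax + tol) return true;
  }
  return false;
}

bool feasible(const DipWork& w, double delta) {
  double dd = 2.0 * delta;
  int phi = pmax_left(w, dd);
  if (phi < 0) return false;
  int plo = pmin_right(w, dd);
  if (plo >= w.n) return false;
  if (plo > phi) return false;
  return coupling_ok(w, delta, plo, phi);
}

} // namespace

// [[Rcpp::export(name = ".dip_cpp")]]
double dip_cpp(NumericVector xsorted) {
  DipWork w;
  w.n = xsorted.size();
  if (w.n < 4) stop("dip statistic requires at least 4 observations");
  w.x.assign(xsorted.begin(), xsorted.end());
  for (int i = 1; i < w.n; ++i)
    if (w.x[i] < w.x[i - 1]) stop("input to .dip_cpp must be sorted");
  // ties: infinitesimal separation, realised as a deterministic micro-offset
  bool ties = false;
  for (int i = 1; i < w.n; ++i) if (w.x[i] == w.x[i - 1]) { ties = true; break; }
  if (ties) {
    double range = w.x[w.n - 1] - w.x[0];
    double eps = (range > 0 ? range : 1.0) * 1e-9 / w.n;
    for (int i = 0; i < w.n; ++i) w.x[i] += (i + 1) * eps;
  }
  w.u.resize(w.n); w.l.resize(w.n);
  for (int i = 0; i < w.n; ++i) {
    w.u[i] = (double)i / w.n;
    w.l[i] = (double)(i + 1) / w.n;
  }
  double lo = 0.0, hi = 0.3;
  for (int it = 0; it < 60; ++it) {
    double mid = 0.5 * (lo + hi);
    if (feasible(w, mid)) hi = mid; else lo = mid;
  }
  return hi;
}
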