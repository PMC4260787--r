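#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
#include <numeric>

using namespace Rcpp;

// k-nearest-neighbour (conditional) mutual information estimators with the
// Chebyshev (max) norm: KSG algorithm 1 for I(X;Y), Frenzel-Pompe for
// I(X;Y|Z).  Neighbour searches scan points in the order of one projected
// coordinate and stop once the projected gap alone exceeds the current
// radius (the Chebyshev distance dominates every per-dimension gap), which
// keeps the estimators near-linear in practice without tree structures.

// Chebyshev distance between rows i and j over a column-block [c0, c0+dc)
// of a column-major matrix; abandons once the running max reaches `cap`.
static inline double cheb_dist(const double* m, int n, int i, int j,
                               int c0, int dc, double cap) {
  double d = 0.0;
  for (int c = c0; c < c0 + dc; ++c) {
    double v = std::fabs(m[(size_t)c * n + i] - m[(size_t)c * n + j]);
    if (v > d) {
      d = v;
      if (d >= cap) return d;
    }
  }
  return d;
}

// rank of each point when sorted by column `col`
static void sort_order(const double* col, int n, std::vector<int>& ord,
                       std::vector<int>& pos) {
  ord.resize((size_t)n); pos.resize((size_t)n);
  std::iota(ord.begin(), ord.end(), 0);
  std::sort(ord.begin(), ord.end(),
            [col](int a, int b) { return col[a] < col[b]; });
  for (int r = 0; r < n; ++r) pos[(size_t)ord[(size_t)r]] = r;
}

// For each point, Chebyshev distance to its k-th nearest neighbour in the
// full joint space (all columns).  Scans outward from the point's rank in
// the first coordinate, maintaining the k best distances seen so far.
static std::vector<double> knn_radius(const NumericMatrix& joint, int k) {
  const int n = joint.nrow(), d = joint.ncol();
  const double* m = &joint(0, 0);
  const double* c0 = m;                      // first column
  std::vector<int> ord, pos;
  sort_order(c0, n, ord, pos);
  std::vector<double> eps((size_t)n);
  std::vector<double> best((size_t)k);
  for (int i = 0; i < n; ++i) {
    std::fill(best.begin(), best.end(), R_PosInf);
    double cap = R_PosInf;
    const int p0 = pos[(size_t)i];
    int lo = p0 - 1, hi = p0 + 1;
    while (lo >= 0 || hi < n) {
      int j = -1;
      // take the side whose projected gap is smaller
      double glo = (lo >= 0) ? std::fabs(c0[ord[(size_t)lo]] - c0[i]) : R_PosInf;
      double ghi = (hi < n) ? std::fabs(c0[ord[(size_t)hi]] - c0[i]) : R_PosInf;
      double gap;
      if (glo <= ghi) { j = ord[(size_t)lo]; gap = glo; --lo; }
      else            { j = ord[(size_t)hi]; gap = ghi; ++hi; }
      if (gap >= cap) break;                 // no closer point remains
      double dv = cheb_dist(m, n, i, j, 0, d, cap);
      if (dv >= cap) continue;
      int p = k - 1;
      while (p > 0 && best[(size_t)p - 1] > dv) {
        best[(size_t)p] = best[(size_t)p - 1];
        --p;
      }
      best[(size_t)p] = dv;
      cap = best[(size_t)k - 1];
    }
    eps[(size_t)i] = cap;
  }
  return eps;
}

// Count, for each point i, the neighbours j != i with Chebyshev distance
// strictly below eps[i] over the column-block [c0b, c0b+dc), scanning in
// the order of the block's first coordinate.
static void count_within(const NumericMatrix& joint, int c0b, int dc,
                         const std::vector<double>& eps,
                         std::vector<int>& cnt) {
  const int n = joint.nrow();
  const double* m = &joint(0, 0);
  const double* cb = m + (size_t)c0b * n;
  std::vector<int> ord, pos;
  sort_order(cb, n, ord, pos);
  cnt.assign((size_t)n, 0);
  for (int i = 0; i < n; ++i) {
    const double e = eps[(size_t)i];
    int c = 0;
    const int p0 = pos[(size_t)i];
    for (int r = p0 - 1; r >= 0; --r) {
      int j = ord[(size_t)r];
      if (cb[i] - cb[j] >= e) break;
      if (dc == 1 || cheb_dist(m, n, i, j, c0b, dc, e) < e) ++c;
    }
    for (int r = p0 + 1; r < n; ++r) {
      int j = ord[(size_t)r];
      if (cb[j] - cb[i] >= e) break;
      if (dc == 1 || cheb_dist(m, n, i, j, c0b, dc, e) < e) ++c;
    }
    cnt[(size_t)i] = c;
  }
}

// [[Rcpp::export(name = ".mi_knn_cpp")]]
double mi_knn_cpp(NumericMatrix x, NumericMatrix y, int k) {
  const int n = x.nrow();
  const int dx = x.ncol(), dy = y.ncol();
  NumericMatrix joint(n, dx + dy);
  for (int c = 0; c < dx; ++c) joint(_, c) = x(_, c);
  for (int c = 0; c < dy; ++c) joint(_, dx + c) = y(_, c);

  std::vector<double> eps = knn_radius(joint, k);
  std::vector<int> nx, ny;
  count_within(joint, 0, dx, eps, nx);
  count_within(joint, dx, dy, eps, ny);

  double s = 0.0;
  for (int i = 0; i < n; ++i)
    s += R::digamma(nx[(size_t)i] + 1.0) + R::digamma(ny[(size_t)i] + 1.0);
  return R::digamma((double)k) + R::digamma((double)n) - s / n;
}

// [[Rcpp::export(name = ".cmi_knn_cpp")]]
double cmi_knn_cpp(NumericMatrix x, NumericMatrix y, NumericMatrix z, int k) {
  const int n = x.nrow();
  const int dx = x.ncol(), dy = y.ncol(), dz = z.ncol();
  NumericMatrix joint(n, dx + dy + dz);
  for (int c = 0; c < dx; ++c) joint(_, c) = x(_, c);
  for (int c = 0; c < dy; ++c) joint(_, dx + c) = y(_, c);
  for (int c = 0; c < dz; ++c) joint(_, dx + dy + c) = z(_, c);

  std::vector<double> eps = knn_radius(joint, k);

  // counts in the marginal spaces (X,Z), (Y,Z) and Z; every count requires
  // the Z-block within eps, so one scan ordered by Z's first coordinate
  // serves all three
  const int n_ = n;
  const double* m = &joint(0, 0);
  const double* cz = m + (size_t)(dx + dy) * n_;
  std::vector<int> ord, pos;
  sort_order(cz, n_, ord, pos);
  std::vector<int> nxz((size_t)n_), nyz((size_t)n_), nz((size_t)n_);
  for (int i = 0; i < n_; ++i) {
    const double e = eps[(size_t)i];
    int cxz = 0, cyz = 0, c_z = 0;
    const int p0 = pos[(size_t)i];
    for (int dir = 0; dir < 2; ++dir) {
      int r = p0 + (dir ? 1 : -1);
      while (r >= 0 && r < n_) {
        int j = ord[(size_t)r];
        double gap = std::fabs(cz[j] - cz[i]);
        if (gap >= e) break;
        double dzv = (dz == 1) ? gap : cheb_dist(m, n_, i, j, dx + dy, dz, e);
        if (dzv < e) {
          ++c_z;
          if (std::max(cheb_dist(m, n_, i, j, 0, dx, e), dzv) < e) ++cxz;
          if (std::max(cheb_dist(m, n_, i, j, dx, dy, e), dzv) < e) ++cyz;
        }
        r += dir ? 1 : -1;
      }
    }
    nxz[(size_t)i] = cxz; nyz[(size_t)i] = cyz; nz[(size_t)i] = c_z;
  }

  double s = 0.0;
  for (int i = 0; i < n_; ++i)
    s += R::digamma(nxz[(size_t)i] + 1.0) + R::digamma(nyz[(size_t)i] + 1.0)
       - R::digamma(nz[(size_t)i] + 1.0);
  return R::digamma((double)k) - s / n_;
}
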