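#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Connected-component labeling of a logical matrix (8- or 4-connectivity).
// Returns an integer matrix: 0 background, 1..n component ids.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(const LogicalMatrix& mask, int connectivity = 8) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 4) ? 4 : 8;
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nnb; ++k) {
          int r2 = rr + dr8[k], c2 = cc + dc8[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}

static void edt_1d(const std::vector<double>& f, std::vector<double>& d,
                   std::vector<int>& v, std::vector<double>& z) {
  // Felzenszwalb & Huttenlocher lower-envelope 1D squared distance transform
  const int n = (int)f.size();
  d.assign(n, 0.0);
  v.assign(n, 0);
  z.assign(n + 1, 0.0);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance (in pixels) from each true pixel to the nearest
// false pixel. False pixels get 0.
// [[Rcpp::export(name = ".edt_sq")]]
NumericMatrix edt_sq(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e18;
  NumericMatrix d(nr, nc);
  std::vector<double> f, out, z;
  std::vector<int> v;
  // pass 1: columns
  f.resize(nr);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = mask(r, c) ? INF : 0.0;
    edt_1d(f, out, v, z);
    for (int r = 0; r < nr; ++r) d(r, c) = out[r];
  }
  // pass 2: rows
  f.resize(nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = d(r, c);
    edt_1d(f, out, v, z);
    for (int c = 0; c < nc; ++c) d(r, c) = out[c];
  }
  return d;
}

// Seeded watershed by priority flooding: grow markers over the mask in order
// of decreasing elevation (here typically the distance transform), so basins
// meet along the ridge between seeds. Unseeded mask pixels reachable from no
// marker stay 0.
// [[Rcpp::export(name = ".flood_assign")]]
IntegerMatrix flood_assign(const NumericMatrix& elev, const IntegerMatrix& markers,
                           const LogicalMatrix& mask) {
  const int nr = elev.nrow(), nc = elev.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  typedef std::pair<double, int> QE; // (elevation, linear index)
  std::priority_queue<QE> pq;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (markers(r, c) > 0 && mask(r, c)) {
        lab(r, c) = markers(r, c);
        pq.push(QE(elev(r, c), r + c * nr));
      }
  const int dr[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  while (!pq.empty()) {
    int idx = pq.top().second; pq.pop();
    int r = idx % nr, c = idx / nr;
    int l = lab(r, c);
    for (int k = 0; k < 8; ++k) {
      int r2 = r + dr[k], c2 = c + dc[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (mask(r2, c2) && lab(r2, c2) == 0) {
        lab(r2, c2) = l;
        pq.push(QE(elev(r2, c2), r2 + c2 * nr));
      }
    }
  }
  return lab;
}
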