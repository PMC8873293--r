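// Geometry primitives: symmetric surface-distance statistics between two
// point clouds (exact, all-pairs) and 3D connected-component labeling.

#include <Rcpp.h>
#include <queue>

using namespace Rcpp;

// Directed min-distance statistics in a single pass over all pairs.
// Returns sums and maxima of min_y dist(x, y) and min_x dist(y, x).
// [[Rcpp::export(name = ".cpp_surface_dist_stats")]]
List cpp_surface_dist_stats(NumericMatrix X, NumericMatrix Y) {
  const int n = X.nrow(), m = Y.nrow();
  if (n == 0 || m == 0) stop("empty surface");
  std::vector<double> colmin(m, R_PosInf);
  double sum_x = 0.0, max_x = 0.0;
  for (int i = 0; i < n; ++i) {
    const double xi = X(i, 0), yi = X(i, 1), zi = X(i, 2);
    double rowmin = R_PosInf;
    for (int j = 0; j < m; ++j) {
      const double dx = xi - Y(j, 0), dy = yi - Y(j, 1), dz = zi - Y(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < rowmin) rowmin = d2;
      if (d2 < colmin[j]) colmin[j] = d2;
    }
    rowmin = std::sqrt(rowmin);
    sum_x += rowmin;
    if (rowmin > max_x) max_x = rowmin;
  }
  double sum_y = 0.0, max_y = 0.0;
  for (int j = 0; j < m; ++j) {
    const double d = std::sqrt(colmin[j]);
    sum_y += d;
    if (d > max_y) max_y = d;
  }
  return List::create(_["sum_x"] = sum_x, _["max_x"] = max_x, _["n_x"] = n,
                      _["sum_y"] = sum_y, _["max_y"] = max_y, _["n_y"] = m);
}

// BFS connected components over a binary mask; connectivity 6 or 26.
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dims,
                                   int connectivity) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const long n = (long)X * Y * Z;
  IntegerVector lab(n);
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        const int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back({dx, dy, dz});
      }
  int next = 0;
  std::queue<long> q;
  for (long s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      const long v = q.front();
      q.pop();
      const int x = (int)(v % X), y = (int)((v / X) % Y), z = (int)(v / ((long)X * Y));
      for (auto &o : offs) {
        const int xn = x + o[0], yn = y + o[1], zn = z + o[2];
        if (xn < 0 || xn >= X || yn < 0 || yn >= Y || zn < 0 || zn >= Z)
          continue;
        const long w = xn + (long)X * (yn + (long)Y * zn);
        if (mask[w] && !lab[w]) {
          lab[w] = next;
          q.push(w);
        }
      }
    }
  }
  return lab;
}
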