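#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Voxel lattices arrive as flat logical/numeric vectors in R's column-major
// order with dims (nx, ny, nz).

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// Largest 26-connected component of a boolean lattice.
// [[Rcpp::export]]
LogicalVector cpp_largest_component(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  std::vector<int> label(n, 0);
  int best_label = 0, best_size = 0, cur = 0;
  std::vector<int> stack;
  for (int s = 0; s < n; ++s) {
    if (!mask[s] || label[s]) continue;
    ++cur;
    int size = 0;
    stack.clear();
    stack.push_back(s);
    label[s] = cur;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      ++size;
      int k = v / (nx * ny), r = v % (nx * ny), j = r / nx, i = r % nx;
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            int w = idx3(ii, jj, kk, nx, ny);
            if (mask[w] && !label[w]) { label[w] = cur; stack.push_back(w); }
          }
    }
    if (size > best_size) { best_size = size; best_label = cur; }
  }
  LogicalVector out(n);
  for (int s = 0; s < n; ++s) out[s] = (label[s] == best_label) && best_label;
  out.attr("dim") = dims;
  return out;
}

// Fill fully enclosed cavities: flood the complement (6-connectivity) from
// every lattice face; complement voxels never reached are cavities.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  std::vector<char> outside(n, 0);
  std::vector<int> stack;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (i && j && k && i < nx - 1 && j < ny - 1 && k < nz - 1) continue;
        int s = idx3(i, j, k, nx, ny);
        if (!mask[s] && !outside[s]) { outside[s] = 1; stack.push_back(s); }
      }
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    int k = v / (nx * ny), r = v % (nx * ny), j = r / nx, i = r % nx;
    for (int t = 0; t < 6; ++t) {
      int ii = i + dx[t], jj = j + dy[t], kk = k + dz[t];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      int w = idx3(ii, jj, kk, nx, ny);
      if (!mask[w] && !outside[w]) { outside[w] = 1; stack.push_back(w); }
    }
  }
  LogicalVector out(n);
  for (int s = 0; s < n; ++s) out[s] = mask[s] || !outside[s];
  out.attr("dim") = dims;
  return out;
}

struct Offset { double ox, oy, oz, r2; };

// 3-D gamma map. ref and ev share one lattice (resample beforehand).
// Search positions lie on a cubic grid of pitch `step` (mm) centred on each
// reference voxel, culled to |r| <= radius; eval dose is trilinearly
// interpolated. dd_abs is the absolute dose tolerance in Gy at each voxel
// (length 1 for global normalization, length n for local). Voxels below
// cutoff_abs (Gy, on ref) get NA.
// [[Rcpp::export]]
NumericVector cpp_gamma_map(NumericVector ref, NumericVector ev,
                            IntegerVector dims, NumericVector spacing,
                            NumericVector dd_abs, double dta,
                            double radius, double step, double cutoff_abs) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const bool local = dd_abs.size() == n;
  const double dta2 = dta * dta;

  std::vector<Offset> offs;
  int m = (int)std::floor(radius / step + 1e-9);
  for (int a = -m; a <= m; ++a)
    for (int b = -m; b <= m; ++b)
      for (int c = -m; c <= m; ++c) {
        double ox = a * step, oy = b * step, oz = c * step;
        double r2 = ox * ox + oy * oy + oz * oz;
        if (r2 <= radius * radius + 1e-9) offs.push_back({ox, oy, oz, r2});
      }
  std::sort(offs.begin(), offs.end(),
            [](const Offset& p, const Offset& q) { return p.r2 < q.r2; });

  NumericVector out(n, NA_REAL);
  out.attr("dim") = dims;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int s = idx3(i, j, k, nx, ny);
        double d0 = ref[s];
        if (d0 < cutoff_abs) continue;
        double tol = local ? dd_abs[s] : dd_abs[0];
        double best = R_PosInf;
        for (const Offset& o : offs) {
          double geo = o.r2 / dta2;
          if (geo >= best) break;  // offsets sorted by radius
          double fx = i + o.ox / sx, fy = j + o.oy / sy, fz = k + o.oz / sz;
          if (fx < 0 || fy < 0 || fz < 0 ||
              fx > nx - 1 || fy > ny - 1 || fz > nz - 1)
            continue;
          int i0 = (int)fx, j0 = (int)fy, k0 = (int)fz;
          int i1 = std::min(i0 + 1, nx - 1);
          int j1 = std::min(j0 + 1, ny - 1);
          int k1 = std::min(k0 + 1, nz - 1);
          double tx = fx - i0, ty = fy - j0, tz = fz - k0;
          double c00 = ev[idx3(i0, j0, k0, nx, ny)] * (1 - tx) +
                       ev[idx3(i1, j0, k0, nx, ny)] * tx;
          double c10 = ev[idx3(i0, j1, k0, nx, ny)] * (1 - tx) +
                       ev[idx3(i1, j1, k0, nx, ny)] * tx;
          double c01 = ev[idx3(i0, j0, k1, nx, ny)] * (1 - tx) +
                       ev[idx3(i1, j0, k1, nx, ny)] * tx;
          double c11 = ev[idx3(i0, j1, k1, nx, ny)] * (1 - tx) +
                       ev[idx3(i1, j1, k1, nx, ny)] * tx;
          double de = (c00 * (1 - ty) + c10 * ty) * (1 - tz) +
                      (c01 * (1 - ty) + c11 * ty) * tz;
          double dd = (de - d0) / tol;
          double g2 = dd * dd + geo;
          if (g2 < best) best = g2;
        }
        out[s] = std::sqrt(best);
      }
  return out;
}
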