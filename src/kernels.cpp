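#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>

using namespace Rcpp;

// 3D grids arrive as R arrays in column-major order: index = x + nx*(y + ny*z).

static inline void neighbour_offsets(int connectivity,
                                     std::vector<int> &dx,
                                     std::vector<int> &dy,
                                     std::vector<int> &dz) {
  dx.clear(); dy.clear(); dz.clear();
  for (int cz = -1; cz <= 1; ++cz)
    for (int cy = -1; cy <= 1; ++cy)
      for (int cx = -1; cx <= 1; ++cx) {
        int manh = std::abs(cx) + std::abs(cy) + std::abs(cz);
        if (manh == 0) continue;
        if (connectivity == 6 && manh != 1) continue;
        dx.push_back(cx); dy.push_back(cy); dz.push_back(cz);
      }
}

// Label connected components of a logical mask. Returns integer array of the
// same shape; background is 0, components numbered 1..k in scan order.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> dx, dy, dz;
  neighbour_offsets(connectivity, dx, dy, dz);
  const int nn = (int)dx.size();
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i] != TRUE || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int cx = (int)(cur % nx);
      int cy = (int)((cur / nx) % ny);
      int cz = (int)(cur / ((R_xlen_t)nx * ny));
      for (int k = 0; k < nn; ++k) {
        int px = cx + dx[k], py = cy + dy[k], pz = cz + dz[k];
        if (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 || pz >= nz)
          continue;
        R_xlen_t j = px + (R_xlen_t)nx * (py + (R_xlen_t)ny * pz);
        if (mask[j] == TRUE && lab[j] == 0) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// One-dimensional squared-distance transform (Felzenszwalb & Huttenlocher),
// with sample spacing `h`; f holds squared distances, d receives the result.
// Samples at +Inf (no background reachable yet) are skipped in the envelope.
static void dt1d(const double *f, double *d, int n, double h,
                 std::vector<int> &v, std::vector<double> &zbuf) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    double qq = (double)q * h;
    if (k < 0) {
      k = 0; v[0] = q; zbuf[0] = -INF; zbuf[1] = INF;
      continue;
    }
    double s = 0.0;
    while (k >= 0) {
      double vp = (double)v[k] * h;
      s = ((f[q] + qq * qq) - (f[v[k]] + vp * vp)) / (2.0 * qq - 2.0 * vp);
      if (s <= zbuf[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    zbuf[k] = (k == 0) ? -INF : s;
    zbuf[k + 1] = INF;
  }
  if (k < 0) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    double qq = (double)q * h;
    while (zbuf[j + 1] < qq) ++j;
    double vp = (double)v[j] * h;
    d[q] = (qq - vp) * (qq - vp) + f[v[j]];
  }
}

// Exact anisotropic Euclidean distance transform: for every TRUE voxel the
// distance (mm) to the nearest FALSE voxel centre; FALSE voxels get 0.
// If border_background, voxels just outside the grid count as background
// (appropriate when the mask boundary must include the image frame).
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dims,
                      NumericVector spacing, bool border_background) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector out(n);
  std::vector<double> f(std::max(nx, std::max(ny, nz)) + 2);
  std::vector<double> d(f.size());
  std::vector<int> v(f.size() + 1);
  std::vector<double> zbuf(f.size() + 2);

  const int pad = border_background ? 1 : 0;
  // pass 1: along x, optionally with virtual background just outside each end
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
      if (pad) { f[0] = 0.0; f[nx + 1] = 0.0; }
      for (int x = 0; x < nx; ++x)
        f[x + pad] = (mask[base + x] == TRUE) ? INF : 0.0;
      dt1d(f.data(), d.data(), nx + 2 * pad, sx, v, zbuf);
      for (int x = 0; x < nx; ++x) out[base + x] = d[x + pad];
    }
  // pass 2: along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      if (pad) { f[0] = 0.0; f[ny + 1] = 0.0; }
      for (int y = 0; y < ny; ++y)
        f[y + pad] = out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
      dt1d(f.data(), d.data(), ny + 2 * pad, sy, v, zbuf);
      for (int y = 0; y < ny; ++y)
        out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = d[y + pad];
    }
  // pass 3: along z
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      if (pad) { f[0] = 0.0; f[nz + 1] = 0.0; }
      for (int z = 0; z < nz; ++z)
        f[z + pad] = out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
      dt1d(f.data(), d.data(), nz + 2 * pad, sz, v, zbuf);
      for (int z = 0; z < nz; ++z)
        out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = d[z + pad];
    }
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = std::isinf(out[i]) ? R_PosInf : std::sqrt(out[i]);
  out.attr("dim") = dims;
  return out;
}

// Region growing from seed voxels (1-based linear indices): breadth-first
// expansion over voxels with lo <= value < hi (hi = +Inf allowed).
// [[Rcpp::export]]
LogicalVector cpp_region_grow(NumericVector vol, IntegerVector dims,
                              NumericVector seeds, double lo, double hi,
                              int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, FALSE);
  std::vector<int> dx, dy, dz;
  neighbour_offsets(connectivity, dx, dy, dz);
  const int nn = (int)dx.size();
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < seeds.size(); ++s) {
    R_xlen_t i = (R_xlen_t)seeds[s] - 1;
    if (i < 0 || i >= n) stop("seed index out of range");
    if (out[i] == TRUE) continue;
    if (!(vol[i] >= lo && vol[i] < hi)) continue;
    out[i] = TRUE;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int cx = (int)(cur % nx);
      int cy = (int)((cur / nx) % ny);
      int cz = (int)(cur / ((R_xlen_t)nx * ny));
      for (int k = 0; k < nn; ++k) {
        int px = cx + dx[k], py = cy + dy[k], pz = cz + dz[k];
        if (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 || pz >= nz)
          continue;
        R_xlen_t j = px + (R_xlen_t)nx * (py + (R_xlen_t)ny * pz);
        if (out[j] == FALSE && vol[j] >= lo && vol[j] < hi) {
          out[j] = TRUE;
          stack.push_back(j);
        }
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// Per-component voxel count, centroid (0-based voxel index coordinates) and
// maximum of an auxiliary volume, for labels 1..nlab.
// [[Rcpp::export]]
List cpp_component_stats(IntegerVector lab, IntegerVector dims,
                         NumericVector vol, int nlab) {
  const int nx = dims[0], ny = dims[1];
  const R_xlen_t n = lab.size();
  NumericVector cnt(nlab), cx(nlab), cy(nlab), cz(nlab);
  NumericVector vmax(nlab, R_NegInf);
  for (R_xlen_t i = 0; i < n; ++i) {
    int l = lab[i];
    if (l <= 0) continue;
    int x = (int)(i % nx);
    int y = (int)((i / nx) % ny);
    int z = (int)(i / ((R_xlen_t)nx * ny));
    cnt[l - 1] += 1.0;
    cx[l - 1] += x; cy[l - 1] += y; cz[l - 1] += z;
    if (vol[i] > vmax[l - 1]) vmax[l - 1] = vol[i];
  }
  for (int l = 0; l < nlab; ++l) {
    if (cnt[l] > 0) { cx[l] /= cnt[l]; cy[l] /= cnt[l]; cz[l] /= cnt[l]; }
  }
  return List::create(_["count"] = cnt, _["cx"] = cx, _["cy"] = cy,
                      _["cz"] = cz, _["max"] = vmax);
}
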