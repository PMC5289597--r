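// Low-level image primitives for vesicle segmentation.
//
// Volumes are R arrays with dim = c(nz, ny, nx), i.e. voxel (z, y, x) sits at
// linear index z + nz * (y + ny * x) (0-based).  Physical spacing is 1 nm in
// x and y (the pipeline works at 1 nm/px) and `dz` nm between slices.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>
#include <limits>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

struct Dim3 {
  int nz, ny, nx;
  R_xlen_t n() const { return (R_xlen_t)nz * ny * nx; }
  R_xlen_t idx(int z, int y, int x) const {
    return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * x);
  }
};

static Dim3 get_dim(SEXP arr) {
  IntegerVector d = as<IntegerVector>(Rf_getAttrib(arr, R_DimSymbol));
  if (d.size() != 3) stop("expected a 3D array");
  Dim3 dm;
  dm.nz = d[0]; dm.ny = d[1]; dm.nx = d[2];
  return dm;
}

// offsets of a flat disk kernel: all (dy, dx) with dy^2 + dx^2 <= r^2
static void disk_offsets(double r, std::vector<int>& dys, std::vector<int>& dxs) {
  int ri = (int)std::floor(r);
  double r2 = r * r;
  for (int dy = -ri; dy <= ri; ++dy)
    for (int dx = -ri; dx <= ri; ++dx)
      if ((double)dy * dy + (double)dx * dx <= r2) {
        dys.push_back(dy); dxs.push_back(dx);
      }
}

// [[Rcpp::export]]
IntegerMatrix cpp_disk_offsets(double radius) {
  std::vector<int> dys, dxs;
  disk_offsets(radius, dys, dxs);
  IntegerMatrix out(dys.size(), 2);
  for (size_t i = 0; i < dys.size(); ++i) { out(i, 0) = dys[i]; out(i, 1) = dxs[i]; }
  return out;
}

// ---------------------------------------------------------------- resampling

// Per-slice bilinear resampling; output pixel center j maps to input
// coordinate (j + 0.5) * scale - 0.5, clamped (edge replication).
// [[Rcpp::export]]
NumericVector cpp_rescale_bilinear(NumericVector vol, int ony, int onx) {
  Dim3 d = get_dim(vol);
  double sy = (double)d.ny / ony, sx = (double)d.nx / onx;
  NumericVector out((R_xlen_t)d.nz * ony * onx);
  out.attr("dim") = IntegerVector::create(d.nz, ony, onx);
  Dim3 od; od.nz = d.nz; od.ny = ony; od.nx = onx;
  for (int x = 0; x < onx; ++x) {
    double fx = (x + 0.5) * sx - 0.5;
    int x0 = (int)std::floor(fx);
    double wx = fx - x0;
    int xa = clampi(x0, 0, d.nx - 1), xb = clampi(x0 + 1, 0, d.nx - 1);
    for (int y = 0; y < ony; ++y) {
      double fy = (y + 0.5) * sy - 0.5;
      int y0 = (int)std::floor(fy);
      double wy = fy - y0;
      int ya = clampi(y0, 0, d.ny - 1), yb = clampi(y0 + 1, 0, d.ny - 1);
      for (int z = 0; z < d.nz; ++z) {
        double vaa = vol[d.idx(z, ya, xa)], vab = vol[d.idx(z, ya, xb)];
        double vba = vol[d.idx(z, yb, xa)], vbb = vol[d.idx(z, yb, xb)];
        out[od.idx(z, y, x)] = (1 - wy) * ((1 - wx) * vaa + wx * vab) +
                               wy * ((1 - wx) * vba + wx * vbb);
      }
    }
  }
  return out;
}

// ------------------------------------------------------------------ filters

// Per-slice mean filter with a flat circular kernel, edge replication.
// [[Rcpp::export]]
NumericVector cpp_mean_filter_disk(NumericVector vol, double radius) {
  Dim3 d = get_dim(vol);
  std::vector<int> dys, dxs;
  disk_offsets(radius, dys, dxs);
  size_t k = dys.size();
  NumericVector out(vol.size());
  out.attr("dim") = vol.attr("dim");
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y) {
      bool interior = (y >= radius && y < d.ny - radius &&
                       x >= radius && x < d.nx - radius);
      for (int z = 0; z < d.nz; ++z) {
        double s = 0;
        if (interior) {
          for (size_t i = 0; i < k; ++i)
            s += vol[d.idx(z, y + dys[i], x + dxs[i])];
        } else {
          for (size_t i = 0; i < k; ++i)
            s += vol[d.idx(z, clampi(y + dys[i], 0, d.ny - 1),
                           clampi(x + dxs[i], 0, d.nx - 1))];
        }
        out[d.idx(z, y, x)] = s / k;
      }
    }
  return out;
}

// Per-slice bilateral filter: spatial Gaussian x range Gaussian weights.
// Range kernel looked up from a precomputed table on squared differences.
// [[Rcpp::export]]
NumericVector cpp_bilateral_filter(NumericVector vol, double spatial_sigma,
                                   double range_sigma) {
  Dim3 d = get_dim(vol);
  int w = std::max(1, (int)std::ceil(2.5 * spatial_sigma));
  std::vector<double> sw((2 * w + 1) * (2 * w + 1));
  for (int dy = -w; dy <= w; ++dy)
    for (int dx = -w; dx <= w; ++dx)
      sw[(dy + w) * (2 * w + 1) + (dx + w)] =
        std::exp(-(dy * dy + dx * dx) / (2.0 * spatial_sigma * spatial_sigma));
  // range table on d^2 in [0, (6 sigma_r)^2]
  const int NT = 4096;
  double maxd2 = 36.0 * range_sigma * range_sigma;
  std::vector<double> rt(NT + 1);
  for (int i = 0; i <= NT; ++i)
    rt[i] = std::exp(-(maxd2 * i / NT) / (2.0 * range_sigma * range_sigma));
  NumericVector out(vol.size());
  out.attr("dim") = vol.attr("dim");
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y)
      for (int z = 0; z < d.nz; ++z) {
        double c = vol[d.idx(z, y, x)];
        double num = 0, den = 0;
        for (int dy = -w; dy <= w; ++dy) {
          int yy = clampi(y + dy, 0, d.ny - 1);
          for (int dx = -w; dx <= w; ++dx) {
            int xx = clampi(x + dx, 0, d.nx - 1);
            double v = vol[d.idx(z, yy, xx)];
            double dv2 = (v - c) * (v - c);
            double rw = dv2 >= maxd2 ? 0.0 :
              rt[(int)(dv2 / maxd2 * NT)];
            double wgt = sw[(dy + w) * (2 * w + 1) + (dx + w)] * rw;
            num += wgt * v; den += wgt;
          }
        }
        out[d.idx(z, y, x)] = num / den;
      }
  return out;
}

// Separable 3D Gaussian, sigma per axis (in index units), truncated at 3
// sigma with kernel renormalization at the borders (replicate-free).
static void gauss1d(std::vector<double>& buf, std::vector<double>& tmp,
                    const std::vector<double>& ker) {
  int n = buf.size(), w = (ker.size() - 1) / 2;
  for (int i = 0; i < n; ++i) {
    double s = 0, wsum = 0;
    int lo = std::max(0, i - w), hi = std::min(n - 1, i + w);
    for (int j = lo; j <= hi; ++j) {
      double kk = ker[j - i + w];
      s += kk * buf[j]; wsum += kk;
    }
    tmp[i] = s / wsum;
  }
  buf.swap(tmp);
}

static std::vector<double> gauss_kernel(double sigma) {
  int w = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * w + 1);
  double s = 0;
  for (int i = -w; i <= w; ++i) {
    k[i + w] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + w];
  }
  for (auto& v : k) v /= s;
  return k;
}

// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector vol, double sigma_z, double sigma_y,
                          double sigma_x) {
  Dim3 d = get_dim(vol);
  NumericVector out = clone(vol);
  if (sigma_z > 0 && d.nz > 1) {
    std::vector<double> ker = gauss_kernel(sigma_z);
    std::vector<double> buf(d.nz), tmp(d.nz);
    for (int x = 0; x < d.nx; ++x)
      for (int y = 0; y < d.ny; ++y) {
        for (int z = 0; z < d.nz; ++z) buf[z] = out[d.idx(z, y, x)];
        gauss1d(buf, tmp, ker);
        for (int z = 0; z < d.nz; ++z) out[d.idx(z, y, x)] = buf[z];
      }
  }
  if (sigma_y > 0 && d.ny > 1) {
    std::vector<double> ker = gauss_kernel(sigma_y);
    std::vector<double> buf(d.ny), tmp(d.ny);
    for (int x = 0; x < d.nx; ++x)
      for (int z = 0; z < d.nz; ++z) {
        for (int y = 0; y < d.ny; ++y) buf[y] = out[d.idx(z, y, x)];
        gauss1d(buf, tmp, ker);
        for (int y = 0; y < d.ny; ++y) out[d.idx(z, y, x)] = buf[y];
      }
  }
  if (sigma_x > 0 && d.nx > 1) {
    std::vector<double> ker = gauss_kernel(sigma_x);
    std::vector<double> buf(d.nx), tmp(d.nx);
    for (int y = 0; y < d.ny; ++y)
      for (int z = 0; z < d.nz; ++z) {
        for (int x = 0; x < d.nx; ++x) buf[x] = out[d.idx(z, y, x)];
        gauss1d(buf, tmp, ker);
        for (int x = 0; x < d.nx; ++x) out[d.idx(z, y, x)] = buf[x];
      }
  }
  return out;
}

// --------------------------------------------------- Euclidean distance map

// Felzenszwalb & Huttenlocher 1D squared distance transform with sampling
// step `h`: d(p) = min_q (h(p-q))^2 + f(q).
static void dt1d(std::vector<double>& f, std::vector<double>& dout,
                 std::vector<int>& v, std::vector<double>& zb, double h) {
  int n = f.size();
  double h2 = h * h;
  int k = 0;
  v[0] = 0;
  zb[0] = -std::numeric_limits<double>::infinity();
  zb[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + h2 * q * q) - (f[v[k]] + h2 * v[k] * v[k])) /
          (2.0 * h2 * (q - v[k]));
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = h * (q - v[k]);
    dout[q] = dq * dq + f[v[k]];
  }
}

// Anisotropic 3D squared EDT of `mask` (distance from foreground voxels to
// the nearest background voxel; background gets 0).  Spacing (dz, 1, 1).
// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector mask, double dz) {
  Dim3 d = get_dim(mask);
  const double INF = 1e30;
  NumericVector out(mask.size());
  out.attr("dim") = mask.attr("dim");
  for (R_xlen_t i = 0; i < mask.size(); ++i) out[i] = mask[i] ? INF : 0.0;
  int nmax = std::max(d.nx, std::max(d.ny, d.nz));
  std::vector<double> f(nmax), dd(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);
  // x pass
  for (int z = 0; z < d.nz; ++z)
    for (int y = 0; y < d.ny; ++y) {
      f.resize(d.nx); dd.resize(d.nx);
      for (int x = 0; x < d.nx; ++x) f[x] = out[d.idx(z, y, x)];
      dt1d(f, dd, v, zb, 1.0);
      for (int x = 0; x < d.nx; ++x) out[d.idx(z, y, x)] = dd[x];
    }
  // y pass
  for (int z = 0; z < d.nz; ++z)
    for (int x = 0; x < d.nx; ++x) {
      f.resize(d.ny); dd.resize(d.ny);
      for (int y = 0; y < d.ny; ++y) f[y] = out[d.idx(z, y, x)];
      dt1d(f, dd, v, zb, 1.0);
      for (int y = 0; y < d.ny; ++y) out[d.idx(z, y, x)] = dd[y];
    }
  // z pass
  if (d.nz > 1) {
    for (int y = 0; y < d.ny; ++y)
      for (int x = 0; x < d.nx; ++x) {
        f.resize(d.nz); dd.resize(d.nz);
        for (int z = 0; z < d.nz; ++z) f[z] = out[d.idx(z, y, x)];
        dt1d(f, dd, v, zb, dz);
        for (int z = 0; z < d.nz; ++z) out[d.idx(z, y, x)] = dd[z];
      }
  }
  for (R_xlen_t i = 0; i < out.size(); ++i)
    out[i] = out[i] >= INF ? INF : std::sqrt(out[i]);
  return out;
}

// 2D EDT of every slice (spacing 1), used by the per-slice watershed.
// [[Rcpp::export]]
NumericVector cpp_edt2d_stack(LogicalVector mask) {
  Dim3 d = get_dim(mask);
  const double INF = 1e30;
  NumericVector out(mask.size());
  out.attr("dim") = mask.attr("dim");
  for (R_xlen_t i = 0; i < mask.size(); ++i) out[i] = mask[i] ? INF : 0.0;
  int nmax = std::max(d.nx, d.ny);
  std::vector<double> f(nmax), dd(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);
  for (int z = 0; z < d.nz; ++z) {
    for (int y = 0; y < d.ny; ++y) {
      f.resize(d.nx); dd.resize(d.nx);
      for (int x = 0; x < d.nx; ++x) f[x] = out[d.idx(z, y, x)];
      dt1d(f, dd, v, zb, 1.0);
      for (int x = 0; x < d.nx; ++x) out[d.idx(z, y, x)] = dd[x];
    }
    for (int x = 0; x < d.nx; ++x) {
      f.resize(d.ny); dd.resize(d.ny);
      for (int y = 0; y < d.ny; ++y) f[y] = out[d.idx(z, y, x)];
      dt1d(f, dd, v, zb, 1.0);
      for (int y = 0; y < d.ny; ++y) out[d.idx(z, y, x)] = dd[y];
    }
  }
  for (R_xlen_t i = 0; i < out.size(); ++i)
    out[i] = out[i] >= INF ? INF : std::sqrt(out[i]);
  return out;
}

// --------------------------------------------------------------- morphology

// [[Rcpp::export]]
LogicalVector cpp_dilate_disk2d(LogicalVector mask, double radius) {
  Dim3 d = get_dim(mask);
  std::vector<int> dys, dxs;
  disk_offsets(radius, dys, dxs);
  LogicalVector out(mask.size());
  out.attr("dim") = mask.attr("dim");
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y)
      for (int z = 0; z < d.nz; ++z) {
        if (!mask[d.idx(z, y, x)]) continue;
        for (size_t i = 0; i < dys.size(); ++i) {
          int yy = y + dys[i], xx = x + dxs[i];
          if (yy >= 0 && yy < d.ny && xx >= 0 && xx < d.nx)
            out[d.idx(z, yy, xx)] = true;
        }
      }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_erode_disk2d(LogicalVector mask, double radius) {
  Dim3 d = get_dim(mask);
  std::vector<int> dys, dxs;
  disk_offsets(radius, dys, dxs);
  LogicalVector out(mask.size());
  out.attr("dim") = mask.attr("dim");
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y)
      for (int z = 0; z < d.nz; ++z) {
        if (!mask[d.idx(z, y, x)]) continue;
        bool keep = true;
        for (size_t i = 0; i < dys.size() && keep; ++i) {
          int yy = y + dys[i], xx = x + dxs[i];
          if (yy < 0 || yy >= d.ny || xx < 0 || xx >= d.nx ||
              !mask[d.idx(z, yy, xx)])
            keep = false;
        }
        out[d.idx(z, y, x)] = keep;
      }
  return out;
}

// ------------------------------------------------------ connected components

// Per-slice 2D connected components of `mask`.  conn = 4 or 8.  Labels are
// globally unique across slices, contiguous from 1.
// [[Rcpp::export]]
IntegerVector cpp_label2d(LogicalVector mask, int conn) {
  Dim3 d = get_dim(mask);
  IntegerVector lab(mask.size());
  lab.attr("dim") = mask.attr("dim");
  int next = 0;
  std::vector<R_xlen_t> stack;
  const int dy8[] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dx8[] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dy4[] = {-1, 0, 0, 1};
  const int dx4[] = {0, -1, 1, 0};
  const int* DY = conn == 4 ? dy4 : dy8;
  const int* DX = conn == 4 ? dx4 : dx8;
  int nn = conn == 4 ? 4 : 8;
  for (int z = 0; z < d.nz; ++z)
    for (int x0 = 0; x0 < d.nx; ++x0)
      for (int y0 = 0; y0 < d.ny; ++y0) {
        R_xlen_t i0 = d.idx(z, y0, x0);
        if (!mask[i0] || lab[i0]) continue;
        ++next;
        lab[i0] = next;
        stack.clear();
        stack.push_back(i0);
        while (!stack.empty()) {
          R_xlen_t i = stack.back(); stack.pop_back();
          int x = (int)(i / ((R_xlen_t)d.nz * d.ny));
          int y = (int)((i / d.nz) % d.ny);
          for (int k = 0; k < nn; ++k) {
            int yy = y + DY[k], xx = x + DX[k];
            if (yy < 0 || yy >= d.ny || xx < 0 || xx >= d.nx) continue;
            R_xlen_t j = d.idx(z, yy, xx);
            if (mask[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
          }
        }
      }
  return lab;
}

// 3D 26-connected components.
// [[Rcpp::export]]
IntegerVector cpp_label3d26(LogicalVector mask) {
  Dim3 d = get_dim(mask);
  IntegerVector lab(mask.size());
  lab.attr("dim") = mask.attr("dim");
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (int x0 = 0; x0 < d.nx; ++x0)
    for (int y0 = 0; y0 < d.ny; ++y0)
      for (int z0 = 0; z0 < d.nz; ++z0) {
        R_xlen_t i0 = d.idx(z0, y0, x0);
        if (!mask[i0] || lab[i0]) continue;
        ++next;
        lab[i0] = next;
        stack.clear();
        stack.push_back(i0);
        while (!stack.empty()) {
          R_xlen_t i = stack.back(); stack.pop_back();
          int x = (int)(i / ((R_xlen_t)d.nz * d.ny));
          int y = (int)((i / d.nz) % d.ny);
          int z = (int)(i % d.nz);
          for (int dzi = -1; dzi <= 1; ++dzi)
            for (int dyi = -1; dyi <= 1; ++dyi)
              for (int dxi = -1; dxi <= 1; ++dxi) {
                if (!dzi && !dyi && !dxi) continue;
                int zz = z + dzi, yy = y + dyi, xx = x + dxi;
                if (zz < 0 || zz >= d.nz || yy < 0 || yy >= d.ny ||
                    xx < 0 || xx >= d.nx) continue;
                R_xlen_t j = d.idx(zz, yy, xx);
                if (mask[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
              }
        }
      }
  return lab;
}

// ------------------------------------------------------------- hole filling

// Per slice: fill background components (4-connected) that do not touch the
// slice border and whose pixel count lies in [minpx, maxpx].
// [[Rcpp::export]]
LogicalVector cpp_fill_holes2d(LogicalVector mask, double minpx, double maxpx) {
  Dim3 d = get_dim(mask);
  LogicalVector out = clone(mask);
  std::vector<int> lab((size_t)d.ny * d.nx);
  std::vector<R_xlen_t> stack, comp;
  const int dy4[] = {-1, 0, 0, 1};
  const int dx4[] = {0, -1, 1, 0};
  for (int z = 0; z < d.nz; ++z) {
    std::fill(lab.begin(), lab.end(), 0);
    int next = 0;
    for (int x0 = 0; x0 < d.nx; ++x0)
      for (int y0 = 0; y0 < d.ny; ++y0) {
        size_t p0 = (size_t)y0 * d.nx + x0;
        if (out[d.idx(z, y0, x0)] || lab[p0]) continue;
        ++next;
        lab[p0] = next;
        bool border = false;
        comp.clear();
        stack.clear();
        stack.push_back(p0);
        comp.push_back(p0);
        while (!stack.empty()) {
          size_t p = stack.back(); stack.pop_back();
          int y = (int)(p / d.nx), x = (int)(p % d.nx);
          if (y == 0 || y == d.ny - 1 || x == 0 || x == d.nx - 1) border = true;
          for (int k = 0; k < 4; ++k) {
            int yy = y + dy4[k], xx = x + dx4[k];
            if (yy < 0 || yy >= d.ny || xx < 0 || xx >= d.nx) continue;
            size_t q = (size_t)yy * d.nx + xx;
            if (!out[d.idx(z, yy, xx)] && !lab[q]) {
              lab[q] = next; stack.push_back(q); comp.push_back(q);
            }
          }
        }
        if (!border && (double)comp.size() >= minpx &&
            (double)comp.size() <= maxpx) {
          for (size_t p : comp)
            out[d.idx(z, (int)(p / d.nx), (int)(p % d.nx))] = true;
        }
      }
  }
  return out;
}

// ------------------------------------------------------------- 2D watershed

// ImageJ-style binary watershed per slice: 2D EDT, lightly smoothed for
// maxima detection, plateau-grouped local maxima as seeds, priority flood,
// pixels claimed by conflicting basins become background separation lines.
// [[Rcpp::export]]
LogicalVector cpp_watershed2d(LogicalVector mask, double maxima_smooth_sigma) {
  Dim3 d = get_dim(mask);
  NumericVector edt = cpp_edt2d_stack(mask);
  NumericVector sm = clone(edt);
  if (maxima_smooth_sigma > 0)
    sm = cpp_gauss3d(edt, 0.0, maxima_smooth_sigma, maxima_smooth_sigma);
  LogicalVector out = clone(mask);
  const int dy8[] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dx8[] = {-1, 0, 1, -1, 1, -1, 0, 1};
  std::vector<int> lab((size_t)d.ny * d.nx);
  std::vector<char> cand((size_t)d.ny * d.nx);
  std::vector<size_t> stack;
  typedef std::pair<double, size_t> QE; // (value, pixel); max-heap by value then lower pixel
  struct Cmp {
    bool operator()(const QE& a, const QE& b) const {
      if (a.first != b.first) return a.first < b.first;
      return a.second > b.second;
    }
  };
  for (int z = 0; z < d.nz; ++z) {
    std::fill(lab.begin(), lab.end(), 0);
    std::fill(cand.begin(), cand.end(), 0);
    // seed candidates: foreground local maxima of the smoothed EDT (>=)
    for (int y = 0; y < d.ny; ++y)
      for (int x = 0; x < d.nx; ++x) {
        if (!mask[d.idx(z, y, x)]) continue;
        double v = sm[d.idx(z, y, x)];
        bool mx = true;
        for (int k = 0; k < 8 && mx; ++k) {
          int yy = y + dy8[k], xx = x + dx8[k];
          if (yy < 0 || yy >= d.ny || xx < 0 || xx >= d.nx) continue;
          if (sm[d.idx(z, yy, xx)] > v + 1e-12) mx = false;
        }
        if (mx) cand[(size_t)y * d.nx + x] = 1;
      }
    // group adjacent candidates into one seed each
    int next = 0;
    for (int y0 = 0; y0 < d.ny; ++y0)
      for (int x0 = 0; x0 < d.nx; ++x0) {
        size_t p0 = (size_t)y0 * d.nx + x0;
        if (!cand[p0] || lab[p0]) continue;
        ++next;
        lab[p0] = next;
        stack.clear();
        stack.push_back(p0);
        while (!stack.empty()) {
          size_t p = stack.back(); stack.pop_back();
          int y = (int)(p / d.nx), x = (int)(p % d.nx);
          for (int k = 0; k < 8; ++k) {
            int yy = y + dy8[k], xx = x + dx8[k];
            if (yy < 0 || yy >= d.ny || xx < 0 || xx >= d.nx) continue;
            size_t q = (size_t)yy * d.nx + xx;
            if (cand[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
          }
        }
      }
    if (next <= 1) continue; // 0 or 1 basin: nothing to split
    // priority flood
    std::priority_queue<QE, std::vector<QE>, Cmp> pq;
    for (int y = 0; y < d.ny; ++y)
      for (int x = 0; x < d.nx; ++x) {
        size_t p = (size_t)y * d.nx + x;
        if (lab[p]) pq.push(QE(sm[d.idx(z, y, x)], p));
      }
    const int WSHED = -1;
    while (!pq.empty()) {
      size_t p = pq.top().second; pq.pop();
      int y = (int)(p / d.nx), x = (int)(p % d.nx);
      int l = lab[p];
      if (l <= 0) continue;
      for (int k = 0; k < 8; ++k) {
        int yy = y + dy8[k], xx = x + dx8[k];
        if (yy < 0 || yy >= d.ny || xx < 0 || xx >= d.nx) continue;
        size_t q = (size_t)yy * d.nx + xx;
        if (!mask[d.idx(z, yy, xx)] || lab[q]) continue;
        // does q touch another basin?
        bool conflict = false;
        for (int k2 = 0; k2 < 8 && !conflict; ++k2) {
          int y2 = yy + dy8[k2], x2 = xx + dx8[k2];
          if (y2 < 0 || y2 >= d.ny || x2 < 0 || x2 >= d.nx) continue;
          int l2 = lab[(size_t)y2 * d.nx + x2];
          if (l2 > 0 && l2 != l) conflict = true;
        }
        if (conflict) {
          lab[q] = WSHED;
          out[d.idx(z, yy, xx)] = false; // separation line
        } else {
          lab[q] = l;
          pq.push(QE(sm[d.idx(z, yy, xx)], q));
        }
      }
    }
  }
  return out;
}

// ---------------------------------------------------- seeded 3D watershed

// Seeds: voxels of the (smoothed) distance map that attain the maximum
// within a physical ball of radius `seed_radius` nm; candidate voxels closer
// than `seed_radius` are merged (single linkage) into one seed.  Flooding by
// decreasing map value, restricted to foreground voxels with map value >=
// `threshold`; ties broken by lower label, then lower linear index.
// [[Rcpp::export]]
IntegerVector cpp_watershed3d_seeded(NumericVector dmap, LogicalVector mask,
                                     double threshold, double seed_radius,
                                     double dz, bool expand_below_threshold) {
  Dim3 d = get_dim(dmap);
  IntegerVector lab(dmap.size());
  lab.attr("dim") = dmap.attr("dim");
  // ball offsets at physical spacing (dz,1,1)
  std::vector<int> bz, by, bx;
  int rz = (int)std::floor(seed_radius / dz);
  int rxy = (int)std::floor(seed_radius);
  double r2 = seed_radius * seed_radius;
  for (int zi = -rz; zi <= rz; ++zi)
    for (int yi = -rxy; yi <= rxy; ++yi)
      for (int xi = -rxy; xi <= rxy; ++xi) {
        if (!zi && !yi && !xi) continue;
        if (zi * zi * dz * dz + yi * yi + xi * xi <= r2) {
          bz.push_back(zi); by.push_back(yi); bx.push_back(xi);
        }
      }
  size_t nb = bz.size();
  // candidate maxima over the domain
  std::vector<R_xlen_t> candidates;
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y)
      for (int z = 0; z < d.nz; ++z) {
        R_xlen_t i = d.idx(z, y, x);
        if (!mask[i] || dmap[i] < threshold) continue;
        double v = dmap[i];
        bool mx = true;
        for (size_t k = 0; k < nb && mx; ++k) {
          int zz = z + bz[k], yy = y + by[k], xx = x + bx[k];
          if (zz < 0 || zz >= d.nz || yy < 0 || yy >= d.ny ||
              xx < 0 || xx >= d.nx) continue;
          if (dmap[d.idx(zz, yy, xx)] > v + 1e-9) mx = false;
        }
        if (mx) candidates.push_back(i);
      }
  // single-linkage clustering of candidates within the same ball
  std::vector<char> iscand(dmap.size(), 0);
  for (R_xlen_t i : candidates) iscand[i] = 1;
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i0 : candidates) {
    if (lab[i0]) continue;
    ++next;
    lab[i0] = next;
    stack.clear();
    stack.push_back(i0);
    while (!stack.empty()) {
      R_xlen_t i = stack.back(); stack.pop_back();
      int x = (int)(i / ((R_xlen_t)d.nz * d.ny));
      int y = (int)((i / d.nz) % d.ny);
      int z = (int)(i % d.nz);
      for (size_t k = 0; k < nb; ++k) {
        int zz = z + bz[k], yy = y + by[k], xx = x + bx[k];
        if (zz < 0 || zz >= d.nz || yy < 0 || yy >= d.ny ||
            xx < 0 || xx >= d.nx) continue;
        R_xlen_t j = d.idx(zz, yy, xx);
        if (iscand[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
      }
    }
  }
  if (next == 0) return lab;
  // priority flood: value desc, then label asc, then index asc
  struct QE { double v; int l; R_xlen_t i; };
  struct Cmp {
    bool operator()(const QE& a, const QE& b) const {
      if (a.v != b.v) return a.v < b.v;
      if (a.l != b.l) return a.l > b.l;
      return a.i > b.i;
    }
  };
  std::priority_queue<QE, std::vector<QE>, Cmp> pq;
  for (R_xlen_t i : candidates) pq.push(QE{dmap[i], lab[i], i});
  while (!pq.empty()) {
    QE e = pq.top(); pq.pop();
    int x = (int)(e.i / ((R_xlen_t)d.nz * d.ny));
    int y = (int)((e.i / d.nz) % d.ny);
    int z = (int)(e.i % d.nz);
    for (int dzi = -1; dzi <= 1; ++dzi)
      for (int dyi = -1; dyi <= 1; ++dyi)
        for (int dxi = -1; dxi <= 1; ++dxi) {
          if (!dzi && !dyi && !dxi) continue;
          int zz = z + dzi, yy = y + dyi, xx = x + dxi;
          if (zz < 0 || zz >= d.nz || yy < 0 || yy >= d.ny ||
              xx < 0 || xx >= d.nx) continue;
          R_xlen_t j = d.idx(zz, yy, xx);
          if (lab[j] || !mask[j] || dmap[j] < threshold) continue;
          lab[j] = e.l;
          pq.push(QE{dmap[j], e.l, j});
        }
  }
  if (expand_below_threshold) {
    // second flood without the threshold restriction: assigns the thin
    // below-threshold rind of each particle to its basin so measured
    // extents correspond to the full foreground particle
    for (R_xlen_t i = 0; i < lab.size(); ++i)
      if (lab[i] > 0) pq.push(QE{dmap[i], lab[i], i});
    while (!pq.empty()) {
      QE e = pq.top(); pq.pop();
      int x = (int)(e.i / ((R_xlen_t)d.nz * d.ny));
      int y = (int)((e.i / d.nz) % d.ny);
      int z = (int)(e.i % d.nz);
      for (int dzi = -1; dzi <= 1; ++dzi)
        for (int dyi = -1; dyi <= 1; ++dyi)
          for (int dxi = -1; dxi <= 1; ++dxi) {
            if (!dzi && !dyi && !dxi) continue;
            int zz = z + dzi, yy = y + dyi, xx = x + dxi;
            if (zz < 0 || zz >= d.nz || yy < 0 || yy >= d.ny ||
                xx < 0 || xx >= d.nx) continue;
            R_xlen_t j = d.idx(zz, yy, xx);
            if (lab[j] || !mask[j]) continue;
            lab[j] = e.l;
            pq.push(QE{dmap[j], e.l, j});
          }
    }
  }
  return lab;
}

// ------------------------------------------------------------ region stats

// Per-label statistics in physical units (voxel center of (z,y,x) index is
// (x, y, z*dz) nm).  Surface area from exposed-face counting with physical
// face areas, corrected by the 2/3 digitization factor (naive face counting
// overestimates a smooth surface by 3/2 on average).  Boundary voxel
// coordinates (any exposed face) are returned per label for Feret search.
// [[Rcpp::export]]
List cpp_region_stats(IntegerVector labels, int nlab, double dz) {
  Dim3 d = get_dim(labels);
  std::vector<double> n(nlab, 0), sx(nlab, 0), sy(nlab, 0), sz(nlab, 0);
  std::vector<double> sxx(nlab, 0), syy(nlab, 0), szz(nlab, 0);
  std::vector<double> sxy(nlab, 0), sxz(nlab, 0), syz(nlab, 0);
  std::vector<double> surf(nlab, 0);
  std::vector<std::vector<double> > bnd(nlab);
  double ax = dz, ay = dz, az = 1.0; // face areas: normal x -> 1*dz, etc.
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y)
      for (int z = 0; z < d.nz; ++z) {
        int l = labels[d.idx(z, y, x)];
        if (l <= 0) continue;
        int li = l - 1;
        if (li >= nlab) stop("label exceeds nlab");
        double X = x, Y = y, Z = z * dz;
        n[li] += 1;
        sx[li] += X; sy[li] += Y; sz[li] += Z;
        sxx[li] += X * X; syy[li] += Y * Y; szz[li] += Z * Z;
        sxy[li] += X * Y; sxz[li] += X * Z; syz[li] += Y * Z;
        double s = 0;
        if (x == 0 || labels[d.idx(z, y, x - 1)] != l) s += ax;
        if (x == d.nx - 1 || labels[d.idx(z, y, x + 1)] != l) s += ax;
        if (y == 0 || labels[d.idx(z, y - 1, x)] != l) s += ay;
        if (y == d.ny - 1 || labels[d.idx(z, y + 1, x)] != l) s += ay;
        if (z == 0 || labels[d.idx(z - 1, y, x)] != l) s += az;
        if (z == d.nz - 1 || labels[d.idx(z + 1, y, x)] != l) s += az;
        if (s > 0) {
          surf[li] += s;
          bnd[li].push_back(X);
          bnd[li].push_back(Y);
          bnd[li].push_back(Z);
        }
      }
  NumericMatrix stats(nlab, 11);
  List bl(nlab);
  for (int i = 0; i < nlab; ++i) {
    stats(i, 0) = n[i];
    stats(i, 1) = sx[i]; stats(i, 2) = sy[i]; stats(i, 3) = sz[i];
    stats(i, 4) = sxx[i]; stats(i, 5) = syy[i]; stats(i, 6) = szz[i];
    stats(i, 7) = sxy[i]; stats(i, 8) = sxz[i]; stats(i, 9) = syz[i];
    stats(i, 10) = surf[i] * (2.0 / 3.0);
    size_t m = bnd[i].size() / 3;
    NumericMatrix bm(m, 3);
    for (size_t j = 0; j < m; ++j) {
      bm(j, 0) = bnd[i][3 * j];
      bm(j, 1) = bnd[i][3 * j + 1];
      bm(j, 2) = bnd[i][3 * j + 2];
    }
    bl[i] = bm;
  }
  return List::create(_["stats"] = stats, _["boundary"] = bl);
}

// Max pairwise Euclidean distance between rows of a coordinate matrix.
// [[Rcpp::export]]
double cpp_feret(NumericMatrix pts) {
  R_xlen_t n = pts.nrow();
  double best = 0;
  for (R_xlen_t i = 0; i < n; ++i)
    for (R_xlen_t j = i + 1; j < n; ++j) {
      double dx = pts(i, 0) - pts(j, 0);
      double dy = pts(i, 1) - pts(j, 1);
      double dzv = pts(i, 2) - pts(j, 2);
      double d2 = dx * dx + dy * dy + dzv * dzv;
      if (d2 > best) best = d2;
    }
  return std::sqrt(best);
}

// ----------------------------------------------------------- polygon masks

// Even-odd (crossing number) point-in-polygon test for all pixel centers
// (x, y) = (col, row), 0-based, of an ny x nx slice.
// [[Rcpp::export]]
LogicalMatrix cpp_polygon_mask(int ny, int nx, NumericVector px,
                               NumericVector py) {
  int nv = px.size();
  LogicalMatrix out(ny, nx);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      bool inside = false;
      for (int i = 0, j = nv - 1; i < nv; j = i++) {
        if (((py[i] > y) != (py[j] > y)) &&
            (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i]))
          inside = !inside;
      }
      out(y, x) = inside;
    }
  return out;
}

// ----------------------------------------------------------------- phantoms

// Composite an anti-aliased solid shape into `vol` (modified copy returned):
// v <- v * (1 - a) + level * a where a is the sub-voxel occupancy fraction of
// the shape, estimated on an nsub^3 sub-grid.  type 0 = ball around p1;
// type 1 = capsule with axis p1-p2.  Coordinates and radius in nm; voxel
// (z,y,x) center at (x, y, z*dz).
// [[Rcpp::export]]
NumericVector cpp_render_shape(NumericVector vol, double dz, int type,
                               NumericVector p1, NumericVector p2,
                               double radius, double level, int nsub) {
  Dim3 d = get_dim(vol);
  NumericVector out = vol; // in-place by contract: caller owns a fresh copy
  double xlo = std::min(p1[0], p2[0]) - radius - 1;
  double xhi = std::max(p1[0], p2[0]) + radius + 1;
  double ylo = std::min(p1[1], p2[1]) - radius - 1;
  double yhi = std::max(p1[1], p2[1]) + radius + 1;
  double zlo = std::min(p1[2], p2[2]) - radius - 1;
  double zhi = std::max(p1[2], p2[2]) + radius + 1;
  int x0 = clampi((int)std::floor(xlo), 0, d.nx - 1);
  int x1 = clampi((int)std::ceil(xhi), 0, d.nx - 1);
  int y0 = clampi((int)std::floor(ylo), 0, d.ny - 1);
  int y1 = clampi((int)std::ceil(yhi), 0, d.ny - 1);
  int z0 = clampi((int)std::floor(zlo / dz), 0, d.nz - 1);
  int z1 = clampi((int)std::ceil(zhi / dz), 0, d.nz - 1);
  double r2 = radius * radius;
  double axx = p2[0] - p1[0], axy = p2[1] - p1[1], axz = p2[2] - p1[2];
  double alen2 = axx * axx + axy * axy + axz * axz;
  int ns3 = nsub * nsub * nsub;
  for (int x = x0; x <= x1; ++x)
    for (int y = y0; y <= y1; ++y)
      for (int z = z0; z <= z1; ++z) {
        int cnt = 0;
        for (int sx = 0; sx < nsub; ++sx) {
          double X = x - 0.5 + (sx + 0.5) / nsub;
          for (int sy = 0; sy < nsub; ++sy) {
            double Y = y - 0.5 + (sy + 0.5) / nsub;
            for (int sz = 0; sz < nsub; ++sz) {
              double Z = (z - 0.5 + (sz + 0.5) / nsub) * dz;
              double qx = X - p1[0], qy = Y - p1[1], qz = Z - p1[2];
              if (type == 1 && alen2 > 0) {
                double t = (qx * axx + qy * axy + qz * axz) / alen2;
                t = t < 0 ? 0 : (t > 1 ? 1 : t);
                qx -= t * axx; qy -= t * axy; qz -= t * axz;
              }
              if (qx * qx + qy * qy + qz * qz <= r2) ++cnt;
            }
          }
        }
        if (cnt > 0) {
          double a = (double)cnt / ns3;
          R_xlen_t i = d.idx(z, y, x);
          out[i] = out[i] * (1 - a) + level * a;
        }
      }
  return out;
}

// ------------------------------------------------- assignment (Hungarian)

// Jonker-Volgenant shortest augmenting path algorithm for the square
// assignment problem; cost(i, j) >= 0, forbidden pairs carry a large cost.
// Returns, for each row, the assigned column (1-based).
// [[Rcpp::export]]
IntegerVector cpp_hungarian(NumericMatrix cost) {
  int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0), v(n + 1, 0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, false);
    do {
      used[j0] = true;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j)
        if (!used[j]) {
          double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
          if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
          if (minv[j] < delta) { delta = minv[j]; j1 = j; }
        }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do {
      int j1 = way[j0];
      p[j0] = p[j1];
      j0 = j1;
    } while (j0);
  }
  IntegerVector row2col(n);
  for (int j = 1; j <= n; ++j)
    if (p[j] > 0) row2col[p[j] - 1] = j;
  return row2col;
}
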