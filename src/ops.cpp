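#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

// Voxel arrays are column-major (R layout): linear = i + nx*(j + ny*k), 0-based.

static inline double sample_trilinear(const double *v, int nx, int ny, int nz,
                                      double x, double y, double z) {
  // caller guarantees x in [0,nx-1] etc. (after clamping)
  int x0 = (int)std::floor(x); if (x0 > nx - 2) x0 = nx - 2; if (x0 < 0) x0 = 0;
  int y0 = (int)std::floor(y); if (y0 > ny - 2) y0 = ny - 2; if (y0 < 0) y0 = 0;
  int z0 = (int)std::floor(z); if (z0 > nz - 2) z0 = nz - 2; if (z0 < 0) z0 = 0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  if (nx == 1) { x0 = 0; fx = 0.0; }
  if (ny == 1) { y0 = 0; fy = 0.0; }
  if (nz == 1) { z0 = 0; fz = 0.0; }
  const size_t sx = 1, sy = nx, sz = (size_t)nx * ny;
  const double *p = v + x0 * sx + y0 * sy + z0 * sz;
  double c00 = p[0]       + fx * (p[sx]           - p[0]);
  double c10 = p[sy]      + fx * (p[sx + sy]      - p[sy]);
  double c01 = p[sz]      + fx * (p[sx + sz]      - p[sz]);
  double c11 = p[sy + sz] + fx * (p[sx + sy + sz] - p[sy + sz]);
  double c0 = c00 + fy * (c10 - c00);
  double c1 = c01 + fy * (c11 - c01);
  return c0 + fz * (c1 - c0);
}

// Resample a volume onto an output grid: continuous source index of output
// voxel (i,j,k) is M %*% c(i,j,k) + b (all 0-based). Returns sampled values
// and a support mask (true where the sample lies inside the source grid).
// [[Rcpp::export]]
List cpp_affine_sample(NumericVector vox, IntegerVector dim,
                       NumericMatrix M, NumericVector b,
                       IntegerVector outDim, double pad, bool nearest) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int ox = outDim[0], oy = outDim[1], oz = outDim[2];
  const double *v = REAL(vox);
  NumericVector out((R_xlen_t)ox * oy * oz);
  LogicalVector sup((R_xlen_t)ox * oy * oz);
  const double eps = 1e-9;
  R_xlen_t idx = 0;
  for (int k = 0; k < oz; ++k) {
    for (int j = 0; j < oy; ++j) {
      for (int i = 0; i < ox; ++i, ++idx) {
        double x = M(0,0)*i + M(0,1)*j + M(0,2)*k + b[0];
        double y = M(1,0)*i + M(1,1)*j + M(1,2)*k + b[1];
        double z = M(2,0)*i + M(2,1)*j + M(2,2)*k + b[2];
        bool inside = (x >= -eps && x <= nx - 1 + eps &&
                       y >= -eps && y <= ny - 1 + eps &&
                       z >= -eps && z <= nz - 1 + eps);
        if (!inside) { out[idx] = pad; sup[idx] = false; continue; }
        sup[idx] = true;
        if (nearest) {
          int xi = (int)std::lround(x), yi = (int)std::lround(y), zi = (int)std::lround(z);
          if (xi < 0) xi = 0; if (xi > nx-1) xi = nx-1;
          if (yi < 0) yi = 0; if (yi > ny-1) yi = ny-1;
          if (zi < 0) zi = 0; if (zi > nz-1) zi = nz-1;
          out[idx] = v[xi + (size_t)nx * (yi + (size_t)ny * zi)];
        } else {
          if (x < 0) x = 0; if (x > nx-1) x = nx-1;
          if (y < 0) y = 0; if (y > ny-1) y = ny-1;
          if (z < 0) z = 0; if (z > nz-1) z = nz-1;
          out[idx] = sample_trilinear(v, nx, ny, nz, x, y, z);
        }
      }
    }
  }
  return List::create(_["values"] = out, _["support"] = sup);
}

// Sample a volume at arbitrary continuous (0-based) voxel coordinates.
// [[Rcpp::export]]
List cpp_sample_points(NumericVector vox, IntegerVector dim,
                       NumericMatrix pts, double pad, bool nearest) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double *v = REAL(vox);
  const R_xlen_t n = pts.nrow();
  NumericVector out(n);
  LogicalVector ins(n);
  const double eps = 1e-9;
  for (R_xlen_t t = 0; t < n; ++t) {
    double x = pts(t,0), y = pts(t,1), z = pts(t,2);
    bool inside = (x >= -eps && x <= nx - 1 + eps &&
                   y >= -eps && y <= ny - 1 + eps &&
                   z >= -eps && z <= nz - 1 + eps);
    if (!inside) { out[t] = pad; ins[t] = false; continue; }
    ins[t] = true;
    if (nearest) {
      int xi = (int)std::lround(x), yi = (int)std::lround(y), zi = (int)std::lround(z);
      if (xi < 0) xi = 0; if (xi > nx-1) xi = nx-1;
      if (yi < 0) yi = 0; if (yi > ny-1) yi = ny-1;
      if (zi < 0) zi = 0; if (zi > nz-1) zi = nz-1;
      out[t] = v[xi + (size_t)nx * (yi + (size_t)ny * zi)];
    } else {
      if (x < 0) x = 0; if (x > nx-1) x = nx-1;
      if (y < 0) y = 0; if (y > ny-1) y = ny-1;
      if (z < 0) z = 0; if (z > nz-1) z = nz-1;
      out[t] = sample_trilinear(v, nx, ny, nz, x, y, z);
    }
  }
  return List::create(_["values"] = out, _["inside"] = ins);
}

static void conv1d_axis(std::vector<double> &buf, int nx, int ny, int nz,
                        int axis, const std::vector<double> &kernel) {
  const int r = ((int)kernel.size() - 1) / 2;
  const int n[3] = {nx, ny, nz};
  const size_t stride[3] = {1, (size_t)nx, (size_t)nx * ny};
  const int len = n[axis];
  const size_t st = stride[axis];
  std::vector<double> line(len);
  // iterate over all 1-D lines along `axis`; zero padding outside
  int a1 = (axis + 1) % 3, a2 = (axis + 2) % 3;
  for (int u = 0; u < n[a1]; ++u) {
    for (int w = 0; w < n[a2]; ++w) {
      size_t base = (size_t)u * stride[a1] + (size_t)w * stride[a2];
      for (int t = 0; t < len; ++t) line[t] = buf[base + (size_t)t * st];
      for (int t = 0; t < len; ++t) {
        double acc = 0.0;
        int lo = std::max(0, t - r), hi = std::min(len - 1, t + r);
        for (int s = lo; s <= hi; ++s) acc += line[s] * kernel[s - t + r];
        buf[base + (size_t)t * st] = acc;
      }
    }
  }
}

// Separable Gaussian convolution with zero padding; sigma per axis in voxels.
// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector vox, IntegerVector dim, NumericVector sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> buf(REAL(vox), REAL(vox) + (size_t)nx * ny * nz);
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma[axis];
    if (s <= 0) continue;
    int r = (int)std::ceil(4.0 * s);
    std::vector<double> k(2 * r + 1);
    double sum = 0.0;
    for (int t = -r; t <= r; ++t) { k[t + r] = std::exp(-0.5 * t * t / (s * s)); sum += k[t + r]; }
    for (size_t t = 0; t < k.size(); ++t) k[t] /= sum;
    conv1d_axis(buf, nx, ny, nz, axis, k);
  }
  NumericVector out((R_xlen_t)nx * ny * nz);
  std::copy(buf.begin(), buf.end(), REAL(out));
  return out;
}

// Connected-component labelling (6- or 26-connectivity), labels 1..n, 0 = background.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(nvox);
  std::vector<int> offs;
  std::vector<std::array<int,3> > doffs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int ad = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (ad == 0) continue;
        if (connectivity == 6 && ad != 1) continue;
        doffs.push_back({{dx, dy, dz}});
      }
  int cur = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t start = 0; start < nvox; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++cur;
    labels[start] = cur;
    stack.clear();
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int i = (int)(p % nx), j = (int)((p / nx) % ny), k = (int)(p / ((R_xlen_t)nx * ny));
      for (size_t d = 0; d < doffs.size(); ++d) {
        int ii = i + doffs[d][0], jj = j + doffs[d][1], kk = k + doffs[d][2];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
        R_xlen_t q = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
        if (mask[q] && labels[q] == 0) { labels[q] = cur; stack.push_back(q); }
      }
    }
  }
  return labels;
}

// Binary dilation/erosion with an explicit offset set (rows of `offsets`,
// voxel units). `outside` is the value assumed beyond the grid.
// [[Rcpp::export]]
LogicalVector cpp_morph(LogicalVector mask, IntegerVector dim,
                        IntegerMatrix offsets, bool dilate, bool outside) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  LogicalVector out(nvox);
  const int noff = offsets.nrow();
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i, ++idx) {
        bool res = dilate ? false : true;
        for (int d = 0; d < noff; ++d) {
          int ii = i + offsets(d,0), jj = j + offsets(d,1), kk = k + offsets(d,2);
          bool val;
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) val = outside;
          else val = mask[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)];
          if (dilate) { if (val) { res = true; break; } }
          else        { if (!val) { res = false; break; } }
        }
        out[idx] = res;
      }
    }
  }
  return out;
}

// Fill holes in each axial (k) slice: background (false) regions 4-connected
// to the slice border stay background; enclosed background becomes foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes_slices(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out = clone(mask);
  std::vector<char> reach((size_t)nx * ny);
  std::vector<int> stack;
  for (int k = 0; k < nz; ++k) {
    const R_xlen_t base = (R_xlen_t)nx * ny * k;
    std::fill(reach.begin(), reach.end(), 0);
    stack.clear();
    for (int i = 0; i < nx; ++i) {
      for (int j : {0, ny - 1}) {
        int p = i + nx * j;
        if (!mask[base + p] && !reach[p]) { reach[p] = 1; stack.push_back(p); }
      }
    }
    for (int j = 0; j < ny; ++j) {
      for (int i : {0, nx - 1}) {
        int p = i + nx * j;
        if (!mask[base + p] && !reach[p]) { reach[p] = 1; stack.push_back(p); }
      }
    }
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      int i = p % nx, j = p / nx;
      const int di[4] = {1, -1, 0, 0}, dj[4] = {0, 0, 1, -1};
      for (int d = 0; d < 4; ++d) {
        int ii = i + di[d], jj = j + dj[d];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny) continue;
        int q = ii + nx * jj;
        if (!mask[base + q] && !reach[q]) { reach[q] = 1; stack.push_back(q); }
      }
    }
    for (int p = 0; p < nx * ny; ++p)
      if (!mask[base + p] && !reach[p]) out[base + p] = true;
  }
  return out;
}
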