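#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Neighbourhood offsets for 6/18/26 connectivity on a 3D lattice.
static std::vector<std::array<int, 3>> neighbour_offsets(int connectivity) {
  std::vector<std::array<int, 3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int ord = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (ord == 0) continue;
        if (connectivity == 6 && ord > 1) continue;
        if (connectivity == 18 && ord > 2) continue;
        off.push_back({dx, dy, dz});
      }
  return off;
}

// Connected-component labelling of a binary volume. Labels are assigned in
// raster-scan discovery order starting at 1; 0 marks background.
// [[Rcpp::export(name = ".cpp_label3d")]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(n, 0);
  std::vector<std::array<int, 3>> off = neighbour_offsets(connectivity);
  std::vector<R_xlen_t> stack;
  int next_label = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++next_label;
    labels[i] = next_label;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int x = cur % nx, y = (cur / nx) % ny, z = cur / ((R_xlen_t)nx * ny);
      for (const auto &o : off) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
        R_xlen_t j = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[j] && labels[j] == 0) {
          labels[j] = next_label;
          stack.push_back(j);
        }
      }
    }
  }
  labels.attr("n_components") = next_label;
  return labels;
}

// One-dimensional squared distance transform (lower envelope of parabolas).
static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n) {
  static const double INF = 1e30;
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Squared Euclidean distance transform of a binary volume: for each foreground
// voxel, squared distance (voxel units) to the nearest background voxel.
// Voxels outside the array are treated as foreground (pad in the caller if the
// array border should count as background).
// [[Rcpp::export(name = ".cpp_edt3d")]]
NumericVector cpp_edt3d(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  static const double INF = 1e30;
  NumericVector d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = mask[i] ? INF : 0.0;
  std::vector<double> f(std::max(nx, std::max(ny, nz))), g(f.size());
  // pass along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
      for (int x = 0; x < nx; ++x) f[x] = d[base + x];
      dt1d(f, g, nx);
      for (int x = 0; x < nx; ++x) d[base + x] = g[x];
    }
  // pass along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = d[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
      dt1d(f, g, ny);
      for (int y = 0; y < ny; ++y) d[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = g[y];
    }
  // pass along z
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = d[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
      dt1d(f, g, nz);
      for (int z = 0; z < nz; ++z) d[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = g[z];
    }
  return d;
}

// Cubic-window median filter with window truncation at the array border.
// [[Rcpp::export(name = ".cpp_median3d")]]
NumericVector cpp_median3d(NumericVector values, IntegerVector dims, int radius) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  std::vector<double> window;
  window.reserve((2 * radius + 1) * (2 * radius + 1) * (2 * radius + 1));
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        window.clear();
        for (int dz = -radius; dz <= radius; ++dz)
          for (int dy = -radius; dy <= radius; ++dy)
            for (int dx = -radius; dx <= radius; ++dx) {
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
              window.push_back(values[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)]);
            }
        size_t m = window.size() / 2;
        std::nth_element(window.begin(), window.begin() + m, window.end());
        double med = window[m];
        if (window.size() % 2 == 0) {
          double lo = *std::max_element(window.begin(), window.begin() + m);
          med = 0.5 * (med + lo);
        }
        out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = med;
      }
  return out;
}

// Morphological grayscale reconstruction by dilation (marker under mask),
// hybrid raster/anti-raster sweeps followed by a FIFO queue (Vincent 1993).
// [[Rcpp::export(name = ".cpp_grayreconstruct")]]
NumericVector cpp_grayreconstruct(NumericVector marker, NumericVector mask,
                                  IntegerVector dims, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector J(n);
  for (R_xlen_t i = 0; i < n; ++i) J[i] = std::min(marker[i], mask[i]);
  std::vector<std::array<int, 3>> off = neighbour_offsets(connectivity);
  bool changed = true;
  int sweeps = 0;
  while (changed && sweeps < 1000) {
    changed = false;
    ++sweeps;
    // forward raster
    for (R_xlen_t i = 0; i < n; ++i) {
      int x = i % nx, y = (i / nx) % ny, z = i / ((R_xlen_t)nx * ny);
      double m = J[i];
      for (const auto &o : off) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
        R_xlen_t j = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (j < i && J[j] > m) m = J[j];
      }
      m = std::min(m, mask[i]);
      if (m > J[i]) { J[i] = m; changed = true; }
    }
    // backward raster
    for (R_xlen_t i = n - 1; i >= 0; --i) {
      int x = i % nx, y = (i / nx) % ny, z = i / ((R_xlen_t)nx * ny);
      double m = J[i];
      for (const auto &o : off) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
        R_xlen_t j = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (j > i && J[j] > m) m = J[j];
      }
      m = std::min(m, mask[i]);
      if (m > J[i]) { J[i] = m; changed = true; }
      if (i == 0) break;
    }
  }
  return J;
}

// Gray-level co-occurrence accumulation: bins is a 0-based quantized volume
// with -1 outside the region of interest; offsets is an n x 3 matrix of voxel
// displacements. Pairs are counted in both directions (symmetric GLCM).
// [[Rcpp::export(name = ".cpp_glcm_accumulate")]]
NumericMatrix cpp_glcm_accumulate(IntegerVector bins, IntegerVector dims,
                                  IntegerMatrix offsets, int levels) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericMatrix counts(levels, levels);
  const int noff = offsets.nrow();
  for (R_xlen_t i = 0; i < n; ++i) {
    int a = bins[i];
    if (a < 0) continue;
    int x = i % nx, y = (i / nx) % ny, z = i / ((R_xlen_t)nx * ny);
    for (int k = 0; k < noff; ++k) {
      int xx = x + offsets(k, 0), yy = y + offsets(k, 1), zz = z + offsets(k, 2);
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
      int b = bins[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
      if (b < 0) continue;
      counts(a, b) += 1.0;
      counts(b, a) += 1.0;
    }
  }
  return counts;
}
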