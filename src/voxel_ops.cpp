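#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <queue>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable 1D lower-envelope passes along each axis.
// ---------------------------------------------------------------------------

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  static const double INF = 1e20;
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// phase: logical array (true = voxels of the phase of interest); returns squared
// distance, in voxel units, from each phase voxel center to the nearest
// non-phase voxel center (0 on non-phase voxels).
// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector phase, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double INF = 1e20;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = phase[i] ? INF : 0.0;
  std::vector<double> f, d;
  // pass along x (fastest-varying)
  f.resize(nx); d.resize(nx);
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; i++) f[i] = out[base + i];
      dt1d(f, d, nx);
      for (int i = 0; i < nx; i++) out[base + i] = d[i];
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; j++) f[j] = out[base + (R_xlen_t)nx * j];
      dt1d(f, d, ny);
      for (int j = 0; j < ny; j++) out[base + (R_xlen_t)nx * j] = d[j];
    }
  // pass along z
  if (nz > 1) {
    f.resize(nz); d.resize(nz);
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        R_xlen_t base = i + (R_xlen_t)nx * j;
        R_xlen_t stride = (R_xlen_t)nx * ny;
        for (int k = 0; k < nz; k++) f[k] = out[base + stride * k];
        dt1d(f, d, nz);
        for (int k = 0; k < nz; k++) out[base + stride * k] = d[k];
      }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Local thickness by maximal inscribed spheres: each phase voxel carries the
// diameter of the largest sphere (centered anywhere in the phase) containing
// it. Sphere radii come from the EDT; a sphere centered at c with squared
// distance d2 to the nearest background voxel center has inscribed radius
// sqrt(d2) - 1/2 (the interface lies half a voxel short of that center), so
// its diameter is 2*sqrt(d2) - 1 voxels.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector local_thickness_cpp(LogicalVector phase, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector d2 = edt_sq_cpp(phase, dims);
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector th(n);
  for (R_xlen_t i = 0; i < n; i++) th[i] = 0.0;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        R_xlen_t idx = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        if (!phase[idx]) continue;
        double r = std::sqrt(d2[idx]);         // paint radius (to bg center)
        double diam = 2.0 * r - 1.0;           // interface half a voxel short
        int ri = (int)std::floor(r);
        double r2 = r * r;
        int k0 = std::max(0, k - ri), k1 = std::min(nz - 1, k + ri);
        int j0 = std::max(0, j - ri), j1 = std::min(ny - 1, j + ri);
        int i0 = std::max(0, i - ri), i1 = std::min(nx - 1, i + ri);
        for (int kk = k0; kk <= k1; kk++) {
          double dz2 = (kk - k) * (double)(kk - k);
          for (int jj = j0; jj <= j1; jj++) {
            double dyz2 = dz2 + (jj - j) * (double)(jj - j);
            if (dyz2 > r2) continue;
            R_xlen_t base = (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            for (int ii = i0; ii <= i1; ii++) {
              if (dyz2 + (ii - i) * (double)(ii - i) <= r2) {
                R_xlen_t t = base + ii;
                if (phase[t] && th[t] < diam) th[t] = diam;
              }
            }
          }
        }
        if (th[idx] < diam) th[idx] = diam;  // sphere always covers own center
      }
  return th;
}

// ---------------------------------------------------------------------------
// Face-connected (6-connectivity) components spanning the first and last
// slice; returns a logical mask keeping only voxels in spanning components.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalVector spanning_components_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<int> label(n, 0);
  int next = 0;
  std::vector<char> touches_bottom, touches_top;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || label[s]) continue;
    next++;
    touches_bottom.push_back(0);
    touches_top.push_back(0);
    stack.clear();
    stack.push_back(s);
    label[s] = next;
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int i = (int)(v % nx);
      int j = (int)((v / nx) % ny);
      int k = (int)(v / ((R_xlen_t)nx * ny));
      if (k == 0) touches_bottom[next - 1] = 1;
      if (k == nz - 1) touches_top[next - 1] = 1;
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int d = 0; d < 6; d++) {
        int ii = i + di[d], jj = j + dj[d], kk = k + dk[d];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
        R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
        if (mask[w] && !label[w]) {
          label[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t s = 0; s < n; s++) {
    int l = label[s];
    out[s] = (l > 0 && touches_bottom[l - 1] && touches_top[l - 1]);
  }
  return out;
}

// Number of 6-connected foreground components.
// [[Rcpp::export]]
int count_components_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<R_xlen_t> stack;
  int count = 0;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || seen[s]) continue;
    count++;
    stack.clear();
    stack.push_back(s);
    seen[s] = 1;
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int i = (int)(v % nx);
      int j = (int)((v / nx) % ny);
      int k = (int)(v / ((R_xlen_t)nx * ny));
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int d = 0; d < 6; d++) {
        int ii = i + di[d], jj = j + dj[d], kk = k + dk[d];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
        R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
        if (mask[w] && !seen[w]) {
          seen[w] = 1;
          stack.push_back(w);
        }
      }
    }
  }
  return count;
}

// ---------------------------------------------------------------------------
// Separable Gaussian smoothing with reflective boundaries (phantom texture).
// ---------------------------------------------------------------------------

static void blur_axis(std::vector<double>& a, int nx, int ny, int nz,
                      int axis, const std::vector<double>& kern) {
  const int kr = ((int)kern.size() - 1) / 2;
  const int len = axis == 0 ? nx : (axis == 1 ? ny : nz);
  std::vector<double> line(len), res(len);
  R_xlen_t stride = axis == 0 ? 1 : (axis == 1 ? (R_xlen_t)nx : (R_xlen_t)nx * ny);
  int n1 = axis == 0 ? ny : nx;
  int n2 = axis == 2 ? ny : nz;
  for (int b = 0; b < n2; b++)
    for (int a1 = 0; a1 < n1; a1++) {
      R_xlen_t base;
      if (axis == 0) base = (R_xlen_t)nx * (a1 + (R_xlen_t)ny * b);
      else if (axis == 1) base = a1 + (R_xlen_t)nx * ny * b;
      else base = a1 + (R_xlen_t)nx * b;
      for (int t = 0; t < len; t++) line[t] = a[base + stride * t];
      for (int t = 0; t < len; t++) {
        double s = 0.0;
        for (int u = -kr; u <= kr; u++) {
          int p = t + u;
          if (p < 0) p = -p - 1;
          if (p >= len) p = 2 * len - p - 1;
          s += kern[u + kr] * line[p];
        }
        res[t] = s;
      }
      for (int t = 0; t < len; t++) a[base + stride * t] = res[t];
    }
}

// [[Rcpp::export]]
NumericVector gauss_blur3d_cpp(NumericVector field, IntegerVector dims, double sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  int kr = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> kern(2 * kr + 1);
  double s = 0.0;
  for (int u = -kr; u <= kr; u++) {
    kern[u + kr] = std::exp(-0.5 * u * u / (sigma * sigma));
    s += kern[u + kr];
  }
  for (auto& v : kern) v /= s;
  std::vector<double> a(n);
  for (R_xlen_t i = 0; i < n; i++) a[i] = field[i];
  blur_axis(a, nx, ny, nz, 0, kern);
  blur_axis(a, nx, ny, nz, 1, kern);
  if (nz > 1) blur_axis(a, nx, ny, nz, 2, kern);
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = a[i];
  return out;
}

// ---------------------------------------------------------------------------
// Mean-intercept-length sampling: for each direction, march parallel test
// lines with random in-plane offsets through the grid, accumulating bone path
// length and the number of void->bone crossings inside the region of interest.
// Random offsets use R's RNG so results are reproducible under set.seed().
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix mil_sample_cpp(LogicalVector mask, LogicalVector region,
                             IntegerVector dims, NumericMatrix dirs,
                             int n_lines, double step) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nd = dirs.nrow();
  NumericMatrix out(nd, 2); // columns: total bone length (voxel units), intercepts
  const double cx = nx / 2.0, cy = ny / 2.0, cz = nz / 2.0;
  const double R = 0.5 * std::sqrt((double)nx * nx + (double)ny * ny + (double)nz * nz) + 1.0;
  for (int d = 0; d < nd; d++) {
    double ux = dirs(d, 0), uy = dirs(d, 1), uz = dirs(d, 2);
    // orthonormal in-plane basis
    double ax = 1.0, ay = 0.0, az = 0.0;
    if (std::fabs(ux) > 0.9) { ax = 0.0; ay = 1.0; }
    double e1x = uy * az - uz * ay, e1y = uz * ax - ux * az, e1z = ux * ay - uy * ax;
    double n1 = std::sqrt(e1x * e1x + e1y * e1y + e1z * e1z);
    e1x /= n1; e1y /= n1; e1z /= n1;
    double e2x = uy * e1z - uz * e1y, e2y = uz * e1x - ux * e1z, e2z = ux * e1y - uy * e1x;
    double blen = 0.0;
    double nint = 0.0;
    for (int l = 0; l < n_lines; l++) {
      double r = R * std::sqrt(unif_rand());
      double phi = 2.0 * M_PI * unif_rand();
      double ox = cx + r * std::cos(phi) * e1x + r * std::sin(phi) * e2x;
      double oy = cy + r * std::cos(phi) * e1y + r * std::sin(phi) * e2y;
      double oz = cz + r * std::cos(phi) * e1z + r * std::sin(phi) * e2z;
      bool prev_bone = false;
      bool prev_in = false;
      int nb = 0;
      for (double t = -R; t <= R; t += step) {
        double x = ox + t * ux, y = oy + t * uy, z = oz + t * uz;
        int i = (int)std::floor(x), j = (int)std::floor(y), k = (int)std::floor(z);
        bool in = (i >= 0 && i < nx && j >= 0 && j < ny && k >= 0 && k < nz);
        bool bone = false;
        if (in) {
          R_xlen_t idx = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
          in = region[idx];
          bone = in && mask[idx];
        }
        if (bone) {
          nb++;
          if (!prev_bone || !prev_in) nint += 1.0; // entered bone
        }
        prev_bone = bone;
        prev_in = in;
      }
      blen += nb * step;
    }
    out(d, 0) = blen;
    out(d, 1) = nint;
  }
  return out;
}
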