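// Low-level 3D voxel operations for nuclear segmentation.
// All arrays are R arrays with dim = c(nz, ny, nx); linear index
// (0-based) is z + nz * (y + ny * x), matching R's column-major layout.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

static inline R_xlen_t vidx(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * x);
}

// 6-connected neighbour offsets in (z, y, x)
static const int DZ[6] = {-1, 1, 0, 0, 0, 0};
static const int DY[6] = {0, 0, -1, 1, 0, 0};
static const int DX[6] = {0, 0, 0, 0, -1, 1};

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask size does not match dims");
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int z = (int)(cur % nz);
      R_xlen_t rest = cur / nz;
      int y = (int)(rest % ny);
      int x = (int)(rest / ny);
      for (int k = 0; k < 6; ++k) {
        int zz = z + DZ[k], yy = y + DY[k], xx = x + DX[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        R_xlen_t j = vidx(zz, yy, xx, nz, ny);
        if (mask[j] && lab[j] == 0) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  lab.attr("n_labels") = next;
  return lab;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher), applied
// along one axis of f in place via gather/scatter with stride.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z, int n) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance (in voxels) from each foreground voxel to the
// nearest background voxel; 0 on background.
// [[Rcpp::export]]
NumericVector cpp_distance_transform(LogicalVector fg, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (fg.size() != n) stop("fg size does not match dims");
  const double INF = 1e30;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = fg[i] ? INF : 0.0;

  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along z
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = vidx(0, y, x, nz, ny);
      for (int zi = 0; zi < nz; ++zi) f[zi] = g[base + zi];
      dt1d(f, d, v, z, nz);
      for (int zi = 0; zi < nz; ++zi) g[base + zi] = d[zi];
    }
  // pass along y
  for (int x = 0; x < nx; ++x)
    for (int zi = 0; zi < nz; ++zi) {
      for (int y = 0; y < ny; ++y) f[y] = g[vidx(zi, y, x, nz, ny)];
      dt1d(f, d, v, z, ny);
      for (int y = 0; y < ny; ++y) g[vidx(zi, y, x, nz, ny)] = d[y];
    }
  // pass along x
  for (int y = 0; y < ny; ++y)
    for (int zi = 0; zi < nz; ++zi) {
      for (int x = 0; x < nx; ++x) f[x] = g[vidx(zi, y, x, nz, ny)];
      dt1d(f, d, v, z, nx);
      for (int x = 0; x < nx; ++x) g[vidx(zi, y, x, nz, ny)] = d[x];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(g[i]);
  out.attr("dim") = dims;
  return out;
}

// Separable Gaussian smoothing with reflected boundaries.
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector img, IntegerVector dims,
                               double sigma) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (img.size() != n) stop("img size does not match dims");
  if (sigma <= 0) return clone(img);
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> kern(2 * r + 1);
  double ksum = 0.0;
  for (int i = -r; i <= r; ++i) {
    kern[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    ksum += kern[i + r];
  }
  for (double &k : kern) k /= ksum;

  std::vector<double> a(img.begin(), img.end()), b(n);
  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> line(nmax), out(nmax);

  auto conv_line = [&](int len) {
    for (int i = 0; i < len; ++i) {
      double s = 0.0;
      for (int k = -r; k <= r; ++k) {
        int j = i + k;
        if (j < 0) j = -j - 1;            // reflect
        if (j >= len) j = 2 * len - j - 1;
        if (j < 0) j = 0;                 // very short lines
        if (j >= len) j = len - 1;
        s += kern[k + r] * line[j];
      }
      out[i] = s;
    }
  };

  // z
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = vidx(0, y, x, nz, ny);
      for (int zi = 0; zi < nz; ++zi) line[zi] = a[base + zi];
      conv_line(nz);
      for (int zi = 0; zi < nz; ++zi) b[base + zi] = out[zi];
    }
  std::swap(a, b);
  // y
  for (int x = 0; x < nx; ++x)
    for (int zi = 0; zi < nz; ++zi) {
      for (int y = 0; y < ny; ++y) line[y] = a[vidx(zi, y, x, nz, ny)];
      conv_line(ny);
      for (int y = 0; y < ny; ++y) b[vidx(zi, y, x, nz, ny)] = out[y];
    }
  std::swap(a, b);
  // x
  for (int y = 0; y < ny; ++y)
    for (int zi = 0; zi < nz; ++zi) {
      for (int x = 0; x < nx; ++x) line[x] = a[vidx(zi, y, x, nz, ny)];
      conv_line(nx);
      for (int x = 0; x < nx; ++x) b[vidx(zi, y, x, nz, ny)] = out[x];
    }

  NumericVector res(n);
  for (R_xlen_t i = 0; i < n; ++i) res[i] = b[i];
  res.attr("dim") = dims;
  return res;
}

// Local maxima of img within a Chebyshev window of given radius,
// restricted to voxels with img > minval. Plateaus give multiple TRUEs;
// the caller merges them with cpp_label_components.
// [[Rcpp::export]]
LogicalVector cpp_local_maxima(NumericVector img, IntegerVector dims,
                               int radius, double minval) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  LogicalVector res(n, false);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = vidx(z, y, x, nz, ny);
        double v = img[i];
        if (v <= minval) continue;
        bool ismax = true;
        for (int dx = -radius; dx <= radius && ismax; ++dx)
          for (int dy = -radius; dy <= radius && ismax; ++dy)
            for (int dz = -radius; dz <= radius && ismax; ++dz) {
              int zz = z + dz, yy = y + dy, xx = x + dx;
              if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 ||
                  xx >= nx)
                continue;
              if (img[vidx(zz, yy, xx, nz, ny)] > v) ismax = false;
            }
        res[i] = ismax;
      }
  res.attr("dim") = dims;
  return res;
}

struct QNode {
  double prio;
  R_xlen_t order;
  R_xlen_t idx;
};
struct QNodeCmp {
  bool operator()(const QNode &a, const QNode &b) const {
    if (a.prio != b.prio) return a.prio > b.prio; // min-heap on priority
    return a.order > b.order;                     // FIFO tie-break
  }
};

// Seeded watershed by priority flooding: flood from seed voxels in order
// of increasing priority (use the negated distance transform so basins
// grow outward from distance maxima), restricted to mask.
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector priority, IntegerVector seed_lab,
                            LogicalVector mask, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  std::priority_queue<QNode, std::vector<QNode>, QNodeCmp> pq;
  R_xlen_t order = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (seed_lab[i] > 0 && mask[i]) {
      lab[i] = seed_lab[i];
      pq.push({priority[i], order++, i});
    }
  }
  while (!pq.empty()) {
    QNode node = pq.top();
    pq.pop();
    R_xlen_t cur = node.idx;
    int curlab = lab[cur];
    int z = (int)(cur % nz);
    R_xlen_t rest = cur / nz;
    int y = (int)(rest % ny);
    int x = (int)(rest / ny);
    for (int k = 0; k < 6; ++k) {
      int zz = z + DZ[k], yy = y + DY[k], xx = x + DX[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      R_xlen_t j = vidx(zz, yy, xx, nz, ny);
      if (mask[j] && lab[j] == 0) {
        lab[j] = curlab;
        double p = priority[j] > node.prio ? priority[j] : node.prio;
        pq.push({p, order++, j});
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Multi-source breadth-first region growing over the foreground mask:
// each seed claims the voxels nearest to it (in BFS steps), which
// partitions merged blobs between their seeds. Seeds on background get a
// single-voxel label.
// [[Rcpp::export]]
IntegerVector cpp_region_grow(LogicalVector mask, IntegerMatrix seeds,
                              IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  std::queue<R_xlen_t> q;
  for (int s = 0; s < seeds.nrow(); ++s) {
    int z = seeds(s, 0), y = seeds(s, 1), x = seeds(s, 2); // 0-based
    if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx)
      stop("seed outside stack");
    R_xlen_t i = vidx(z, y, x, nz, ny);
    lab[i] = s + 1;
    if (mask[i]) q.push(i);
  }
  while (!q.empty()) {
    R_xlen_t cur = q.front();
    q.pop();
    int curlab = lab[cur];
    int z = (int)(cur % nz);
    R_xlen_t rest = cur / nz;
    int y = (int)(rest % ny);
    int x = (int)(rest / ny);
    for (int k = 0; k < 6; ++k) {
      int zz = z + DZ[k], yy = y + DY[k], xx = x + DX[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      R_xlen_t j = vidx(zz, yy, xx, nz, ny);
      if (mask[j] && lab[j] == 0) {
        lab[j] = curlab;
        q.push(j);
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
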