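// 3D primitives for anisotropic confocal stacks.
// All arrays arrive from R as numeric/integer vectors with dim = c(nz, ny, nx)
// and column-major layout, i.e. index = z + nz*(y + ny*x). Physical spacing
// (dz, dy, dx) in micrometres is carried explicitly; every distance computed
// here is Euclidean in micrometres, never in voxel counts.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

// Felzenszwalb & Huttenlocher 1D squared-distance transform with sample
// spacing `step`. f holds squared distances on input, d on output.
void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
          double step) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  for (int q = 1; q < n; q++) {
    double qq = q * step, vv;
    double s;
    for (;;) {
      vv = v[k] * step;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2 * qq - 2 * vv);
      if (s <= z[k]) {
        k--;
      } else {
        break;
      }
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double qq = q * step;
    while (z[k + 1] < qq) k++;
    double vv = v[k] * step;
    d[q] = (qq - vv) * (qq - vv) + f[v[k]];
  }
}

inline int64_t idx3(int z, int y, int x, int nz, int ny) {
  return (int64_t)z + (int64_t)nz * ((int64_t)y + (int64_t)ny * x);
}

}  // namespace

// Euclidean distance (um) from each foreground voxel to the nearest
// background voxel. Voxels outside the grid count as background, so objects
// clipped by the field edge get small distances there.
// [[Rcpp::export(name = ".cpp_edt3d")]]
NumericVector cpp_edt3d(LogicalVector mask, IntegerVector dims,
                        NumericVector spacing) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  const int64_t n = (int64_t)nz * ny * nx;
  const double big = 1e30;
  NumericVector out(n);
  for (int64_t i = 0; i < n; i++) out[i] = mask[i] ? big : 0.0;

  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax);

  // pass along z
  for (int x = 0; x < nx; x++)
    for (int y = 0; y < ny; y++) {
      int64_t base = idx3(0, y, x, nz, ny);
      for (int z = 0; z < nz; z++) f[z] = out[base + z];
      dt1d(f, d, nz, dz);
      for (int z = 0; z < nz; z++) out[base + z] = d[z];
    }
  double* op = REAL(out);
  // pass along y: buffer each (z, y) plane at fixed x for locality
  {
    std::vector<double> plane((size_t)nz * ny);
    for (int x = 0; x < nx; x++) {
      double* base = op + idx3(0, 0, x, nz, ny);
      std::copy(base, base + (size_t)nz * ny, plane.begin());
      for (int z = 0; z < nz; z++) {
        for (int y = 0; y < ny; y++) f[y] = plane[(size_t)nz * y + z];
        dt1d(f, d, ny, dy);
        for (int y = 0; y < ny; y++) plane[(size_t)nz * y + z] = d[y];
      }
      std::copy(plane.begin(), plane.end(), base);
    }
  }
  // pass along x: buffer each (z, x) plane at fixed y
  {
    std::vector<double> plane((size_t)nz * nx);
    for (int y = 0; y < ny; y++) {
      for (int x = 0; x < nx; x++) {
        const double* src = op + idx3(0, y, x, nz, ny);
        std::copy(src, src + nz, plane.begin() + (size_t)nz * x);
      }
      for (int z = 0; z < nz; z++) {
        for (int x = 0; x < nx; x++) f[x] = plane[(size_t)nz * x + z];
        dt1d(f, d, nx, dx);
        for (int x = 0; x < nx; x++) plane[(size_t)nz * x + z] = d[x];
      }
      for (int x = 0; x < nx; x++) {
        double* dst = op + idx3(0, y, x, nz, ny);
        std::copy(plane.begin() + (size_t)nz * x,
                  plane.begin() + (size_t)nz * (x + 1), dst);
      }
    }
  }
  // clip edge effect: distance to the grid border also counts as background
  for (int x = 0; x < nx; x++)
    for (int y = 0; y < ny; y++)
      for (int z = 0; z < nz; z++) {
        int64_t i = idx3(z, y, x, nz, ny);
        if (out[i] <= 0) continue;
        double db = std::min(std::min((z + 1) * dz, (nz - z) * dz),
                             std::min(std::min((y + 1) * dy, (ny - y) * dy),
                                      std::min((x + 1) * dx, (nx - x) * dx)));
        double dd = std::sqrt(out[i]);
        out[i] = std::min(dd, db);
      }
  return out;
}

// 6-connected components of a logical 3D mask; labels 1..k in scan order.
// [[Rcpp::export(name = ".cpp_label3d")]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int64_t n = (int64_t)nz * ny * nx;
  IntegerVector lab(n);
  std::vector<int64_t> stack;
  int next = 0;
  for (int64_t start = 0; start < n; start++) {
    if (!mask[start] || lab[start]) continue;
    next++;
    lab[start] = next;
    stack.push_back(start);
    while (!stack.empty()) {
      int64_t i = stack.back();
      stack.pop_back();
      int x = (int)(i / ((int64_t)nz * ny));
      int rem = (int)(i - (int64_t)x * nz * ny);
      int y = rem / nz, z = rem % nz;
      const int dzs[6] = {1, -1, 0, 0, 0, 0};
      const int dys[6] = {0, 0, 1, -1, 0, 0};
      const int dxs[6] = {0, 0, 0, 0, 1, -1};
      for (int k = 0; k < 6; k++) {
        int zz = z + dzs[k], yy = y + dys[k], xx = x + dxs[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        int64_t j = idx3(zz, yy, xx, nz, ny);
        if (mask[j] && !lab[j]) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  return lab;
}

// Local maxima (26-neighbourhood, >= with plateau inclusion) of a distance
// field restricted to the foreground; returns 1-based linear indices in
// deterministic scan order.
// [[Rcpp::export(name = ".cpp_local_maxima3d")]]
NumericVector cpp_local_maxima3d(NumericVector dist, IntegerVector dims,
                                 double floor_val) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  std::vector<double> hits;
  for (int x = 0; x < nx; x++)
    for (int y = 0; y < ny; y++)
      for (int z = 0; z < nz; z++) {
        int64_t i = idx3(z, y, x, nz, ny);
        double v = dist[i];
        if (v <= floor_val) continue;
        bool top = true;
        for (int az = -1; az <= 1 && top; az++)
          for (int ay = -1; ay <= 1 && top; ay++)
            for (int ax = -1; ax <= 1 && top; ax++) {
              if (!az && !ay && !ax) continue;
              int zz = z + az, yy = y + ay, xx = x + ax;
              if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 ||
                  xx >= nx)
                continue;
              if (dist[idx3(zz, yy, xx, nz, ny)] > v) top = false;
            }
        if (top) hits.push_back((double)(i + 1));
      }
  return wrap(hits);
}

// Seeded watershed by priority flood on -dist: seeds carry labels > 0;
// growth is 6-connected within the foreground, highest distance first,
// ties broken by smaller linear index (deterministic).
// [[Rcpp::export(name = ".cpp_watershed_seeded")]]
IntegerVector cpp_watershed_seeded(NumericVector dist, IntegerVector seeds,
                                   LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int64_t n = (int64_t)nz * ny * nx;
  IntegerVector lab(n);
  struct Node {
    double d;
    int64_t i;
  };
  struct Cmp {
    bool operator()(const Node& a, const Node& b) const {
      if (a.d != b.d) return a.d < b.d;  // max-heap on distance
      return a.i > b.i;                  // then smallest index first
    }
  };
  std::priority_queue<Node, std::vector<Node>, Cmp> pq;
  for (int64_t i = 0; i < n; i++) {
    if (seeds[i] > 0) {
      lab[i] = seeds[i];
      pq.push({dist[i], i});
    }
  }
  const int dzs[6] = {1, -1, 0, 0, 0, 0};
  const int dys[6] = {0, 0, 1, -1, 0, 0};
  const int dxs[6] = {0, 0, 0, 0, 1, -1};
  while (!pq.empty()) {
    Node nd = pq.top();
    pq.pop();
    int64_t i = nd.i;
    int x = (int)(i / ((int64_t)nz * ny));
    int rem = (int)(i - (int64_t)x * nz * ny);
    int y = rem / nz, z = rem % nz;
    int li = lab[i];
    for (int k = 0; k < 6; k++) {
      int zz = z + dzs[k], yy = y + dys[k], xx = x + dxs[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      int64_t j = idx3(zz, yy, xx, nz, ny);
      if (mask[j] && !lab[j]) {
        lab[j] = li;
        pq.push({dist[j], j});
      }
    }
  }
  return lab;
}

// Separable convolution of a 3D array along one axis (0=z,1=y,2=x) with an
// odd-length kernel; replicate padding at the borders. Implemented as slab
// accumulation (contiguous inner loops) to stay cache-friendly on large
// stacks.
// [[Rcpp::export(name = ".cpp_conv_axis3d")]]
NumericVector cpp_conv_axis3d(NumericVector arr, IntegerVector dims,
                              NumericVector kernel, int axis) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int kl = kernel.size(), half = kl / 2;
  NumericVector out(arr.size());
  const double* in = REAL(arr);
  double* o = REAL(out);
  const double* kn = REAL(kernel);

  if (axis == 2) {  // slab = contiguous nz*ny block per x
    const int64_t B = (int64_t)nz * ny;
    for (int x = 0; x < nx; x++) {
      double* os = o + B * x;
      for (int k = 0; k < kl; k++) {
        int s = x + k - half;
        if (s < 0) s = 0;
        if (s >= nx) s = nx - 1;
        const double* is = in + B * s;
        const double w = kn[k];
        if (k == 0)
          for (int64_t i = 0; i < B; i++) os[i] = w * is[i];
        else
          for (int64_t i = 0; i < B; i++) os[i] += w * is[i];
      }
    }
  } else if (axis == 1) {  // run = contiguous nz column per (y, x)
    for (int x = 0; x < nx; x++)
      for (int y = 0; y < ny; y++) {
        double* os = o + idx3(0, y, x, nz, ny);
        for (int k = 0; k < kl; k++) {
          int s = y + k - half;
          if (s < 0) s = 0;
          if (s >= ny) s = ny - 1;
          const double* is = in + idx3(0, s, x, nz, ny);
          const double w = kn[k];
          if (k == 0)
            for (int i = 0; i < nz; i++) os[i] = w * is[i];
          else
            for (int i = 0; i < nz; i++) os[i] += w * is[i];
        }
      }
  } else {  // z: stride-1 lines
    std::vector<double> line(nz);
    for (int x = 0; x < nx; x++)
      for (int y = 0; y < ny; y++) {
        const double* is = in + idx3(0, y, x, nz, ny);
        double* os = o + idx3(0, y, x, nz, ny);
        for (int t = 0; t < nz; t++) line[t] = is[t];
        for (int t = 0; t < nz; t++) {
          double acc = 0;
          for (int k = 0; k < kl; k++) {
            int s = t + k - half;
            if (s < 0) s = 0;
            if (s >= nz) s = nz - 1;
            acc += kn[k] * line[s];
          }
          os[t] = acc;
        }
      }
  }
  return out;
}
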