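// Low-level 3D image primitives shared by all pipeline stages.
// Arrays are R arrays with dim = c(nz, ny, nx); linear index = z + nz*(y + ny*x).
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

static inline void get_dim3(const RObject& x, int& nz, int& ny, int& nx) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("expected a 3D array");
  nz = d[0]; ny = d[1]; nx = d[2];
}

// reflect index into [0, n-1] (mirror without repeating the edge sample
// unless n == 1)
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * (n - 1) - i;
  }
  return i;
}

// Separable convolution along one axis (0=z, 1=y, 2=x) with an odd-length
// kernel, mirror boundary. Kernel is applied as a correlation, which equals
// convolution for the symmetric/antisymmetric kernels used here up to sign
// handled by the caller.
static void conv_axis(const std::vector<double>& in, std::vector<double>& out,
                      int nz, int ny, int nx, int axis, const NumericVector& k) {
  int kl = k.size();
  int r = (kl - 1) / 2;
  int n[3] = {nz, ny, nx};
  int stride[3] = {1, nz, nz * ny};
  int na = n[axis], sa = stride[axis];
  // iterate over all lines along `axis`
  int b1 = (axis == 0) ? 1 : 0;
  int b2 = (axis == 2) ? 1 : 2;
  int nb1 = n[b1], nb2 = n[b2];
  int sb1 = stride[b1], sb2 = stride[b2];
  for (int i2 = 0; i2 < nb2; ++i2) {
    for (int i1 = 0; i1 < nb1; ++i1) {
      int base = i1 * sb1 + i2 * sb2;
      for (int j = 0; j < na; ++j) {
        double acc = 0.0;
        for (int t = -r; t <= r; ++t) {
          int jj = reflect(j + t, na);
          acc += k[t + r] * in[base + jj * sa];
        }
        out[base + j * sa] = acc;
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_sepconv3")]]
NumericVector cpp_sepconv3(NumericVector x, NumericVector kz, NumericVector ky,
                           NumericVector kx) {
  int nz, ny, nx;
  get_dim3(x, nz, ny, nx);
  size_t n = (size_t)nz * ny * nx;
  std::vector<double> a(x.begin(), x.end()), b(n);
  conv_axis(a, b, nz, ny, nx, 0, kz);
  conv_axis(b, a, nz, ny, nx, 1, ky);
  conv_axis(a, b, nz, ny, nx, 2, kx);
  NumericVector out(b.begin(), b.end());
  out.attr("dim") = x.attr("dim");
  return out;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher) with argmin
// tracking. f: input squared distances (INF where no feature), s2: squared
// sample spacing. Writes output into d[] and the argmin source position
// into arg[].
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& arg, int n, double s2) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[k]] == INF) { v[k] = q; continue; }
    double s = ((f[q] + (double)q * q * s2) - (f[v[k]] + (double)v[k] * v[k] * s2)) /
               (2.0 * s2 * (q - v[k]));
    while (k > 0 && s <= z[k]) {
      k--;
      s = ((f[q] + (double)q * q * s2) - (f[v[k]] + (double)v[k] * v[k] * s2)) /
          (2.0 * s2 * (q - v[k]));
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  int kk = 0;
  for (int q = 0; q < n; ++q) {
    if (f[v[0]] == INF) { d[q] = INF; arg[q] = -1; continue; }
    while (z[kk + 1] < q) kk++;
    double dq = (double)(q - v[kk]) * (q - v[kk]) * s2 + f[v[kk]];
    d[q] = dq;
    arg[q] = v[kk];
  }
}

// Exact anisotropic Euclidean distance transform with feature transform.
// mask: nonzero entries are features. spacing: c(sz, sy, sx) in physical
// units. Returns list(dist = physical distances, feature = 1-based linear
// index of the nearest feature voxel, 0 where no feature exists).
// [[Rcpp::export(name = ".cpp_edt3")]]
List cpp_edt3(IntegerVector mask, NumericVector spacing) {
  int nz, ny, nx;
  get_dim3(mask, nz, ny, nx);
  size_t n = (size_t)nz * ny * nx;
  const double INF = std::numeric_limits<double>::infinity();
  double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  std::vector<double> D(n);
  // nearest feature coordinate per processed axis
  std::vector<int> FZ(n, -1), FY(n, -1), FX(n, -1);
  for (size_t i = 0; i < n; ++i) D[i] = mask[i] != 0 ? 0.0 : INF;
  size_t strideZ = 1, strideY = nz, strideX = (size_t)nz * ny;

  std::vector<double> f, d;
  std::vector<int> arg;

  // pass along z
  f.resize(nz); d.resize(nz); arg.resize(nz);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      size_t base = y * strideY + x * strideX;
      for (int z = 0; z < nz; ++z) f[z] = D[base + z];
      dt1d(f, d, arg, nz, sz * sz);
      for (int z = 0; z < nz; ++z) { D[base + z] = d[z]; FZ[base + z] = arg[z]; }
    }
  // pass along y: track for each voxel which y' minimized; nearest feature z
  // is FZ at (z, y', x)
  f.resize(ny); d.resize(ny); arg.resize(ny);
  std::vector<int> FZ2(n, -1);
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      size_t base = z + x * strideX;
      for (int y = 0; y < ny; ++y) f[y] = D[base + y * strideY];
      dt1d(f, d, arg, ny, sy * sy);
      for (int y = 0; y < ny; ++y) {
        size_t i = base + y * strideY;
        D[i] = d[y];
        FY[i] = arg[y];
        FZ2[i] = (arg[y] >= 0) ? FZ[base + (size_t)arg[y] * strideY] : -1;
      }
    }
  // pass along x
  f.resize(nx); d.resize(nx); arg.resize(nx);
  std::vector<int> FY2(n, -1), FZ3(n, -1);
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      size_t base = z + y * strideY;
      for (int x = 0; x < nx; ++x) f[x] = D[base + x * strideX];
      dt1d(f, d, arg, nx, sx * sx);
      for (int x = 0; x < nx; ++x) {
        size_t i = base + x * strideX;
        D[i] = d[x];
        FX[i] = arg[x];
        if (arg[x] >= 0) {
          size_t j = base + (size_t)arg[x] * strideX;
          FY2[i] = FY[j];
          FZ3[i] = FZ2[j];
        }
      }
    }

  NumericVector dist(n);
  IntegerVector feat(n);
  for (size_t i = 0; i < n; ++i) {
    dist[i] = std::isinf(D[i]) ? R_PosInf : std::sqrt(D[i]);
    if (FX[i] >= 0 && FY2[i] >= 0 && FZ3[i] >= 0)
      feat[i] = 1 + FZ3[i] + nz * (FY2[i] + (size_t)ny * FX[i]);
    else
      feat[i] = 0;
  }
  dist.attr("dim") = mask.attr("dim");
  feat.attr("dim") = mask.attr("dim");
  return List::create(_["dist"] = dist, _["feature"] = feat);
}

// Grey-scale erosion/dilation by a cube of half-width r (separable running
// min/max). do_max = true gives dilation.
// [[Rcpp::export(name = ".cpp_minmax_box3")]]
NumericVector cpp_minmax_box3(NumericVector x, IntegerVector r, bool do_max) {
  int nz, ny, nx;
  get_dim3(x, nz, ny, nx);
  size_t n = (size_t)nz * ny * nx;
  std::vector<double> a(x.begin(), x.end()), b(n);
  int nn[3] = {nz, ny, nx};
  size_t stride[3] = {1, (size_t)nz, (size_t)nz * ny};
  for (int axis = 0; axis < 3; ++axis) {
    int ra = r[axis];
    if (ra <= 0) continue;
    int na = nn[axis];
    size_t sa = stride[axis];
    int b1 = (axis == 0) ? 1 : 0;
    int b2 = (axis == 2) ? 1 : 2;
    for (int i2 = 0; i2 < nn[b2]; ++i2)
      for (int i1 = 0; i1 < nn[b1]; ++i1) {
        size_t base = i1 * stride[b1] + i2 * stride[b2];
        for (int j = 0; j < na; ++j) {
          int lo = std::max(0, j - ra), hi = std::min(na - 1, j + ra);
          double v = a[base + (size_t)lo * sa];
          for (int t = lo + 1; t <= hi; ++t) {
            double w = a[base + (size_t)t * sa];
            if (do_max ? (w > v) : (w < v)) v = w;
          }
          b[base + (size_t)j * sa] = v;
        }
      }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = x.attr("dim");
  return out;
}

struct WSNode {
  double value;
  int label;
  long long order;
  size_t idx;
};
struct WSCmp {
  bool operator()(const WSNode& a, const WSNode& b) const {
    if (a.value != b.value) return a.value > b.value;   // lower value first
    if (a.order != b.order) return a.order > b.order;   // FIFO within level
    return a.label > b.label;                           // lower label last
  }
};

// Marker-controlled watershed by priority flood on `priority` (flooded from
// low to high), restricted to mask, 6-connectivity. Equal-priority voxels
// resolve first-queued-first (so each basin claims its own ridge flank
// before a front arriving later from elsewhere), then lower label.
// [[Rcpp::export(name = ".cpp_watershed_seeded")]]
IntegerVector cpp_watershed_seeded(NumericVector priority, IntegerVector seeds,
                                   IntegerVector mask) {
  int nz, ny, nx;
  get_dim3(priority, nz, ny, nx);
  size_t n = (size_t)nz * ny * nx;
  IntegerVector out(n);
  out.attr("dim") = priority.attr("dim");
  std::priority_queue<WSNode, std::vector<WSNode>, WSCmp> pq;
  long long order = 0;
  for (size_t i = 0; i < n; ++i) {
    out[i] = 0;
    if (seeds[i] > 0 && mask[i] != 0)
      pq.push({priority[i], seeds[i], order++, i});
  }
  const int dz[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dx[6] = {0, 0, 0, 0, 1, -1};
  while (!pq.empty()) {
    WSNode nd = pq.top();
    pq.pop();
    if (out[nd.idx] != 0) continue;
    out[nd.idx] = nd.label;
    int z = (int)(nd.idx % nz);
    int y = (int)((nd.idx / nz) % ny);
    int x = (int)(nd.idx / ((size_t)nz * ny));
    for (int k = 0; k < 6; ++k) {
      int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      size_t j = zz + nz * (yy + (size_t)ny * xx);
      if (mask[j] == 0 || out[j] != 0) continue;
      pq.push({priority[j], nd.label, order++, j});
    }
  }
  return out;
}

// Connected-component labelling of nonzero voxels, 6- or 26-connectivity.
// Components numbered in raster-scan order of their first voxel.
// [[Rcpp::export(name = ".cpp_label3")]]
IntegerVector cpp_label3(IntegerVector mask, int connectivity) {
  int nz, ny, nx;
  get_dim3(mask, nz, ny, nx);
  size_t n = (size_t)nz * ny * nx;
  IntegerVector out(n);
  out.attr("dim") = mask.attr("dim");
  std::vector<std::array<int, 3>> nbr;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int man = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && man != 1) continue;
        nbr.push_back({dz, dy, dx});
      }
  int next = 0;
  std::vector<size_t> stack;
  for (size_t i = 0; i < n; ++i) {
    if (mask[i] == 0 || out[i] != 0) continue;
    ++next;
    stack.clear();
    stack.push_back(i);
    out[i] = next;
    while (!stack.empty()) {
      size_t c = stack.back();
      stack.pop_back();
      int z = (int)(c % nz);
      int y = (int)((c / nz) % ny);
      int x = (int)(c / ((size_t)nz * ny));
      for (auto& d : nbr) {
        int zz = z + d[0], yy = y + d[1], xx = x + d[2];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        size_t j = zz + nz * (yy + (size_t)ny * xx);
        if (mask[j] != 0 && out[j] == 0) {
          out[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  return out;
}

// Trilinear resampling onto a new grid. Voxel i (0-based) sits at physical
// position i * spacing along each axis; output positions are clamped to the
// input extent.
// [[Rcpp::export(name = ".cpp_resize3_trilinear")]]
NumericVector cpp_resize3_trilinear(NumericVector x, IntegerVector out_dim,
                                    NumericVector in_spacing,
                                    NumericVector out_spacing) {
  int nz, ny, nx;
  get_dim3(x, nz, ny, nx);
  int oz = out_dim[0], oy = out_dim[1], ox = out_dim[2];
  NumericVector out((size_t)oz * oy * ox);
  out.attr("dim") = IntegerVector::create(oz, oy, ox);
  for (int xx = 0; xx < ox; ++xx) {
    double px = xx * out_spacing[2] / in_spacing[2];
    px = std::min(std::max(px, 0.0), (double)(nx - 1));
    int x0 = (int)px, x1 = std::min(x0 + 1, nx - 1);
    double fx = px - x0;
    for (int yy = 0; yy < oy; ++yy) {
      double py = yy * out_spacing[1] / in_spacing[1];
      py = std::min(std::max(py, 0.0), (double)(ny - 1));
      int y0 = (int)py, y1 = std::min(y0 + 1, ny - 1);
      double fy = py - y0;
      for (int zz = 0; zz < oz; ++zz) {
        double pz = zz * out_spacing[0] / in_spacing[0];
        pz = std::min(std::max(pz, 0.0), (double)(nz - 1));
        int z0 = (int)pz, z1 = std::min(z0 + 1, nz - 1);
        double fz = pz - z0;
        auto at = [&](int a, int b, int c) {
          return x[a + nz * (b + (size_t)ny * c)];
        };
        double v =
            (1 - fz) * ((1 - fy) * ((1 - fx) * at(z0, y0, x0) + fx * at(z0, y0, x1)) +
                        fy * ((1 - fx) * at(z0, y1, x0) + fx * at(z0, y1, x1))) +
            fz * ((1 - fy) * ((1 - fx) * at(z1, y0, x0) + fx * at(z1, y0, x1)) +
                  fy * ((1 - fx) * at(z1, y1, x0) + fx * at(z1, y1, x1)));
        out[zz + oz * (yy + (size_t)oy * xx)] = v;
      }
    }
  }
  return out;
}

// TRUE where a voxel's label differs from at least one 6-neighbour
// (out-of-bounds neighbours count as background 0 when include_border).
// [[Rcpp::export(name = ".cpp_boundary6")]]
LogicalVector cpp_boundary6(IntegerVector labels, bool include_border) {
  int nz, ny, nx;
  get_dim3(labels, nz, ny, nx);
  size_t n = (size_t)nz * ny * nx;
  LogicalVector out(n);
  out.attr("dim") = labels.attr("dim");
  const int dz[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dx[6] = {0, 0, 0, 0, 1, -1};
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        size_t i = z + nz * (y + (size_t)ny * x);
        int v = labels[i];
        if (v == 0) { out[i] = FALSE; continue; }
        bool b = false;
        for (int k = 0; k < 6 && !b; ++k) {
          int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) {
            if (include_border) b = true;
            continue;
          }
          size_t j = zz + nz * (yy + (size_t)ny * xx);
          if (labels[j] != v) b = true;
        }
        out[i] = b;
      }
  return out;
}
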