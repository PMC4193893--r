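#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline int clampi(int x, int lo, int hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

static inline R_xlen_t vidx(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// Catmull-Rom weights for fractional offset t in [0,1); reproduces
// polynomials up to degree 2, interpolating (passes through samples).
static inline void catrom_w(double t, double w[4]) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = -0.5 * t3 + t2 - 0.5 * t;
  w[1] = 1.5 * t3 - 2.5 * t2 + 1.0;
  w[2] = -1.5 * t3 + 2.0 * t2 + 0.5 * t;
  w[3] = 0.5 * t3 - 0.5 * t2;
}

// Sample a 3-D volume at continuous 0-based voxel coordinates.
// order: 0 nearest, 1 trilinear, 3 cubic (Catmull-Rom). Points with any
// coordinate outside [0, n-1] return `fill`; border samples replicate.
// [[Rcpp::export]]
NumericVector cpp_sample_volume(NumericVector vol, IntegerVector dims,
                                NumericMatrix pts, int order, double fill) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = pts.nrow();
  NumericVector out(n);
  const double *v = vol.begin();

  for (R_xlen_t p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (!R_finite(x) || !R_finite(y) || !R_finite(z) ||
        x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
      out[p] = fill;
      continue;
    }
    if (order == 0) {
      int i = (int)std::floor(x + 0.5), j = (int)std::floor(y + 0.5),
          k = (int)std::floor(z + 0.5);
      out[p] = v[vidx(clampi(i, 0, nx - 1), clampi(j, 0, ny - 1),
                      clampi(k, 0, nz - 1), nx, ny)];
    } else if (order == 1) {
      int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
      i0 = clampi(i0, 0, nx - 2 >= 0 ? nx - 2 : 0);
      j0 = clampi(j0, 0, ny - 2 >= 0 ? ny - 2 : 0);
      k0 = clampi(k0, 0, nz - 2 >= 0 ? nz - 2 : 0);
      double fx = x - i0, fy = y - j0, fz = z - k0;
      int i1 = clampi(i0 + 1, 0, nx - 1), j1 = clampi(j0 + 1, 0, ny - 1),
          k1 = clampi(k0 + 1, 0, nz - 1);
      double c00 = v[vidx(i0, j0, k0, nx, ny)] * (1 - fx) + v[vidx(i1, j0, k0, nx, ny)] * fx;
      double c10 = v[vidx(i0, j1, k0, nx, ny)] * (1 - fx) + v[vidx(i1, j1, k0, nx, ny)] * fx;
      double c01 = v[vidx(i0, j0, k1, nx, ny)] * (1 - fx) + v[vidx(i1, j0, k1, nx, ny)] * fx;
      double c11 = v[vidx(i0, j1, k1, nx, ny)] * (1 - fx) + v[vidx(i1, j1, k1, nx, ny)] * fx;
      double c0 = c00 * (1 - fy) + c10 * fy;
      double c1 = c01 * (1 - fy) + c11 * fy;
      out[p] = c0 * (1 - fz) + c1 * fz;
    } else {
      int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
      double wx[4], wy[4], wz[4];
      catrom_w(x - i0, wx);
      catrom_w(y - j0, wy);
      catrom_w(z - k0, wz);
      double acc = 0.0;
      for (int c = 0; c < 4; ++c) {
        int kk = clampi(k0 - 1 + c, 0, nz - 1);
        double accy = 0.0;
        for (int b = 0; b < 4; ++b) {
          int jj = clampi(j0 - 1 + b, 0, ny - 1);
          double accx = 0.0;
          for (int a = 0; a < 4; ++a) {
            int ii = clampi(i0 - 1 + a, 0, nx - 1);
            accx += wx[a] * v[vidx(ii, jj, kk, nx, ny)];
          }
          accy += wy[b] * accx;
        }
        acc += wz[c] * accy;
      }
      out[p] = acc;
    }
  }
  return out;
}

// 1-D squared distance transform (Felzenszwalb & Huttenlocher), spacing s.
static void dt1d(const double *f, double *d, int n, double s) {
  std::vector<int> vv(n);
  std::vector<double> zz(n + 1);
  int k = 0;
  vv[0] = 0;
  zz[0] = -HUGE_VAL;
  zz[1] = HUGE_VAL;
  double s2 = s * s;
  for (int q = 1; q < n; ++q) {
    double sden, snum;
    while (true) {
      int p = vv[k];
      snum = (f[q] + s2 * q * q) - (f[p] + s2 * p * p);
      sden = 2.0 * s2 * (q - p);
      double inter = snum / sden;
      if (inter <= zz[k]) {
        --k;
      } else {
        ++k;
        vv[k] = q;
        zz[k] = inter;
        zz[k + 1] = HUGE_VAL;
        break;
      }
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zz[k + 1] < q) ++k;
    int p = vv[k];
    d[q] = s2 * (q - p) * (q - p) + f[p];
  }
}

// Euclidean distance (mm) from each voxel to the nearest TRUE voxel,
// anisotropic spacing supported. Returns +Inf if mask empty.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  // large finite sentinel: infinities break the lower-envelope arithmetic
  const double FAR = 1e18;
  std::vector<double> d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = mask[i] ? 0.0 : FAR;

  std::vector<double> f(std::max(nx, std::max(ny, nz)));
  std::vector<double> g(f.size());

  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) f[i] = d[vidx(i, j, k, nx, ny)];
      dt1d(f.data(), g.data(), nx, spacing[0]);
      for (int i = 0; i < nx; ++i) d[vidx(i, j, k, nx, ny)] = g[i];
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = d[vidx(i, j, k, nx, ny)];
      dt1d(f.data(), g.data(), ny, spacing[1]);
      for (int j = 0; j < ny; ++j) d[vidx(i, j, k, nx, ny)] = g[j];
    }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = d[vidx(i, j, k, nx, ny)];
      dt1d(f.data(), g.data(), nz, spacing[2]);
      for (int k = 0; k < nz; ++k) d[vidx(i, j, k, nx, ny)] = g[k];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(d[i]);
  return out;
}

// 6-connected component labelling of a 3-D logical array.
// Labels start at 1 in scan order; background is 0.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      R_xlen_t q = stack.back();
      stack.pop_back();
      int k = (int)(q / ((R_xlen_t)nx * ny));
      int rem = (int)(q % ((R_xlen_t)nx * ny));
      int j = rem / nx, i = rem % nx;
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int t = 0; t < 6; ++t) {
        int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        R_xlen_t w = vidx(ii, jj, kk, nx, ny);
        if (mask[w] && !lab[w]) {
          lab[w] = cur;
          stack.push_back(w);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// ---- Statistical region merging (Nock & Nielsen predicate) ----

struct UF {
  std::vector<int> parent, size;
  std::vector<double> sum;
  UF(int n) : parent(n), size(n, 1), sum(n, 0.0) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
  void unite(int a, int b) {
    if (size[a] < size[b]) std::swap(a, b);
    parent[b] = a;
    size[a] += size[b];
    sum[a] += sum[b];
  }
};

// SRM on one 2-D slice. Pixel pairs (4-neighbourhood) are sorted by
// absolute intensity difference; adjacent regions merge while the squared
// mean difference stays under b^2(R1) + b^2(R2) with
// b(R) = g * sqrt(ln(2/delta) / (2 Q |R|)), delta = 1/(6 n^2).
// Larger Q -> finer segmentation. Returns 1-based labels in raster order.
// [[Rcpp::export]]
IntegerMatrix cpp_srm(NumericMatrix img, double Q) {
  const int nr = img.nrow(), nc = img.ncol();
  const int n = nr * nc;
  double lo = img[0], hi = img[0];
  for (int i = 1; i < n; ++i) {
    if (img[i] < lo) lo = img[i];
    if (img[i] > hi) hi = img[i];
  }
  double g = hi - lo;
  if (g <= 0) g = 1.0;

  struct Pair { int a, b; double d; };
  std::vector<Pair> pairs;
  pairs.reserve(2 * (size_t)n);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int id = r + nr * c;
      if (r + 1 < nr)
        pairs.push_back({id, id + 1, std::fabs(img[id] - img[id + 1])});
      if (c + 1 < nc)
        pairs.push_back({id, id + nr, std::fabs(img[id] - img[id + nr])});
    }
  std::stable_sort(pairs.begin(), pairs.end(),
                   [](const Pair &x, const Pair &y) { return x.d < y.d; });

  UF uf(n);
  for (int i = 0; i < n; ++i) uf.sum[i] = img[i];
  const double delta = 1.0 / (6.0 * (double)n * (double)n);
  const double lg = std::log(2.0 / delta);

  for (const Pair &pr : pairs) {
    int ra = uf.find(pr.a), rb = uf.find(pr.b);
    if (ra == rb) continue;
    double ma = uf.sum[ra] / uf.size[ra];
    double mb = uf.sum[rb] / uf.size[rb];
    double b2a = g * g * lg / (2.0 * Q * uf.size[ra]);
    double b2b = g * g * lg / (2.0 * Q * uf.size[rb]);
    double diff = ma - mb;
    if (diff * diff <= b2a + b2b) uf.unite(ra, rb);
  }

  IntegerMatrix lab(nr, nc);
  std::vector<int> remap(n, 0);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = uf.find(i);
    if (!remap[r]) remap[r] = ++next;
    lab[i] = remap[r];
  }
  return lab;
}

// Separable Gaussian smoothing, sigma per axis in voxel units,
// replicated borders. sigma <= 0 skips that axis.
// [[Rcpp::export]]
NumericVector cpp_smooth3(NumericVector vol, IntegerVector dims, NumericVector sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(vol.begin(), vol.end()), b(n);

  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma[axis];
    if (s <= 0) continue;
    int rad = (int)std::ceil(3.0 * s);
    std::vector<double> w(2 * rad + 1);
    double tot = 0;
    for (int t = -rad; t <= rad; ++t) {
      w[t + rad] = std::exp(-0.5 * t * t / (s * s));
      tot += w[t + rad];
    }
    for (double &x : w) x /= tot;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          double acc = 0;
          for (int t = -rad; t <= rad; ++t) {
            int ii = i, jj = j, kk = k;
            if (axis == 0) ii = clampi(i + t, 0, nx - 1);
            else if (axis == 1) jj = clampi(j + t, 0, ny - 1);
            else kk = clampi(k + t, 0, nz - 1);
            acc += w[t + rad] * a[vidx(ii, jj, kk, nx, ny)];
          }
          b[vidx(i, j, k, nx, ny)] = acc;
        }
    std::swap(a, b);
  }
  NumericVector out(n);
  std::copy(a.begin(), a.end(), out.begin());
  out.attr("dim") = dims;
  return out;
}

// ---- Marching tetrahedra iso-surface ----

static inline void edge_pt(const double p1[3], const double p2[3],
                           double v1, double v2, double level, double out[3]) {
  double t = (level - v1) / (v2 - v1);
  if (!R_finite(t)) t = 0.5;
  if (t < 0) t = 0;
  if (t > 1) t = 1;
  for (int a = 0; a < 3; ++a) out[a] = p1[a] + t * (p2[a] - p1[a]);
}

// Triangulate the `level` iso-surface of a scalar volume with marching
// tetrahedra (6 tetrahedra per cube). Coordinates are voxel-centre mm
// (index * spacing). Triangles are oriented so the right-hand normal
// points from values > level towards values < level (outward).
// Returns an ntri x 9 matrix (x1 y1 z1 x2 y2 z2 x3 y3 z3).
// [[Rcpp::export]]
NumericMatrix cpp_march_tets(NumericVector vol, IntegerVector dims,
                             NumericVector spacing, double level) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *v = vol.begin();
  // cube corner offsets
  static const int co[8][3] = {{0,0,0},{1,0,0},{1,1,0},{0,1,0},
                               {0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  // 6-tet decomposition of the cube
  static const int tets[6][4] = {{0,5,1,6},{0,1,2,6},{0,2,3,6},
                                 {0,3,7,6},{0,7,4,6},{0,4,5,6}};
  std::vector<double> tris;
  double P[8][3], V[8];

  auto emit = [&](double a[3], double b[3], double c[3],
                  const double inC[3], const double outC[3]) {
    // orient: normal should point along (outC - inC)
    double u1[3], u2[3], nn[3], ref[3];
    for (int t = 0; t < 3; ++t) {
      u1[t] = b[t] - a[t];
      u2[t] = c[t] - a[t];
      ref[t] = outC[t] - inC[t];
    }
    nn[0] = u1[1] * u2[2] - u1[2] * u2[1];
    nn[1] = u1[2] * u2[0] - u1[0] * u2[2];
    nn[2] = u1[0] * u2[1] - u1[1] * u2[0];
    double dp = nn[0] * ref[0] + nn[1] * ref[1] + nn[2] * ref[2];
    if (dp >= 0) {
      for (int t = 0; t < 3; ++t) tris.push_back(a[t]);
      for (int t = 0; t < 3; ++t) tris.push_back(b[t]);
      for (int t = 0; t < 3; ++t) tris.push_back(c[t]);
    } else {
      for (int t = 0; t < 3; ++t) tris.push_back(a[t]);
      for (int t = 0; t < 3; ++t) tris.push_back(c[t]);
      for (int t = 0; t < 3; ++t) tris.push_back(b[t]);
    }
  };

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        bool any = false, all = true;
        for (int c = 0; c < 8; ++c) {
          int ii = i + co[c][0], jj = j + co[c][1], kk = k + co[c][2];
          V[c] = v[vidx(ii, jj, kk, nx, ny)];
          P[c][0] = ii * spacing[0];
          P[c][1] = jj * spacing[1];
          P[c][2] = kk * spacing[2];
          if (V[c] > level) any = true; else all = false;
        }
        if (!any || all) continue;
        for (int t = 0; t < 6; ++t) {
          int id[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          int ins[4], outs[4], ni = 0, no = 0;
          for (int c = 0; c < 4; ++c) {
            if (V[id[c]] > level) ins[ni++] = id[c];
            else outs[no++] = id[c];
          }
          if (ni == 0 || ni == 4) continue;
          double inC[3] = {0, 0, 0}, outC[3] = {0, 0, 0};
          for (int c = 0; c < ni; ++c)
            for (int a = 0; a < 3; ++a) inC[a] += P[ins[c]][a] / ni;
          for (int c = 0; c < no; ++c)
            for (int a = 0; a < 3; ++a) outC[a] += P[outs[c]][a] / no;
          double e[4][3];
          if (ni == 1) {
            for (int c = 0; c < 3; ++c)
              edge_pt(P[ins[0]], P[outs[c]], V[ins[0]], V[outs[c]], level, e[c]);
            emit(e[0], e[1], e[2], inC, outC);
          } else if (ni == 3) {
            for (int c = 0; c < 3; ++c)
              edge_pt(P[ins[c]], P[outs[0]], V[ins[c]], V[outs[0]], level, e[c]);
            emit(e[0], e[1], e[2], inC, outC);
          } else { // ni == 2: quad from the four in-out edges
            edge_pt(P[ins[0]], P[outs[0]], V[ins[0]], V[outs[0]], level, e[0]);
            edge_pt(P[ins[0]], P[outs[1]], V[ins[0]], V[outs[1]], level, e[1]);
            edge_pt(P[ins[1]], P[outs[1]], V[ins[1]], V[outs[1]], level, e[2]);
            edge_pt(P[ins[1]], P[outs[0]], V[ins[1]], V[outs[0]], level, e[3]);
            emit(e[0], e[1], e[2], inC, outC);
            emit(e[0], e[2], e[3], inC, outC);
          }
        }
      }

  size_t ntri = tris.size() / 9;
  NumericMatrix out(ntri, 9);
  for (size_t r = 0; r < ntri; ++r)
    for (int c = 0; c < 9; ++c) out(r, c) = tris[9 * r + c];
  return out;
}
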