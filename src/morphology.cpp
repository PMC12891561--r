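// 3D morphology kernels shared by the segmentation and morphometrics code.
//
// All volumes are R arrays with dim = c(nz, ny, nx), i.e. column-major with
// z fastest; flat index = z + nz*(y + ny*x).  Physical spacing is passed per
// axis in the same (z, y, x) order so every distance is in micrometres.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
#include <algorithm>

using namespace Rcpp;

static inline long long flat(int z, int y, int x, int nz, int ny) {
  return (long long)z + (long long)nz * ((long long)y + (long long)ny * x);
}

// Separable Gaussian blur with mirror boundary; sigma in voxels per axis
// (z, y, x).  A non-positive sigma skips that axis.
// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector vol, IntegerVector dim,
                          NumericVector sigma) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const long long n = (long long)nz * ny * nx;
  std::vector<double> buf(vol.begin(), vol.end());
  std::vector<double> out(n);
  const long long stride[3] = {1, (long long)nz, (long long)nz * ny};
  const int len3[3] = {nz, ny, nx};

  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma[axis];
    if (s <= 0.0) continue;
    int r = (int)std::ceil(3.0 * s);
    if (r < 1) r = 1;
    std::vector<double> k(2 * r + 1);
    double ksum = 0.0;
    for (int i = -r; i <= r; ++i) {
      k[i + r] = std::exp(-0.5 * (double)i * i / (s * s));
      ksum += k[i + r];
    }
    for (double& v : k) v /= ksum;

    const int len = len3[axis];
    const long long st = stride[axis];
    const int a1 = (axis + 1) % 3, a2 = (axis + 2) % 3;
    for (int i2 = 0; i2 < len3[a2]; ++i2) {
      for (int i1 = 0; i1 < len3[a1]; ++i1) {
        const long long base = i1 * stride[a1] + i2 * stride[a2];
        for (int p = 0; p < len; ++p) {
          double acc = 0.0;
          for (int q = -r; q <= r; ++q) {
            int pp = p + q;
            if (pp < 0) pp = -pp - 1;
            else if (pp >= len) pp = 2 * len - pp - 1;
            if (pp < 0) pp = 0;
            else if (pp >= len) pp = len - 1;
            acc += k[q + r] * buf[base + (long long)pp * st];
          }
          out[base + (long long)p * st] = acc;
        }
      }
    }
    std::swap(buf, out);
  }
  return NumericVector(buf.begin(), buf.end());
}

// Connected-component labelling under 26-connectivity.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const long long n = (long long)nz * ny * nx;
  IntegerVector lab(n, 0);
  std::vector<long long> stack;
  int next = 0;
  for (long long i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      long long cur = stack.back();
      stack.pop_back();
      int z = (int)(cur % nz);
      int y = (int)((cur / nz) % ny);
      int x = (int)(cur / ((long long)nz * ny));
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz;
        if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            int xx = x + dx;
            if (xx < 0 || xx >= nx) continue;
            long long nb = flat(zz, yy, xx, nz, ny);
            if (mask[nb] && lab[nb] == 0) {
              lab[nb] = next;
              stack.push_back(nb);
            }
          }
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// One pass of the 1-D squared-distance transform (lower envelope of
// parabolas) with sample spacing s (so positions are q*s).
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double s) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  int k = 0;
  v[0] = 0;
  zb[0] = -INF;
  zb[1] = INF;
  const double s2 = s * s;
  for (int q = 1; q < n; ++q) {
    double fq = f[q] + s2 * (double)q * q;
    while (true) {
      double fv = f[v[k]] + s2 * (double)v[k] * v[k];
      double inter = (fq - fv) / (2.0 * s2 * (q - v[k]));
      if (inter <= zb[k]) {
        --k;
      } else {
        ++k;
        v[k] = q;
        zb[k] = inter;
        zb[k + 1] = INF;
        break;
      }
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < (double)q) ++k;
    double dq = s * (double)(q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// Euclidean distance (micrometres) from each foreground voxel to the nearest
// background voxel, with anisotropic spacing.  Voxels outside the volume are
// not treated as background.
// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector mask, IntegerVector dim,
                        NumericVector spacing) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const long long n = (long long)nz * ny * nx;
  const double BIG = 1e30;
  std::vector<double> g(n);
  for (long long i = 0; i < n; ++i) g[i] = mask[i] ? BIG : 0.0;

  const long long stride[3] = {1, (long long)nz, (long long)nz * ny};
  const int len3[3] = {nz, ny, nx};
  std::vector<double> line, dline;
  for (int axis = 0; axis < 3; ++axis) {
    const int len = len3[axis];
    const long long st = stride[axis];
    const double s = spacing[axis];
    const int a1 = (axis + 1) % 3, a2 = (axis + 2) % 3;
    line.resize(len);
    dline.resize(len);
    for (int i2 = 0; i2 < len3[a2]; ++i2) {
      for (int i1 = 0; i1 < len3[a1]; ++i1) {
        const long long base = i1 * stride[a1] + i2 * stride[a2];
        for (int p = 0; p < len; ++p) line[p] = g[base + (long long)p * st];
        dt1d(line, dline, len, s);
        for (int p = 0; p < len; ++p) g[base + (long long)p * st] = dline[p];
      }
    }
  }
  NumericVector out(n);
  for (long long i = 0; i < n; ++i)
    out[i] = g[i] >= 1e29 ? std::sqrt(1e29) : std::sqrt(g[i]);
  out.attr("dim") = dim;
  return out;
}

// 3x3x3 maximum filter (26-neighbourhood plus centre).
// [[Rcpp::export]]
NumericVector cpp_maxfilter26(NumericVector vol, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const long long n = (long long)nz * ny * nx;
  NumericVector out(n);
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        double m = -std::numeric_limits<double>::infinity();
        for (int dz = -1; dz <= 1; ++dz) {
          int zz = z + dz;
          if (zz < 0 || zz >= nz) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            int yy = y + dy;
            if (yy < 0 || yy >= ny) continue;
            for (int dx = -1; dx <= 1; ++dx) {
              int xx = x + dx;
              if (xx < 0 || xx >= nx) continue;
              double v = vol[flat(zz, yy, xx, nz, ny)];
              if (v > m) m = v;
            }
          }
        }
        out[flat(z, y, x, nz, ny)] = m;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

struct QEntry {
  double prio;
  long long order;
  long long idx;
};
struct QCmp {
  bool operator()(const QEntry& a, const QEntry& b) const {
    if (a.prio != b.prio) return a.prio < b.prio;  // max-heap on priority
    return a.order > b.order;                       // FIFO on ties
  }
};

// Seeded watershed by priority flooding: voxels are claimed in order of
// decreasing priority (here: the distance transform), starting from labelled
// seed voxels, and restricted to the foreground mask.
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector prio, IntegerVector seeds,
                            LogicalVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const long long n = (long long)nz * ny * nx;
  IntegerVector lab(n, 0);
  std::priority_queue<QEntry, std::vector<QEntry>, QCmp> pq;
  long long order = 0;
  for (long long i = 0; i < n; ++i) {
    if (seeds[i] > 0 && mask[i]) {
      lab[i] = seeds[i];
      pq.push({prio[i], order++, i});
    }
  }
  while (!pq.empty()) {
    QEntry e = pq.top();
    pq.pop();
    long long cur = e.idx;
    int z = (int)(cur % nz);
    int y = (int)((cur / nz) % ny);
    int x = (int)(cur / ((long long)nz * ny));
    int curlab = lab[cur];
    for (int dz = -1; dz <= 1; ++dz) {
      int zz = z + dz;
      if (zz < 0 || zz >= nz) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int yy = y + dy;
        if (yy < 0 || yy >= ny) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          int xx = x + dx;
          if (xx < 0 || xx >= nx) continue;
          long long nb = flat(zz, yy, xx, nz, ny);
          if (mask[nb] && lab[nb] == 0) {
            lab[nb] = curlab;
            pq.push({prio[nb], order++, nb});
          }
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

static inline double tri_area(const double a[3], const double b[3],
                              const double c[3]) {
  double u[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double v[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double cx = u[1] * v[2] - u[2] * v[1];
  double cy = u[2] * v[0] - u[0] * v[2];
  double cz = u[0] * v[1] - u[1] * v[0];
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

#include <unordered_map>

// Iso-surface of vol at `level` by marching tetrahedra: each grid cell
// between 8 voxel centres is split into 6 tetrahedra around the main
// diagonal and the linear iso-surface is accumulated per tetrahedron into
// an indexed, consistently outward-oriented triangle mesh.  With
// smooth_iter > 0 the mesh is relaxed by that many uniform Laplacian
// iterations (vertex -> (1-lambda)*vertex + lambda*mean(neighbours))
// before measuring.  Returns c(area um^2, enclosed volume um^3), the
// latter via the divergence theorem over the oriented mesh.  The caller is
// expected to zero-pad the volume so the surface closes.  Spacing is
// (z, y, x) in micrometres.
// [[Rcpp::export]]
NumericVector cpp_isosurface_measure(NumericVector vol, IntegerVector dim,
                                     NumericVector spacing, double level,
                                     int smooth_iter = 0,
                                     double lambda = 0.5) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  // cube corner offsets (z, y, x) indexed 0..7 by bits (x + 2y + 4z)
  static const int off[8][3] = {
      {0, 0, 0}, {0, 0, 1}, {0, 1, 0}, {0, 1, 1},
      {1, 0, 0}, {1, 0, 1}, {1, 1, 0}, {1, 1, 1}};
  // 6-tetrahedra fan around the 0-7 diagonal
  static const int tets[6][4] = {{0, 5, 1, 7}, {0, 1, 3, 7}, {0, 3, 2, 7},
                                 {0, 2, 6, 7}, {0, 6, 4, 7}, {0, 4, 5, 7}};
  std::vector<double> vx;            // vertex coords, 3 per vertex
  std::vector<int> tris;             // vertex indices, 3 per triangle
  std::unordered_map<long long, int> vmap;
  const double q = 16384.0;          // dedup quantum (~6e-5 um)
  auto add_point = [&](const double p[3]) -> int {
    long long kz = (long long)std::llround(p[0] * q);
    long long ky = (long long)std::llround(p[1] * q);
    long long kx = (long long)std::llround(p[2] * q);
    long long key = (kz << 42) ^ (ky << 21) ^ kx;
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    int id = (int)(vx.size() / 3);
    vmap.emplace(key, id);
    vx.push_back(p[0]); vx.push_back(p[1]); vx.push_back(p[2]);
    return id;
  };
  // orient so the normal points away from the inside reference point
  auto add_tri = [&](const double a[3], const double b[3], const double c[3],
                     const double inside[3]) {
    int ia = add_point(a), ib = add_point(b), ic = add_point(c);
    if (ia == ib || ib == ic || ia == ic) return;  // degenerate
    double u[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
    double v[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
    double nrm[3] = {u[1] * v[2] - u[2] * v[1], u[2] * v[0] - u[0] * v[2],
                     u[0] * v[1] - u[1] * v[0]};
    double cen[3] = {(a[0] + b[0] + c[0]) / 3 - inside[0],
                     (a[1] + b[1] + c[1]) / 3 - inside[1],
                     (a[2] + b[2] + c[2]) / 3 - inside[2]};
    double dot = nrm[0] * cen[0] + nrm[1] * cen[1] + nrm[2] * cen[2];
    if (dot >= 0) {
      tris.push_back(ia); tris.push_back(ib); tris.push_back(ic);
    } else {
      tris.push_back(ia); tris.push_back(ic); tris.push_back(ib);
    }
  };

  double P[8][3];
  double V[8];
  for (int x = 0; x + 1 < nx; ++x) {
    for (int y = 0; y + 1 < ny; ++y) {
      for (int z = 0; z + 1 < nz; ++z) {
        bool anyIn = false, anyOut = false;
        for (int c = 0; c < 8; ++c) {
          int zz = z + off[c][0], yy = y + off[c][1], xx = x + off[c][2];
          V[c] = vol[flat(zz, yy, xx, nz, ny)];
          P[c][0] = zz * sz;
          P[c][1] = yy * sy;
          P[c][2] = xx * sx;
          if (V[c] >= level) anyIn = true; else anyOut = true;
        }
        if (!anyIn || !anyOut) continue;
        for (int t = 0; t < 6; ++t) {
          const int* tv = tets[t];
          int in[4], nin = 0, out[4], nout = 0;
          for (int c = 0; c < 4; ++c) {
            if (V[tv[c]] >= level) in[nin++] = tv[c];
            else out[nout++] = tv[c];
          }
          if (nin == 0 || nin == 4) continue;
          double qd[4][3];
          auto interp = [&](int a, int b, double* p) {
            double tt = (level - V[a]) / (V[b] - V[a]);
            for (int k = 0; k < 3; ++k)
              p[k] = P[a][k] + tt * (P[b][k] - P[a][k]);
          };
          if (nin == 1 || nin == 3) {
            int apex = (nin == 1) ? in[0] : out[0];
            int* oth = (nin == 1) ? out : in;
            for (int c = 0; c < 3; ++c) interp(apex, oth[c], qd[c]);
            add_tri(qd[0], qd[1], qd[2], P[in[0]]);
          } else {  // 2 in, 2 out: quad a-c, a-d, b-d, b-c
            interp(in[0], out[0], qd[0]);
            interp(in[0], out[1], qd[1]);
            interp(in[1], out[1], qd[2]);
            interp(in[1], out[0], qd[3]);
            add_tri(qd[0], qd[1], qd[2], P[in[0]]);
            add_tri(qd[0], qd[2], qd[3], P[in[0]]);
          }
        }
      }
    }
  }

  const int nv = (int)(vx.size() / 3);
  if (smooth_iter > 0 && nv > 0) {
    // adjacency from triangle edges
    std::vector<std::vector<int>> nbr(nv);
    for (size_t t = 0; t < tris.size(); t += 3) {
      int a = tris[t], b = tris[t + 1], c = tris[t + 2];
      nbr[a].push_back(b); nbr[a].push_back(c);
      nbr[b].push_back(a); nbr[b].push_back(c);
      nbr[c].push_back(a); nbr[c].push_back(b);
    }
    for (int v = 0; v < nv; ++v) {
      std::sort(nbr[v].begin(), nbr[v].end());
      nbr[v].erase(std::unique(nbr[v].begin(), nbr[v].end()), nbr[v].end());
    }
    std::vector<double> nvx(vx.size());
    for (int it = 0; it < smooth_iter; ++it) {
      for (int v = 0; v < nv; ++v) {
        double m[3] = {0, 0, 0};
        const std::vector<int>& nb = nbr[v];
        if (nb.empty()) {
          for (int k = 0; k < 3; ++k) nvx[3 * v + k] = vx[3 * v + k];
          continue;
        }
        for (int u : nb)
          for (int k = 0; k < 3; ++k) m[k] += vx[3 * u + k];
        for (int k = 0; k < 3; ++k) {
          m[k] /= nb.size();
          nvx[3 * v + k] = (1.0 - lambda) * vx[3 * v + k] + lambda * m[k];
        }
      }
      std::swap(vx, nvx);
    }
  }

  double area = 0.0, svol = 0.0;
  for (size_t t = 0; t < tris.size(); t += 3) {
    const double* a = &vx[3 * tris[t]];
    const double* b = &vx[3 * tris[t + 1]];
    const double* c = &vx[3 * tris[t + 2]];
    area += tri_area(a, b, c);
    // signed tetra volume with the origin (divergence theorem)
    svol += (a[0] * (b[1] * c[2] - b[2] * c[1]) -
             a[1] * (b[0] * c[2] - b[2] * c[0]) +
             a[2] * (b[0] * c[1] - b[1] * c[0])) / 6.0;
  }
  return NumericVector::create(area, std::fabs(svol));
}
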