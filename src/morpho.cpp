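// 3D image-processing primitives backing the segmentation and morphometry
// modules: separable Gaussian smoothing, squared Euclidean distance
// transform (Felzenszwalb), 6-connected labelling, marker-controlled
// watershed (priority flood), per-slice hole filling, local maxima, and
// isosurface area by marching tetrahedra.
//
// Volumes are passed as flat vectors with dim = (nz, ny, nx); element
// (z, y, x) lives at linear index z + nz * (y + ny * x) (R column-major
// with z as the first array dimension). spacing is the physical voxel
// size per axis in the same (z, y, x) order, in micrometres.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline int idx3(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// ---------------------------------------------------------------------------
// Separable Gaussian smoothing with reflecting boundaries.
// sigma is per-axis in voxel units; sigma <= 0 skips that axis.
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector vol, IntegerVector dim,
                               NumericVector sigma) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<double> buf(vol.begin(), vol.end());
  std::vector<double> out(buf.size());
  const int n[3] = {nz, ny, nx};

  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma[axis];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> k(2 * r + 1);
    double norm = 0.0;
    for (int i = -r; i <= r; ++i) {
      k[i + r] = std::exp(-0.5 * (double)i * i / (s * s));
      norm += k[i + r];
    }
    for (double &v : k) v /= norm;

    const int len = n[axis];
    for (int a2 = 0; a2 < (axis == 0 ? ny : nz); ++a2) {
      for (int a3 = 0; a3 < (axis == 2 ? ny : nx); ++a3) {
        for (int i = 0; i < len; ++i) {
          double acc = 0.0;
          for (int j = -r; j <= r; ++j) {
            int p = i + j;
            // reflect (iterated, kernels can exceed the axis length)
            while (p < 0 || p >= len) {
              if (p < 0) p = -p - 1;
              if (p >= len) p = 2 * len - p - 1;
            }
            int src;
            if (axis == 0)      src = idx3(p, a2, a3, nz, ny);
            else if (axis == 1) src = idx3(a2, p, a3, nz, ny);
            else                src = idx3(a2, a3, p, nz, ny);
            acc += k[j + r] * buf[src];
          }
          int dst;
          if (axis == 0)      dst = idx3(i, a2, a3, nz, ny);
          else if (axis == 1) dst = idx3(a2, i, a3, nz, ny);
          else                dst = idx3(a2, a3, i, nz, ny);
          out[dst] = acc;
        }
      }
    }
    buf.swap(out);
  }
  return NumericVector(buf.begin(), buf.end());
}

// ---------------------------------------------------------------------------
// 1D squared-distance transform (Felzenszwalb & Huttenlocher 2012) with
// anisotropic sample spacing `w`.
static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 double w) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  const double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * q - 2.0 * w2 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)(q - v[k]) * w;
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared EDT: distance from each foreground voxel to the nearest
// background voxel (background gets 0). `fg` is 0/1.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(IntegerVector fg, IntegerVector dim,
                         NumericVector spacing) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double INF = 1e30;
  std::vector<double> d(fg.size());
  for (int i = 0; i < (int)fg.size(); ++i) d[i] = fg[i] ? INF : 0.0;

  std::vector<double> f, t;
  // z axis
  f.resize(nz); t.resize(nz);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) f[z] = d[idx3(z, y, x, nz, ny)];
      dt1d(f, t, spacing[0]);
      for (int z = 0; z < nz; ++z) d[idx3(z, y, x, nz, ny)] = t[z];
    }
  // y axis
  f.resize(ny); t.resize(ny);
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) f[y] = d[idx3(z, y, x, nz, ny)];
      dt1d(f, t, spacing[1]);
      for (int y = 0; y < ny; ++y) d[idx3(z, y, x, nz, ny)] = t[y];
    }
  // x axis
  f.resize(nx); t.resize(nx);
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      for (int x = 0; x < nx; ++x) f[x] = d[idx3(z, y, x, nz, ny)];
      dt1d(f, t, spacing[2]);
      for (int x = 0; x < nx; ++x) d[idx3(z, y, x, nz, ny)] = t[x];
    }
  return NumericVector(d.begin(), d.end());
}

// ---------------------------------------------------------------------------
// 6-connected component labelling of a 0/1 volume. Labels are assigned in
// raster-scan order of the first voxel met, so the result is deterministic.
// [[Rcpp::export]]
IntegerVector cpp_label6(IntegerVector fg, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  IntegerVector lab(fg.size(), 0);
  int next = 0;
  std::vector<int> stack;
  const int dz[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dx[6] = {0, 0, 0, 0, 1, -1};
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int i = idx3(z, y, x, nz, ny);
        if (!fg[i] || lab[i]) continue;
        ++next;
        lab[i] = next;
        stack.push_back(i);
        while (!stack.empty()) {
          int c = stack.back();
          stack.pop_back();
          int cz = c % nz, rem = c / nz, cy = rem % ny, cx = rem / ny;
          for (int k = 0; k < 6; ++k) {
            int pz = cz + dz[k], py = cy + dy[k], px = cx + dx[k];
            if (pz < 0 || pz >= nz || py < 0 || py >= ny || px < 0 || px >= nx)
              continue;
            int p = idx3(pz, py, px, nz, ny);
            if (fg[p] && !lab[p]) { lab[p] = next; stack.push_back(p); }
          }
        }
      }
  return lab;
}

// ---------------------------------------------------------------------------
// Marker-controlled watershed by priority flooding. Voxels are popped in
// order of increasing elevation (FIFO within ties for determinism).
// markers: 0 = unassigned, >0 = seed label. mask: 1 = floodable.
// centers: one row per label id (z, y, x in micrometres) or 0-row matrix;
// max_radius > 0 limits each label to a ball around its seed centre.
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector elev, IntegerVector markers,
                            IntegerVector mask, IntegerVector dim,
                            NumericVector spacing, NumericMatrix centers,
                            double max_radius) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  IntegerVector out(elev.size(), 0);
  struct Node { double pri; long order; int idx; int lab; };
  struct Cmp {
    bool operator()(const Node &a, const Node &b) const {
      if (a.pri != b.pri) return a.pri > b.pri;
      return a.order > b.order;
    }
  };
  std::priority_queue<Node, std::vector<Node>, Cmp> pq;
  long counter = 0;
  const bool limited = max_radius > 0 && centers.nrow() > 0;

  for (int i = 0; i < (int)elev.size(); ++i)
    if (markers[i] > 0) {
      out[i] = markers[i];
      pq.push({elev[i], counter++, i, markers[i]});
    }

  const int dz[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dx[6] = {0, 0, 0, 0, 1, -1};
  const double mr2 = max_radius * max_radius;

  while (!pq.empty()) {
    Node nd = pq.top();
    pq.pop();
    int c = nd.idx;
    int cz = c % nz, rem = c / nz, cy = rem % ny, cx = rem / ny;
    for (int k = 0; k < 6; ++k) {
      int pz = cz + dz[k], py = cy + dy[k], px = cx + dx[k];
      if (pz < 0 || pz >= nz || py < 0 || py >= ny || px < 0 || px >= nx)
        continue;
      int p = idx3(pz, py, px, nz, ny);
      if (out[p] != 0 || !mask[p]) continue;
      if (limited && nd.lab <= centers.nrow()) {
        double ddz = pz * spacing[0] - centers(nd.lab - 1, 0);
        double ddy = py * spacing[1] - centers(nd.lab - 1, 1);
        double ddx = px * spacing[2] - centers(nd.lab - 1, 2);
        if (ddz * ddz + ddy * ddy + ddx * ddx > mr2) continue;
      }
      out[p] = nd.lab;
      pq.push({elev[p], counter++, p, nd.lab});
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Fill holes slice-by-slice (xy slices at fixed... here the first axis is z,
// a "slice" is the (y, x) plane at each z): background connected to the
// slice border stays background, enclosed background becomes foreground.
// [[Rcpp::export]]
IntegerVector cpp_fill_holes_slices(IntegerVector fg, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  IntegerVector out = clone(fg);
  std::vector<char> open((size_t)ny * nx);
  std::vector<int> stack;
  for (int z = 0; z < nz; ++z) {
    std::fill(open.begin(), open.end(), 0);
    stack.clear();
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        bool border = (y == 0 || y == ny - 1 || x == 0 || x == nx - 1);
        if (border && !fg[idx3(z, y, x, nz, ny)]) {
          size_t s = (size_t)y * nx + x;
          if (!open[s]) { open[s] = 1; stack.push_back((int)s); }
        }
      }
    const int dy[4] = {1, -1, 0, 0};
    const int dx[4] = {0, 0, 1, -1};
    while (!stack.empty()) {
      int s = stack.back();
      stack.pop_back();
      int y = s / nx, x = s % nx;
      for (int k = 0; k < 4; ++k) {
        int py = y + dy[k], px = x + dx[k];
        if (py < 0 || py >= ny || px < 0 || px >= nx) continue;
        size_t p = (size_t)py * nx + px;
        if (!open[p] && !fg[idx3(z, py, px, nz, ny)]) {
          open[p] = 1;
          stack.push_back((int)p);
        }
      }
    }
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x)
        if (!fg[idx3(z, y, x, nz, ny)] && !open[(size_t)y * nx + x])
          out[idx3(z, y, x, nz, ny)] = 1;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Local maxima of `vol` above min_val, maximal within a physical radius
// min_dist. Returns linear 1-based indices in decreasing value order.
// [[Rcpp::export]]
IntegerVector cpp_local_maxima(NumericVector vol, IntegerVector dim,
                               NumericVector spacing, double min_dist,
                               double min_val) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  int rz = std::max(1, (int)std::floor(min_dist / spacing[0]));
  int ry = std::max(1, (int)std::floor(min_dist / spacing[1]));
  int rx = std::max(1, (int)std::floor(min_dist / spacing[2]));
  std::vector<std::pair<double, int> > cand;
  const double md2 = min_dist * min_dist;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int i = idx3(z, y, x, nz, ny);
        double v = vol[i];
        if (v <= min_val) continue;
        bool is_max = true;
        for (int az = std::max(0, z - rz); is_max && az <= std::min(nz - 1, z + rz); ++az)
          for (int ay = std::max(0, y - ry); is_max && ay <= std::min(ny - 1, y + ry); ++ay)
            for (int ax = std::max(0, x - rx); ax <= std::min(nx - 1, x + rx); ++ax) {
              double dz = (az - z) * spacing[0], dy = (ay - y) * spacing[1],
                     dx = (ax - x) * spacing[2];
              if (dz * dz + dy * dy + dx * dx > md2) continue;
              int j = idx3(az, ay, ax, nz, ny);
              if (j == i) continue;
              if (vol[j] > v || (vol[j] == v && j < i)) { is_max = false; break; }
            }
        if (is_max) cand.push_back(std::make_pair(v, i));
      }
  std::sort(cand.begin(), cand.end(),
            [](const std::pair<double, int> &a, const std::pair<double, int> &b) {
              if (a.first != b.first) return a.first > b.first;
              return a.second < b.second;
            });
  IntegerVector out(cand.size());
  for (size_t i = 0; i < cand.size(); ++i) out[i] = cand[i].second + 1;
  return out;
}

// ---------------------------------------------------------------------------
// Isosurface area by marching tetrahedra. The volume is implicitly padded
// with zeros so surfaces touching the array edge are closed. Cube corners
// are voxel centres; each cube is split into 6 tetrahedra sharing the
// main diagonal.
static inline double samplev(const NumericVector &vol, int z, int y, int x,
                             int nz, int ny, int nx) {
  if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx) return 0.0;
  return vol[idx3(z, y, x, nz, ny)];
}

static inline void interp_pt(const double *pa, const double *pb, double va,
                             double vb, double level, double *out) {
  double t = (level - va) / (vb - va);
  for (int k = 0; k < 3; ++k) out[k] = pa[k] + t * (pb[k] - pa[k]);
}

static inline double tri_area(const double *a, const double *b,
                              const double *c) {
  double u[3], v[3];
  for (int k = 0; k < 3; ++k) { u[k] = b[k] - a[k]; v[k] = c[k] - a[k]; }
  double cx = u[1] * v[2] - u[2] * v[1];
  double cy = u[2] * v[0] - u[0] * v[2];
  double cz = u[0] * v[1] - u[1] * v[0];
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

// [[Rcpp::export]]
double cpp_mesh_area(NumericVector vol, IntegerVector dim,
                     NumericVector spacing, double level) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  // cube corner offsets (z, y, x)
  const int off[8][3] = {{0, 0, 0}, {0, 0, 1}, {0, 1, 1}, {0, 1, 0},
                         {1, 0, 0}, {1, 0, 1}, {1, 1, 1}, {1, 1, 0}};
  const int tets[6][4] = {{0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
                          {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}};
  double area = 0.0;
  double cv[8], cp[8][3];
  for (int x = -1; x < nx; ++x)
    for (int y = -1; y < ny; ++y)
      for (int z = -1; z < nz; ++z) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int pz = z + off[c][0], py = y + off[c][1], px = x + off[c][2];
          cv[c] = samplev(vol, pz, py, px, nz, ny, nx);
          cp[c][0] = pz * spacing[0];
          cp[c][1] = py * spacing[1];
          cp[c][2] = px * spacing[2];
          if (cv[c] > level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int vi[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          int in[4], out[4], ni = 0, no = 0;
          for (int k = 0; k < 4; ++k) {
            if (cv[vi[k]] > level) in[ni++] = vi[k];
            else out[no++] = vi[k];
          }
          if (ni == 0 || ni == 4) continue;
          double p[4][3];
          if (ni == 1 || ni == 3) {
            int apex = (ni == 1) ? in[0] : out[0];
            int *others = (ni == 1) ? out : in;
            for (int k = 0; k < 3; ++k)
              interp_pt(cp[apex], cp[others[k]], cv[apex], cv[others[k]],
                        level, p[k]);
            area += tri_area(p[0], p[1], p[2]);
          } else { // 2 in, 2 out -> quad
            interp_pt(cp[in[0]], cp[out[0]], cv[in[0]], cv[out[0]], level, p[0]);
            interp_pt(cp[in[0]], cp[out[1]], cv[in[0]], cv[out[1]], level, p[1]);
            interp_pt(cp[in[1]], cp[out[1]], cv[in[1]], cv[out[1]], level, p[2]);
            interp_pt(cp[in[1]], cp[out[0]], cv[in[1]], cv[out[0]], level, p[3]);
            area += tri_area(p[0], p[1], p[2]);
            area += tri_area(p[0], p[2], p[3]);
          }
        }
      }
  return area;
}

// ---------------------------------------------------------------------------
// Boundary voxels of a label volume: voxels whose 6-neighbourhood (or the
// array edge, if include_edge) contains a different value.
// [[Rcpp::export]]
IntegerVector cpp_label_boundary(IntegerVector lab, IntegerVector dim,
                                 bool include_edge) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  IntegerVector out(lab.size(), 0);
  const int dz[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dx[6] = {0, 0, 0, 0, 1, -1};
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int i = idx3(z, y, x, nz, ny);
        if (!lab[i]) continue;
        bool bnd = false;
        for (int k = 0; k < 6 && !bnd; ++k) {
          int pz = z + dz[k], py = y + dy[k], px = x + dx[k];
          if (pz < 0 || pz >= nz || py < 0 || py >= ny || px < 0 || px >= nx) {
            if (include_edge) bnd = true;
            continue;
          }
          if (lab[idx3(pz, py, px, nz, ny)] != lab[i]) bnd = true;
        }
        if (bnd) out[i] = 1;
      }
  return out;
}
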