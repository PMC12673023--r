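// Computational kernels for the aorta4d pipeline.
//
// Voxel arrays use R's column-major layout: linear index = i + nx*(j + ny*k),
// 0-based here, with voxel centers at world = origin + index * spacing.
// All world coordinates are in millimetres.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <queue>
#include <vector>
#include <unordered_map>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// ---------------------------------------------------------------- voxelization

// Union of spheres along a polyline: mask voxel centers within radius of any
// sample point. Radii may vary per sample (tapered tubes).
// [[Rcpp::export]]
IntegerVector cpp_stamp_tube(IntegerVector dim, NumericVector origin,
                             NumericVector spacing, NumericMatrix centers,
                             NumericVector radii) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector out((R_xlen_t)nx * ny * nz);
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  for (int c = 0; c < centers.nrow(); ++c) {
    const double cx = centers(c, 0), cy = centers(c, 1), cz = centers(c, 2);
    const double r = radii[c], r2 = r * r;
    int i0 = clampi((int)std::ceil((cx - r - ox) / sx), 0, nx - 1);
    int i1 = clampi((int)std::floor((cx + r - ox) / sx), 0, nx - 1);
    int j0 = clampi((int)std::ceil((cy - r - oy) / sy), 0, ny - 1);
    int j1 = clampi((int)std::floor((cy + r - oy) / sy), 0, ny - 1);
    int k0 = clampi((int)std::ceil((cz - r - oz) / sz), 0, nz - 1);
    int k1 = clampi((int)std::floor((cz + r - oz) / sz), 0, nz - 1);
    for (int k = k0; k <= k1; ++k) {
      const double dz = oz + k * sz - cz, dz2 = dz * dz;
      if (dz2 > r2) continue;
      for (int j = j0; j <= j1; ++j) {
        const double dy = oy + j * sy - cy, d2yz = dz2 + dy * dy;
        if (d2yz > r2) continue;
        const R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        for (int i = i0; i <= i1; ++i) {
          const double dx = ox + i * sx - cx;
          if (d2yz + dx * dx <= r2) out[base + i] = 1;
        }
      }
    }
  }
  return out;
}

// Clear foreground on the positive side of a plane, within `limit` mm of
// `point` (used to cut tube ends flat).
// [[Rcpp::export]]
IntegerVector cpp_clip_halfspace(IntegerVector mask, IntegerVector dim,
                                 NumericVector origin, NumericVector spacing,
                                 NumericVector point, NumericVector normal,
                                 double limit) {
  IntegerVector out = clone(mask);
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  int i0 = clampi((int)std::floor((point[0] - limit - ox) / sx), 0, nx - 1);
  int i1 = clampi((int)std::ceil((point[0] + limit - ox) / sx), 0, nx - 1);
  int j0 = clampi((int)std::floor((point[1] - limit - oy) / sy), 0, ny - 1);
  int j1 = clampi((int)std::ceil((point[1] + limit - oy) / sy), 0, ny - 1);
  int k0 = clampi((int)std::floor((point[2] - limit - oz) / sz), 0, nz - 1);
  int k1 = clampi((int)std::ceil((point[2] + limit - oz) / sz), 0, nz - 1);
  for (int k = k0; k <= k1; ++k)
    for (int j = j0; j <= j1; ++j)
      for (int i = i0; i <= i1; ++i) {
        const double px = ox + i * sx - point[0];
        const double py = oy + j * sy - point[1];
        const double pz = oz + k * sz - point[2];
        if (px * normal[0] + py * normal[1] + pz * normal[2] > 0.0)
          out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = 0;
      }
  return out;
}

// ------------------------------------------------------ distance transform

// 1D squared distance transform (Felzenszwalb & Huttenlocher) with sample
// spacing h.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 double h) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      const double qq = (double)q * h, vv = (double)v[k] * h;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2 * qq - 2 * vv);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    const double qq = (double)q * h;
    while (z[k + 1] < qq) ++k;
    const double dv = qq - (double)v[k] * h;
    d[q] = dv * dv + f[v[k]];
  }
}

// Euclidean distance (mm) from each voxel to the nearest background voxel.
// Background voxels get 0. Assumes foreground does not touch the array edge.
// [[Rcpp::export]]
NumericVector cpp_edt(IntegerVector mask, IntegerVector dim,
                      NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  const double INF = 1e30;
  for (R_xlen_t t = 0; t < n; ++t) out[t] = mask[t] ? INF : 0.0;
  // pass along x
  {
    std::vector<double> f(nx), d(nx);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        const R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        for (int i = 0; i < nx; ++i) f[i] = out[base + i];
        dt1d(f, d, nx, spacing[0]);
        for (int i = 0; i < nx; ++i) out[base + i] = d[i];
      }
  }
  // pass along y
  {
    std::vector<double> f(ny), d(ny);
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i < nx; ++i) {
        for (int j = 0; j < ny; ++j)
          f[j] = out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
        dt1d(f, d, ny, spacing[1]);
        for (int j = 0; j < ny; ++j)
          out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = d[j];
      }
  }
  // pass along z
  {
    std::vector<double> f(nz), d(nz);
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        for (int k = 0; k < nz; ++k)
          f[k] = out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
        dt1d(f, d, nz, spacing[2]);
        for (int k = 0; k < nz; ++k)
          out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = std::sqrt(d[k]);
      }
  }
  return out;
}

// ------------------------------------------------------ connected components

// 26-connected component labels (0 = background, components numbered from 1,
// in scan order).
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int i = (int)(cur % nx);
      const int j = (int)((cur / nx) % ny);
      const int k = (int)(cur / ((R_xlen_t)nx * ny));
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            const int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            const R_xlen_t q = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            if (mask[q] && !lab[q]) {
              lab[q] = next;
              stack.push_back(q);
            }
          }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// ---------------------------------------------------------------- Dijkstra

// Medialness-weighted shortest path through the foreground: edge cost is
// step length / (1e-3 + boundary distance of the target voxel). Returns the
// path as 0-based voxel indices (rows), src first; 0 rows if unreachable.
// [[Rcpp::export]]
IntegerMatrix cpp_dijkstra_path(IntegerVector mask, NumericVector dtb,
                                IntegerVector dim, NumericVector spacing,
                                IntegerVector src, IntegerVector dst) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const R_xlen_t s0 = src[0] + (R_xlen_t)nx * (src[1] + (R_xlen_t)ny * src[2]);
  const R_xlen_t s1 = dst[0] + (R_xlen_t)nx * (dst[1] + (R_xlen_t)ny * dst[2]);
  if (!mask[s0] || !mask[s1]) stop("seed voxel outside foreground");
  std::vector<double> dist(n, INFINITY);
  std::vector<R_xlen_t> prev(n, -1);
  typedef std::pair<double, R_xlen_t> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  dist[s0] = 0.0;
  pq.push(QE(0.0, s0));
  double step[3][3][3];
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di)
        step[di + 1][dj + 1][dk + 1] =
            std::sqrt(di * di * spacing[0] * spacing[0] +
                      dj * dj * spacing[1] * spacing[1] +
                      dk * dk * spacing[2] * spacing[2]);
  while (!pq.empty()) {
    const QE top = pq.top();
    pq.pop();
    const R_xlen_t u = top.second;
    if (top.first > dist[u]) continue;
    if (u == s1) break;
    const int i = (int)(u % nx);
    const int j = (int)((u / nx) % ny);
    const int k = (int)(u / ((R_xlen_t)nx * ny));
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (!di && !dj && !dk) continue;
          const int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;
          const R_xlen_t v = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
          if (!mask[v]) continue;
          const double c =
              step[di + 1][dj + 1][dk + 1] / (1e-3 + dtb[v]);
          if (dist[u] + c < dist[v]) {
            dist[v] = dist[u] + c;
            prev[v] = u;
            pq.push(QE(dist[v], v));
          }
        }
  }
  if (!std::isfinite(dist[s1])) return IntegerMatrix(0, 3);
  std::vector<R_xlen_t> path;
  for (R_xlen_t v = s1; v != -1; v = prev[v]) path.push_back(v);
  IntegerMatrix out((int)path.size(), 3);
  for (int r = 0; r < (int)path.size(); ++r) {
    const R_xlen_t v = path[path.size() - 1 - r];
    out(r, 0) = (int)(v % nx);
    out(r, 1) = (int)((v / nx) % ny);
    out(r, 2) = (int)(v / ((R_xlen_t)nx * ny));
  }
  return out;
}

// ------------------------------------------------------------- smoothing

// Separable Gaussian smoothing (sigma in voxel units, truncated at 3 sigma,
// renormalized at array edges).
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector vol, IntegerVector dim,
                               double sigma_vox) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int rad = std::max(1, (int)std::ceil(3.0 * sigma_vox));
  std::vector<double> w(2 * rad + 1);
  for (int t = -rad; t <= rad; ++t)
    w[t + rad] = std::exp(-0.5 * t * t / (sigma_vox * sigma_vox));
  NumericVector a = clone(vol), b((R_xlen_t)nx * ny * nz);
  const int dims[3] = {nx, ny, nz};
  const R_xlen_t strides[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    const int nA = dims[ax];
    const R_xlen_t sA = strides[ax];
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const int idx3[3] = {i, j, k};
          const int p = idx3[ax];
          const R_xlen_t lin = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
          double acc = 0.0, norm = 0.0;
          const int t0 = std::max(-rad, -p), t1 = std::min(rad, nA - 1 - p);
          for (int t = t0; t <= t1; ++t) {
            acc += w[t + rad] * a[lin + t * sA];
            norm += w[t + rad];
          }
          b[lin] = acc / norm;
        }
    std::swap(a, b);
  }
  return a;
}

// -------------------------------------------------------- marching tetrahedra

// Iso-surface of a scalar volume by marching tetrahedra (6 tetrahedra per
// cube sharing the main diagonal; watertight across cube faces). Vertices are
// deduplicated by grid edge. Returns world-mm vertices and 1-based triangles.
// [[Rcpp::export]]
List cpp_march_tets(NumericVector vol, IntegerVector dim, NumericVector origin,
                    NumericVector spacing, double level) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  static const int TETS[6][4] = {{0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
                                 {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}};
  static const int CIDX[8][3] = {{0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
                                 {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}};
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> verts;  // x,y,z triplets
  std::vector<int> tris;      // 0-based vertex indices
  std::vector<R_xlen_t> node(8);
  std::vector<double> val(8);

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        bool lo = false, hi = false;
        for (int c = 0; c < 8; ++c) {
          const int ii = i + CIDX[c][0], jj = j + CIDX[c][1],
                    kk = k + CIDX[c][2];
          node[c] = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
          val[c] = vol[node[c]];
          if (val[c] < level) lo = true; else hi = true;
        }
        if (!lo || !hi) continue;
        for (int t = 0; t < 6; ++t) {
          int above[4], nab = 0;
          for (int c = 0; c < 4; ++c)
            above[c] = val[TETS[t][c]] >= level ? (++nab, 1) : 0;
          if (nab == 0 || nab == 4) continue;
          // collect crossing edges of this tetrahedron
          int ev[4], ne = 0;  // vertex ids on crossing edges
          // order edges so the 2-2 case forms a fan-able quad
          int order[4][2], no = 0;
          if (nab == 1 || nab == 3) {
            const int ref = (nab == 1)
                                ? (above[0] ? 0 : above[1] ? 1 : above[2] ? 2 : 3)
                                : (!above[0] ? 0 : !above[1] ? 1 : !above[2] ? 2 : 3);
            for (int c = 0; c < 4; ++c)
              if (c != ref) { order[no][0] = ref; order[no][1] = c; ++no; }
          } else {
            // two above (a1,a2), two below (b1,b2): quad a1b1, a2b1, a2b2, a1b2
            int aa[2], bb[2], na = 0, nb = 0;
            for (int c = 0; c < 4; ++c)
              (above[c] ? aa[na++] : bb[nb++]) = c;
            order[0][0] = aa[0]; order[0][1] = bb[0];
            order[1][0] = aa[1]; order[1][1] = bb[0];
            order[2][0] = aa[1]; order[2][1] = bb[1];
            order[3][0] = aa[0]; order[3][1] = bb[1];
            no = 4;
          }
          for (int e = 0; e < no; ++e) {
            const int ca = TETS[t][order[e][0]], cb = TETS[t][order[e][1]];
            const R_xlen_t na_ = node[ca], nb_ = node[cb];
            const uint64_t key =
                na_ < nb_ ? ((uint64_t)na_ << 32) | (uint64_t)nb_
                          : ((uint64_t)nb_ << 32) | (uint64_t)na_;
            std::unordered_map<uint64_t, int>::iterator it =
                edge_vertex.find(key);
            if (it == edge_vertex.end()) {
              const double fa = val[ca], fb = val[cb];
              double tt = (level - fa) / (fb - fa);
              if (!std::isfinite(tt)) tt = 0.5;
              const double pa[3] = {origin[0] + (i + CIDX[ca][0]) * spacing[0],
                                    origin[1] + (j + CIDX[ca][1]) * spacing[1],
                                    origin[2] + (k + CIDX[ca][2]) * spacing[2]};
              const double pb[3] = {origin[0] + (i + CIDX[cb][0]) * spacing[0],
                                    origin[1] + (j + CIDX[cb][1]) * spacing[1],
                                    origin[2] + (k + CIDX[cb][2]) * spacing[2]};
              verts.push_back(pa[0] + tt * (pb[0] - pa[0]));
              verts.push_back(pa[1] + tt * (pb[1] - pa[1]));
              verts.push_back(pa[2] + tt * (pb[2] - pa[2]));
              const int id = (int)(verts.size() / 3) - 1;
              edge_vertex.insert(std::make_pair(key, id));
              ev[e] = id;
            } else {
              ev[e] = it->second;
            }
          }
          ne = no;
          if (ne == 3) {
            tris.push_back(ev[0]); tris.push_back(ev[1]); tris.push_back(ev[2]);
          } else if (ne == 4) {
            tris.push_back(ev[0]); tris.push_back(ev[1]); tris.push_back(ev[2]);
            tris.push_back(ev[0]); tris.push_back(ev[2]); tris.push_back(ev[3]);
          }
        }
      }
  const int nv = (int)(verts.size() / 3), nt = (int)(tris.size() / 3);
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) {
    V(v, 0) = verts[3 * v];
    V(v, 1) = verts[3 * v + 1];
    V(v, 2) = verts[3 * v + 2];
  }
  IntegerMatrix T(nt, 3);
  for (int t = 0; t < nt; ++t) {
    T(t, 0) = tris[3 * t] + 1;
    T(t, 1) = tris[3 * t + 1] + 1;
    T(t, 2) = tris[3 * t + 2] + 1;
  }
  return List::create(Named("vertices") = V, Named("triangles") = T);
}

// ------------------------------------------------------------- interpolation

static inline double trilerp(const NumericVector& vol, const int* dim,
                             const double* origin, const double* spacing,
                             double x, double y, double z) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  double fx = (x - origin[0]) / spacing[0];
  double fy = (y - origin[1]) / spacing[1];
  double fz = (z - origin[2]) / spacing[2];
  int i = (int)std::floor(fx), j = (int)std::floor(fy), k = (int)std::floor(fz);
  if (i < 0 || j < 0 || k < 0 || i > nx - 2 || j > ny - 2 || k > nz - 2) {
    // outside the grid: clamp (volumes are padded so this is background)
    i = clampi(i, 0, nx - 2); j = clampi(j, 0, ny - 2); k = clampi(k, 0, nz - 2);
    fx = std::min(std::max(fx, (double)i), (double)i + 1);
    fy = std::min(std::max(fy, (double)j), (double)j + 1);
    fz = std::min(std::max(fz, (double)k), (double)k + 1);
  }
  const double ax = fx - i, ay = fy - j, az = fz - k;
  double acc = 0.0;
  for (int dk = 0; dk <= 1; ++dk)
    for (int dj = 0; dj <= 1; ++dj)
      for (int di = 0; di <= 1; ++di) {
        const double wgt = (di ? ax : 1 - ax) * (dj ? ay : 1 - ay) *
                           (dk ? az : 1 - az);
        acc += wgt * vol[(i + di) +
                         (R_xlen_t)nx * ((j + dj) + (R_xlen_t)ny * (k + dk))];
      }
  return acc;
}

// Trilinear interpolation of a volume at world-mm points.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dim,
                            NumericVector origin, NumericVector spacing,
                            NumericMatrix pts) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  const double o[3] = {origin[0], origin[1], origin[2]};
  const double s[3] = {spacing[0], spacing[1], spacing[2]};
  NumericVector out(pts.nrow());
  for (int p = 0; p < pts.nrow(); ++p)
    out[p] = trilerp(vol, d, o, s, pts(p, 0), pts(p, 1), pts(p, 2));
  return out;
}

// Central-difference gradient of a volume, trilinearly interpolated at
// world-mm points (per-mm units).
// [[Rcpp::export]]
NumericMatrix cpp_gradient_at(NumericVector vol, IntegerVector dim,
                              NumericVector origin, NumericVector spacing,
                              NumericMatrix pts) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  const double o[3] = {origin[0], origin[1], origin[2]};
  const double s[3] = {spacing[0], spacing[1], spacing[2]};
  NumericMatrix out(pts.nrow(), 3);
  for (int p = 0; p < pts.nrow(); ++p)
    for (int ax = 0; ax < 3; ++ax) {
      double hi[3] = {pts(p, 0), pts(p, 1), pts(p, 2)};
      double lo[3] = {pts(p, 0), pts(p, 1), pts(p, 2)};
      hi[ax] += s[ax];
      lo[ax] -= s[ax];
      out(p, ax) = (trilerp(vol, d, o, s, hi[0], hi[1], hi[2]) -
                    trilerp(vol, d, o, s, lo[0], lo[1], lo[2])) /
                   (2.0 * s[ax]);
    }
  return out;
}

// ------------------------------------------------------------- decimation

// Farthest-point sampling: k indices (1-based), starting from `start`
// (0-based). Deterministic.
// [[Rcpp::export]]
IntegerVector cpp_fps(NumericMatrix pts, int k, int start) {
  const int n = pts.nrow();
  if (k >= n) {
    IntegerVector all(n);
    for (int i = 0; i < n; ++i) all[i] = i + 1;
    return all;
  }
  std::vector<double> mind(n, INFINITY);
  IntegerVector out(k);
  int cur = start;
  for (int s = 0; s < k; ++s) {
    out[s] = cur + 1;
    const double cx = pts(cur, 0), cy = pts(cur, 1), cz = pts(cur, 2);
    double best = -1.0;
    int bi = 0;
    for (int i = 0; i < n; ++i) {
      const double dx = pts(i, 0) - cx, dy = pts(i, 1) - cy,
                   dz = pts(i, 2) - cz;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < mind[i]) mind[i] = d2;
      if (mind[i] > best) { best = mind[i]; bi = i; }
    }
    cur = bi;
  }
  return out;
}

// ------------------------------------------------- coherent point drift (EM)

// Eigendecomposition of the Gaussian kernel G_ij = exp(-|y_i-y_j|^2/(2 beta^2))
// truncated to the K largest eigenpairs (low-rank motion basis).
// [[Rcpp::export]]
List cpp_kernel_eig(arma::mat Y, double beta, int K) {
  const int M = Y.n_rows;
  K = std::min(K, M);
  arma::colvec yy = arma::sum(Y % Y, 1);
  arma::mat G = Y * Y.t();
  G *= -2.0;
  G.each_col() += yy;
  G.each_row() += yy.t();
  G = arma::exp(G / (-2.0 * beta * beta));
  arma::vec eval;
  arma::mat evec;
  arma::eig_sym(eval, evec, G);  // ascending
  arma::uvec idx = arma::regspace<arma::uvec>(M - K, M - 1);
  arma::mat Q = evec.cols(idx);
  arma::vec lam = eval.elem(idx);
  lam.transform([](double v) { return v < 1e-10 ? 1e-10 : v; });
  return List::create(Named("Q") = Q, Named("lam") = lam);
}

// Non-rigid coherent point drift of moving set Y onto target X, motion field
// restricted to the span of the supplied kernel eigenbasis (Q, lam).
// Returns coefficients W, displacements V = G W, and EM diagnostics.
// [[Rcpp::export]]
List cpp_cpd_nonrigid(arma::mat X, arma::mat Y, arma::mat Q, arma::vec lam,
                      double lambda, double w, int maxit, double tol,
                      arma::mat Winit, double sigma2_init) {
  const int M = Y.n_rows, N = X.n_rows, D = 3;
  arma::mat W = Winit;
  arma::mat GW = Q * (arma::diagmat(lam) * (Q.t() * W));
  arma::mat T = Y + GW;
  arma::rowvec xx = arma::sum(X % X, 1).t();  // 1 x N
  double sigma2 = sigma2_init;
  if (sigma2 <= 0) {
    const double sx = arma::accu(xx), st = arma::accu(arma::sum(T % T, 1));
    const arma::rowvec mx = arma::mean(X, 0), mt = arma::mean(T, 0);
    sigma2 = (sx * M + st * N - 2.0 * M * N * arma::dot(mx, mt)) /
             ((double)M * N * D);
    if (sigma2 <= 0) sigma2 = 1.0;
  }
  int it = 0;
  bool converged = false;
  for (it = 1; it <= maxit; ++it) {
    // E-step
    arma::colvec tt = arma::sum(T % T, 1);
    arma::mat Kmat = T * X.t();
    Kmat *= -2.0;
    Kmat.each_col() += tt;
    Kmat.each_row() += xx;
    Kmat = arma::exp(Kmat / (-2.0 * sigma2));
    double c = 0.0;
    if (w > 0)
      c = std::pow(2.0 * M_PI * sigma2, 1.5) * (w / (1.0 - w)) *
          ((double)M / (double)N);
    arma::rowvec denom = arma::sum(Kmat, 0) + c;
    denom.transform([](double v) { return v < 1e-300 ? 1e-300 : v; });
    Kmat.each_row() /= denom;  // Kmat is now P
    arma::colvec p1 = arma::sum(Kmat, 1);
    arma::rowvec pt1 = arma::sum(Kmat, 0);
    const double Np = arma::accu(p1);
    arma::mat PX = Kmat * X;
    // M-step (Woodbury with low-rank G)
    arma::mat RHS = PX - (Y.each_col() % p1);
    const double csig = lambda * sigma2;
    arma::mat DQ = Q.each_col() % p1;
    arma::mat inner = Q.t() * DQ;
    inner += csig * arma::diagmat(1.0 / lam);
    W = (RHS - DQ * arma::solve(inner, Q.t() * RHS,
                                arma::solve_opts::fast)) /
        csig;
    GW = Q * (arma::diagmat(lam) * (Q.t() * W));
    T = Y + GW;
    const double s_old = sigma2;
    sigma2 = (arma::dot(pt1, xx.t()) - 2.0 * arma::accu(PX % T) +
              arma::dot(p1, arma::sum(T % T, 1))) /
             (Np * D);
    if (sigma2 < 1e-12) sigma2 = 1e-12;
    if (sigma2 <= 1e-10 ||
        std::fabs(sigma2 - s_old) / std::max(s_old, 1e-12) < tol) {
      converged = true;  // below ~1e-5 mm RMS the fit cannot improve
      break;
    }
  }
  // residual: mean nearest-neighbour distance of mapped ref to target
  arma::colvec tt = arma::sum(T % T, 1);
  arma::mat D2 = T * X.t();
  D2 *= -2.0;
  D2.each_col() += tt;
  D2.each_row() += xx;
  const double resid = arma::mean(arma::sqrt(arma::clamp(
      arma::min(D2, 1), 0.0, arma::datum::inf)));
  return List::create(Named("W") = W, Named("V") = GW, Named("sigma2") = sigma2,
                      Named("iterations") = std::min(it, maxit),
                      Named("converged") = converged,
                      Named("residual") = resid);
}

// Normal-constrained CPD refinement: moving points T1 (already bulk-aligned)
// are displaced along fixed unit normals Nrm by a scalar field g = G w
// expanded in the supplied kernel eigenbasis. Removes the tangential
// (aperture-null) degrees of freedom; used as the fine stage after the
// stiff vector stage.
// [[Rcpp::export]]
List cpp_cpd_normal(arma::mat X, arma::mat T1, arma::mat Nrm, arma::mat Q,
                    arma::vec lam, double lambda, double w, int maxit,
                    double tol, arma::vec winit, double sigma2_init) {
  const int M = T1.n_rows, N = X.n_rows, D = 3;
  arma::vec wv = winit;
  arma::vec g = Q * (lam % (Q.t() * wv));
  arma::mat T = T1 + (Nrm.each_col() % g);
  arma::rowvec xx = arma::sum(X % X, 1).t();
  double sigma2 = sigma2_init;
  if (sigma2 <= 0) {
    const double sx = arma::accu(xx), st = arma::accu(arma::sum(T % T, 1));
    const arma::rowvec mx = arma::mean(X, 0), mt = arma::mean(T, 0);
    sigma2 = (sx * M + st * N - 2.0 * M * N * arma::dot(mx, mt)) /
             ((double)M * N * D);
    if (sigma2 <= 0) sigma2 = 1.0;
  }
  int it = 0;
  bool converged = false;
  for (it = 1; it <= maxit; ++it) {
    arma::colvec tt = arma::sum(T % T, 1);
    arma::mat Kmat = T * X.t();
    Kmat *= -2.0;
    Kmat.each_col() += tt;
    Kmat.each_row() += xx;
    Kmat = arma::exp(Kmat / (-2.0 * sigma2));
    double c = 0.0;
    if (w > 0)
      c = std::pow(2.0 * M_PI * sigma2, 1.5) * (w / (1.0 - w)) *
          ((double)M / (double)N);
    arma::rowvec denom = arma::sum(Kmat, 0) + c;
    denom.transform([](double v) { return v < 1e-300 ? 1e-300 : v; });
    Kmat.each_row() /= denom;
    arma::colvec p1 = arma::sum(Kmat, 1);
    arma::rowvec pt1 = arma::sum(Kmat, 0);
    const double Np = arma::accu(p1);
    arma::mat PX = Kmat * X;
    arma::vec b = arma::sum(PX % Nrm, 1);           // n_m . (PX)_m
    arma::vec cproj = arma::sum(T1 % Nrm, 1);       // n_m . t1_m
    arma::vec RHS = b - p1 % cproj;
    const double csig = lambda * sigma2;
    arma::mat DQ = Q.each_col() % p1;
    arma::mat inner = Q.t() * DQ;
    inner += csig * arma::diagmat(1.0 / lam);
    wv = (RHS - DQ * arma::solve(inner, Q.t() * RHS,
                                 arma::solve_opts::fast)) /
         csig;
    g = Q * (lam % (Q.t() * wv));
    T = T1 + (Nrm.each_col() % g);
    const double s_old = sigma2;
    sigma2 = (arma::dot(pt1, xx.t()) - 2.0 * arma::accu(PX % T) +
              arma::dot(p1, arma::sum(T % T, 1))) /
             (Np * D);
    if (sigma2 < 1e-12) sigma2 = 1e-12;
    if (sigma2 <= 1e-10 ||
        std::fabs(sigma2 - s_old) / std::max(s_old, 1e-12) < tol) {
      converged = true;  // below ~1e-5 mm RMS the fit cannot improve
      break;
    }
  }
  arma::colvec tt = arma::sum(T % T, 1);
  arma::mat D2 = T * X.t();
  D2 *= -2.0;
  D2.each_col() += tt;
  D2.each_row() += xx;
  const double resid = arma::mean(arma::sqrt(arma::clamp(
      arma::min(D2, 1), 0.0, arma::datum::inf)));
  return List::create(Named("w") = wv,
                      Named("V") = arma::mat(Nrm.each_col() % g),
                      Named("sigma2") = sigma2,
                      Named("iterations") = std::min(it, maxit),
                      Named("converged") = converged,
                      Named("residual") = resid);
}

// Normalized Gaussian-kernel interpolation of displacements defined at
// reference points onto arbitrary query points.
// [[Rcpp::export]]
NumericMatrix cpp_kernel_interp(NumericMatrix query, NumericMatrix ref,
                                NumericMatrix disp, double h) {
  const int nq = query.nrow(), nr = ref.nrow();
  NumericMatrix out(nq, 3);
  const double inv = -0.5 / (h * h);
  for (int q = 0; q < nq; ++q) {
    double sw = 0.0, ax = 0.0, ay = 0.0, az = 0.0;
    double bestd = INFINITY;
    int besti = 0;
    for (int r = 0; r < nr; ++r) {
      const double dx = query(q, 0) - ref(r, 0);
      const double dy = query(q, 1) - ref(r, 1);
      const double dz = query(q, 2) - ref(r, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < bestd) { bestd = d2; besti = r; }
      const double wgt = std::exp(d2 * inv);
      sw += wgt;
      ax += wgt * disp(r, 0);
      ay += wgt * disp(r, 1);
      az += wgt * disp(r, 2);
    }
    if (sw > 1e-12) {
      out(q, 0) = ax / sw; out(q, 1) = ay / sw; out(q, 2) = az / sw;
    } else {  // isolated query: fall back to nearest reference point
      out(q, 0) = disp(besti, 0);
      out(q, 1) = disp(besti, 1);
      out(q, 2) = disp(besti, 2);
    }
  }
  return out;
}

// ----------------------------------------------- arc-length (nearest-s) map

// For every voxel within rmax of the polyline, the arc-length coordinate of
// the nearest polyline sample (and the distance). Voxels further than rmax
// get s = NA. Voxels whose nearest sample is an endpoint have their s
// linearly extrapolated along the end tangent, so the coordinate keeps
// increasing past the distal end (and decreasing before the proximal end)
// instead of accumulating at the terminal value.
// [[Rcpp::export]]
List cpp_nearest_arclength(IntegerVector dim, NumericVector origin,
                           NumericVector spacing, NumericMatrix cpts,
                           NumericVector svals, double rmax) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int nc = cpts.nrow();
  NumericVector smap(n, NA_REAL), dmap(n, R_PosInf);
  std::vector<int> imap(n, -1);
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double r2max = rmax * rmax;
  for (int c = 0; c < nc; ++c) {
    const double cx = cpts(c, 0), cy = cpts(c, 1), cz = cpts(c, 2);
    const double sv = svals[c];
    int i0 = clampi((int)std::ceil((cx - rmax - ox) / sx), 0, nx - 1);
    int i1 = clampi((int)std::floor((cx + rmax - ox) / sx), 0, nx - 1);
    int j0 = clampi((int)std::ceil((cy - rmax - oy) / sy), 0, ny - 1);
    int j1 = clampi((int)std::floor((cy + rmax - oy) / sy), 0, ny - 1);
    int k0 = clampi((int)std::ceil((cz - rmax - oz) / sz), 0, nz - 1);
    int k1 = clampi((int)std::floor((cz + rmax - oz) / sz), 0, nz - 1);
    for (int k = k0; k <= k1; ++k) {
      const double dz = oz + k * sz - cz, dz2 = dz * dz;
      if (dz2 > r2max) continue;
      for (int j = j0; j <= j1; ++j) {
        const double dy = oy + j * sy - cy, d2yz = dz2 + dy * dy;
        if (d2yz > r2max) continue;
        const R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        for (int i = i0; i <= i1; ++i) {
          const double dx = ox + i * sx - cx;
          const double d2 = d2yz + dx * dx;
          if (d2 < dmap[base + i]) {
            dmap[base + i] = d2;
            smap[base + i] = sv;
            imap[base + i] = c;
          }
        }
      }
    }
  }
  // end extrapolation: unit tangents at the two ends
  double t0[3] = {0, 0, 0}, t1[3] = {0, 0, 0};
  if (nc >= 2) {
    double n0 = 0, n1 = 0;
    for (int ax = 0; ax < 3; ++ax) {
      t0[ax] = cpts(1, ax) - cpts(0, ax);
      t1[ax] = cpts(nc - 1, ax) - cpts(nc - 2, ax);
      n0 += t0[ax] * t0[ax];
      n1 += t1[ax] * t1[ax];
    }
    for (int ax = 0; ax < 3; ++ax) {
      t0[ax] /= std::sqrt(n0);
      t1[ax] /= std::sqrt(n1);
    }
  }
  for (R_xlen_t t = 0; t < n; ++t) {
    if (!std::isfinite(dmap[t])) continue;
    dmap[t] = std::sqrt(dmap[t]);
    if (imap[t] == 0 || imap[t] == nc - 1) {
      const int i = (int)(t % nx);
      const int j = (int)((t / nx) % ny);
      const int k = (int)(t / ((R_xlen_t)nx * ny));
      const double px = ox + i * sx, py = oy + j * sy, pz = oz + k * sz;
      if (imap[t] == 0) {
        const double proj = (px - cpts(0, 0)) * t0[0] +
                            (py - cpts(0, 1)) * t0[1] +
                            (pz - cpts(0, 2)) * t0[2];
        if (proj < 0) smap[t] = svals[0] + proj;
      } else {
        const double proj = (px - cpts(nc - 1, 0)) * t1[0] +
                            (py - cpts(nc - 1, 1)) * t1[1] +
                            (pz - cpts(nc - 1, 2)) * t1[2];
        if (proj > 0) smap[t] = svals[nc - 1] + proj;
      }
    }
  }
  return List::create(Named("s") = smap, Named("dist") = dmap);
}

// ------------------------------------------------- supersampled volume

// Segment volume with sub-voxel accuracy: candidate voxels are those whose
// arc-length coordinate falls near [s_lo, s_hi]; each is subdivided into
// factor^3 sample points, counted when the (smoothed) mask field exceeds
// `level` and the trilinearly interpolated arc-length map falls inside the
// range. Sub-voxel sampling against a smooth field suppresses the lattice
// quantization that coherently biases plain voxel counts of a tube.
// [[Rcpp::export]]
double cpp_segment_volume_fine(NumericVector vol, NumericVector smap,
                               IntegerVector dim, NumericVector origin,
                               NumericVector spacing, double s_lo,
                               double s_hi, double level, int factor) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  const double o[3] = {origin[0], origin[1], origin[2]};
  const double sp[3] = {spacing[0], spacing[1], spacing[2]};
  const int nx = d[0], ny = d[1], nz = d[2];
  const double pad = 2.0 * std::max(sp[0], std::max(sp[1], sp[2]));
  const double cell = (sp[0] / factor) * (sp[1] / factor) * (sp[2] / factor);
  // replace NA in smap by a far-out value so trilinear stays defined at the
  // map edge (candidates are well inside the map)
  NumericVector smap2 = clone(smap);
  for (R_xlen_t t = 0; t < smap2.size(); ++t)
    if (!R_finite(smap2[t])) smap2[t] = -1e9;
  double acc = 0.0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t lin = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        if (vol[lin] < 0.02) continue;
        const double sv = smap2[lin];
        if (sv < s_lo - pad || sv > s_hi + pad) continue;
        const double bx = o[0] + i * sp[0], by = o[1] + j * sp[1],
                     bz = o[2] + k * sp[2];
        // irrational sub-step offsets, rotated per z-layer, decohere the
        // lattice error along an axis-aligned tube
        const double jx0 = 0.2376 + 0.7548 * k;
        const double jy0 = 0.4873 + 0.5698 * k;
        const double jx = jx0 - std::floor(jx0);
        const double jy = jy0 - std::floor(jy0);
        for (int fk = 0; fk < factor; ++fk)
          for (int fj = 0; fj < factor; ++fj)
            for (int fi = 0; fi < factor; ++fi) {
              const double px = bx + (fi + jx) * sp[0] / factor - sp[0] / 2;
              const double py = by + (fj + jy) * sp[1] / factor - sp[1] / 2;
              const double pz = bz + (fk + 0.3259) * sp[2] / factor - sp[2] / 2;
              if (trilerp(vol, d, o, sp, px, py, pz) < level) continue;
              const double ss = trilerp(smap2, d, o, sp, px, py, pz);
              if (ss >= s_lo && ss <= s_hi) acc += cell;
            }
      }
  return acc;
}

// ---------------------------------------------- in-plane region centroid

// Centroid (world mm) and area of the in-plane connected region containing
// the plane center (same sampling scheme as cpp_plane_area). Used for
// centerline re-centering. Returns c(area, cx, cy, cz); area = -1 if the
// center sample is outside the region.
// [[Rcpp::export]]
NumericVector cpp_plane_region(NumericVector vol, IntegerVector dim,
                               NumericVector origin, NumericVector spacing,
                               NumericVector center, NumericVector e1,
                               NumericVector e2, double step, double extent) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  const double o[3] = {origin[0], origin[1], origin[2]};
  const double s[3] = {spacing[0], spacing[1], spacing[2]};
  const int half = (int)std::floor(extent / step);
  const int n = 2 * half + 1;
  const double du = 0.2376 * step, dv = 0.4873 * step;
  std::vector<char> in((size_t)n * n, 0), seen((size_t)n * n, 0);
  for (int v = 0; v < n; ++v)
    for (int u = 0; u < n; ++u) {
      const double uu = (u - half) * step + du, vv = (v - half) * step + dv;
      const double px = center[0] + uu * e1[0] + vv * e2[0];
      const double py = center[1] + uu * e1[1] + vv * e2[1];
      const double pz = center[2] + uu * e1[2] + vv * e2[2];
      in[(size_t)v * n + u] = trilerp(vol, d, o, s, px, py, pz) >= 0.5;
    }
  const size_t c0 = (size_t)half * n + half;
  NumericVector out(4);
  if (!in[c0]) { out[0] = -1.0; return out; }
  std::vector<size_t> stack;
  stack.push_back(c0);
  seen[c0] = 1;
  double count = 0, su = 0, sv = 0;
  while (!stack.empty()) {
    const size_t cur = stack.back();
    stack.pop_back();
    const int u = (int)(cur % n), v = (int)(cur / n);
    count += 1;
    su += (u - half) * step + du;
    sv += (v - half) * step + dv;
    const int duq[4] = {1, -1, 0, 0}, dvq[4] = {0, 0, 1, -1};
    for (int q = 0; q < 4; ++q) {
      const int uu = u + duq[q], vv = v + dvq[q];
      if (uu < 0 || vv < 0 || uu >= n || vv >= n) continue;
      const size_t nxt = (size_t)vv * n + uu;
      if (in[nxt] && !seen[nxt]) {
        seen[nxt] = 1;
        stack.push_back(nxt);
      }
    }
  }
  su /= count; sv /= count;
  out[0] = count * step * step;
  out[1] = center[0] + su * e1[0] + sv * e2[0];
  out[2] = center[1] + su * e1[1] + sv * e2[1];
  out[3] = center[2] + su * e1[2] + sv * e2[2];
  return out;
}

// -------------------------------------------------------- in-plane area

// Cross-sectional area of the in-plane connected region containing the plane
// center: trilinear samples of the mask on a 2D grid (step mm), thresholded
// at 0.5, 4-connected flood fill from the center. Returns -1 if the center
// sample is below threshold (outside the lumen).
// [[Rcpp::export]]
double cpp_plane_area(NumericVector vol, IntegerVector dim,
                      NumericVector origin, NumericVector spacing,
                      NumericVector center, NumericVector e1, NumericVector e2,
                      double step, double extent) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  const double o[3] = {origin[0], origin[1], origin[2]};
  const double s[3] = {spacing[0], spacing[1], spacing[2]};
  const int half = (int)std::floor(extent / step);
  const int n = 2 * half + 1;
  // irrational sub-step offset avoids coherent lattice counting error when
  // the section is symmetric to the sampling grid
  const double du = 0.2376 * step, dv = 0.4873 * step;
  std::vector<char> in((size_t)n * n, 0), seen((size_t)n * n, 0);
  for (int v = 0; v < n; ++v)
    for (int u = 0; u < n; ++u) {
      const double uu = (u - half) * step + du, vv = (v - half) * step + dv;
      const double px = center[0] + uu * e1[0] + vv * e2[0];
      const double py = center[1] + uu * e1[1] + vv * e2[1];
      const double pz = center[2] + uu * e1[2] + vv * e2[2];
      in[(size_t)v * n + u] = trilerp(vol, d, o, s, px, py, pz) >= 0.5;
    }
  const size_t c0 = (size_t)half * n + half;
  if (!in[c0]) return -1.0;
  std::vector<size_t> stack;
  stack.push_back(c0);
  seen[c0] = 1;
  size_t count = 0;
  while (!stack.empty()) {
    const size_t cur = stack.back();
    stack.pop_back();
    ++count;
    const int u = (int)(cur % n), v = (int)(cur / n);
    const int du[4] = {1, -1, 0, 0}, dv[4] = {0, 0, 1, -1};
    for (int q = 0; q < 4; ++q) {
      const int uu = u + du[q], vv = v + dv[q];
      if (uu < 0 || vv < 0 || uu >= n || vv >= n) continue;
      const size_t nxt = (size_t)vv * n + uu;
      if (in[nxt] && !seen[nxt]) {
        seen[nxt] = 1;
        stack.push_back(nxt);
      }
    }
  }
  return (double)count * step * step;
}
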