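// 3D voxel kernels: binary morphology, labeling, hole filling, exact
// Euclidean distance transform, homotopic thinning, isosurface area.
// Volumes arrive as R logical arrays in column-major order (x fastest);
// linear index = x + nx*(y + ny*z). Volumes are limited to < 2^31 voxels.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <set>
#include <cstdint>
#include <cmath>
#include <limits>
using namespace Rcpp;

static inline size_t lin(int x, int y, int z, int nx, int ny) {
  return (size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * (size_t)z);
}

// 26-neighborhood offsets, raster order (z, y, x slowest to fastest)
static void neigh_offsets(int conn, std::vector<int> &dx, std::vector<int> &dy,
                          std::vector<int> &dz) {
  dx.clear(); dy.clear(); dz.clear();
  for (int z = -1; z <= 1; ++z)
    for (int y = -1; y <= 1; ++y)
      for (int x = -1; x <= 1; ++x) {
        if (x == 0 && y == 0 && z == 0) continue;
        int m = std::abs(x) + std::abs(y) + std::abs(z);
        if (conn == 6 && m != 1) continue;
        dx.push_back(x); dy.push_back(y); dz.push_back(z);
      }
}

// [[Rcpp::export]]
LogicalVector cpp_erode(LogicalVector mask, IntegerVector dims,
                        IntegerMatrix off) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int K = off.nrow();
  std::vector<int> ox(K), oy(K), oz(K);
  for (int k = 0; k < K; ++k) { ox[k] = off(k,0); oy[k] = off(k,1); oz[k] = off(k,2); }
  LogicalVector out(mask.size());
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        size_t i = lin(x, y, z, nx, ny);
        if (!mask[i]) { out[i] = FALSE; continue; }
        bool keep = true;
        for (int k = 0; k < K; ++k) {
          int xx = x + ox[k], yy = y + oy[k], zz = z + oz[k];
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) {
            keep = false; break;            // outside the grid is background
          }
          if (!mask[lin(xx, yy, zz, nx, ny)]) { keep = false; break; }
        }
        out[i] = keep;
      }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_dilate(LogicalVector mask, IntegerVector dims,
                         IntegerMatrix off) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int K = off.nrow();
  std::vector<int> ox(K), oy(K), oz(K);
  for (int k = 0; k < K; ++k) { ox[k] = off(k,0); oy[k] = off(k,1); oz[k] = off(k,2); }
  LogicalVector out(mask.size());
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        size_t i = lin(x, y, z, nx, ny);
        if (!mask[i]) continue;
        out[i] = TRUE;
        for (int k = 0; k < K; ++k) {
          int xx = x + ox[k], yy = y + oy[k], zz = z + oz[k];
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            continue;
          out[lin(xx, yy, zz, nx, ny)] = TRUE;
        }
      }
  return out;
}

// Connected components; labels assigned in raster order of each
// component's first voxel (deterministic).
// [[Rcpp::export]]
List cpp_label(LogicalVector mask, IntegerVector dims, int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<int> dx, dy, dz;
  neigh_offsets(connectivity, dx, dy, dz);
  int K = (int)dx.size();
  IntegerVector labels(mask.size(), 0);
  int lab = 0;
  std::queue<size_t> q;
  for (size_t i = 0; i < (size_t)mask.size(); ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++lab;
    labels[i] = lab;
    q.push(i);
    while (!q.empty()) {
      size_t c = q.front(); q.pop();
      int z = (int)(c / ((size_t)nx * ny));
      int rem = (int)(c % ((size_t)nx * ny));
      int y = rem / nx, x = rem % nx;
      for (int k = 0; k < K; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        size_t j = lin(xx, yy, zz, nx, ny);
        if (mask[j] && labels[j] == 0) { labels[j] = lab; q.push(j); }
      }
    }
  }
  return List::create(_["labels"] = labels, _["n"] = lab);
}

// Background voxels reachable from any volume face (used by fill_holes).
// [[Rcpp::export]]
LogicalVector cpp_background_reachable(LogicalVector mask, IntegerVector dims,
                                       int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<int> dx, dy, dz;
  neigh_offsets(connectivity, dx, dy, dz);
  int K = (int)dx.size();
  LogicalVector reach(mask.size());
  std::queue<size_t> q;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (x != 0 && y != 0 && z != 0 && x != nx - 1 && y != ny - 1 && z != nz - 1)
          continue;
        size_t i = lin(x, y, z, nx, ny);
        if (!mask[i] && !reach[i]) { reach[i] = TRUE; q.push(i); }
      }
  while (!q.empty()) {
    size_t c = q.front(); q.pop();
    int z = (int)(c / ((size_t)nx * ny));
    int rem = (int)(c % ((size_t)nx * ny));
    int y = rem / nx, x = rem % nx;
    for (int k = 0; k < K; ++k) {
      int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
        continue;
      size_t j = lin(xx, yy, zz, nx, ny);
      if (!mask[j] && !reach[j]) { reach[j] = TRUE; q.push(j); }
    }
  }
  return reach;
}

// ---- exact Euclidean distance transform (Felzenszwalb & Huttenlocher) ----
static const double DT_INF = 1e15;

static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n,
                 double s) {
  const double POS_INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  int k = 0;
  v[0] = 0;
  zb[0] = -POS_INF;          // envelope sentinels must dominate any
  zb[1] = POS_INF;           // finite parabola intersection
  for (int q = 1; q < n; ++q) {
    double qs = q * s;
    double inter;
    while (true) {
      double ps = v[k] * s;
      inter = ((f[q] + qs * qs) - (f[v[k]] + ps * ps)) / (2.0 * qs - 2.0 * ps);
      if (inter <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = inter;
    zb[k + 1] = POS_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qs = q * s;
    while (zb[k + 1] < qs) ++k;
    double ps = v[k] * s;
    d[q] = (qs - ps) * (qs - ps) + f[v[k]];
  }
}

// Squared Euclidean distance (in physical units) from each foreground voxel
// to the nearest background voxel centre; 0 on background. Outside the grid
// is NOT treated as background.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims,
                         NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector D(mask.size());
  for (size_t i = 0; i < n; ++i) D[i] = mask[i] ? DT_INF : 0.0;
  // pass along x
  {
    std::vector<double> f(nx), d(nx);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        size_t base = lin(0, y, z, nx, ny);
        for (int x = 0; x < nx; ++x) f[x] = D[base + x];
        dt1d(f, d, nx, spacing[0]);
        for (int x = 0; x < nx; ++x) D[base + x] = d[x];
      }
  }
  // pass along y
  {
    std::vector<double> f(ny), d(ny);
    for (int z = 0; z < nz; ++z)
      for (int x = 0; x < nx; ++x) {
        for (int y = 0; y < ny; ++y) f[y] = D[lin(x, y, z, nx, ny)];
        dt1d(f, d, ny, spacing[1]);
        for (int y = 0; y < ny; ++y) D[lin(x, y, z, nx, ny)] = d[y];
      }
  }
  // pass along z
  {
    std::vector<double> f(nz), d(nz);
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        for (int z = 0; z < nz; ++z) f[z] = D[lin(x, y, z, nx, ny)];
        dt1d(f, d, nz, spacing[2]);
        for (int z = 0; z < nz; ++z) D[lin(x, y, z, nx, ny)] = d[z];
      }
  }
  for (size_t i = 0; i < n; ++i) if (D[i] >= DT_INF) D[i] = NA_REAL;
  return D;
}

// ---- simple-point test (Bertrand & Malandain characterization) ----
// p is simple iff (a) the object voxels in its 26-neighborhood form exactly
// one 26-connected component, and (b) the background voxels in its
// 18-neighborhood form exactly one 6-connected component that is 6-adjacent
// to p.
namespace {
struct NbTables {
  int cx[27], cy[27], cz[27];
  bool adj26[27][27];
  bool adj6[27][27];
  bool inN18[27];
  bool faceNb[27];
  NbTables() {
    int i = 0;
    for (int z = -1; z <= 1; ++z)
      for (int y = -1; y <= 1; ++y)
        for (int x = -1; x <= 1; ++x, ++i) { cx[i] = x; cy[i] = y; cz[i] = z; }
    for (int a = 0; a < 27; ++a) {
      int m = std::abs(cx[a]) + std::abs(cy[a]) + std::abs(cz[a]);
      inN18[a] = (m >= 1 && m <= 2);
      faceNb[a] = (m == 1);
      for (int b = 0; b < 27; ++b) {
        int ddx = std::abs(cx[a] - cx[b]), ddy = std::abs(cy[a] - cy[b]),
            ddz = std::abs(cz[a] - cz[b]);
        int mx = std::max(ddx, std::max(ddy, ddz));
        adj26[a][b] = (a != b && mx <= 1);
        adj6[a][b] = (ddx + ddy + ddz == 1);
      }
    }
  }
};
const NbTables NBT;
}

static bool is_simple(const bool nb[27]) {
  // (a) one 26-component of object among the 26 neighbors (center = 13)
  int comp = 0;
  bool seen[27] = {false};
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    if (++comp > 1) return false;
    int top = 0;
    stack[top++] = s; seen[s] = true;
    while (top > 0) {
      int c = stack[--top];
      for (int t = 0; t < 27; ++t) {
        if (t == 13 || seen[t] || !nb[t]) continue;
        if (NBT.adj26[c][t]) { seen[t] = true; stack[top++] = t; }
      }
    }
  }
  if (comp != 1) return false;  // isolated voxel is not simple
  // (b) one 6-component of background within N18 touching a face neighbor
  int bcomp = 0;
  bool bseen[27] = {false};
  for (int s = 0; s < 27; ++s) {
    if (!NBT.inN18[s] || nb[s] || bseen[s] || !NBT.faceNb[s]) continue;
    // grow the component containing face-neighbor s
    ++bcomp;
    if (bcomp > 1) return false;
    int top = 0;
    stack[top++] = s; bseen[s] = true;
    while (top > 0) {
      int c = stack[--top];
      for (int t = 0; t < 27; ++t) {
        if (!NBT.inN18[t] || nb[t] || bseen[t]) continue;
        if (NBT.adj6[c][t]) { bseen[t] = true; stack[top++] = t; }
      }
    }
  }
  if (bcomp != 1) return false;
  return true;
}

// Distance-ordered homotopic thinning: delete simple, non-endpoint voxels
// in increasing order of Euclidean distance to the background, keeping the
// skeleton centered on the distance ridge. Topology (component and cavity
// structure) is preserved because only simple points are removed; curve
// endpoints (exactly one 26-neighbor) and isolated voxels are kept.
// [[Rcpp::export]]
LogicalVector cpp_thin(LogicalVector mask, IntegerVector dims,
                       NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector dsq = cpp_edt_sq(mask, dims, spacing);
  std::vector<uint8_t> obj(n);
  for (size_t i = 0; i < n; ++i) obj[i] = mask[i] ? 1 : 0;

  typedef std::pair<double, size_t> Item;
  std::priority_queue<Item, std::vector<Item>, std::greater<Item> > pq;
  std::vector<int> dx, dy, dz;
  neigh_offsets(26, dx, dy, dz);

  auto dval = [&](size_t i) {
    double v = dsq[i];
    return ISNA(v) ? DT_INF : v;
  };
  // seed with border voxels (any background 26-neighbor or grid edge)
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        size_t i = lin(x, y, z, nx, ny);
        if (!obj[i]) continue;
        bool border = false;
        for (int k = 0; k < 26; ++k) {
          int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) {
            continue;  // outside grid: not background for thinning
          }
          if (!obj[lin(xx, yy, zz, nx, ny)]) { border = true; break; }
        }
        if (border) pq.push(Item(dval(i), i));
      }

  bool nb[27];
  while (!pq.empty()) {
    size_t i = pq.top().second;
    pq.pop();
    if (!obj[i]) continue;
    int z = (int)(i / ((size_t)nx * ny));
    int rem = (int)(i % ((size_t)nx * ny));
    int y = rem / nx, x = rem % nx;
    int cnt = 0, m = 0;
    for (int zz = -1; zz <= 1; ++zz)
      for (int yy = -1; yy <= 1; ++yy)
        for (int xx = -1; xx <= 1; ++xx, ++m) {
          int X = x + xx, Y = y + yy, Z = z + zz;
          bool v = (X >= 0 && Y >= 0 && Z >= 0 && X < nx && Y < ny && Z < nz)
                     ? (obj[lin(X, Y, Z, nx, ny)] != 0) : false;
          nb[m] = v;
          if (v && m != 13) ++cnt;
        }
    if (cnt <= 1) continue;      // endpoint or isolated voxel: keep
    if (!is_simple(nb)) continue;
    obj[i] = 0;                  // delete; re-examine neighbors
    for (int k = 0; k < 26; ++k) {
      int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
        continue;
      size_t j = lin(xx, yy, zz, nx, ny);
      if (obj[j]) pq.push(Item(dval(j), j));
    }
  }
  LogicalVector out(mask.size());
  for (size_t i = 0; i < n; ++i) out[i] = obj[i] ? TRUE : FALSE;
  return out;
}

// ---- triangulated isosurface area (marching tetrahedra) ----
// Scalar field sampled at voxel-grid corners as the mean of the 8 incident
// voxels (box reconstruction); the 0.5-level surface is triangulated by
// splitting each corner cell into 6 tetrahedra around the main diagonal.
namespace {
inline int vidx(int x, int y, int z) { return x + 2 * y + 4 * z; }
const int TETS[6][4] = {
  {vidx(0,0,0), vidx(1,0,0), vidx(1,1,0), vidx(1,1,1)},
  {vidx(0,0,0), vidx(1,1,0), vidx(0,1,0), vidx(1,1,1)},
  {vidx(0,0,0), vidx(0,1,0), vidx(0,1,1), vidx(1,1,1)},
  {vidx(0,0,0), vidx(0,1,1), vidx(0,0,1), vidx(1,1,1)},
  {vidx(0,0,0), vidx(0,0,1), vidx(1,0,1), vidx(1,1,1)},
  {vidx(0,0,0), vidx(1,0,1), vidx(1,0,0), vidx(1,1,1)}};
const int VOFF[8][3] = {{0,0,0},{1,0,0},{0,1,0},{1,1,0},
                        {0,0,1},{1,0,1},{0,1,1},{1,1,1}};

inline double tri_area(const double a[3], const double b[3], const double c[3]) {
  double u[3] = {b[0]-a[0], b[1]-a[1], b[2]-a[2]};
  double v[3] = {c[0]-a[0], c[1]-a[1], c[2]-a[2]};
  double w0 = u[1]*v[2]-u[2]*v[1], w1 = u[2]*v[0]-u[0]*v[2],
         w2 = u[0]*v[1]-u[1]*v[0];
  return 0.5 * std::sqrt(w0*w0 + w1*w1 + w2*w2);
}
}

// [[Rcpp::export]]
double cpp_mt_area(LogicalVector mask, IntegerVector dims,
                   NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  auto vox = [&](int x, int y, int z) -> double {
    if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return 0.0;
    return mask[lin(x, y, z, nx, ny)] ? 1.0 : 0.0;
  };
  // corner (i,j,k), i in 0..nx: mean of voxels (i-1..i, j-1..j, k-1..k)
  auto corner = [&](int i, int j, int k) -> double {
    double s = 0.0;
    for (int a = -1; a <= 0; ++a)
      for (int b = -1; b <= 0; ++b)
        for (int c = -1; c <= 0; ++c) s += vox(i + a, j + b, k + c);
    return s / 8.0;
  };
  double area = 0.0;
  double vals[8];
  double pts[8][3];
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        // cell between corners (i..i+1, j..j+1, k..k+1); skip cells whose
        // 2x2x2 voxel support is uniform
        bool any = false, all = true;
        for (int a = -1; a <= 1; ++a)
          for (int b = -1; b <= 1; ++b)
            for (int c = -1; c <= 1; ++c) {
              bool v = vox(i + a, j + b, k + c) > 0.5;
              any = any || v; all = all && v;
            }
        if (!any || all) continue;
        int nin = 0;
        for (int v = 0; v < 8; ++v) {
          vals[v] = corner(i + VOFF[v][0], j + VOFF[v][1], k + VOFF[v][2]);
          pts[v][0] = (i + VOFF[v][0]) * sx;
          pts[v][1] = (j + VOFF[v][1]) * sy;
          pts[v][2] = (k + VOFF[v][2]) * sz;
          if (vals[v] >= 0.5) ++nin;
        }
        if (nin == 0 || nin == 8) continue;
        for (int t = 0; t < 6; ++t) {
          const int *T = TETS[t];
          bool in[4];
          int s = 0;
          for (int v = 0; v < 4; ++v) { in[v] = vals[T[v]] >= 0.5; s += in[v]; }
          if (s == 0 || s == 4) continue;
          auto cross = [&](int a, int b, double out[3]) {
            double va = vals[T[a]], vb = vals[T[b]];
            double tt = (0.5 - va) / (vb - va);
            for (int c = 0; c < 3; ++c)
              out[c] = pts[T[a]][c] + tt * (pts[T[b]][c] - pts[T[a]][c]);
          };
          if (s == 1 || s == 3) {
            bool lookFor = (s == 1);
            int lone = -1;
            for (int v = 0; v < 4; ++v) if (in[v] == lookFor) lone = v;
            double p[3][3];
            int m = 0;
            for (int v = 0; v < 4; ++v)
              if (v != lone) cross(lone, v, p[m++]);
            area += tri_area(p[0], p[1], p[2]);
          } else {
            int ins[2], outs[2], a = 0, b = 0;
            for (int v = 0; v < 4; ++v) (in[v] ? ins[a++] : outs[b++]) = v;
            double p00[3], p01[3], p10[3], p11[3];
            cross(ins[0], outs[0], p00);
            cross(ins[0], outs[1], p01);
            cross(ins[1], outs[0], p10);
            cross(ins[1], outs[1], p11);
            area += tri_area(p00, p01, p10) + tri_area(p01, p11, p10);
          }
        }
      }
  return area;
}

// Exposed voxel-face area (debug / sub-resolution fallback).
// [[Rcpp::export]]
double cpp_face_area(LogicalVector mask, IntegerVector dims,
                     NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double ax = spacing[1] * spacing[2], ay = spacing[0] * spacing[2],
         az = spacing[0] * spacing[1];
  double area = 0.0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (!mask[lin(x, y, z, nx, ny)]) continue;
        if (x == 0 || !mask[lin(x-1, y, z, nx, ny)]) area += ax;
        if (x == nx-1 || !mask[lin(x+1, y, z, nx, ny)]) area += ax;
        if (y == 0 || !mask[lin(x, y-1, z, nx, ny)]) area += ay;
        if (y == ny-1 || !mask[lin(x, y+1, z, nx, ny)]) area += ay;
        if (z == 0 || !mask[lin(x, y, z-1, nx, ny)]) area += az;
        if (z == nz-1 || !mask[lin(x, y, z+1, nx, ny)]) area += az;
      }
  return area;
}

// Per-label bounding boxes and voxel counts in one pass.
// Returns an n_labels x 7 matrix: count, x0, x1, y0, y1, z0, z1 (0-based,
// inclusive).
// [[Rcpp::export]]
IntegerMatrix cpp_label_bbox(IntegerVector labels, IntegerVector dims,
                             int n_labels) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerMatrix out(n_labels, 7);
  for (int l = 0; l < n_labels; ++l) {
    out(l, 1) = nx; out(l, 3) = ny; out(l, 5) = nz;
    out(l, 2) = -1; out(l, 4) = -1; out(l, 6) = -1;
  }
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int lab = labels[lin(x, y, z, nx, ny)];
        if (lab <= 0) continue;
        int l = lab - 1;
        out(l, 0) += 1;
        if (x < out(l, 1)) out(l, 1) = x;
        if (x > out(l, 2)) out(l, 2) = x;
        if (y < out(l, 3)) out(l, 3) = y;
        if (y > out(l, 4)) out(l, 4) = y;
        if (z < out(l, 5)) out(l, 5) = z;
        if (z > out(l, 6)) out(l, 6) = z;
      }
  return out;
}
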