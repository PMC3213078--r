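#include <Rcpp.h>
#include <vector>
#include <queue>
#include <array>
#include <cmath>
#include <cstring>
using namespace Rcpp;

// Internal axis order is (z, y, x): z is the fastest-varying array index.
// Linear index = z + nz * (y + ny * x), 0-based. All physical quantities in um.

static inline double seg_dist(double pz, double py, double px,
                              double az, double ay, double ax,
                              double bz, double by, double bx) {
  double dz = bz - az, dy = by - ay, dx = bx - ax;
  double L2 = dz * dz + dy * dy + dx * dx;
  double t = 0.0;
  if (L2 > 0) {
    t = ((pz - az) * dz + (py - ay) * dy + (px - ax) * dx) / L2;
    if (t < 0) t = 0; else if (t > 1) t = 1;
  }
  double qz = az + t * dz - pz, qy = ay + t * dy - py, qx = ax + t * dx - px;
  return std::sqrt(qz * qz + qy * qy + qx * qx);
}

// Signed distance from point to the scene boundary (negative inside).
// spheres: n x 4 (cz, cy, cx, r); capsules: m x 7 (az,ay,ax,bz,by,bx,r).
static inline double scene_sdist(double pz, double py, double px,
                                 const NumericMatrix &sph,
                                 const NumericMatrix &cap) {
  double d = 1e30;
  for (int i = 0; i < sph.nrow(); ++i) {
    double dz = pz - sph(i, 0), dy = py - sph(i, 1), dx = px - sph(i, 2);
    double v = std::sqrt(dz * dz + dy * dy + dx * dx) - sph(i, 3);
    if (v < d) d = v;
  }
  for (int i = 0; i < cap.nrow(); ++i) {
    double v = seg_dist(pz, py, px, cap(i, 0), cap(i, 1), cap(i, 2),
                        cap(i, 3), cap(i, 4), cap(i, 5)) - cap(i, 6);
    if (v < d) d = v;
  }
  return d;
}

// Rasterize a union of spheres and capsules onto an anisotropic voxel grid.
// Voxel centers sit at ((i + 0.5) * v) for 0-based index i. Interior voxels
// get coverage 1, exterior 0; voxels within half a voxel diagonal of the
// surface are supersampled at 8 (2x2x2) subpoints for partial-volume
// antialiasing.
// [[Rcpp::export]]
NumericVector rasterize_scene_cpp(IntegerVector dim, NumericVector voxel,
                                  NumericMatrix spheres, NumericMatrix capsules) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double vz = voxel[0], vy = voxel[1], vx = voxel[2];
  const R_xlen_t nvox = (R_xlen_t)nz * ny * nx;
  const double h = 0.5 * std::sqrt(vz * vz + vy * vy + vx * vx);

  std::vector<double> D(nvox, 1e30);

  // per-primitive bounding-box sweep updating the min signed distance
  auto sweep = [&](double loz, double loy, double lox,
                   double hiz, double hiy, double hix,
                   double r, bool is_sphere, int idx,
                   const NumericMatrix &prim) {
    double pad = r + h + 2.0 * std::max(vz, std::max(vy, vx));
    int z0 = std::max(0, (int)std::floor((loz - pad) / vz - 0.5));
    int z1 = std::min(nz - 1, (int)std::ceil((hiz + pad) / vz - 0.5));
    int y0 = std::max(0, (int)std::floor((loy - pad) / vy - 0.5));
    int y1 = std::min(ny - 1, (int)std::ceil((hiy + pad) / vy - 0.5));
    int x0 = std::max(0, (int)std::floor((lox - pad) / vx - 0.5));
    int x1 = std::min(nx - 1, (int)std::ceil((hix + pad) / vx - 0.5));
    for (int x = x0; x <= x1; ++x) {
      double px = (x + 0.5) * vx;
      for (int y = y0; y <= y1; ++y) {
        double py = (y + 0.5) * vy;
        R_xlen_t base = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
        for (int z = z0; z <= z1; ++z) {
          double pz = (z + 0.5) * vz;
          double d;
          if (is_sphere) {
            double dz = pz - prim(idx, 0), dy = py - prim(idx, 1),
                   dx = px - prim(idx, 2);
            d = std::sqrt(dz * dz + dy * dy + dx * dx) - prim(idx, 3);
          } else {
            d = seg_dist(pz, py, px, prim(idx, 0), prim(idx, 1), prim(idx, 2),
                         prim(idx, 3), prim(idx, 4), prim(idx, 5)) - prim(idx, 6);
          }
          if (d < D[base + z]) D[base + z] = d;
        }
      }
    }
  };

  for (int i = 0; i < spheres.nrow(); ++i)
    sweep(spheres(i, 0), spheres(i, 1), spheres(i, 2),
          spheres(i, 0), spheres(i, 1), spheres(i, 2),
          spheres(i, 3), true, i, spheres);
  for (int i = 0; i < capsules.nrow(); ++i)
    sweep(std::min(capsules(i, 0), capsules(i, 3)),
          std::min(capsules(i, 1), capsules(i, 4)),
          std::min(capsules(i, 2), capsules(i, 5)),
          std::max(capsules(i, 0), capsules(i, 3)),
          std::max(capsules(i, 1), capsules(i, 4)),
          std::max(capsules(i, 2), capsules(i, 5)),
          capsules(i, 6), false, i, capsules);

  NumericVector out(nvox);
  const double qz = vz / 4.0, qy = vy / 4.0, qx = vx / 4.0;
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
      for (int z = 0; z < nz; ++z) {
        double d = D[base + z];
        if (d <= -h) { out[base + z] = 1.0; continue; }
        if (d >= h) { out[base + z] = 0.0; continue; }
        double cz = (z + 0.5) * vz, cy = (y + 0.5) * vy, cx = (x + 0.5) * vx;
        int inside = 0;
        for (int sz = -1; sz <= 1; sz += 2)
          for (int sy = -1; sy <= 1; sy += 2)
            for (int sx = -1; sx <= 1; sx += 2)
              if (scene_sdist(cz + sz * qz, cy + sy * qy, cx + sx * qx,
                              spheres, capsules) < 0.0)
                ++inside;
        out[base + z] = inside / 8.0;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher, separable
// parabola method) with per-axis spacing. Distance to the nearest background
// voxel center; background voxels get 0.

static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n,
                 double w, std::vector<int> &v, std::vector<double> &zb) {
  int k = 0;
  v[0] = 0;
  zb[0] = -1e30; zb[1] = 1e30;
  const double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = 1e30;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = w * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector edt_cpp(LogicalVector mask, IntegerVector dim, NumericVector voxel) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nz * ny * nx;
  std::vector<double> g(nvox);
  for (R_xlen_t i = 0; i < nvox; ++i) g[i] = mask[i] ? 1e30 : 0.0;

  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);

  // along z
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
      for (int z = 0; z < nz; ++z) f[z] = g[base + z];
      dt1d(f, d, nz, voxel[0], v, zb);
      for (int z = 0; z < nz; ++z) g[base + z] = d[z];
    }
  // along y
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      R_xlen_t base = z + (R_xlen_t)nz * ny * x;
      for (int y = 0; y < ny; ++y) f[y] = g[base + (R_xlen_t)nz * y];
      dt1d(f, d, ny, voxel[1], v, zb);
      for (int y = 0; y < ny; ++y) g[base + (R_xlen_t)nz * y] = d[y];
    }
  // along x
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      R_xlen_t base = z + (R_xlen_t)nz * y;
      R_xlen_t stride = (R_xlen_t)nz * ny;
      for (int x = 0; x < nx; ++x) f[x] = g[base + stride * x];
      dt1d(f, d, nx, voxel[2], v, zb);
      for (int x = 0; x < nx; ++x) g[base + stride * x] = d[x];
    }

  NumericVector out(nvox);
  for (R_xlen_t i = 0; i < nvox; ++i) out[i] = std::sqrt(g[i]);
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// 3D curve-skeleton extraction by sequential directional thinning.
// A border voxel is deleted when it is a simple point for the (26, 6)
// adjacency pair (removal preserves topology) and not a curve endpoint.
// Simple-point characterization (Bertrand & Malandain): exactly one
// 26-connected foreground component in the punctured 26-neighborhood, and
// exactly one 6-connected background component within the 18-neighborhood
// that touches the center by a face.

namespace thin {

static int off26[26][3];
static int n26init = 0;

static void init_offsets() {
  if (n26init) return;
  int k = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        off26[k][0] = dz; off26[k][1] = dy; off26[k][2] = dx;
        ++k;
      }
  n26init = 1;
}

// cube index 0..26 for offsets in {-1,0,1}^3
static inline int cidx(int dz, int dy, int dx) {
  return (dz + 1) + 3 * ((dy + 1) + 3 * (dx + 1));
}

struct Grid {
  const unsigned char *img;
  int nz, ny, nx;
  inline int at(int z, int y, int x) const {
    if (z < 0 || y < 0 || x < 0 || z >= nz || y >= ny || x >= nx) return 0;
    return img[z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)];
  }
};

// number of foreground 26-neighbors
static inline int count26(const Grid &g, int z, int y, int x) {
  int c = 0;
  for (int k = 0; k < 26; ++k)
    c += g.at(z + off26[k][0], y + off26[k][1], x + off26[k][2]);
  return c;
}

static bool is_simple(const Grid &g, int z, int y, int x) {
  unsigned char nb[27];
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx)
        nb[cidx(dz, dy, dx)] = (unsigned char)g.at(z + dz, y + dy, x + dx);
  const int center = cidx(0, 0, 0);

  // condition A: one 26-component of foreground in N26 \ {center}
  {
    int seen[27]; std::memset(seen, 0, sizeof(seen));
    int ncomp = 0;
    for (int s = 0; s < 27; ++s) {
      if (s == center || !nb[s] || seen[s]) continue;
      ++ncomp;
      if (ncomp > 1) return false;
      std::array<int, 27> stack; int top = 0;
      stack[top++] = s; seen[s] = 1;
      while (top) {
        int c = stack[--top];
        int cz = c % 3 - 1, cy = (c / 3) % 3 - 1, cx = c / 9 - 1;
        for (int k = 0; k < 26; ++k) {
          int tz = cz + off26[k][0], ty = cy + off26[k][1], tx = cx + off26[k][2];
          if (tz < -1 || tz > 1 || ty < -1 || ty > 1 || tx < -1 || tx > 1) continue;
          int t = cidx(tz, ty, tx);
          if (t == center || !nb[t] || seen[t]) continue;
          seen[t] = 1; stack[top++] = t;
        }
      }
    }
    if (ncomp != 1) return false;
  }

  // condition B: one 6-component of background in N18 touching center's faces
  {
    // N18: offsets with |dz|+|dy|+|dx| <= 2 (faces + edges), excluding center
    int seen[27]; std::memset(seen, 0, sizeof(seen));
    int ncomp = 0;
    static const int face[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
    for (int fidx = 0; fidx < 6; ++fidx) {
      int s = cidx(face[fidx][0], face[fidx][1], face[fidx][2]);
      if (nb[s] || seen[s]) continue;
      ++ncomp;
      if (ncomp > 1) return false;
      std::array<int, 27> stack; int top = 0;
      stack[top++] = s; seen[s] = 1;
      while (top) {
        int c = stack[--top];
        int cz = c % 3 - 1, cy = (c / 3) % 3 - 1, cx = c / 9 - 1;
        for (int f = 0; f < 6; ++f) {
          int tz = cz + face[f][0], ty = cy + face[f][1], tx = cx + face[f][2];
          if (tz < -1 || tz > 1 || ty < -1 || ty > 1 || tx < -1 || tx > 1) continue;
          if (std::abs(tz) + std::abs(ty) + std::abs(tx) > 2) continue; // stay in N18
          int t = cidx(tz, ty, tx);
          if (t == cidx(0, 0, 0) || nb[t] || seen[t]) continue;
          seen[t] = 1; stack[top++] = t;
        }
      }
    }
    if (ncomp != 1) return false;
  }
  return true;
}

} // namespace thin

// Distance-ordered homotopic thinning (Pudney-style): foreground voxels are
// deleted in increasing distance-transform order when deletion preserves
// topology (simple point), skipping curve endpoints and anchor voxels.
// Anchors are the ridge of the distance transform (voxels with no strictly
// greater 26-neighbor), so tube axes survive whatever their parity — naive
// directional thinning lets deletions cascade along two-voxel-wide
// structures and can consume an even-diameter tube end to end.
// [[Rcpp::export]]
LogicalVector thin3d_cpp(LogicalVector mask, IntegerVector dim,
                         NumericVector edt) {
  thin::init_offsets();
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nz * ny * nx;
  std::vector<unsigned char> img(nvox);
  for (R_xlen_t i = 0; i < nvox; ++i) img[i] = mask[i] ? 1 : 0;
  thin::Grid g{img.data(), nz, ny, nx};

  // The EDT of a discrete tube has plateaus (e.g. the 2x2 axis bundle of an
  // even-diameter tube); a deterministic sub-resolution perturbation breaks
  // the ties so the anchored ridge is sparse and the skeleton collapses to
  // a single connected line.
  std::vector<double> pedt(nvox);
  for (R_xlen_t i = 0; i < nvox; ++i)
    pedt[i] = edt[i] + 1e-6 * (double)((i * 2654435761u) % 9973u) / 9973.0;

  // anchor = strict local maximum of the perturbed EDT over the 26-neighborhood
  std::vector<unsigned char> anchor(nvox, 0);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
        if (!img[i]) continue;
        bool mx = true;
        for (int k = 0; k < 26 && mx; ++k) {
          int tz = z + thin::off26[k][0], ty = y + thin::off26[k][1],
              tx = x + thin::off26[k][2];
          if (tz < 0 || ty < 0 || tx < 0 || tz >= nz || ty >= ny || tx >= nx)
            continue;
          R_xlen_t t = tz + (R_xlen_t)nz * (ty + (R_xlen_t)ny * tx);
          if (img[t] && pedt[t] > pedt[i]) mx = false;
        }
        anchor[i] = mx ? 1 : 0;
      }

  typedef std::pair<double, R_xlen_t> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  auto is_border = [&](int z, int y, int x) {
    return !g.at(z - 1, y, x) || !g.at(z + 1, y, x) ||
           !g.at(z, y - 1, x) || !g.at(z, y + 1, x) ||
           !g.at(z, y, x - 1) || !g.at(z, y, x + 1);
  };
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
        if (img[i] && !anchor[i] && is_border(z, y, x))
          pq.push(QE(pedt[i], i));
      }

  auto drain = [&](bool use_anchor) {
    while (!pq.empty()) {
      R_xlen_t i = pq.top().second;
      pq.pop();
      if (!img[i] || (use_anchor && anchor[i])) continue;
      int z = (int)(i % nz);
      int y = (int)((i / nz) % ny);
      int x = (int)(i / ((R_xlen_t)nz * ny));
      if (thin::count26(g, z, y, x) <= 1) continue;  // endpoint or isolated
      if (!thin::is_simple(g, z, y, x)) continue;
      img[i] = 0;
      for (int k = 0; k < 26; ++k) {
        int tz = z + thin::off26[k][0], ty = y + thin::off26[k][1],
            tx = x + thin::off26[k][2];
        if (tz < 0 || ty < 0 || tx < 0 || tz >= nz || ty >= ny || tx >= nx)
          continue;
        R_xlen_t t = tz + (R_xlen_t)nz * (ty + (R_xlen_t)ny * tx);
        if (img[t] && !(use_anchor && anchor[t])) pq.push(QE(pedt[t], t));
      }
    }
  };
  drain(true);

  LogicalVector out(nvox);
  for (R_xlen_t i = 0; i < nvox; ++i) out[i] = img[i] != 0;
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// 26-connected component containing a seed voxel (0-based linear index).
// [[Rcpp::export]]
LogicalVector label_from_seed_cpp(LogicalVector mask, IntegerVector dim,
                                  double seed0) {
  thin::init_offsets();
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nz * ny * nx;
  R_xlen_t seed = (R_xlen_t)seed0;
  LogicalVector out(nvox);
  if (seed < 0 || seed >= nvox || !mask[seed]) {
    out.attr("dim") = dim;
    return out;
  }
  std::vector<unsigned char> vis(nvox, 0);
  std::queue<R_xlen_t> q;
  q.push(seed); vis[seed] = 1;
  while (!q.empty()) {
    R_xlen_t i = q.front(); q.pop();
    int z = (int)(i % nz);
    int y = (int)((i / nz) % ny);
    int x = (int)(i / ((R_xlen_t)nz * ny));
    for (int k = 0; k < 26; ++k) {
      int tz = z + thin::off26[k][0], ty = y + thin::off26[k][1],
          tx = x + thin::off26[k][2];
      if (tz < 0 || ty < 0 || tx < 0 || tz >= nz || ty >= ny || tx >= nx) continue;
      R_xlen_t t = tz + (R_xlen_t)nz * (ty + (R_xlen_t)ny * tx);
      if (vis[t] || !mask[t]) continue;
      vis[t] = 1;
      q.push(t);
    }
  }
  for (R_xlen_t i = 0; i < nvox; ++i) out[i] = vis[i] != 0;
  out.attr("dim") = dim;
  return out;
}
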