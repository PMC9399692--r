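// Grid-based Boolean kernel: signed-distance sampling of a watertight
// triangle mesh on a regular lattice, and marching-tetrahedra contouring of
// a scalar field.  Combining per-mesh fields with min/max realizes CSG
// intersection/difference/union; contouring the combined field yields a
// closed, consistently oriented triangle mesh.
//
// Distances are computed exactly in a narrow band around the surface (the
// only region where the contouring interpolates); farther points carry the
// capped band value with the correct sign.  Signs come from ray-crossing
// parity along x-columns of the lattice, with a small fixed jitter to dodge
// edge/vertex grazing.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// exact point-triangle squared distance (Ericson, Real-Time Collision
// Detection, closest-point-on-triangle)
static double point_tri_dist2(const double* p, const double* a,
                              const double* b, const double* c) {
  double ab[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double ac[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double ap[3] = {p[0] - a[0], p[1] - a[1], p[2] - a[2]};
  double d1 = dot3(ab, ap), d2 = dot3(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return dot3(ap, ap);
  double bp[3] = {p[0] - b[0], p[1] - b[1], p[2] - b[2]};
  double d3 = dot3(ab, bp), d4 = dot3(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return dot3(bp, bp);
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    double q[3] = {ap[0] - v * ab[0], ap[1] - v * ab[1], ap[2] - v * ab[2]};
    return dot3(q, q);
  }
  double cp[3] = {p[0] - c[0], p[1] - c[1], p[2] - c[2]};
  double d5 = dot3(ab, cp), d6 = dot3(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return dot3(cp, cp);
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    double q[3] = {ap[0] - w * ac[0], ap[1] - w * ac[1], ap[2] - w * ac[2]};
    return dot3(q, q);
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    double q[3] = {bp[0] - w * (c[0] - b[0]), bp[1] - w * (c[1] - b[1]),
                   bp[2] - w * (c[2] - b[2])};
    return dot3(q, q);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  double q[3] = {ap[0] - v * ab[0] - w * ac[0],
                 ap[1] - v * ab[1] - w * ac[1],
                 ap[2] - v * ab[2] - w * ac[2]};
  return dot3(q, q);
}

// [[Rcpp::export]]
NumericVector cpp_sdf_grid(NumericMatrix V, IntegerMatrix F,
                           NumericVector origin, double h,
                           IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nF = F.nrow();
  const double band = 3.0 * h;
  const R_xlen_t npts = (R_xlen_t)nx * ny * nz;
  NumericVector out(npts);
  std::vector<double> dist(npts, band);

  std::vector<double> vx(V.nrow()), vy(V.nrow()), vz(V.nrow());
  for (int i = 0; i < V.nrow(); ++i) {
    vx[i] = V(i, 0); vy[i] = V(i, 1); vz[i] = V(i, 2);
  }

  // --- narrow-band unsigned distance ---
  const int bandc = 4;  // cells of padding around each triangle AABB
  for (int t = 0; t < nF; ++t) {
    int ia = F(t, 0), ib = F(t, 1), ic = F(t, 2);
    double a[3] = {vx[ia], vy[ia], vz[ia]};
    double b[3] = {vx[ib], vy[ib], vz[ib]};
    double c[3] = {vx[ic], vy[ic], vz[ic]};
    int lo[3], hi[3];
    for (int d = 0; d < 3; ++d) {
      double mn = std::min(a[d], std::min(b[d], c[d]));
      double mx = std::max(a[d], std::max(b[d], c[d]));
      lo[d] = std::max(0, (int)std::floor((mn - origin[d]) / h) - bandc);
      int n = (d == 0 ? nx : (d == 1 ? ny : nz));
      hi[d] = std::min(n - 1, (int)std::ceil((mx - origin[d]) / h) + bandc);
    }
    for (int k = lo[2]; k <= hi[2]; ++k)
      for (int j = lo[1]; j <= hi[1]; ++j) {
        R_xlen_t base = ((R_xlen_t)k * ny + j) * nx;
        double p[3];
        p[1] = origin[1] + j * h;
        p[2] = origin[2] + k * h;
        for (int i = lo[0]; i <= hi[0]; ++i) {
          p[0] = origin[0] + i * h;
          double& dref = dist[base + i];
          double d2 = point_tri_dist2(p, a, b, c);
          if (d2 < dref * dref) dref = std::sqrt(d2);
        }
      }
  }

  // --- sign by x-ray parity per (j,k) column ---
  // bin triangles over the columns their yz-AABB covers
  std::vector<std::vector<int>> colbin((R_xlen_t)ny * nz);
  for (int t = 0; t < nF; ++t) {
    int ia = F(t, 0), ib = F(t, 1), ic = F(t, 2);
    double ymn = std::min(vy[ia], std::min(vy[ib], vy[ic]));
    double ymx = std::max(vy[ia], std::max(vy[ib], vy[ic]));
    double zmn = std::min(vz[ia], std::min(vz[ib], vz[ic]));
    double zmx = std::max(vz[ia], std::max(vz[ib], vz[ic]));
    int jlo = std::max(0, (int)std::floor((ymn - origin[1]) / h));
    int jhi = std::min(ny - 1, (int)std::ceil((ymx - origin[1]) / h));
    int klo = std::max(0, (int)std::floor((zmn - origin[2]) / h));
    int khi = std::min(nz - 1, (int)std::ceil((zmx - origin[2]) / h));
    for (int k = klo; k <= khi; ++k)
      for (int j = jlo; j <= jhi; ++j)
        colbin[(R_xlen_t)k * ny + j].push_back(t);
  }

  const double jy = 1.3e-5 * h, jz = 0.7e-5 * h;  // grazing-avoidance jitter
  std::vector<double> xhits;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      const std::vector<int>& tris = colbin[(R_xlen_t)k * ny + j];
      R_xlen_t base = ((R_xlen_t)k * ny + j) * nx;
      if (tris.empty()) {
        for (int i = 0; i < nx; ++i) out[base + i] = -dist[base + i];
        continue;
      }
      double oy = origin[1] + j * h + jy;
      double oz = origin[2] + k * h + jz;
      xhits.clear();
      for (int t : tris) {
        int ia = F(t, 0), ib = F(t, 1), ic = F(t, 2);
        // Moller-Trumbore specialized to direction (1,0,0)
        double e1[3] = {vx[ib] - vx[ia], vy[ib] - vy[ia], vz[ib] - vz[ia]};
        double e2[3] = {vx[ic] - vx[ia], vy[ic] - vy[ia], vz[ic] - vz[ia]};
        // pvec = dir x e2 = (0, -e2z, e2y)
        double det = e1[1] * e2[2] - e1[2] * e2[1];
        if (std::fabs(det) < 1e-300) continue;  // ray parallel to plane
        double inv = 1.0 / det;
        double ty = oy - vy[ia], tz = oz - vz[ia];
        // u = (tvec . pvec) * inv, tvec has x-component irrelevant to u,v
        double u = (ty * e2[2] - tz * e2[1]) * inv;
        if (u < 0.0 || u > 1.0) continue;
        double v = (tz * e1[1] - ty * e1[2]) * inv;
        if (v < 0.0 || u + v > 1.0) continue;
        double xh = vx[ia] + u * e1[0] + v * e2[0];
        xhits.push_back(xh);
      }
      std::sort(xhits.begin(), xhits.end());
      size_t idx = 0;
      for (int i = 0; i < nx; ++i) {
        double x = origin[0] + i * h;
        while (idx < xhits.size() && xhits[idx] < x) ++idx;
        bool inside = (idx & 1) != 0;  // odd number of crossings behind us
        out[base + i] = inside ? dist[base + i] : -dist[base + i];
      }
    }
  }
  return out;
}

// six positively-oriented tetrahedra tiling the unit cube around the main
// diagonal v0-v6; shared cube faces split along matching diagonals so
// adjacent cells contour compatibly
static const int TETS[6][4] = {
  {0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
  {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}};
// cube corner offsets, bit order (x, y, z)
static const int CUBE[8][3] = {
  {0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
  {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}};

struct EdgeKeyHash {
  size_t operator()(const uint64_t& k) const { return std::hash<uint64_t>()(k); }
};

// [[Rcpp::export]]
List cpp_marching_tets(NumericVector field, IntegerVector dims,
                       NumericVector origin, double h) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  auto gid = [&](int i, int j, int k) -> R_xlen_t {
    return ((R_xlen_t)k * ny + j) * nx + i;
  };
  auto fval = [&](R_xlen_t g) -> double {
    double f = field[g];
    return f == 0.0 ? 1e-30 : f;  // zero-free field keeps t in (0,1)
  };

  std::unordered_map<uint64_t, int, EdgeKeyHash> vmap;
  std::vector<double> VX, VY, VZ;
  std::vector<int> FI;

  auto edge_vertex = [&](R_xlen_t g1, R_xlen_t g2) -> int {
    uint64_t a = (uint64_t)g1, b = (uint64_t)g2;
    if (a > b) std::swap(a, b);
    uint64_t key = a * (uint64_t)(nx * (R_xlen_t)ny * nz) + b;
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    double fa = fval((R_xlen_t)a), fb = fval((R_xlen_t)b);
    double t = fa / (fa - fb);
    int ia = (int)(a % nx), ja = (int)((a / nx) % ny), ka = (int)(a / ((R_xlen_t)nx * ny));
    int ib = (int)(b % nx), jb = (int)((b / nx) % ny), kb = (int)(b / ((R_xlen_t)nx * ny));
    double px = origin[0] + (ia + t * (ib - ia)) * h;
    double py = origin[1] + (ja + t * (jb - ja)) * h;
    double pz = origin[2] + (ka + t * (kb - ka)) * h;
    int id = (int)VX.size();
    VX.push_back(px); VY.push_back(py); VZ.push_back(pz);
    vmap.emplace(key, id);
    return id;
  };

  // orient (q1,q2,q3) so its normal points away from the inside region
  auto emit = [&](int q1, int q2, int q3, const double* inctr) {
    double ax = VX[q2] - VX[q1], ay = VY[q2] - VY[q1], az = VZ[q2] - VZ[q1];
    double bx = VX[q3] - VX[q1], by = VY[q3] - VY[q1], bz = VZ[q3] - VZ[q1];
    double nxv = ay * bz - az * by, nyv = az * bx - ax * bz,
           nzv = ax * by - ay * bx;
    double cx = (VX[q1] + VX[q2] + VX[q3]) / 3.0;
    double cy = (VY[q1] + VY[q2] + VY[q3]) / 3.0;
    double cz = (VZ[q1] + VZ[q2] + VZ[q3]) / 3.0;
    double d = nxv * (inctr[0] - cx) + nyv * (inctr[1] - cy) +
               nzv * (inctr[2] - cz);
    if (d > 0) { FI.push_back(q1); FI.push_back(q3); FI.push_back(q2); }
    else       { FI.push_back(q1); FI.push_back(q2); FI.push_back(q3); }
  };

  R_xlen_t corner[8];
  double cpos[8][3];
  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        bool anyin = false, anyout = false;
        for (int c = 0; c < 8; ++c) {
          corner[c] = gid(i + CUBE[c][0], j + CUBE[c][1], k + CUBE[c][2]);
          double f = fval(corner[c]);
          if (f > 0) anyin = true; else anyout = true;
          cpos[c][0] = origin[0] + (i + CUBE[c][0]) * h;
          cpos[c][1] = origin[1] + (j + CUBE[c][1]) * h;
          cpos[c][2] = origin[2] + (k + CUBE[c][2]) * h;
        }
        if (!anyin || !anyout) continue;
        for (int t = 0; t < 6; ++t) {
          int tin[4], tout[4];
          int nin = 0, nout = 0;
          for (int c = 0; c < 4; ++c) {
            int cc = TETS[t][c];
            if (fval(corner[cc]) > 0) tin[nin++] = cc; else tout[nout++] = cc;
          }
          if (nin == 0 || nin == 4) continue;
          double inctr[3] = {0, 0, 0};
          for (int c = 0; c < nin; ++c)
            for (int d = 0; d < 3; ++d) inctr[d] += cpos[tin[c]][d] / nin;
          if (nin == 1) {
            int q1 = edge_vertex(corner[tin[0]], corner[tout[0]]);
            int q2 = edge_vertex(corner[tin[0]], corner[tout[1]]);
            int q3 = edge_vertex(corner[tin[0]], corner[tout[2]]);
            emit(q1, q2, q3, inctr);
          } else if (nin == 3) {
            int q1 = edge_vertex(corner[tin[0]], corner[tout[0]]);
            int q2 = edge_vertex(corner[tin[1]], corner[tout[0]]);
            int q3 = edge_vertex(corner[tin[2]], corner[tout[0]]);
            emit(q1, q2, q3, inctr);
          } else {  // 2 in, 2 out: planar quad on four edges
            int qAC = edge_vertex(corner[tin[0]], corner[tout[0]]);
            int qAD = edge_vertex(corner[tin[0]], corner[tout[1]]);
            int qBC = edge_vertex(corner[tin[1]], corner[tout[0]]);
            int qBD = edge_vertex(corner[tin[1]], corner[tout[1]]);
            emit(qAC, qAD, qBD, inctr);
            emit(qAC, qBD, qBC, inctr);
          }
        }
      }

  int nv = (int)VX.size(), nf = (int)FI.size() / 3;
  NumericMatrix Vout(nv, 3);
  for (int i = 0; i < nv; ++i) {
    Vout(i, 0) = VX[i]; Vout(i, 1) = VY[i]; Vout(i, 2) = VZ[i];
  }
  IntegerMatrix Fout(nf, 3);
  for (int i = 0; i < nf; ++i) {
    Fout(i, 0) = FI[3 * i] + 1;      // 1-based for R
    Fout(i, 1) = FI[3 * i + 1] + 1;
    Fout(i, 2) = FI[3 * i + 2] + 1;
  }
  return List::create(Named("vertices") = Vout, Named("faces") = Fout);
}
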