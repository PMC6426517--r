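#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Voxel grids are column-major (x fastest), 0-based linear index i + nx*(j + ny*k).

static inline bool inb(int i, int j, int k, int nx, int ny, int nz) {
  return i >= 0 && i < nx && j >= 0 && j < ny && k >= 0 && k < nz;
}

// Label connected components of a binary mask. connectivity: 6 or 26.
// Labels assigned in scan order (deterministic); 0 = background.
// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<std::array<int,3>> offs;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        int man = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (connectivity == 6 && man != 1) continue;
        offs.push_back({di, dj, dk});
      }
  int cur = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    lab[s] = cur;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t v = q.front(); q.pop();
      int i = (int)(v % nx), j = (int)((v / nx) % ny), k = (int)(v / ((R_xlen_t)nx * ny));
      for (auto &o : offs) {
        int ii = i + o[0], jj = j + o[1], kk = k + o[2];
        if (!inb(ii, jj, kk, nx, ny, nz)) continue;
        R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
        if (mask[w] && lab[w] == 0) { lab[w] = cur; q.push(w); }
      }
    }
  }
  lab.attr("n_components") = cur;
  return lab;
}

// Linear 0-based indices of mask voxels with >=1 face-adjacent (6-conn) voxel
// that is outside the mask (grid border counts as outside if border_outside).
// [[Rcpp::export(name = ".boundary_voxels")]]
IntegerVector boundary_voxels(LogicalVector mask, IntegerVector dims, bool border_outside) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<int> out;
  const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t v = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        if (!mask[v]) continue;
        bool b = false;
        for (int t = 0; t < 6 && !b; ++t) {
          int ii = i + d6[t][0], jj = j + d6[t][1], kk = k + d6[t][2];
          if (!inb(ii, jj, kk, nx, ny, nz)) { if (border_outside) b = true; continue; }
          if (!mask[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)]) b = true;
        }
        if (b) out.push_back((int)v);
      }
  return wrap(out);
}

// Mark all voxels reachable from the seed set through the structuring-element
// offsets (each seed stamps seed+offset). Offsets are an m x 3 integer matrix.
// [[Rcpp::export(name = ".dilate_seeds")]]
LogicalVector dilate_seeds(IntegerVector seeds, IntegerMatrix offsets, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, false);
  const int m = offsets.nrow();
  for (R_xlen_t s = 0; s < seeds.size(); ++s) {
    R_xlen_t v = seeds[s];
    int i = (int)(v % nx), j = (int)((v / nx) % ny), k = (int)(v / ((R_xlen_t)nx * ny));
    for (int t = 0; t < m; ++t) {
      int ii = i + offsets(t, 0), jj = j + offsets(t, 1), kk = k + offsets(t, 2);
      if (!inb(ii, jj, kk, nx, ny, nz)) continue;
      out[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)] = true;
    }
  }
  return out;
}

// Directed surface distances: for each source voxel (rows of src_idx, 0-based
// i,j,k), the distance in mm to the nearest occupied voxel center of occ.
// Expanding Chebyshev-shell search; exact because a shell at index radius s
// cannot contain a point closer than s * min(spacing).
// [[Rcpp::export(name = ".surface_dist_directed")]]
NumericVector surface_dist_directed(IntegerMatrix src_idx, LogicalVector occ,
                                    IntegerVector dims, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double minsp = std::min(sx, std::min(sy, sz));
  const int smax = std::max(nx, std::max(ny, nz));
  NumericVector out(src_idx.nrow());
  for (int p = 0; p < src_idx.nrow(); ++p) {
    const int ci = src_idx(p, 0), cj = src_idx(p, 1), ck = src_idx(p, 2);
    double best = R_PosInf;
    for (int s = 0; s <= smax; ++s) {
      if ((double)s * minsp > best) break;
      bool any_in_bounds = false;
      // iterate the Chebyshev shell of radius s around (ci,cj,ck)
      int di0 = -s, di1 = s;
      for (int dk = -s; dk <= s; ++dk) {
        int kk = ck + dk;
        if (kk < 0 || kk >= nz) continue;
        bool kface = (std::abs(dk) == s);
        for (int dj = -s; dj <= s; ++dj) {
          int jj = cj + dj;
          if (jj < 0 || jj >= ny) continue;
          bool jface = (std::abs(dj) == s);
          int istep = (kface || jface) ? 1 : (s == 0 ? 1 : 2 * s); // full row on faces, else only +-s
          for (int di = di0; di <= di1; di += istep) {
            int ii = ci + di;
            if (ii < 0 || ii >= nx) continue;
            any_in_bounds = true;
            if (occ[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)]) {
              double dx = di * sx, dy = dj * sy, dz = dk * sz;
              double d = std::sqrt(dx * dx + dy * dy + dz * dz);
              if (d < best) best = d;
            }
          }
        }
      }
      if (!any_in_bounds && (double)s * minsp > 0 && s > smax) break;
    }
    out[p] = best;
  }
  return out;
}

struct Grid {
  int nx, ny, nz;
  double ox, oy, oz, sx, sy, sz;
};

// radiological path length (mm) inside `body` along the segment source -> P,
// by uniform midpoint sampling with nearest-voxel lookup, step <= step_mm.
static double ray_depth(const LogicalVector &body, const Grid &g,
                        const double S[3], const double P[3], double step_mm) {
  // clip segment to the sampling box [origin - sp/2, origin + (n-1/2) sp]
  double t0 = 0.0, t1 = 1.0;
  const double lo[3] = { g.ox - 0.5 * g.sx, g.oy - 0.5 * g.sy, g.oz - 0.5 * g.sz };
  const double hi[3] = { g.ox + (g.nx - 0.5) * g.sx, g.oy + (g.ny - 0.5) * g.sy,
                         g.oz + (g.nz - 0.5) * g.sz };
  const double d[3] = { P[0] - S[0], P[1] - S[1], P[2] - S[2] };
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(d[a]) < 1e-12) {
      if (S[a] < lo[a] || S[a] > hi[a]) return 0.0;
    } else {
      double ta = (lo[a] - S[a]) / d[a], tb = (hi[a] - S[a]) / d[a];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
    }
  }
  if (t1 <= t0) return 0.0;
  double seglen = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]) * (t1 - t0);
  if (seglen <= 0) return 0.0;
  int m = (int)std::ceil(seglen / step_mm);
  if (m < 1) m = 1;
  double dt = (t1 - t0) / m, ds = seglen / m;
  int cnt = 0;
  for (int q = 0; q < m; ++q) {
    double t = t0 + (q + 0.5) * dt;
    double x = S[0] + t * d[0], y = S[1] + t * d[1], z = S[2] + t * d[2];
    int i = (int)std::lround((x - g.ox) / g.sx);
    int j = (int)std::lround((y - g.oy) / g.sy);
    int k = (int)std::lround((z - g.oz) / g.sz);
    if (i < 0 || i >= g.nx || j < 0 || j >= g.ny || k < 0 || k >= g.nz) continue;
    if (body[i + (R_xlen_t)g.nx * (j + (R_xlen_t)g.ny * k)]) ++cnt;
  }
  return cnt * ds;
}

// [[Rcpp::export(name = ".ray_depth_mm")]]
double ray_depth_mm(LogicalVector body, IntegerVector dims, NumericVector spacing,
                    NumericVector origin, NumericVector source, NumericVector point,
                    double step_mm) {
  Grid g{dims[0], dims[1], dims[2], origin[0], origin[1], origin[2],
         spacing[0], spacing[1], spacing[2]};
  double S[3] = {source[0], source[1], source[2]};
  double P[3] = {point[0], point[1], point[2]};
  return ray_depth(body, g, S, P, step_mm);
}

// MLC in-field test in BEV coordinates. Leaves: uniform v-bands starting at
// v_first with width leaf_w; leaf_u is k x 2 (open interval; min>max = closed).
static inline bool mlc_open(double u, double v, double v_first, double leaf_w,
                            const NumericMatrix &leaf_u) {
  int band = (int)std::floor((v - v_first) / leaf_w);
  if (band < 0 || band >= leaf_u.nrow()) return false;
  return u >= leaf_u(band, 0) && u <= leaf_u(band, 1);
}

// For every voxel center, whether its divergent projection onto the isocenter
// plane falls inside the MLC opening of the beam.
// [[Rcpp::export(name = ".infield_mask")]]
LogicalVector infield_mask(IntegerVector dims, NumericVector spacing, NumericVector origin,
                           NumericVector source, NumericVector iso, NumericVector axis,
                           NumericVector eu, NumericVector ev, double sad,
                           double v_first, double leaf_w, NumericMatrix leaf_u) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out((R_xlen_t)nx * ny * nz, false);
  R_xlen_t v = 0;
  for (int k = 0; k < nz; ++k) {
    double pz = origin[2] + k * spacing[2];
    for (int j = 0; j < ny; ++j) {
      double py = origin[1] + j * spacing[1];
      for (int i = 0; i < nx; ++i, ++v) {
        double px = origin[0] + i * spacing[0];
        double w0 = px - source[0], w1 = py - source[1], w2 = pz - source[2];
        double ta = w0 * axis[0] + w1 * axis[1] + w2 * axis[2];
        if (ta <= 1e-9) continue;
        double f = sad / ta;
        double qx = source[0] + f * w0 - iso[0];
        double qy = source[1] + f * w1 - iso[1];
        double qz = source[2] + f * w2 - iso[2];
        double uu = qx * eu[0] + qy * eu[1] + qz * eu[2];
        double vv = qx * ev[0] + qy * ev[1] + qz * ev[2];
        if (mlc_open(uu, vv, v_first, leaf_w, leaf_u)) out[v] = true;
      }
    }
  }
  return out;
}

// Simplified primary-photon dose for one beam, per unit beam weight:
// dose = B(d) * exp(-mu * max(0, d - buildup)) * (SAD / r)^2 inside the body
// and inside the MLC opening; zero elsewhere. d = radiological depth (cm),
// B ramps linearly 0 -> 1 over the buildup depth, r = source distance (mm).
// [[Rcpp::export(name = ".beam_dose")]]
NumericVector beam_dose(LogicalVector body, IntegerVector dims, NumericVector spacing,
                        NumericVector origin, NumericVector source, NumericVector iso,
                        NumericVector axis, NumericVector eu, NumericVector ev,
                        double sad, double v_first, double leaf_w, NumericMatrix leaf_u,
                        double mu_cm, double buildup_cm, double step_mm) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  Grid g{nx, ny, nz, origin[0], origin[1], origin[2], spacing[0], spacing[1], spacing[2]};
  NumericVector out((R_xlen_t)nx * ny * nz, 0.0);
  double S[3] = {source[0], source[1], source[2]};
  R_xlen_t v = 0;
  for (int k = 0; k < nz; ++k) {
    double pz = origin[2] + k * spacing[2];
    for (int j = 0; j < ny; ++j) {
      double py = origin[1] + j * spacing[1];
      for (int i = 0; i < nx; ++i, ++v) {
        if (!body[v]) continue;
        double px = origin[0] + i * spacing[0];
        double w0 = px - S[0], w1 = py - S[1], w2 = pz - S[2];
        double ta = w0 * axis[0] + w1 * axis[1] + w2 * axis[2];
        if (ta <= 1e-9) continue;
        double f = sad / ta;
        double qx = S[0] + f * w0 - iso[0];
        double qy = S[1] + f * w1 - iso[1];
        double qz = S[2] + f * w2 - iso[2];
        double uu = qx * eu[0] + qy * eu[1] + qz * eu[2];
        double vv = qx * ev[0] + qy * ev[1] + qz * ev[2];
        if (!mlc_open(uu, vv, v_first, leaf_w, leaf_u)) continue;
        double P[3] = {px, py, pz};
        double d_cm = ray_depth(body, g, S, P, step_mm) / 10.0;
        double B = (buildup_cm <= 0) ? 1.0 : std::min(1.0, d_cm / buildup_cm);
        double att = std::exp(-mu_cm * std::max(0.0, d_cm - buildup_cm));
        double r = std::sqrt(w0 * w0 + w1 * w1 + w2 * w2);
        out[v] = B * att * (sad / r) * (sad / r);
      }
    }
  }
  return out;
}
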