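#include <Rcpp.h>
#include <cfloat>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Signed ray/mesh first-hit query used by the elastic-foundation contact
// model. For each ray (origin o_i, unit direction d_i) the smallest
// Moller-Trumbore intersection parameter t within [t_min, t_max] is
// returned (NA when the ray misses). Negative t means the surface lies
// behind the origin along the ray, i.e. the foundation point has
// penetrated the rigid body. Triangles are binned into a uniform 2D grid
// over their xy bounding boxes and each ray walks the grid cells along
// its projected path in order of increasing t, stopping as soon as a hit
// closer than the next cell boundary is known (the rays of the contact
// model are near-vertical, so the walk touches few cells).

struct TriData {
  std::vector<double> ax, ay, az, e1x, e1y, e1z, e2x, e2y, e2z;
};

static inline bool hit_tri(const TriData &T, int f, double ox, double oy,
                           double oz, double dx, double dy, double dz,
                           double &t_out) {
  const double eps = 1e-12;
  const double hx = dy * T.e2z[f] - dz * T.e2y[f];
  const double hy = dz * T.e2x[f] - dx * T.e2z[f];
  const double hz = dx * T.e2y[f] - dy * T.e2x[f];
  const double det = T.e1x[f] * hx + T.e1y[f] * hy + T.e1z[f] * hz;
  if (det > -eps && det < eps) return false;
  const double inv = 1.0 / det;
  const double sx = ox - T.ax[f], sy = oy - T.ay[f], sz = oz - T.az[f];
  const double u = inv * (sx * hx + sy * hy + sz * hz);
  if (u < -1e-9 || u > 1.0 + 1e-9) return false;
  const double qx = sy * T.e1z[f] - sz * T.e1y[f];
  const double qy = sz * T.e1x[f] - sx * T.e1z[f];
  const double qz = sx * T.e1y[f] - sy * T.e1x[f];
  const double v = inv * (dx * qx + dy * qy + dz * qz);
  if (v < -1e-9 || u + v > 1.0 + 1e-9) return false;
  t_out = inv * (T.e2x[f] * qx + T.e2y[f] * qy + T.e2z[f] * qz);
  return true;
}

// [[Rcpp::export]]
NumericVector ray_mesh_first_hit(NumericMatrix orig, NumericMatrix dir,
                                 NumericMatrix V, IntegerMatrix F,
                                 double t_min, double t_max) {
  const int nr = orig.nrow();
  const int nf = F.nrow();
  NumericVector out(nr, NA_REAL);
  if (nf == 0) return out;

  TriData T;
  T.ax.resize(nf); T.ay.resize(nf); T.az.resize(nf);
  T.e1x.resize(nf); T.e1y.resize(nf); T.e1z.resize(nf);
  T.e2x.resize(nf); T.e2y.resize(nf); T.e2z.resize(nf);
  double gx0 = DBL_MAX, gy0 = DBL_MAX, gx1 = -DBL_MAX, gy1 = -DBL_MAX;
  std::vector<double> bx0(nf), by0(nf), bx1(nf), by1(nf);
  for (int f = 0; f < nf; ++f) {
    const int i0 = F(f, 0) - 1, i1 = F(f, 1) - 1, i2 = F(f, 2) - 1;
    const double x0 = V(i0, 0), y0 = V(i0, 1), z0 = V(i0, 2);
    const double x1 = V(i1, 0), y1 = V(i1, 1), z1 = V(i1, 2);
    const double x2 = V(i2, 0), y2 = V(i2, 1), z2 = V(i2, 2);
    T.ax[f] = x0; T.ay[f] = y0; T.az[f] = z0;
    T.e1x[f] = x1 - x0; T.e1y[f] = y1 - y0; T.e1z[f] = z1 - z0;
    T.e2x[f] = x2 - x0; T.e2y[f] = y2 - y0; T.e2z[f] = z2 - z0;
    bx0[f] = std::min(x0, std::min(x1, x2));
    bx1[f] = std::max(x0, std::max(x1, x2));
    by0[f] = std::min(y0, std::min(y1, y2));
    by1[f] = std::max(y0, std::max(y1, y2));
    gx0 = std::min(gx0, bx0[f]); gx1 = std::max(gx1, bx1[f]);
    gy0 = std::min(gy0, by0[f]); gy1 = std::max(gy1, by1[f]);
  }
  const double pad = 1e-9 + 1e-9 * (std::fabs(gx1) + std::fabs(gy1));
  gx0 -= pad; gy0 -= pad; gx1 += pad; gy1 += pad;

  int nc = (int)std::ceil(std::sqrt((double)nf / 2.0));
  nc = std::max(4, std::min(nc, 128));
  const double cw = (gx1 - gx0) / nc, ch = (gy1 - gy0) / nc;
  std::vector<std::vector<int>> cells(nc * nc);
  for (int f = 0; f < nf; ++f) {
    int cx0 = (int)((bx0[f] - gx0) / cw), cx1 = (int)((bx1[f] - gx0) / cw);
    int cy0 = (int)((by0[f] - gy0) / ch), cy1 = (int)((by1[f] - gy0) / ch);
    cx0 = std::max(0, std::min(cx0, nc - 1));
    cx1 = std::max(0, std::min(cx1, nc - 1));
    cy0 = std::max(0, std::min(cy0, nc - 1));
    cy1 = std::max(0, std::min(cy1, nc - 1));
    for (int cy = cy0; cy <= cy1; ++cy)
      for (int cx = cx0; cx <= cx1; ++cx)
        cells[cy * nc + cx].push_back(f);
  }

  for (int r = 0; r < nr; ++r) {
    const double ox = orig(r, 0), oy = orig(r, 1), oz = orig(r, 2);
    const double dx = dir(r, 0), dy = dir(r, 1), dz = dir(r, 2);

    // clip the traversal parameter range to the grid in x and y
    double lo = t_min, hi = t_max;
    if (std::fabs(dx) > 1e-14) {
      double ta = (gx0 - ox) / dx, tb = (gx1 - ox) / dx;
      if (ta > tb) std::swap(ta, tb);
      lo = std::max(lo, ta); hi = std::min(hi, tb);
    } else if (ox < gx0 || ox > gx1) continue;
    if (std::fabs(dy) > 1e-14) {
      double ta = (gy0 - oy) / dy, tb = (gy1 - oy) / dy;
      if (ta > tb) std::swap(ta, tb);
      lo = std::max(lo, ta); hi = std::min(hi, tb);
    } else if (oy < gy0 || oy > gy1) continue;
    if (lo > hi) continue;

    double best = DBL_MAX;
    bool hit = false;

    // 2D DDA over grid cells in order of increasing t
    double px = ox + lo * dx, py = oy + lo * dy;
    int cx = std::max(0, std::min((int)((px - gx0) / cw), nc - 1));
    int cy = std::max(0, std::min((int)((py - gy0) / ch), nc - 1));
    const int step_x = dx > 0 ? 1 : -1, step_y = dy > 0 ? 1 : -1;
    double tmax_x = (std::fabs(dx) > 1e-14)
      ? ((gx0 + (cx + (dx > 0 ? 1 : 0)) * cw) - ox) / dx : DBL_MAX;
    double tmax_y = (std::fabs(dy) > 1e-14)
      ? ((gy0 + (cy + (dy > 0 ? 1 : 0)) * ch) - oy) / dy : DBL_MAX;
    const double tdx = (std::fabs(dx) > 1e-14) ? cw / std::fabs(dx)
                                               : DBL_MAX;
    const double tdy = (std::fabs(dy) > 1e-14) ? ch / std::fabs(dy)
                                               : DBL_MAX;
    double t_entry = lo;
    while (true) {
      const std::vector<int> &cell = cells[cy * nc + cx];
      for (size_t k = 0; k < cell.size(); ++k) {
        double t;
        if (hit_tri(T, cell[k], ox, oy, oz, dx, dy, dz, t) &&
            t >= t_min && t <= t_max && t < best) {
          best = t; hit = true;
        }
      }
      const double t_next = std::min(tmax_x, tmax_y);
      if (hit && best <= t_next) break;
      if (t_next > hi || t_next <= t_entry - 1e-15) {
        if (t_next > hi) break;
      }
      t_entry = t_next;
      if (tmax_x < tmax_y) {
        cx += step_x; tmax_x += tdx;
        if (cx < 0 || cx >= nc) break;
      } else {
        cy += step_y; tmax_y += tdy;
        if (cy < 0 || cy >= nc) break;
      }
    }
    if (hit) out[r] = best;
  }
  return out;
}
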