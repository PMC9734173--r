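#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bulk Lagrangian tracker: classical RK4 on hourly gridded currents with
// bilinear space / linear time interpolation, an age-dependent depth layer,
// optional random-walk diffusion, land snap-back, open-boundary loss and
// first-contact sensory-zone settlement. Positions in km, time in hours,
// velocities stored in m/s (converted to km/h internally).

static const double MS_TO_KMH = 3.6;

struct Field {
  const double *u, *v;
  int nx, ny, nd, nt;
  double x0, dx, y0, dy, t0, dt;
  double xmax, ymax, tmax;

  inline bool in_hull(double x, double y) const {
    return x >= x0 && x <= xmax && y >= y0 && y <= ymax;
  }
  // bilinear in (x,y), linear in t, at layer d; returns false outside hull
  inline bool eval(double x, double y, double t, int d,
                   double &uu, double &vv) const {
    if (!in_hull(x, y) || t < t0 || t > tmax) return false;
    double fx = (x - x0) / dx, fy = (y - y0) / dy, ft = (t - t0) / dt;
    int ix = (int)std::floor(fx), iy = (int)std::floor(fy),
        it = (int)std::floor(ft);
    if (ix > nx - 2) ix = nx - 2;
    if (iy > ny - 2) iy = ny - 2;
    if (it > nt - 2) it = nt - 2;
    fx -= ix; fy -= iy; ft -= it;
    const long nxl = nx, nyl = ny, ndl = nd;
    long base0 = ((long)it * ndl + d) * nyl;  // index: ix + nx*(iy + ny*(d + nd*it))
    long base1 = ((long)(it + 1) * ndl + d) * nyl;
    double w00 = (1 - fx) * (1 - fy), w10 = fx * (1 - fy),
           w01 = (1 - fx) * fy, w11 = fx * fy;
    long i00 = (base0 + iy) * nxl + ix, i01 = (base0 + iy + 1) * nxl + ix;
    long j00 = (base1 + iy) * nxl + ix, j01 = (base1 + iy + 1) * nxl + ix;
    double u0 = w00 * u[i00] + w10 * u[i00 + 1] + w01 * u[i01] + w11 * u[i01 + 1];
    double u1 = w00 * u[j00] + w10 * u[j00 + 1] + w01 * u[j01] + w11 * u[j01 + 1];
    double v0 = w00 * v[i00] + w10 * v[i00 + 1] + w01 * v[i01] + w11 * v[i01 + 1];
    double v1 = w00 * v[j00] + w10 * v[j00 + 1] + w01 * v[j01] + w11 * v[j01 + 1];
    uu = ((1 - ft) * u0 + ft * u1) * MS_TO_KMH;
    vv = ((1 - ft) * v0 + ft * v1) * MS_TO_KMH;
    return true;
  }
  inline bool on_land(double x, double y, const int *land) const {
    int ix = (int)std::floor((x - x0) / dx + 0.5);
    int iy = (int)std::floor((y - y0) / dy + 0.5);
    if (ix < 0 || ix >= nx || iy < 0 || iy >= ny) return false;
    return land[iy * (long)nx + ix] != 0;
  }
};

// squared distance from a point to an axis-aligned rectangle
static inline double rect_dist2(double x, double y, double xmin, double xmax,
                                double ymin, double ymax) {
  double ddx = (x < xmin) ? xmin - x : (x > xmax ? x - xmax : 0.0);
  double ddy = (y < ymin) ? ymin - y : (y > ymax ? y - ymax : 0.0);
  return ddx * ddx + ddy * ddy;
}

// [[Rcpp::export(name = ".track_cpp")]]
List track_cpp(NumericVector u, NumericVector v, IntegerVector dims,
               double gx0, double gdx, double gy0, double gdy,
               double gt0, double gdt,
               IntegerVector land,
               NumericVector px0, NumericVector py0, NumericVector release_h,
               double dt, double pld_hours,
               NumericVector age_breaks_h,
               double diffusion_km2h,
               NumericMatrix reefs, IntegerVector reef_region,
               double zone_radius, double competency_h, bool do_settle,
               bool record) {
  Field F;
  F.u = u.begin(); F.v = v.begin();
  F.nx = dims[0]; F.ny = dims[1]; F.nd = dims[2]; F.nt = dims[3];
  F.x0 = gx0; F.dx = gdx; F.y0 = gy0; F.dy = gdy; F.t0 = gt0; F.dt = gdt;
  F.xmax = gx0 + gdx * (F.nx - 1);
  F.ymax = gy0 + gdy * (F.ny - 1);
  F.tmax = gt0 + gdt * (F.nt - 1);

  const int np = px0.size();
  const int nreef = reefs.nrow();
  const int nsteps = (int)std::lround(pld_hours / dt);
  const double zr2 = zone_radius * zone_radius;
  const double diff_sd = std::sqrt(2.0 * diffusion_km2h * dt);

  IntegerVector status(np);       // 0 pelagic, 1 settled, 2 lost
  IntegerVector settle_reef(np, NA_INTEGER);
  IntegerVector settle_region(np, NA_INTEGER);
  NumericVector settle_age(np, NA_REAL);
  NumericVector fx(np), fy(np);
  List traj(record ? np : 0);

  RNGScope rng;

  for (int p = 0; p < np; ++p) {
    double x = px0[p], y = py0[p];
    double t = release_h[p];
    int st = 0, sreef = NA_INTEGER, sregion = NA_INTEGER;
    double sage = NA_REAL;
    NumericMatrix tr;
    if (record) { tr = NumericMatrix(nsteps + 1, 3); }

    int step = 0;
    bool done = false;
    // settlement check at the current state (including release)
    auto try_settle = [&](double age_h) {
      if (!do_settle || age_h < competency_h) return false;
      double best = R_PosInf; int best_r = -1;
      for (int r = 0; r < nreef; ++r) {
        double ddy = y < reefs(r, 2) ? reefs(r, 2) - y
                     : (y > reefs(r, 3) ? y - reefs(r, 3) : 0.0);
        if (ddy * ddy > zr2) continue;       // quick along-shelf reject
        double d2 = rect_dist2(x, y, reefs(r, 0), reefs(r, 1),
                               reefs(r, 2), reefs(r, 3));
        if (d2 <= zr2 && d2 < best) { best = d2; best_r = r; }
      }
      if (best_r >= 0) {
        st = 1; sreef = best_r + 1; sregion = reef_region[best_r];
        sage = age_h / 24.0;
        return true;
      }
      return false;
    };

    if (record) { tr(0, 0) = t; tr(0, 1) = x; tr(0, 2) = y; }
    done = try_settle(0.0);

    while (!done && step < nsteps) {
      double age_h = step * dt;
      int layer = F.nd - 1;
      for (int b = 0; b < age_breaks_h.size(); ++b)
        if (age_h < age_breaks_h[b]) { layer = b; break; }
      double u1, v1, u2, v2, u3, v3, u4, v4;
      bool ok =
        F.eval(x, y, t, layer, u1, v1) &&
        F.eval(x + 0.5 * dt * u1, y + 0.5 * dt * v1, t + 0.5 * dt, layer, u2, v2) &&
        F.eval(x + 0.5 * dt * u2, y + 0.5 * dt * v2, t + 0.5 * dt, layer, u3, v3) &&
        F.eval(x + dt * u3, y + dt * v3, t + dt, layer, u4, v4);
      if (!ok) { st = 2; break; }            // stage outside open boundary
      double xn = x + dt / 6.0 * (u1 + 2 * u2 + 2 * u3 + u4);
      double yn = y + dt / 6.0 * (v1 + 2 * v2 + 2 * v3 + v4);
      if (diff_sd > 0) {
        xn += R::norm_rand() * diff_sd;
        yn += R::norm_rand() * diff_sd;
      }
      if (!F.in_hull(xn, yn)) { st = 2; break; }
      if (F.on_land(xn, yn, land.begin())) { xn = x; yn = y; } // snap back
      x = xn; y = yn;
      t += dt; ++step;
      if (record) { tr(step, 0) = t; tr(step, 1) = x; tr(step, 2) = y; }
      done = try_settle(step * dt);
    }
    status[p] = st; settle_reef[p] = sreef; settle_region[p] = sregion;
    settle_age[p] = sage; fx[p] = x; fy[p] = y;
    if (record) {
      traj[p] = tr(Range(0, step), _);
    }
    if (p % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
    _["status"] = status, _["settle_reef"] = settle_reef,
    _["settle_region"] = settle_region, _["settle_age_days"] = settle_age,
    _["final_x"] = fx, _["final_y"] = fy);
  if (record) out["trajectories"] = traj;
  return out;
}
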