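#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Social-forces engine. Agents are circular bodies driven towards their
// target exit and interacting through psychological repulsion plus the
// contact law (radial restoring + normal damping + sliding friction), with
// walls treated as zero-radius, zero-velocity individuals at the nearest
// wall point. Integration is semi-implicit Euler with a hard speed clamp.
//
// The per-step mutual-information inputs (bin occupancy counts for x, y and
// heading) and the contact-force statistics are accumulated passively: they
// read state but never write it and never touch the RNG.

struct Seg {
  double x1, y1, x2, y2, gap_from, gap_until;
  bool solid_at(double t) const { return !(gap_from <= t && t < gap_until); }
};

static inline void closest_on_seg(double px, double py, const Seg& s,
                                  double& qx, double& qy) {
  double dx = s.x2 - s.x1, dy = s.y2 - s.y1;
  double len2 = dx * dx + dy * dy;
  double t = ((px - s.x1) * dx + (py - s.y1) * dy) / len2;
  if (t < 0) t = 0; else if (t > 1) t = 1;
  qx = s.x1 + t * dx;
  qy = s.y1 + t * dy;
}

static inline double coincident_angle(double id_i, double id_j) {
  double lo = id_i < id_j ? id_i : id_j;
  double hi = id_i < id_j ? id_j : id_i;
  double h = std::sin(lo * 12.9898 + hi * 78.233) * 43758.5453;
  return 2.0 * M_PI * (h - std::floor(h));
}

struct Agents {
  std::vector<double> x, y, vx, vy, th, r, m, v0, tau, id, spawn_t;
  std::vector<int> target;
  size_t n() const { return x.size(); }
  void remove(size_t i) {
    size_t l = n() - 1;
    x[i] = x[l]; y[i] = y[l]; vx[i] = vx[l]; vy[i] = vy[l]; th[i] = th[l];
    r[i] = r[l]; m[i] = m[l]; v0[i] = v0[l]; tau[i] = tau[l];
    id[i] = id[l]; spawn_t[i] = spawn_t[l]; target[i] = target[l];
    x.pop_back(); y.pop_back(); vx.pop_back(); vy.pop_back(); th.pop_back();
    r.pop_back(); m.pop_back(); v0.pop_back(); tau.pop_back();
    id.pop_back(); spawn_t.pop_back(); target.pop_back();
  }
};

struct Grid {
  double x0, y0, cs;
  int nx, ny;
  std::vector<std::vector<int> > cells;
  void build(const Agents& a, double xmin, double ymin, double xmax,
             double ymax, double cell) {
    cs = cell;
    x0 = xmin - 2 * cell; y0 = ymin - 2 * cell;
    nx = (int)std::ceil((xmax - x0 + 2 * cell) / cs) + 1;
    ny = (int)std::ceil((ymax - y0 + 2 * cell) / cs) + 1;
    cells.assign((size_t)nx * ny, std::vector<int>());
    for (size_t i = 0; i < a.n(); ++i) {
      int cx = (int)std::floor((a.x[i] - x0) / cs);
      int cy = (int)std::floor((a.y[i] - y0) / cs);
      if (cx < 0) cx = 0; if (cx >= nx) cx = nx - 1;
      if (cy < 0) cy = 0; if (cy >= ny) cy = ny - 1;
      cells[(size_t)cy * nx + cx].push_back((int)i);
    }
  }
};

static inline int bin_of(double v, double lo, double w, int B) {
  int b = (int)std::floor((v - lo) / w);
  if (b < 0) b = 0; else if (b >= B) b = B - 1;
  return b;
}

static inline double wrap_angle(double t) {
  while (t <= -M_PI) t += 2 * M_PI;
  while (t > M_PI) t -= 2 * M_PI;
  return t;
}

// Goal point for an agent: closest point on its target exit segment with the
// reachable parameter range shrunk by the body radius (keeps agents off the
// door jambs).
static inline void goal_point(double px, double py, double rad,
                              const NumericMatrix& exits, int e,
                              double& gx, double& gy) {
  double x1 = exits(e, 0), y1 = exits(e, 1), x2 = exits(e, 2), y2 = exits(e, 3);
  double dx = x2 - x1, dy = y2 - y1;
  double len = std::sqrt(dx * dx + dy * dy);
  double t = ((px - x1) * dx + (py - y1) * dy) / (len * len);
  double mgn = rad / len;
  if (mgn > 0.45) mgn = 0.45;
  if (t < mgn) t = mgn; else if (t > 1 - mgn) t = 1 - mgn;
  gx = x1 + t * dx;
  gy = y1 + t * dy;
}

// [[Rcpp::export]]
List run_steps_cpp(NumericMatrix agents_in, IntegerVector target_in,
                   NumericMatrix walls, NumericMatrix exits,
                   NumericMatrix entrances, NumericVector credits_in,
                   NumericVector spawn_pars, List fc, double dt, int n_steps,
                   int substeps, double t0, int step0, int next_id,
                   int spawned0, int exited0, List disc, int record_every,
                   int spawn_retries, NumericVector bounds) {
  RNGScope rngScope;

  const double k_rad = fc["k_radial"], kappa = fc["kappa_friction"],
               cdamp = fc["c_damp"], Asoc = fc["A_social"],
               Bsoc = fc["B_social"], vmax = fc["v_max"],
               sfloor = fc["speed_floor"], cutoff = fc["cutoff"];
  const int B = as<int>(disc["n_bins"]);
  const double xlo = as<double>(disc["x_lo"]), xhi = as<double>(disc["x_hi"]);
  const double ylo = as<double>(disc["y_lo"]), yhi = as<double>(disc["y_hi"]);
  const double wx = (xhi - xlo) / B, wy = (yhi - ylo) / B,
               wt = 2 * M_PI / B, tlo = -M_PI;

  Agents A;
  {
    int n = agents_in.nrow();
    A.x.reserve(n); // columns: x y vx vy theta radius mass v0 tau id spawn_t
    for (int i = 0; i < n; ++i) {
      A.x.push_back(agents_in(i, 0)); A.y.push_back(agents_in(i, 1));
      A.vx.push_back(agents_in(i, 2)); A.vy.push_back(agents_in(i, 3));
      A.th.push_back(agents_in(i, 4)); A.r.push_back(agents_in(i, 5));
      A.m.push_back(agents_in(i, 6)); A.v0.push_back(agents_in(i, 7));
      A.tau.push_back(agents_in(i, 8)); A.id.push_back(agents_in(i, 9));
      A.spawn_t.push_back(agents_in(i, 10));
      A.target.push_back(target_in[i]);
    }
  }

  std::vector<Seg> segs;
  for (int k = 0; k < walls.nrow(); ++k) {
    Seg s = {walls(k, 0), walls(k, 1), walls(k, 2), walls(k, 3),
             walls(k, 4), walls(k, 5)};
    segs.push_back(s);
  }

  std::vector<double> credits(credits_in.begin(), credits_in.end());
  const double m_lo = spawn_pars[0], m_hi = spawn_pars[1],
               r_lo = spawn_pars[2], r_hi = spawn_pars[3],
               v0_lo = spawn_pars[4], v0_hi = spawn_pars[5],
               tau_new = spawn_pars[6];

  IntegerMatrix counts_x(n_steps, B), counts_y(n_steps, B), counts_th(n_steps, B);
  IntegerVector n_agents(n_steps), spawned_cum(n_steps), exited_cum(n_steps);
  NumericVector mean_net(n_steps), mean_scalar(n_steps), max_net(n_steps);
  std::vector<double> exit_events;   // id, time, exit_idx
  std::vector<double> traj;          // step, time, id, x, y, vx, vy, theta, contact_net
  double max_wall_pen = 0.0;
  int spawned = spawned0, exited = exited0, deferred = 0;

  Grid grid;
  const double dts = dt / substeps;
  std::vector<double> fx, fy, cfx, cfy, csc;

  for (int s = 0; s < n_steps; ++s) {
    double t_step = t0 + s * dt;
    size_t n = A.n();
    for (int sub = 0; sub < substeps; ++sub) {
      double t_now = t_step + sub * dts;
      n = A.n();
      fx.assign(n, 0.0); fy.assign(n, 0.0);
      cfx.assign(n, 0.0); cfy.assign(n, 0.0); csc.assign(n, 0.0);

      // driving force
      for (size_t i = 0; i < n; ++i) {
        double ex = 0, ey = 0;
        if (A.target[i] >= 0) {
          double gx, gy;
          goal_point(A.x[i], A.y[i], A.r[i], exits, A.target[i], gx, gy);
          double dx = gx - A.x[i], dy = gy - A.y[i];
          double d = std::sqrt(dx * dx + dy * dy);
          if (d > 1e-12) { ex = dx / d; ey = dy / d; }
        }
        fx[i] += A.m[i] * (A.v0[i] * ex - A.vx[i]) / A.tau[i];
        fy[i] += A.m[i] * (A.v0[i] * ey - A.vy[i]) / A.tau[i];
      }

      // pairwise forces via cell grid
      grid.build(A, bounds[0], bounds[1], bounds[2], bounds[3], cutoff);
      for (int cy = 0; cy < grid.ny; ++cy) {
        for (int cx = 0; cx < grid.nx; ++cx) {
          const std::vector<int>& c0 = grid.cells[(size_t)cy * grid.nx + cx];
          if (c0.empty()) continue;
          for (int oy = -1; oy <= 1; ++oy) {
            for (int ox = -1; ox <= 1; ++ox) {
              int ncx = cx + ox, ncy = cy + oy;
              if (ncx < 0 || ncx >= grid.nx || ncy < 0 || ncy >= grid.ny) continue;
              const std::vector<int>& c1 = grid.cells[(size_t)ncy * grid.nx + ncx];
              for (size_t a = 0; a < c0.size(); ++a) {
                int i = c0[a];
                for (size_t b = 0; b < c1.size(); ++b) {
                  int j = c1[b];
                  if (j <= i) continue;  // unordered pairs once
                  double dx = A.x[i] - A.x[j], dy = A.y[i] - A.y[j];
                  double d2 = dx * dx + dy * dy;
                  if (d2 >= cutoff * cutoff) continue;
                  double d = std::sqrt(d2);
                  double rij = A.r[i] + A.r[j];
                  double nxv, nyv;
                  if (d < 1e-12) {
                    double ang = coincident_angle(A.id[i], A.id[j]);
                    double sgn = (A.id[i] < A.id[j]) ? 1.0 : -1.0;
                    nxv = sgn * std::cos(ang); nyv = sgn * std::sin(ang);
                  } else {
                    nxv = dx / d; nyv = dy / d;
                  }
                  double fsoc = Asoc * std::exp((rij - d) / Bsoc);
                  double pfx = fsoc * nxv, pfy = fsoc * nyv;
                  if (d < rij) {
                    double txv = -nyv, tyv = nxv;
                    double ol = rij - d;
                    double dvx = A.vx[j] - A.vx[i], dvy = A.vy[j] - A.vy[i];
                    double dv_n = dvx * nxv + dvy * nyv;
                    double dv_t = dvx * txv + dvy * tyv;
                    double fn = k_rad * ol + cdamp * dv_n;
                    double ft = kappa * ol * dv_t;
                    double ccx = fn * nxv + ft * txv;
                    double ccy = fn * nyv + ft * tyv;
                    pfx += ccx; pfy += ccy;
                    cfx[i] += ccx; cfy[i] += ccy;
                    cfx[j] -= ccx; cfy[j] -= ccy;
                    double mag = std::sqrt(ccx * ccx + ccy * ccy);
                    csc[i] += mag; csc[j] += mag;
                  }
                  fx[i] += pfx; fy[i] += pfy;
                  fx[j] -= pfx; fy[j] -= pfy;
                }
              }
            }
          }
        }
      }

      // wall forces (contact + psychological), solid segments only
      for (size_t i = 0; i < n; ++i) {
        for (size_t k = 0; k < segs.size(); ++k) {
          if (!segs[k].solid_at(t_now)) continue;
          double qx, qy;
          closest_on_seg(A.x[i], A.y[i], segs[k], qx, qy);
          double dx = A.x[i] - qx, dy = A.y[i] - qy;
          double d = std::sqrt(dx * dx + dy * dy);
          if (d >= A.r[i] + 8 * Bsoc) continue;
          double nxv, nyv;
          if (d < 1e-12) {
            double sx = segs[k].x2 - segs[k].x1, sy = segs[k].y2 - segs[k].y1;
            double sl = std::sqrt(sx * sx + sy * sy);
            nxv = -sy / sl; nyv = sx / sl;
          } else {
            nxv = dx / d; nyv = dy / d;
          }
          double fsoc = Asoc * std::exp((A.r[i] - d) / Bsoc);
          fx[i] += fsoc * nxv; fy[i] += fsoc * nyv;
          if (d < A.r[i]) {
            double ol = A.r[i] - d;
            if (ol > max_wall_pen) max_wall_pen = ol;
            double txv = -nyv, tyv = nxv;
            double dv_n = (-A.vx[i]) * nxv + (-A.vy[i]) * nyv;
            double dv_t = (-A.vx[i]) * txv + (-A.vy[i]) * tyv;
            double fn = k_rad * ol + cdamp * dv_n;
            double ft = kappa * ol * dv_t;
            double ccx = fn * nxv + ft * txv;
            double ccy = fn * nyv + ft * tyv;
            fx[i] += ccx; fy[i] += ccy;
            cfx[i] += ccx; cfy[i] += ccy;
            csc[i] += std::sqrt(ccx * ccx + ccy * ccy);
          }
        }
      }

      // semi-implicit Euler with speed clamp
      for (size_t i = 0; i < n; ++i) {
        if (!std::isfinite(fx[i]) || !std::isfinite(fy[i])) {
          stop("non-finite force on agent id %d at t = %.3f s",
               (int)A.id[i], t_now);
        }
        A.vx[i] += fx[i] / A.m[i] * dts;
        A.vy[i] += fy[i] / A.m[i] * dts;
        double sp = std::sqrt(A.vx[i] * A.vx[i] + A.vy[i] * A.vy[i]);
        if (sp > vmax) { A.vx[i] *= vmax / sp; A.vy[i] *= vmax / sp; }
        A.x[i] += A.vx[i] * dts;
        A.y[i] += A.vy[i] * dts;
      }
    }

    double t_new = t_step + dt;

    // heading update (carried over below the speed floor)
    for (size_t i = 0; i < A.n(); ++i) {
      double sp = std::sqrt(A.vx[i] * A.vx[i] + A.vy[i] * A.vy[i]);
      if (sp > sfloor) A.th[i] = std::atan2(A.vy[i], A.vx[i]);
    }

    // force statistics over the population present during the step
    {
      size_t nn = A.n();
      double smean = 0, scmean = 0, mx = 0;
      for (size_t i = 0; i < nn; ++i) {
        double mag = std::sqrt(cfx[i] * cfx[i] + cfy[i] * cfy[i]);
        smean += mag; scmean += csc[i];
        if (mag > mx) mx = mag;
      }
      mean_net[s] = nn ? smean / nn : 0.0;
      mean_scalar[s] = nn ? scmean / nn : 0.0;
      max_net[s] = mx;
    }

    // absorption at open target exits
    for (size_t i = 0; i < A.n();) {
      int e = A.target[i];
      bool gone = false;
      if (e >= 0 && exits(e, 4) <= t_new && t_new < exits(e, 5)) {
        Seg es = {exits(e, 0), exits(e, 1), exits(e, 2), exits(e, 3), 0, 0};
        double qx, qy;
        closest_on_seg(A.x[i], A.y[i], es, qx, qy);
        double dx = A.x[i] - qx, dy = A.y[i] - qy;
        if (dx * dx + dy * dy <= A.r[i] * A.r[i]) {
          exit_events.push_back(A.id[i]);
          exit_events.push_back(t_new);
          exit_events.push_back((double)(e + 1));  // 1-based for R
          A.remove(i);
          ++exited;
          gone = true;
        }
      }
      if (!gone) ++i;
    }

    // inflow: deterministic credit accumulator, uniform placement along the
    // entrance segment offset inward by one body radius; overlapping
    // placements are retried then deferred to the next step
    for (int q = 0; q < entrances.nrow(); ++q) {
      credits[q] += entrances(q, 4) * dt;
      // 1e-9 slack absorbs float drift in the credit accumulation so that
      // rate * time agents are spawned exactly
      while (credits[q] >= 1.0 - 1e-9) {
        double mass_n = m_lo + unif_rand() * (m_hi - m_lo);
        double r_n = r_lo + unif_rand() * (r_hi - r_lo);
        double v0_n = v0_lo + unif_rand() * (v0_hi - v0_lo);
        bool placed = false;
        double px = 0, py = 0;
        for (int att = 0; att <= spawn_retries && !placed; ++att) {
          double u = unif_rand();
          px = entrances(q, 0) + u * (entrances(q, 2) - entrances(q, 0)) +
               entrances(q, 5) * (r_n + 1e-6);
          py = entrances(q, 1) + u * (entrances(q, 3) - entrances(q, 1)) +
               entrances(q, 6) * (r_n + 1e-6);
          bool ok = true;
          for (size_t j = 0; j < A.n() && ok; ++j) {
            double dx = px - A.x[j], dy = py - A.y[j];
            double rr = r_n + A.r[j];
            if (dx * dx + dy * dy < rr * rr) ok = false;
          }
          for (size_t k = 0; k < segs.size() && ok; ++k) {
            if (!segs[k].solid_at(t_new)) continue;
            double qx, qy;
            closest_on_seg(px, py, segs[k], qx, qy);
            double dx = px - qx, dy = py - qy;
            if (dx * dx + dy * dy < r_n * r_n) ok = false;
          }
          placed = ok;
        }
        if (!placed) { ++deferred; break; }
        // nearest open exit by segment midpoint
        int best = -1;
        double bestd = 0;
        for (int e = 0; e < exits.nrow(); ++e) {
          if (!(exits(e, 4) <= t_new && t_new < exits(e, 5))) continue;
          double mxp = 0.5 * (exits(e, 0) + exits(e, 2));
          double myp = 0.5 * (exits(e, 1) + exits(e, 3));
          double dd = (mxp - px) * (mxp - px) + (myp - py) * (myp - py);
          if (best < 0 || dd < bestd) { best = e; bestd = dd; }
        }
        double th0 = 0;
        if (best >= 0) {
          double gx, gy;
          goal_point(px, py, r_n, exits, best, gx, gy);
          th0 = std::atan2(gy - py, gx - px);
        }
        A.x.push_back(px); A.y.push_back(py);
        A.vx.push_back(0); A.vy.push_back(0);
        A.th.push_back(th0); A.r.push_back(r_n); A.m.push_back(mass_n);
        A.v0.push_back(v0_n); A.tau.push_back(tau_new);
        A.id.push_back((double)next_id++);
        A.spawn_t.push_back(t_new);
        A.target.push_back(best);
        credits[q] -= 1.0;
        ++spawned;
      }
    }

    // passive recordings: occupancy counts for the MI detector
    {
      size_t nn = A.n();
      n_agents[s] = (int)nn;
      spawned_cum[s] = spawned;
      exited_cum[s] = exited;
      for (size_t i = 0; i < nn; ++i) {
        counts_x(s, bin_of(A.x[i], xlo, wx, B))++;
        counts_y(s, bin_of(A.y[i], ylo, wy, B))++;
        counts_th(s, bin_of(wrap_angle(A.th[i]), tlo, wt, B))++;
      }
    }

    // trajectory snapshots
    int gstep = step0 + s + 1;
    if (record_every > 0 && gstep % record_every == 0) {
      for (size_t i = 0; i < A.n(); ++i) {
        double mag = 0;
        if (i < cfx.size()) mag = std::sqrt(cfx[i] * cfx[i] + cfy[i] * cfy[i]);
        double row[9] = {(double)gstep, t_new, A.id[i], A.x[i], A.y[i],
                         A.vx[i], A.vy[i], A.th[i], mag};
        traj.insert(traj.end(), row, row + 9);
      }
    }
  }

  size_t n_out = A.n();
  NumericMatrix agents_out(n_out, 11);
  IntegerVector target_out(n_out);
  for (size_t i = 0; i < n_out; ++i) {
    agents_out(i, 0) = A.x[i]; agents_out(i, 1) = A.y[i];
    agents_out(i, 2) = A.vx[i]; agents_out(i, 3) = A.vy[i];
    agents_out(i, 4) = A.th[i]; agents_out(i, 5) = A.r[i];
    agents_out(i, 6) = A.m[i]; agents_out(i, 7) = A.v0[i];
    agents_out(i, 8) = A.tau[i]; agents_out(i, 9) = A.id[i];
    agents_out(i, 10) = A.spawn_t[i];
    target_out[i] = A.target[i];
  }
  NumericMatrix ev((int)(exit_events.size() / 3), 3);
  for (int i = 0; i < ev.nrow(); ++i) {
    ev(i, 0) = exit_events[3 * i];
    ev(i, 1) = exit_events[3 * i + 1];
    ev(i, 2) = exit_events[3 * i + 2];
  }
  NumericMatrix tr((int)(traj.size() / 9), 9);
  for (int i = 0; i < tr.nrow(); ++i) {
    for (int j = 0; j < 9; ++j) tr(i, j) = traj[9 * i + j];
  }
  return List::create(
      _["agents"] = agents_out, _["target"] = target_out,
      _["counts_x"] = counts_x, _["counts_y"] = counts_y,
      _["counts_theta"] = counts_th, _["n_agents"] = n_agents,
      _["spawned_cum"] = spawned_cum, _["exited_cum"] = exited_cum,
      _["mean_net"] = mean_net, _["mean_scalar"] = mean_scalar,
      _["max_net"] = max_net, _["exit_events"] = ev, _["traj"] = tr,
      _["credits"] = NumericVector(credits.begin(), credits.end()),
      _["next_id"] = next_id, _["spawned"] = spawned, _["exited"] = exited,
      _["deferred"] = deferred, _["max_wall_penetration"] = max_wall_pen);
}
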