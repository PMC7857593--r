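#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline double min_image_delta(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

// Cross minimum-image distance matrix between two coordinate sets (nm).
// A: na x 3, B: nb x 3, box: (Lx, Ly, Lz). Orthorhombic only.
// [[Rcpp::export]]
NumericMatrix cpp_cross_min_dist(NumericMatrix A, NumericMatrix B,
                                 NumericVector box) {
  const int na = A.nrow(), nb = B.nrow();
  NumericMatrix out(na, nb);
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      double dx = min_image_delta(A(i, 0) - B(j, 0), box[0]);
      double dy = min_image_delta(A(i, 1) - B(j, 1), box[1]);
      double dz = min_image_delta(A(i, 2) - B(j, 2), box[2]);
      out(i, j) = std::sqrt(dx * dx + dy * dy + dz * dz);
    }
  }
  return out;
}

// Molecule-molecule minimum distance matrix. grp is a 0-based molecule
// index per particle; the (g,h) entry is the smallest minimum-image
// particle-particle distance between molecules g and h (diagonal 0).
// [[Rcpp::export]]
NumericMatrix cpp_group_min_dist(NumericMatrix X, IntegerVector grp,
                                 int ngrp, NumericVector box) {
  const int n = X.nrow();
  NumericMatrix out(ngrp, ngrp);
  std::fill(out.begin(), out.end(), R_PosInf);
  for (int g = 0; g < ngrp; ++g) out(g, g) = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int g = grp[i], h = grp[j];
      if (g == h) continue;
      double dx = min_image_delta(X(i, 0) - X(j, 0), box[0]);
      double dy = min_image_delta(X(i, 1) - X(j, 1), box[1]);
      double dz = min_image_delta(X(i, 2) - X(j, 2), box[2]);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < out(g, h)) { out(g, h) = d; out(h, g) = d; }
    }
  }
  return out;
}

struct Capture { int particle; int site; double dist; };

// Overdamped 2D Langevin dynamics of TAG particles in a periodic box with
// a short-range pairwise attraction and an optional ring of binding sites.
// Units: nm, ns, kT = 1.  step = sqrt(2 D dt) g + D F dt.
// Pair potential U(r) = -eps (1 - (r/rc)^2)^2 for r < rc (smooth well).
// A free particle entering capture_radius of an unoccupied site binds
// (nearest-first when several candidates compete); a bound particle moves
// with D_bound, is tethered inside the capture disk, and unbinds as a
// Poisson process with rate k_off.  After unbinding it must leave the
// capture disk before it can rebind to the same site.
// Uses R's RNG: results are reproducible under set.seed().
// [[Rcpp::export]]
List cpp_bd_simulate(NumericMatrix xy0, double Lx, double Ly,
                     double D_free, double D_bound, double eps, double rc,
                     NumericMatrix sites, double capture_radius,
                     double k_off, double dt, int n_steps, int save_every) {
  const int n = xy0.nrow();
  const int ns = sites.nrow();
  const int n_save = n_steps / save_every + 1;
  const double p_off = 1.0 - std::exp(-k_off * dt);
  const double rc2 = rc * rc;
  const double cap2 = capture_radius * capture_radius;

  std::vector<double> x(n), y(n);
  for (int i = 0; i < n; ++i) { x[i] = xy0(i, 0); y[i] = xy0(i, 1); }

  std::vector<int> state(n, -1);       // -1 free, else site index
  std::vector<int> refractory(n, -1);  // site to escape before rebinding
  std::vector<int> site_occ(ns, -1);   // -1 empty, else particle index
  std::vector<int> bind_start(n, -1);  // step at which current event began

  NumericMatrix xs(n_save, n), ys(n_save, n);
  IntegerMatrix states(n_save, n);
  std::vector<int> ev_particle, ev_site, ev_start, ev_end;
  std::vector<int> ev_censored;

  std::vector<double> fx(n), fy(n);

  int save_row = 0;
  for (int i = 0; i < n; ++i) {
    xs(0, i) = x[i]; ys(0, i) = y[i]; states(0, i) = -1;
  }
  save_row = 1;

  for (int step = 1; step <= n_steps; ++step) {
    // pairwise attraction
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    if (eps > 0.0) {
      for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) {
          double dx = min_image_delta(x[i] - x[j], Lx);
          double dy = min_image_delta(y[i] - y[j], Ly);
          double r2 = dx * dx + dy * dy;
          if (r2 >= rc2 || r2 == 0.0) continue;
          double s = 1.0 - r2 / rc2;
          // radial force -dU/dr along r_hat; expressed per-component:
          // F_i = -(4 eps / rc^2) s * (x_i - x_j)
          double fac = -4.0 * eps * s / rc2;
          fx[i] += fac * dx; fy[i] += fac * dy;
          fx[j] -= fac * dx; fy[j] -= fac * dy;
        }
      }
    }

    // displace
    for (int i = 0; i < n; ++i) {
      double D = (state[i] >= 0) ? D_bound : D_free;
      double sig = std::sqrt(2.0 * D * dt);
      x[i] += sig * norm_rand() + D * fx[i] * dt;
      y[i] += sig * norm_rand() + D * fy[i] * dt;
      if (state[i] >= 0) {
        // tether: project back into the capture disk of the bound site
        int s = state[i];
        double dx = min_image_delta(x[i] - sites(s, 0), Lx);
        double dy = min_image_delta(y[i] - sites(s, 1), Ly);
        double r2 = dx * dx + dy * dy;
        if (r2 > cap2) {
          // project strictly inside so the bound => within-capture-radius
          // invariant survives floating-point round-off
          double fac = capture_radius * (1.0 - 1e-9) / std::sqrt(r2);
          x[i] = sites(s, 0) + dx * fac;
          y[i] = sites(s, 1) + dy * fac;
        }
      }
      x[i] -= Lx * std::floor(x[i] / Lx);
      y[i] -= Ly * std::floor(y[i] / Ly);
    }

    if (ns > 0) {
      // unbinding (Poisson, rate k_off)
      for (int i = 0; i < n; ++i) {
        if (state[i] >= 0 && unif_rand() < p_off) {
          int s = state[i];
          ev_particle.push_back(i); ev_site.push_back(s);
          ev_start.push_back(bind_start[i]); ev_end.push_back(step);
          ev_censored.push_back(0);
          site_occ[s] = -1; state[i] = -1; bind_start[i] = -1;
          refractory[i] = s;
        }
      }
      // refractory release: must exit the capture disk first
      for (int i = 0; i < n; ++i) {
        if (refractory[i] >= 0) {
          int s = refractory[i];
          double dx = min_image_delta(x[i] - sites(s, 0), Lx);
          double dy = min_image_delta(y[i] - sites(s, 1), Ly);
          if (dx * dx + dy * dy > cap2) refractory[i] = -1;
        }
      }
      // capture, nearest-first
      std::vector<Capture> cand;
      for (int i = 0; i < n; ++i) {
        if (state[i] >= 0) continue;
        for (int s = 0; s < ns; ++s) {
          if (site_occ[s] >= 0 || refractory[i] == s) continue;
          double dx = min_image_delta(x[i] - sites(s, 0), Lx);
          double dy = min_image_delta(y[i] - sites(s, 1), Ly);
          double d2 = dx * dx + dy * dy;
          if (d2 <= cap2) cand.push_back({i, s, std::sqrt(d2)});
        }
      }
      std::sort(cand.begin(), cand.end(),
                [](const Capture &a, const Capture &b) {
                  if (a.dist != b.dist) return a.dist < b.dist;
                  if (a.particle != b.particle) return a.particle < b.particle;
                  return a.site < b.site;
                });
      for (const Capture &c : cand) {
        if (state[c.particle] >= 0 || site_occ[c.site] >= 0) continue;
        state[c.particle] = c.site;
        site_occ[c.site] = c.particle;
        bind_start[c.particle] = step;
      }
    }

    if (step % save_every == 0) {
      for (int i = 0; i < n; ++i) {
        xs(save_row, i) = x[i]; ys(save_row, i) = y[i];
        states(save_row, i) = state[i];
      }
      ++save_row;
    }
  }

  // events still open at the end are censored by the trajectory end
  for (int i = 0; i < n; ++i) {
    if (state[i] >= 0) {
      ev_particle.push_back(i); ev_site.push_back(state[i]);
      ev_start.push_back(bind_start[i]); ev_end.push_back(n_steps);
      ev_censored.push_back(1);
    }
  }

  return List::create(
    _["x"] = xs, _["y"] = ys, _["state"] = states,
    _["ev_particle"] = wrap(ev_particle), _["ev_site"] = wrap(ev_site),
    _["ev_start"] = wrap(ev_start), _["ev_end"] = wrap(ev_end),
    _["ev_censored"] = wrap(ev_censored));
}
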