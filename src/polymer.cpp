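#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Coarse-grained bead-spring chromosome dynamics.
//
// Overdamped Langevin integration (friction = 1, kT = 1, length unit = one
// monomer diameter) of harmonic backbone bonds, harmonic LEF bonds and a soft
// purely repulsive excluded-volume force, in a cubic periodic box. Positions
// are kept unwrapped; the minimum-image convention is applied only to the
// excluded-volume interaction and to inter-chain contact detection, so the
// intra-chain geometry is the true chain geometry.

struct CellList {
  int m;              // cells per side
  double cell;        // cell edge
  double box;
  std::vector<int> head;
  std::vector<int> next;

  void build(const std::vector<double>& x, const std::vector<double>& y,
             const std::vector<double>& z, double box_, double cutoff) {
    box = box_;
    m = std::max(3, std::min((int)std::floor(box / cutoff), 256));
    cell = box / m;
    head.assign((size_t)m * m * m, -1);
    int n = x.size();
    next.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      int cx = wrap_cell(x[i]), cy = wrap_cell(y[i]), cz = wrap_cell(z[i]);
      int c = (cx * m + cy) * m + cz;
      next[i] = head[c];
      head[c] = i;
    }
  }
  inline int wrap_cell(double v) const {
    double w = v - box * std::floor(v / box);
    if (w < 0) w += box;
    if (w >= box) w -= box;
    int c = (int)(w / cell);
    if (c >= m) c = m - 1;
    return c;
  }
};

static inline double min_image(double d, double box) {
  return d - box * std::nearbyint(d / box);
}

// [[Rcpp::export]]
NumericMatrix cpp_md_run(NumericMatrix coords,
                         double box,
                         IntegerVector chain_id,
                         IntegerMatrix extra_bonds,
                         int n_steps,
                         double dt,
                         double k_bond,
                         double ev_eps,
                         double ev_cut) {
  const int n = coords.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    x[i] = coords(i, 0);
    y[i] = coords(i, 1);
    z[i] = coords(i, 2);
  }
  // backbone bonds between consecutive monomers of the same chain
  std::vector<int> bi, bj;
  for (int i = 0; i + 1 < n; ++i)
    if (chain_id[i] == chain_id[i + 1]) {
      bi.push_back(i);
      bj.push_back(i + 1);
    }
  for (int k = 0; k < extra_bonds.nrow(); ++k) {
    bi.push_back(extra_bonds(k, 0));
    bj.push_back(extra_bonds(k, 1));
  }
  const int nb = bi.size();
  std::vector<double> fx(n), fy(n), fz(n);
  CellList cl;
  const double noise = std::sqrt(2.0 * dt);
  const double rc2 = ev_cut * ev_cut;

  for (int step = 0; step < n_steps; ++step) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    // bonds (unwrapped displacement; rest length 1)
    for (int k = 0; k < nb; ++k) {
      int i = bi[k], j = bj[k];
      double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-9) continue;
      double f = k_bond * (r - 1.0) / r;
      fx[i] += f * dx; fy[i] += f * dy; fz[i] += f * dz;
      fx[j] -= f * dx; fy[j] -= f * dy; fz[j] -= f * dz;
    }
    // soft repulsion, minimum image
    if (ev_eps > 0 && box < 3.0 * ev_cut) {
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) {
          double dx = min_image(x[j] - x[i], box);
          double dy = min_image(y[j] - y[i], box);
          double dz = min_image(z[j] - z[i], box);
          double r2 = dx * dx + dy * dy + dz * dz;
          if (r2 >= rc2 || r2 < 1e-12) continue;
          double r = std::sqrt(r2);
          double f = -(ev_eps / ev_cut) * (1.0 - r / ev_cut) / r;
          fx[i] += f * dx; fy[i] += f * dy; fz[i] += f * dz;
          fx[j] -= f * dx; fy[j] -= f * dy; fz[j] -= f * dz;
        }
    } else if (ev_eps > 0) {
      cl.build(x, y, z, box, ev_cut);
      const int m = cl.m;
      auto wrap = [m](int c) {
        if (c < 0) return c + m;
        if (c >= m) return c - m;
        return c;
      };
      for (int cx = 0; cx < m; ++cx) {
        const int wx[3] = {wrap(cx - 1), cx, wrap(cx + 1)};
        for (int cy = 0; cy < m; ++cy) {
          const int wy[3] = {wrap(cy - 1), cy, wrap(cy + 1)};
          for (int cz = 0; cz < m; ++cz) {
            int c = (cx * m + cy) * m + cz;
            if (cl.head[c] < 0) continue;
            const int wz[3] = {wrap(cz - 1), cz, wrap(cz + 1)};
            for (int i = cl.head[c]; i >= 0; i = cl.next[i]) {
              for (int ox = 0; ox < 3; ++ox)
                for (int oy = 0; oy < 3; ++oy) {
                  int base = (wx[ox] * m + wy[oy]) * m;
                  for (int oz = 0; oz < 3; ++oz) {
                    for (int j = cl.head[base + wz[oz]]; j >= 0;
                         j = cl.next[j]) {
                      if (j <= i) continue;
                      double dx = min_image(x[j] - x[i], box);
                      double dy = min_image(y[j] - y[i], box);
                      double dz = min_image(z[j] - z[i], box);
                      double r2 = dx * dx + dy * dy + dz * dz;
                      if (r2 >= rc2 || r2 < 1e-12) continue;
                      double r = std::sqrt(r2);
                      // linear-ramp repulsion, max ev_eps/ev_cut at r = 0
                      double f = -(ev_eps / ev_cut) * (1.0 - r / ev_cut) / r;
                      fx[i] += f * dx; fy[i] += f * dy; fz[i] += f * dz;
                      fx[j] -= f * dx; fy[j] -= f * dy; fz[j] -= f * dz;
                    }
                  }
                }
            }
          }
        }
      }
    }
    for (int i = 0; i < n; ++i) {
      x[i] += dt * fx[i] + noise * norm_rand();
      y[i] += dt * fy[i] + noise * norm_rand();
      z[i] += dt * fz[i] + noise * norm_rand();
    }
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    if (!std::isfinite(x[i]) || !std::isfinite(y[i]) || !std::isfinite(z[i]))
      stop("polymer dynamics diverged (non-finite coordinate at monomer %d)",
           i + 1);
    out(i, 0) = x[i];
    out(i, 1) = y[i];
    out(i, 2) = z[i];
  }
  return out;
}

// Contact detection. Pairs with minimum-image distance <= radius are
// candidates; intra-chain pairs are kept only if their direct (unwrapped)
// distance is within the radius, otherwise they are flagged as contacts with
// a periodic self-image. type: 0 = intra, 1 = trans (distinct chains),
// 2 = intra self-image.
// [[Rcpp::export]]
List cpp_contacts(NumericMatrix coords,
                  double box,
                  IntegerVector chain_id,
                  double radius) {
  if (radius <= 0) stop("contact radius must be positive");
  const int n = coords.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    x[i] = coords(i, 0);
    y[i] = coords(i, 1);
    z[i] = coords(i, 2);
  }
  const double r2 = radius * radius;
  std::vector<int> ci, cj, ty;
  auto classify_push = [&](int i, int j, double d2) {
    int type;
    if (chain_id[i] != chain_id[j]) {
      type = 1;
    } else {
      double ux = x[j] - x[i], uy = y[j] - y[i], uz = z[j] - z[i];
      double du2 = ux * ux + uy * uy + uz * uz;
      type = (du2 <= r2) ? 0 : 2;
    }
    ci.push_back(i);
    cj.push_back(j);
    ty.push_back(type);
  };
  if (box < 3.0 * radius) {
    // box too small for a periodic cell list: brute force
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double dx = min_image(x[j] - x[i], box);
        double dy = min_image(y[j] - y[i], box);
        double dz = min_image(z[j] - z[i], box);
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 <= r2) classify_push(i, j, d2);
      }
    return List::create(_["i"] = IntegerVector(ci.begin(), ci.end()),
                        _["j"] = IntegerVector(cj.begin(), cj.end()),
                        _["type"] = IntegerVector(ty.begin(), ty.end()));
  }
  CellList cl;
  cl.build(x, y, z, box, radius);
  const int m = cl.m;
  auto wrap = [m](int c) {
    if (c < 0) return c + m;
    if (c >= m) return c - m;
    return c;
  };
  for (int cx = 0; cx < m; ++cx)
    for (int cy = 0; cy < m; ++cy)
      for (int cz = 0; cz < m; ++cz) {
        int c = (cx * m + cy) * m + cz;
        if (cl.head[c] < 0) continue;
        for (int i = cl.head[c]; i >= 0; i = cl.next[i]) {
          for (int ox = -1; ox <= 1; ++ox)
            for (int oy = -1; oy <= 1; ++oy)
              for (int oz = -1; oz <= 1; ++oz) {
                int c2 = (wrap(cx + ox) * m + wrap(cy + oy)) * m +
                         wrap(cz + oz);
                for (int j = cl.head[c2]; j >= 0; j = cl.next[j]) {
                  if (j <= i) continue;
                  double dx = min_image(x[j] - x[i], box);
                  double dy = min_image(y[j] - y[i], box);
                  double dz = min_image(z[j] - z[i], box);
                  double d2 = dx * dx + dy * dy + dz * dz;
                  if (d2 > r2) continue;
                  int type;
                  if (chain_id[i] != chain_id[j]) {
                    type = 1;
                  } else {
                    double ux = x[j] - x[i], uy = y[j] - y[i],
                           uz = z[j] - z[i];
                    double du2 = ux * ux + uy * uy + uz * uz;
                    type = (du2 <= r2) ? 0 : 2;
                  }
                  ci.push_back(i);
                  cj.push_back(j);
                  ty.push_back(type);
                }
              }
        }
      }
  return List::create(_["i"] = IntegerVector(ci.begin(), ci.end()),
                      _["j"] = IntegerVector(cj.begin(), cj.end()),
                      _["type"] = IntegerVector(ty.begin(), ty.end()));
}

// Surface area and volume of a union of equal spheres centred on the
// monomers (the concave hull of the chromatin fiber at the capture radius).
// Area: Shrake-Rupley point counting on a deterministic Fibonacci lattice of
// directions. Volume: per-sphere Monte Carlo with inverse-multiplicity
// weights (an unbiased estimator of the union volume). Uses R's RNG.
// [[Rcpp::export]]
List cpp_hull_metrics(NumericMatrix coords,
                      double radius,
                      int n_dirs,
                      int n_vol_samples) {
  const int n = coords.nrow();
  if (n < 1) stop("need at least one monomer");
  std::vector<double> x(n), y(n), z(n);
  double xmin = R_PosInf, ymin = R_PosInf, zmin = R_PosInf;
  for (int i = 0; i < n; ++i) {
    x[i] = coords(i, 0); y[i] = coords(i, 1); z[i] = coords(i, 2);
    xmin = std::min(xmin, x[i]);
    ymin = std::min(ymin, y[i]);
    zmin = std::min(zmin, z[i]);
  }
  // shift well into positive territory (sample points extend a radius past
  // the monomers) and use a huge "box" so that the periodic cell list acts
  // like a plain spatial grid
  double cutoff = 2.0 * radius;
  double span = 0;
  for (int i = 0; i < n; ++i) {
    x[i] += cutoff - xmin; y[i] += cutoff - ymin; z[i] += cutoff - zmin;
    span = std::max(span, std::max(x[i], std::max(y[i], z[i])));
  }
  double box = span + 3.0 * cutoff + 1.0;
  CellList cl;
  cl.build(x, y, z, box, cutoff);

  // neighbour lookup
  auto neighbours = [&](double px, double py, double pz, std::vector<int>& out) {
    out.clear();
    int cx = cl.wrap_cell(px), cy = cl.wrap_cell(py), cz = cl.wrap_cell(pz);
    int m = cl.m;
    for (int ox = -1; ox <= 1; ++ox)
      for (int oy = -1; oy <= 1; ++oy)
        for (int oz = -1; oz <= 1; ++oz) {
          int nx = cx + ox, ny = cy + oy, nz = cz + oz;
          if (nx < 0 || ny < 0 || nz < 0 || nx >= m || ny >= m || nz >= m)
            continue;
          int c = (nx * m + ny) * m + nz;
          for (int j = cl.head[c]; j >= 0; j = cl.next[j]) out.push_back(j);
        }
  };

  // Fibonacci sphere directions
  std::vector<double> dx(n_dirs), dy(n_dirs), dz(n_dirs);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_dirs; ++k) {
    double zz = 1.0 - 2.0 * (k + 0.5) / n_dirs;
    double rr = std::sqrt(std::max(0.0, 1.0 - zz * zz));
    double th = ga * k;
    dx[k] = rr * std::cos(th);
    dy[k] = rr * std::sin(th);
    dz[k] = zz;
  }

  const double r2 = radius * radius;
  std::vector<int> nb;
  double area = 0.0;
  for (int i = 0; i < n; ++i) {
    neighbours(x[i], y[i], z[i], nb);
    int exposed = 0;
    for (int k = 0; k < n_dirs; ++k) {
      double px = x[i] + radius * dx[k];
      double py = y[i] + radius * dy[k];
      double pz = z[i] + radius * dz[k];
      bool inside = false;
      for (int jj : nb) {
        if (jj == i) continue;
        double ddx = px - x[jj], ddy = py - y[jj], ddz = pz - z[jj];
        if (ddx * ddx + ddy * ddy + ddz * ddz < r2) {
          inside = true;
          break;
        }
      }
      if (!inside) ++exposed;
    }
    area += 4.0 * M_PI * r2 * exposed / n_dirs;
  }

  double vol_weight = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int s = 0; s < n_vol_samples; ++s) {
      // uniform point in the sphere of monomer i
      double u = std::cbrt(unif_rand()) * radius;
      double ct = 2.0 * unif_rand() - 1.0;
      double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      double ph = 2.0 * M_PI * unif_rand();
      double px = x[i] + u * st * std::cos(ph);
      double py = y[i] + u * st * std::sin(ph);
      double pz = z[i] + u * ct;
      neighbours(px, py, pz, nb);
      int mult = 0;
      for (int jj : nb) {
        double ddx = px - x[jj], ddy = py - y[jj], ddz = pz - z[jj];
        if (ddx * ddx + ddy * ddy + ddz * ddz < r2) ++mult;
      }
      if (mult < 1) mult = 1;   // numeric edge: the sample lies in sphere i
      vol_weight += 1.0 / mult;
    }
  }
  double volume =
      (4.0 / 3.0) * M_PI * radius * radius * radius * vol_weight /
      std::max(1, n_vol_samples);
  return List::create(_["area"] = area, _["volume"] = volume);
}
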