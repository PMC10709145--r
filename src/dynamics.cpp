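// Core Brownian-dynamics integrator and force field for 2D chiral
// self-propelled worm-like chains in a periodic square box.
//
// Beads are stored filament-contiguously: bead index i belongs to filament
// i / M with rank i % M, rank 0 being the head (leading end).  All lengths
// are in units of the effective bead diameter d = 2*sqrt(2)*r0, energies in
// kBT, times in the single-filament rotation period tau.
//
// Determinism contract: given (positions, parameters, seed) the trajectory
// is bit-reproducible, and the cell-list and brute-force pair paths
// accumulate per-bead forces in the same (ascending-partner) order so they
// agree to the last bit.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <random>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

// Standard-normal sampler: mt19937_64 (bit-stable across platforms) feeding
// a 128-layer ziggurat (Doornik's ZIGNOR layout).  The ziggurat avoids the
// log/sin/cos calls of Box-Muller in the per-step noise loop; the rare
// wedge/tail branches fall back to exact exp/log evaluations, so the
// distribution is exact.
struct Rng {
  std::mt19937_64 eng;
  double zigX[129];   // layer x-coordinates, zigX[0] = V/f(R), zigX[128] = 0
  double zigR[128];   // acceptance ratios X[i+1]/X[i]

  explicit Rng(uint64_t seed) : eng(seed) {
    const double R = 3.442619855899;        // rightmost layer edge
    const double V = 9.91256303526217e-3;   // common layer area
    double f = std::exp(-0.5 * R * R);
    zigX[0] = V / f;
    zigX[1] = R;
    zigX[128] = 0.0;
    for (int i = 2; i < 128; ++i) {
      zigX[i] = std::sqrt(-2.0 * std::log(V / zigX[i - 1] +
                                          std::exp(-0.5 * zigX[i - 1] * zigX[i - 1])));
    }
    for (int i = 0; i < 128; ++i) zigR[i] = zigX[i + 1] / zigX[i];
  }

  double runif01() {
    // in (0,1), never exactly 0 or 1
    return (static_cast<double>(eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  double tail(bool neg) {
    const double R = 3.442619855899;
    double x, y;
    do {
      x = -std::log(runif01()) / R;
      y = -std::log(runif01());
    } while (y + y < x * x);
    return neg ? -(R + x) : (R + x);
  }

  double rnorm() {
    for (;;) {
      uint64_t b = eng();
      int i = static_cast<int>(b & 0x7F);
      double u = (static_cast<double>(b >> 11) + 0.5) *
                 (2.0 / 9007199254740992.0) - 1.0;   // uniform in (-1, 1)
      if (std::fabs(u) < zigR[i]) return u * zigX[i];     // fast path
      if (i == 0) return tail(u < 0);
      double x = u * zigX[i];
      double f0 = std::exp(-0.5 * (zigX[i] * zigX[i] - x * x));
      double f1 = std::exp(-0.5 * (zigX[i + 1] * zigX[i + 1] - x * x));
      if (f1 + runif01() * (f0 - f1) < 1.0) return x;
    }
  }
};

struct Par {
  int M;           // beads per filament
  double boxL;
  double r0, dtheta;
  double k_bond, kb_d;     // kb_d = k_bend / d (d = 1 in reduced units)
  double eps, sigma, rcut;
  double gamma, v0, kBT, dt;
  double vshift, fshift;   // pair potential linear-shift constants
  bool finite_eps;
};

// Minimum-image fold for coordinates already wrapped into [0, L):
// |dx| < L always holds, so one conditional fold suffices (and avoids a
// libm rounding call in the innermost loop).
inline double min_img(double dx, double L) {
  if (dx > 0.5 * L) return dx - L;
  if (dx < -0.5 * L) return dx + L;
  return dx;
}

// general wrap for arbitrary input (used on entry only)
inline double wrap_any(double x, double L) {
  x -= L * std::floor(x / L);
  if (x >= L) x -= L;   // guard against rounding to exactly L
  return x;
}

// fast wrap for a post-step coordinate (displacement bounded well below L)
inline double wrap_step(double x, double L) {
  if (x >= L) return x - L;
  if (x < 0) return x + L;
  return x;
}

// soft (4,2) Lennard-Jones, unshifted
inline void pair_vf(double r, const Par& p, double& v, double& fmag) {
  double s2 = (p.sigma * p.sigma) / (r * r);
  double s4 = s2 * s2;
  v = 4.0 * p.eps * (s4 - s2);
  // fmag = -dv/dr
  fmag = 4.0 * p.eps * (4.0 * s4 - 2.0 * s2) / r;
}

Par unpack(const List& params, int M, double boxL) {
  Par p;
  p.M = M;
  p.boxL = boxL;
  p.r0 = as<double>(params["r0"]);
  p.dtheta = as<double>(params["dtheta"]);
  p.k_bond = as<double>(params["k_bond"]);
  p.kb_d = as<double>(params["k_bend"]);  // divided by d = 1
  p.eps = as<double>(params["epsilon"]);
  p.sigma = as<double>(params["sigma"]);
  p.rcut = as<double>(params["r_cut"]);
  p.gamma = as<double>(params["gamma"]);
  p.v0 = as<double>(params["v0"]);
  p.kBT = as<double>(params["kBT"]);
  p.dt = as<double>(params["dt"]);
  p.finite_eps = p.eps > 0.0;
  if (p.finite_eps) {
    double vc, fc;
    pair_vf(p.rcut, p, vc, fc);
    p.vshift = vc;
    p.fshift = fc;   // subtracting fshift makes force vanish at rcut
  } else {
    p.vshift = 0.0; p.fshift = 0.0;
  }
  return p;
}

struct CellList {
  int nc;            // cells per side (0 => brute force)
  double cs;
  std::vector<int> head, nxt;
  void build(const std::vector<double>& x, const std::vector<double>& y,
             int n, double L, double rcut) {
    nc = (rcut > 0) ? static_cast<int>(std::floor(L / rcut)) : 0;
    if (nc < 4) { nc = 0; return; }   // too small: brute force
    cs = L / nc;
    head.assign(nc * nc, -1);
    nxt.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      int cx = static_cast<int>(x[i] / cs); if (cx >= nc) cx = nc - 1;
      int cy = static_cast<int>(y[i] / cs); if (cy >= nc) cy = nc - 1;
      int c = cy * nc + cx;
      nxt[i] = head[c];
      head[c] = i;
    }
  }
};

class Forces {
public:
  int n, nf;
  Par p;
  std::vector<double> x, y;
  std::vector<int> fil, rnk;
  std::vector<double> fx, fy;
  double e_bond, e_bend, e_pair;
  bool use_cells;
  CellList cl;
  std::vector<int> cand;
  // Verlet neighbour list (cell-list path only): half lists (j > i) in
  // ascending order, built with cutoff rcut + skin and rebuilt whenever the
  // accumulated maximum single-bead displacement exceeds skin/2, which
  // guarantees no interacting pair is ever missed.
  double skin = 0.4;
  std::vector<int> nbr, nbr_start;
  bool have_list = false;
  double acc_disp = 0.0;
  int bad_bead = -1;          // diagnostic on failure
  std::string bad_what;

  Forces(const NumericMatrix& pos, const Par& par, bool cells)
      : p(par), use_cells(cells) {
    n = pos.nrow();
    nf = n / p.M;
    x.resize(n); y.resize(n);
    for (int i = 0; i < n; ++i) {
      x[i] = wrap_any(pos(i, 0), p.boxL);
      y[i] = wrap_any(pos(i, 1), p.boxL);
    }
    fx.resize(n); fy.resize(n);
    fil.resize(n); rnk.resize(n);
    for (int i = 0; i < n; ++i) { fil[i] = i / p.M; rnk[i] = i % p.M; }
    cand.reserve(128);
  }

  bool bond_ok(double len, int i) {
    if (len < 1e-12) { bad_bead = i; bad_what = "zero-length bond"; return false; }
    return true;
  }

  // Harmonic stretching along each bond.
  bool add_bond() {
    e_bond = 0.0;
    for (int f = 0; f < nf; ++f) {
      int o = f * p.M;
      for (int j = 0; j < p.M - 1; ++j) {
        int a = o + j, b = o + j + 1;
        double dx = min_img(x[b] - x[a], p.boxL);
        double dy = min_img(y[b] - y[a], p.boxL);
        double len = std::sqrt(dx * dx + dy * dy);
        if (!bond_ok(len, a)) return false;
        double dl = len - p.r0;
        e_bond += 0.5 * p.k_bond * dl * dl;
        double fm = -p.k_bond * dl / len;   // along (dx,dy) on bead b
        fx[b] += fm * dx; fy[b] += fm * dy;
        fx[a] -= fm * dx; fy[a] -= fm * dy;
      }
    }
    return true;
  }

  // Chiral harmonic bending on the signed turn angle phi (head-to-tail);
  // rest turn is -dtheta so that a positive dtheta yields anticlockwise
  // rotation of the propelled filament.
  bool add_bend() {
    e_bend = 0.0;
    for (int f = 0; f < nf; ++f) {
      int o = f * p.M;
      for (int j = 1; j < p.M - 1; ++j) {
        int ia = o + j - 1, ib = o + j, ic = o + j + 1;
        double b1x = min_img(x[ib] - x[ia], p.boxL);
        double b1y = min_img(y[ib] - y[ia], p.boxL);
        double b2x = min_img(x[ic] - x[ib], p.boxL);
        double b2y = min_img(y[ic] - y[ib], p.boxL);
        double l1s = b1x * b1x + b1y * b1y;
        double l2s = b2x * b2x + b2y * b2y;
        if (l1s < 1e-24 || l2s < 1e-24) {
          bad_bead = ib; bad_what = "zero-length bond at joint"; return false;
        }
        double cr = b1x * b2y - b1y * b2x;
        double dt_ = b1x * b2x + b1y * b2y;
        double phi = std::atan2(cr, dt_);
        double dev = phi + p.dtheta;
        e_bend += 0.5 * p.kb_d * dev * dev;
        double g = -p.kb_d * dev;   // force prefactor on grad(phi)
        // grad_A phi = (-b1y, b1x)/|b1|^2 ; grad_C phi = (-b2y, b2x)/|b2|^2
        double gax = -b1y / l1s, gay = b1x / l1s;
        double gcx = -b2y / l2s, gcy = b2x / l2s;
        fx[ia] += g * gax;           fy[ia] += g * gay;
        fx[ic] += g * gcx;           fy[ic] += g * gcy;
        fx[ib] -= g * (gax + gcx);   fy[ib] -= g * (gay + gcy);
      }
    }
    return true;
  }

  // Tangential propulsion toward the head; head bead carries the chiral
  // steering term (bond vector plus a unit vector rotated by dtheta).
  bool add_prop() {
    if (p.v0 == 0.0) return true;
    double gv = p.gamma * p.v0;
    double cd = std::cos(p.dtheta), sd = std::sin(p.dtheta);
    for (int f = 0; f < nf; ++f) {
      int o = f * p.M;
      // interior beads 1..M-2 pushed toward their predecessor
      for (int j = 1; j < p.M - 1; ++j) {
        int i = o + j;
        double ux = min_img(x[i - 1] - x[i], p.boxL);
        double uy = min_img(y[i - 1] - y[i], p.boxL);
        double len = std::sqrt(ux * ux + uy * uy);
        if (!bond_ok(len, i)) return false;
        fx[i] += gv * ux / len;
        fy[i] += gv * uy / len;
      }
      // head bead: first-bond vector plus rotated unit vector
      double ux = min_img(x[o] - x[o + 1], p.boxL);
      double uy = min_img(y[o] - y[o + 1], p.boxL);
      double len = std::sqrt(ux * ux + uy * uy);
      if (!bond_ok(len, o)) return false;
      double hx = ux / len, hy = uy / len;
      double cx = cd * hx - sd * hy, cy = sd * hx + cd * hy;
      double wx = ux + cx, wy = uy + cy;
      double wl = std::sqrt(wx * wx + wy * wy);
      fx[o] += gv * wx / wl;
      fy[o] += gv * wy / wl;
    }
    return true;
  }

  inline bool excluded(int i, int j) const {
    if (fil[i] != fil[j]) return false;
    int dr = rnk[i] - rnk[j];
    return dr >= -2 && dr <= 2;      // nearest and next-nearest on chain
  }

  inline bool pair_kernel(int i, int j, double dx, double dy, double r2,
                          double overlap2) {
    if (r2 < overlap2) { bad_bead = i; bad_what = "bead overlap"; return false; }
    double r = std::sqrt(r2);
    double v, fm;
    pair_vf(r, p, v, fm);
    // linear shift: v -> v - v(rc) - v'(rc)*(r - rc), so both the potential
    // and the radial force vanish at the cutoff
    double vs = v - p.vshift + p.fshift * (r - p.rcut);
    double fs = fm - p.fshift;
    e_pair += vs;
    double frx = fs / r * dx;
    double fry = fs / r * dy;
    fx[i] += frx;  fy[i] += fry;
    fx[j] -= frx;  fy[j] -= fry;
    return true;
  }

  void note_max_displacement(double d) {
    acc_disp += d;
  }

  void build_nlist() {
    double rlist = p.rcut + skin;
    cl.build(x, y, n, p.boxL, rlist);
    double rl2 = rlist * rlist;
    nbr.clear();
    nbr_start.assign(n + 1, 0);
    if (cl.nc == 0) {
      // box too small for cells even with skin: list everything (j > i)
      for (int i = 0; i < n; ++i) {
        nbr_start[i] = static_cast<int>(nbr.size());
        for (int j = i + 1; j < n; ++j) {
          if (excluded(i, j)) continue;
          double dx = min_img(x[i] - x[j], p.boxL);
          double dy = min_img(y[i] - y[j], p.boxL);
          if (dx * dx + dy * dy < rl2) nbr.push_back(j);
        }
      }
    } else {
      double inv_cs = 1.0 / cl.cs;
      for (int i = 0; i < n; ++i) {
        nbr_start[i] = static_cast<int>(nbr.size());
        double xi = x[i], yi = y[i];
        int cx = static_cast<int>(xi * inv_cs); if (cx >= cl.nc) cx = cl.nc - 1;
        int cy = static_cast<int>(yi * inv_cs); if (cy >= cl.nc) cy = cl.nc - 1;
        size_t first = nbr.size();
        for (int dy_ = -1; dy_ <= 1; ++dy_) {
          int wy_ = cy + dy_;
          if (wy_ < 0) wy_ += cl.nc; else if (wy_ >= cl.nc) wy_ -= cl.nc;
          int rowoff = wy_ * cl.nc;
          for (int dx_ = -1; dx_ <= 1; ++dx_) {
            int wx_ = cx + dx_;
            if (wx_ < 0) wx_ += cl.nc; else if (wx_ >= cl.nc) wx_ -= cl.nc;
            for (int j = cl.head[rowoff + wx_]; j >= 0; j = cl.nxt[j]) {
              if (j <= i) continue;
              double dx = min_img(xi - x[j], p.boxL);
              double dy = min_img(yi - y[j], p.boxL);
              if (dx * dx + dy * dy >= rl2 || excluded(i, j)) continue;
              nbr.push_back(j);
            }
          }
        }
        // insertion sort of this bead's slice (short)
        for (size_t a = first + 1; a < nbr.size(); ++a) {
          int v_ = nbr[a];
          size_t b_ = a;
          while (b_ > first && nbr[b_ - 1] > v_) { nbr[b_] = nbr[b_ - 1]; --b_; }
          nbr[b_] = v_;
        }
      }
    }
    nbr_start[n] = static_cast<int>(nbr.size());
    have_list = true;
    acc_disp = 0.0;
  }

  // Shifted soft LJ between non-excluded beads; per-bead accumulation in
  // ascending partner order (identical for neighbour-list and brute paths).
  bool add_pair() {
    e_pair = 0.0;
    if (!p.finite_eps || p.rcut <= 0.0) return true;
    double rc2 = p.rcut * p.rcut;
    double overlap2 = 1e-6 * p.sigma * p.sigma;   // (1e-3 sigma)^2
    // Half-neighbour iteration: bead i interacts with partners j > i in
    // ascending order and forces are applied to both members of the pair.
    // The floating-point accumulation order is therefore identical for the
    // neighbour-list and brute-force paths, so trajectories agree bit for
    // bit.
    if (use_cells) {
      if (!have_list || acc_disp > 0.5 * skin) build_nlist();
      for (int i = 0; i < n; ++i) {
        double xi = x[i], yi = y[i];
        for (int k = nbr_start[i]; k < nbr_start[i + 1]; ++k) {
          int j = nbr[k];
          double dx = min_img(xi - x[j], p.boxL);
          double dy = min_img(yi - y[j], p.boxL);
          double r2 = dx * dx + dy * dy;
          if (r2 >= rc2) continue;
          if (!pair_kernel(i, j, dx, dy, r2, overlap2)) return false;
        }
      }
    } else {
      for (int i = 0; i < n; ++i) {
        double xi = x[i], yi = y[i];
        for (int j = i + 1; j < n; ++j) {
          if (excluded(i, j)) continue;
          double dx = min_img(xi - x[j], p.boxL);
          double dy = min_img(yi - y[j], p.boxL);
          double r2 = dx * dx + dy * dy;
          if (r2 >= rc2) continue;
          if (!pair_kernel(i, j, dx, dy, r2, overlap2)) return false;
        }
      }
    }
    return true;
  }

  bool compute(bool with_prop = true) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    if (!add_bond()) return false;
    if (!add_bend()) return false;
    if (!add_pair()) return false;
    if (with_prop && !add_prop()) return false;
    return true;
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_force_components(NumericMatrix pos, int M, double boxL, List params,
                          bool use_cells = true) {
  Par p = unpack(params, M, boxL);
  Forces F(pos, p, use_cells);
  int n = F.n;
  NumericMatrix bond(n, 2), bend(n, 2), pair(n, 2), prop(n, 2);
  double eb = 0, ek = 0, ep = 0;

  std::fill(F.fx.begin(), F.fx.end(), 0.0);
  std::fill(F.fy.begin(), F.fy.end(), 0.0);
  if (!F.add_bond()) stop("bond forces: %s (bead %d)", F.bad_what, F.bad_bead + 1);
  for (int i = 0; i < n; ++i) { bond(i, 0) = F.fx[i]; bond(i, 1) = F.fy[i]; }
  eb = F.e_bond;

  std::fill(F.fx.begin(), F.fx.end(), 0.0);
  std::fill(F.fy.begin(), F.fy.end(), 0.0);
  if (!F.add_bend()) stop("bend forces: %s (bead %d)", F.bad_what, F.bad_bead + 1);
  for (int i = 0; i < n; ++i) { bend(i, 0) = F.fx[i]; bend(i, 1) = F.fy[i]; }
  ek = F.e_bend;

  std::fill(F.fx.begin(), F.fx.end(), 0.0);
  std::fill(F.fy.begin(), F.fy.end(), 0.0);
  if (!F.add_pair()) stop("pair forces: %s (bead %d)", F.bad_what, F.bad_bead + 1);
  for (int i = 0; i < n; ++i) { pair(i, 0) = F.fx[i]; pair(i, 1) = F.fy[i]; }
  ep = F.e_pair;

  std::fill(F.fx.begin(), F.fx.end(), 0.0);
  std::fill(F.fy.begin(), F.fy.end(), 0.0);
  if (!F.add_prop()) stop("propulsion forces: %s (bead %d)", F.bad_what, F.bad_bead + 1);
  for (int i = 0; i < n; ++i) { prop(i, 0) = F.fx[i]; prop(i, 1) = F.fy[i]; }

  return List::create(_["bond"] = bond, _["bend"] = bend, _["pair"] = pair,
                      _["propulsion"] = prop,
                      _["e_bond"] = eb, _["e_bend"] = ek, _["e_pair"] = ep);
}

// [[Rcpp::export]]
double cpp_potential_energy(NumericMatrix pos, int M, double boxL, List params,
                            bool use_cells = true) {
  Par p = unpack(params, M, boxL);
  Forces F(pos, p, use_cells);
  if (!F.compute(false))
    stop("energy: %s (bead %d)", F.bad_what, F.bad_bead + 1);
  return F.e_bond + F.e_bend + F.e_pair;
}

// [[Rcpp::export]]
NumericMatrix cpp_noise_forces(int n, double kBT, double gamma, double dt,
                               double seed) {
  NumericMatrix out(n, 2);
  if (kBT <= 0.0) return out;
  Rng rng(static_cast<uint64_t>(seed));
  double amp = std::sqrt(2.0 * kBT * gamma / dt);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = amp * rng.rnorm();
    out(i, 1) = amp * rng.rnorm();
  }
  return out;
}

// [[Rcpp::export]]
List cpp_simulate(NumericMatrix pos, int M, double boxL, List params,
                  int n_steps, int save_every, double seed, double t0 = 0.0,
                  bool use_cells = true) {
  Par p = unpack(params, M, boxL);
  Forces F(pos, p, use_cells);
  int n = F.n;
  if (n % M != 0) stop("bead count %d is not a multiple of beads-per-filament %d", n, M);
  if (save_every < 1) save_every = 1;
  Rng rng(static_cast<uint64_t>(seed));
  double amp = (p.kBT > 0.0) ? std::sqrt(2.0 * p.kBT * p.gamma / p.dt) : 0.0;
  double mob = p.dt / p.gamma;
  double max_disp = 0.45 * boxL;

  int n_saved_max = 2 + n_steps / save_every;
  std::vector<double> frames;
  frames.reserve(static_cast<size_t>(n_saved_max) * n * 2);
  std::vector<double> times;
  times.reserve(n_saved_max);

  auto save = [&](int step) {
    for (int i = 0; i < n; ++i) frames.push_back(F.x[i]);
    for (int i = 0; i < n; ++i) frames.push_back(F.y[i]);
    times.push_back(t0 + static_cast<double>(step) * p.dt);
  };
  save(0);

  for (int s = 1; s <= n_steps; ++s) {
    if (!F.compute(true))
      stop("step %d: %s (bead %d)", s, F.bad_what, F.bad_bead + 1);
    if (amp > 0.0) {
      for (int i = 0; i < n; ++i) {
        F.fx[i] += amp * rng.rnorm();
        F.fy[i] += amp * rng.rnorm();
      }
    }
    double step_max2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double ddx = mob * F.fx[i];
      double ddy = mob * F.fy[i];
      if (!std::isfinite(ddx) || !std::isfinite(ddy) ||
          std::fabs(ddx) > max_disp || std::fabs(ddy) > max_disp)
        stop("step %d: non-finite or runaway displacement at bead %d "
             "(dx = %g, dy = %g); reduce dt or check parameters",
             s, i + 1, ddx, ddy);
      double d2 = ddx * ddx + ddy * ddy;
      if (d2 > step_max2) step_max2 = d2;
      F.x[i] = wrap_step(F.x[i] + ddx, boxL);
      F.y[i] = wrap_step(F.y[i] + ddy, boxL);
    }
    F.note_max_displacement(std::sqrt(step_max2));
    if (s % save_every == 0) save(s);
    if (s % 20000 == 0) Rcpp::checkUserInterrupt();
  }
  if (n_steps % save_every != 0) save(n_steps);

  int nf_frames = static_cast<int>(times.size());
  NumericVector arr(frames.begin(), frames.end());
  arr.attr("dim") = IntegerVector::create(n, 2, nf_frames);
  return List::create(_["frames"] = arr,
                      _["times"] = NumericVector(times.begin(), times.end()));
}
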