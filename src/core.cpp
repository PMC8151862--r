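// Core numerics for the 2D ring-polymer RBC model: energies, forces,
// overdamped Langevin integration (deformable and rigid cells), occupancy
// rasterization and periodic connected-component labeling of free space.
//
// Units: lengths in micrometres, energies in k_BT, friction gamma per vertex,
// time in gamma * um^2 / k_BT.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
#include <cstdint>
#include <set>
#include <map>
#include <functional>

using namespace Rcpp;

namespace {

struct PairParams {
  double sigma;      // LJ length scale of the adhesive potential
  double rcut;       // cutoff of the adhesive tail
  double eps_attr;   // depth of the adhesive minimum (k_BT)
  double eps_rep;    // strength of the WCA excluded-volume core (k_BT)
  double sigma_rep;  // length scale of the WCA core (== sigma in production)
  // derived
  double rc_att_min; // 2^(1/6) sigma : location/plateau edge of adhesive min
  double rc_rep;     // 2^(1/6) sigma_rep : WCA cutoff
  double shift;      // plain LJ (eps=1) value at rcut, used to shift tail to 0
  double rmax;       // max interaction range
  void init() {
    rc_att_min = std::pow(2.0, 1.0 / 6.0) * sigma;
    rc_rep = std::pow(2.0, 1.0 / 6.0) * sigma_rep;
    double s6 = std::pow(sigma / rcut, 6.0);
    shift = 4.0 * (s6 * s6 - s6); // lj1(rcut), negative for rcut > sigma
    rmax = std::max(rcut, rc_rep);
  }
};

inline double lj1(double r, double sigma) {
  double s2 = (sigma * sigma) / (r * r);
  double s6 = s2 * s2 * s2;
  return 4.0 * (s6 * s6 - s6);
}
inline double lj1_du(double r, double sigma) { // d/dr of lj1
  double s2 = (sigma * sigma) / (r * r);
  double s6 = s2 * s2 * s2;
  return 4.0 * (-12.0 * s6 * s6 + 6.0 * s6) / r;
}

// Pair potential: WCA excluded-volume core plus an adhesive tail.  The tail
// is the attractive remainder of the plain truncated LJ, shifted to zero at
// rcut and normalized so its minimum is exactly -eps_attr at 2^(1/6) sigma.
inline double pair_energy(double r, const PairParams& pp) {
  double u = 0.0;
  if (r < pp.rc_rep)
    u += lj1(r, pp.sigma_rep) * pp.eps_rep + pp.eps_rep;
  if (pp.eps_attr > 0.0 && r < pp.rcut) {
    double a = (r <= pp.rc_att_min) ? -1.0 : lj1(r, pp.sigma);
    u += pp.eps_attr * (a - pp.shift) / (1.0 + pp.shift);
  }
  return u;
}
// returns dU/dr
inline double pair_dudr(double r, const PairParams& pp) {
  double du = 0.0;
  if (r < pp.rc_rep)
    du += lj1_du(r, pp.sigma_rep) * pp.eps_rep;
  if (pp.eps_attr > 0.0 && r > pp.rc_att_min && r < pp.rcut)
    du += pp.eps_attr * lj1_du(r, pp.sigma) / (1.0 + pp.shift);
  return du;
}

// dU/dr * (1/r) as a function of r^2 (saves a sqrt in the hot loop)
inline double pair_fcoef(double r2, const PairParams& pp) {
  double coef = 0.0;
  if (r2 < pp.rc_rep * pp.rc_rep) {
    double s2 = (pp.sigma_rep * pp.sigma_rep) / r2;
    double s6 = s2 * s2 * s2;
    coef += pp.eps_rep * 4.0 * (-12.0 * s6 * s6 + 6.0 * s6) / r2;
  }
  if (pp.eps_attr > 0.0 && r2 > pp.rc_att_min * pp.rc_att_min &&
      r2 < pp.rcut * pp.rcut) {
    double s2 = (pp.sigma * pp.sigma) / r2;
    double s6 = s2 * s2 * s2;
    coef += pp.eps_attr * 4.0 * (-12.0 * s6 * s6 + 6.0 * s6) / r2 /
            (1.0 + pp.shift);
  }
  return coef;
}

// ---------------------------------------------------------------------------
// Fast deterministic RNG (xoshiro256++) with a ziggurat normal sampler
// ---------------------------------------------------------------------------

struct FastRng {
  std::uint64_t s[4];
  static std::uint64_t splitmix(std::uint64_t& x) {
    x += 0x9e3779b97f4a7c15ULL;
    std::uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  explicit FastRng(std::uint64_t seed) {
    std::uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }
  static std::uint64_t rotl(std::uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  std::uint64_t next() {
    std::uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    std::uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }        // [0, 1)
  double unif_open() { return ((next() >> 11) + 1) * 0x1.0p-53; } // (0, 1]
};

// Marsaglia-Tsang ziggurat for the standard normal
struct Ziggurat {
  std::uint32_t kn[128];
  double wn[128], fn[128];
  Ziggurat() {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (std::uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1; wn[127] = dn / m1;
    fn[0] = 1.0; fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; i--) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (std::uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
  double draw(FastRng& rng) const {
    for (;;) {
      std::int32_t hz = (std::int32_t)(std::uint32_t)rng.next();
      std::uint32_t iz = hz & 127;
      if ((std::uint32_t)std::abs((long long)hz) < kn[iz])
        return hz * wn[iz];
      const double r = 3.442619855899;
      double x, y;
      if (iz == 0) {
        do {
          x = -std::log(rng.unif_open()) / r;
          y = -std::log(rng.unif_open());
        } while (y + y < x * x);
        return (hz > 0) ? r + x : -(r + x);
      }
      x = hz * wn[iz];
      if (fn[iz] + rng.unif() * (fn[iz - 1] - fn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
    }
  }
};

inline double wrap(double x, double L) {
  x -= L * std::floor(x / L);
  if (x >= L) x -= L; // guard against floor rounding
  return x;
}
inline double min_image(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

// ---------------------------------------------------------------------------
// Single-cell bonded energies and gradients
// ---------------------------------------------------------------------------

double cell_energy_impl(const double* x, const double* y, int nv,
                        double ks, double l0, double kb, double ka, double A0,
                        double* e_spring, double* e_bend, double* e_area) {
  double es = 0.0, eb = 0.0;
  for (int i = 0; i < nv; ++i) {
    int j = (i + 1) % nv;
    double dx = x[j] - x[i], dy = y[j] - y[i];
    double l = std::sqrt(dx * dx + dy * dy);
    double dl = l - l0;
    es += 0.5 * ks * dl * dl / (l0 * l0);
  }
  for (int i = 0; i < nv; ++i) {
    int im = (i - 1 + nv) % nv, ip = (i + 1) % nv;
    double ux = x[i] - x[im], uy = y[i] - y[im];
    double vx = x[ip] - x[i], vy = y[ip] - y[i];
    double lu = std::sqrt(ux * ux + uy * uy);
    double lv = std::sqrt(vx * vx + vy * vy);
    double c = (ux * vx + uy * vy) / (lu * lv);
    if (c > 1.0) c = 1.0;
    if (c < -1.0) c = -1.0;
    eb += kb * (1.0 - c);
  }
  double A = 0.0;
  for (int i = 0; i < nv; ++i) {
    int j = (i + 1) % nv;
    A += x[i] * y[j] - x[j] * y[i];
  }
  A *= 0.5;
  double dA = A - A0;
  double ea = 0.5 * ka * dA * dA / (A0 * A0);
  if (e_spring) *e_spring = es;
  if (e_bend) *e_bend = eb;
  if (e_area) *e_area = ea;
  return es + eb + ea;
}

void cell_grad_impl(const double* x, const double* y, int nv,
                    double ks, double l0, double kb, double ka, double A0,
                    double* gx, double* gy) {
  for (int i = 0; i < nv; ++i) { gx[i] = 0.0; gy[i] = 0.0; }
  // springs
  for (int i = 0; i < nv; ++i) {
    int j = (i + 1) % nv;
    double dx = x[j] - x[i], dy = y[j] - y[i];
    double l = std::sqrt(dx * dx + dy * dy);
    double coef = ks * (l - l0) / (l0 * l0) / l; // dE/dl * (1/l)
    gx[j] += coef * dx; gy[j] += coef * dy;
    gx[i] -= coef * dx; gy[i] -= coef * dy;
  }
  // bending: joint at vertex i between u = x_i - x_{i-1}, v = x_{i+1} - x_i
  for (int i = 0; i < nv; ++i) {
    int im = (i - 1 + nv) % nv, ip = (i + 1) % nv;
    double ux = x[i] - x[im], uy = y[i] - y[im];
    double vx = x[ip] - x[i], vy = y[ip] - y[i];
    double lu = std::sqrt(ux * ux + uy * uy);
    double lv = std::sqrt(vx * vx + vy * vy);
    double inv = 1.0 / (lu * lv);
    double c = (ux * vx + uy * vy) * inv;
    // dc/du and dc/dv
    double dcux = vx * inv - c * ux / (lu * lu);
    double dcuy = vy * inv - c * uy / (lu * lu);
    double dcvx = ux * inv - c * vx / (lv * lv);
    double dcvy = uy * inv - c * vy / (lv * lv);
    // E_i = kb (1 - c)  =>  dE/d(...) = -kb * dc/d(...)
    gx[im] += kb * dcux;      gy[im] += kb * dcuy;
    gx[i]  -= kb * (dcux - dcvx); gy[i] -= kb * (dcuy - dcvy);
    gx[ip] -= kb * dcvx;      gy[ip] -= kb * dcvy;
  }
  // area
  double A = 0.0;
  for (int i = 0; i < nv; ++i) {
    int j = (i + 1) % nv;
    A += x[i] * y[j] - x[j] * y[i];
  }
  A *= 0.5;
  double coefA = ka * (A - A0) / (A0 * A0);
  for (int i = 0; i < nv; ++i) {
    int im = (i - 1 + nv) % nv, ip = (i + 1) % nv;
    gx[i] += coefA * 0.5 * (y[ip] - y[im]);
    gy[i] += coefA * 0.5 * (x[im] - x[ip]);
  }
}

// ---------------------------------------------------------------------------
// System-level pair interactions (binned, periodic)
// ---------------------------------------------------------------------------

struct System {
  int ncell, nv, ntot;
  std::vector<double> x, y;       // unwrapped coordinates (ring-contiguous)
  std::vector<double> kb, A0;     // per cell
  std::vector<char> rigid;        // per cell
  double l0, ks, ka, Lx, Ly;
  PairParams pp;
};

// Callback-style pair loop: calls f(i, j, dx, dy, r) for every interacting
// vertex pair (i < j globally unique), with dx = min-image x_j - x_i.
template <typename F>
void for_each_pair(const System& S, F f) {
  const double rmax = S.pp.rmax;
  int nbx = std::max(1, (int)std::floor(S.Lx / rmax));
  int nby = std::max(1, (int)std::floor(S.Ly / rmax));
  std::vector<double> wx(S.ntot), wy(S.ntot);
  for (int i = 0; i < S.ntot; ++i) {
    wx[i] = wrap(S.x[i], S.Lx);
    wy[i] = wrap(S.y[i], S.Ly);
  }
  auto consider = [&](int i, int j) {
    int ci = i / S.nv, cj = j / S.nv;
    if (ci == cj) {
      int di = std::abs((i % S.nv) - (j % S.nv));
      int sep = std::min(di, S.nv - di);
      if (sep <= 2) return;
    }
    double dx = min_image(wx[j] - wx[i], S.Lx);
    double dy = min_image(wy[j] - wy[i], S.Ly);
    double r2 = dx * dx + dy * dy;
    if (r2 >= rmax * rmax) return;
    f(i, j, dx, dy, std::sqrt(r2));
  };
  if (nbx < 4 || nby < 4) {
    for (int i = 0; i < S.ntot; ++i)
      for (int j = i + 1; j < S.ntot; ++j) consider(i, j);
    return;
  }
  double bwx = S.Lx / nbx, bwy = S.Ly / nby;
  std::vector<int> head(nbx * nby, -1), nxt(S.ntot, -1);
  std::vector<int> bix(S.ntot), biy(S.ntot);
  for (int i = 0; i < S.ntot; ++i) {
    int bx = std::min(nbx - 1, (int)(wx[i] / bwx));
    int by = std::min(nby - 1, (int)(wy[i] / bwy));
    bix[i] = bx; biy[i] = by;
    int b = by * nbx + bx;
    nxt[i] = head[b]; head[b] = i;
  }
  // half-stencil so each bin pair is visited once
  const int offs[5][2] = {{0, 0}, {1, 0}, {-1, 1}, {0, 1}, {1, 1}};
  for (int by = 0; by < nby; ++by) {
    for (int bx = 0; bx < nbx; ++bx) {
      int b = by * nbx + bx;
      for (int k = 0; k < 5; ++k) {
        int obx = (bx + offs[k][0] + nbx) % nbx;
        int oby = (by + offs[k][1] + nby) % nby;
        int ob = oby * nbx + obx;
        for (int i = head[b]; i >= 0; i = nxt[i]) {
          int jstart = (k == 0) ? nxt[i] : head[ob];
          for (int j = jstart; j >= 0; j = nxt[j]) consider(i, j);
        }
      }
    }
  }
}

System build_system(NumericMatrix coords, int nv, NumericVector kb,
                    NumericVector A0, LogicalVector rigid, List par) {
  System S;
  S.ntot = coords.nrow();
  S.nv = nv;
  S.ncell = S.ntot / nv;
  if (S.ncell * nv != S.ntot) stop("coords rows not a multiple of n_vertices");
  S.x.resize(S.ntot); S.y.resize(S.ntot);
  for (int i = 0; i < S.ntot; ++i) { S.x[i] = coords(i, 0); S.y[i] = coords(i, 1); }
  S.kb = as<std::vector<double>>(kb);
  S.A0 = as<std::vector<double>>(A0);
  S.rigid.resize(S.ncell);
  for (int c = 0; c < S.ncell; ++c) S.rigid[c] = rigid[c] ? 1 : 0;
  S.l0 = as<double>(par["l0"]);
  S.ks = as<double>(par["k_spring"]);
  S.ka = as<double>(par["k_area"]);
  S.Lx = as<double>(par["Lx"]);
  S.Ly = as<double>(par["Ly"]);
  S.pp.sigma = as<double>(par["sigma"]);
  S.pp.rcut = as<double>(par["r_cut"]);
  S.pp.eps_attr = as<double>(par["eps_attr"]);
  S.pp.eps_rep = as<double>(par["eps_rep"]);
  S.pp.sigma_rep = par.containsElementNamed("sigma_rep") ?
      as<double>(par["sigma_rep"]) : S.pp.sigma;
  S.pp.init();
  return S;
}

// Total potential energy.  Internal elastic terms of rigid cells are
// constant under rigid-body motion and are defined as zero.
double system_energy_impl(const System& S) {
  double e = 0.0;
  for (int c = 0; c < S.ncell; ++c) {
    if (S.rigid[c]) continue;
    e += cell_energy_impl(&S.x[c * S.nv], &S.y[c * S.nv], S.nv,
                          S.ks, S.l0, S.kb[c], S.ka, S.A0[c],
                          nullptr, nullptr, nullptr);
  }
  double ep = 0.0;
  for_each_pair(S, [&](int i, int j, double, double, double r) {
    int ci = i / S.nv, cj = j / S.nv;
    PairParams pp = S.pp;
    if (ci == cj) pp.eps_attr = 0.0; // same-cell: excluded volume only
    ep += pair_energy(r, pp);
  });
  return e + ep;
}

// Verlet neighbor list: pair indices within rmax + skin, rebuilt when the
// accumulated per-vertex displacement could invalidate it.
struct NeighborList {
  std::vector<int> pi, pj;
  std::vector<char> same_cell;
  double skin = 0.35;
};

void build_nlist(const System& S, NeighborList& nl) {
  nl.pi.clear(); nl.pj.clear(); nl.same_cell.clear();
  const double rlist = S.pp.rmax + nl.skin;
  const double rlist2 = rlist * rlist;
  int nbx = std::max(1, (int)std::floor(S.Lx / rlist));
  int nby = std::max(1, (int)std::floor(S.Ly / rlist));
  std::vector<double> wx(S.ntot), wy(S.ntot);
  for (int i = 0; i < S.ntot; ++i) {
    wx[i] = wrap(S.x[i], S.Lx);
    wy[i] = wrap(S.y[i], S.Ly);
  }
  auto consider = [&](int i, int j) {
    int ci = i / S.nv, cj = j / S.nv;
    bool same = (ci == cj);
    if (same) {
      int di = std::abs((i % S.nv) - (j % S.nv));
      int sep = std::min(di, S.nv - di);
      if (sep <= 2) return;
    }
    double dx = min_image(wx[j] - wx[i], S.Lx);
    double dy = min_image(wy[j] - wy[i], S.Ly);
    if (dx * dx + dy * dy >= rlist2) return;
    nl.pi.push_back(i); nl.pj.push_back(j);
    nl.same_cell.push_back(same ? 1 : 0);
  };
  if (nbx < 4 || nby < 4) {
    for (int i = 0; i < S.ntot; ++i)
      for (int j = i + 1; j < S.ntot; ++j) consider(i, j);
    return;
  }
  // counting sort of vertices into bins for contiguous traversal
  double bwx = S.Lx / nbx, bwy = S.Ly / nby;
  int nb = nbx * nby;
  std::vector<int> binof(S.ntot), start(nb + 1, 0), order(S.ntot);
  for (int i = 0; i < S.ntot; ++i) {
    int bx = std::min(nbx - 1, (int)(wx[i] / bwx));
    int by = std::min(nby - 1, (int)(wy[i] / bwy));
    binof[i] = by * nbx + bx;
    ++start[binof[i] + 1];
  }
  for (int b = 0; b < nb; ++b) start[b + 1] += start[b];
  std::vector<int> fill = start;
  for (int i = 0; i < S.ntot; ++i) order[fill[binof[i]]++] = i;
  const int offs[5][2] = {{0, 0}, {1, 0}, {-1, 1}, {0, 1}, {1, 1}};
  for (int by = 0; by < nby; ++by) {
    for (int bx = 0; bx < nbx; ++bx) {
      int b = by * nbx + bx;
      for (int k = 0; k < 5; ++k) {
        int ob = ((by + offs[k][1] + nby) % nby) * nbx +
                 ((bx + offs[k][0] + nbx) % nbx);
        for (int ii = start[b]; ii < start[b + 1]; ++ii) {
          int i = order[ii];
          int jj0 = (k == 0) ? ii + 1 : start[ob];
          for (int jj = jj0; jj < start[ob + 1]; ++jj) consider(i, order[jj]);
        }
      }
    }
  }
}

// force accumulation from a neighbor list
void nlist_forces(const System& S, const NeighborList& nl,
                  std::vector<double>& fx, std::vector<double>& fy) {
  const double rmax2 = S.pp.rmax * S.pp.rmax;
  PairParams pp_same = S.pp;
  pp_same.eps_attr = 0.0;
  for (size_t k = 0; k < nl.pi.size(); ++k) {
    int i = nl.pi[k], j = nl.pj[k];
    double dx = min_image(S.x[j] - S.x[i], S.Lx);
    double dy = min_image(S.y[j] - S.y[i], S.Ly);
    double r2 = dx * dx + dy * dy;
    if (r2 >= rmax2) continue;
    double coef = pair_fcoef(r2, nl.same_cell[k] ? pp_same : S.pp);
    if (coef == 0.0) continue;
    fx[j] -= coef * dx; fy[j] -= coef * dy;
    fx[i] += coef * dx; fy[i] += coef * dy;
  }
}

void system_forces_impl(const System& S, std::vector<double>& fx,
                        std::vector<double>& fy) {
  fx.assign(S.ntot, 0.0);
  fy.assign(S.ntot, 0.0);
  std::vector<double> gx(S.nv), gy(S.nv);
  for (int c = 0; c < S.ncell; ++c) {
    if (S.rigid[c]) continue;
    cell_grad_impl(&S.x[c * S.nv], &S.y[c * S.nv], S.nv,
                   S.ks, S.l0, S.kb[c], S.ka, S.A0[c], gx.data(), gy.data());
    for (int i = 0; i < S.nv; ++i) {
      fx[c * S.nv + i] -= gx[i];
      fy[c * S.nv + i] -= gy[i];
    }
  }
  for_each_pair(S, [&](int i, int j, double dx, double dy, double r) {
    int ci = i / S.nv, cj = j / S.nv;
    PairParams pp = S.pp;
    if (ci == cj) pp.eps_attr = 0.0;
    double du = pair_dudr(r, pp);
    if (du == 0.0) return;
    double coef = du / r; // force on j is -dU/dr * rhat_ij
    fx[j] -= coef * dx; fy[j] -= coef * dy;
    fx[i] += coef * dx; fy[i] += coef * dy;
  });
}

} // namespace

// ---------------------------------------------------------------------------
// Exported: single-cell energies
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_cell_energy(NumericMatrix verts, double k_spring, double l0,
                     double k_bend, double k_area, double A0) {
  int nv = verts.nrow();
  std::vector<double> x(nv), y(nv);
  for (int i = 0; i < nv; ++i) { x[i] = verts(i, 0); y[i] = verts(i, 1); }
  double es, eb, ea;
  double tot = cell_energy_impl(x.data(), y.data(), nv, k_spring, l0,
                                k_bend, k_area, A0, &es, &eb, &ea);
  return List::create(_["spring"] = es, _["bending"] = eb,
                      _["area"] = ea, _["total"] = tot);
}

// [[Rcpp::export]]
NumericMatrix cpp_cell_grad(NumericMatrix verts, double k_spring, double l0,
                            double k_bend, double k_area, double A0) {
  int nv = verts.nrow();
  std::vector<double> x(nv), y(nv), gx(nv), gy(nv);
  for (int i = 0; i < nv; ++i) { x[i] = verts(i, 0); y[i] = verts(i, 1); }
  cell_grad_impl(x.data(), y.data(), nv, k_spring, l0, k_bend, k_area, A0,
                 gx.data(), gy.data());
  NumericMatrix g(nv, 2);
  for (int i = 0; i < nv; ++i) { g(i, 0) = gx[i]; g(i, 1) = gy[i]; }
  return g;
}

// [[Rcpp::export]]
double cpp_polygon_area(NumericMatrix verts) {
  int nv = verts.nrow();
  double A = 0.0;
  for (int i = 0; i < nv; ++i) {
    int j = (i + 1) % nv;
    A += verts(i, 0) * verts(j, 1) - verts(j, 0) * verts(i, 1);
  }
  return 0.5 * A;
}

// [[Rcpp::export]]
NumericVector cpp_pair_potential(NumericVector r, double sigma, double r_cut,
                                 double eps_attr, double eps_rep,
                                 double sigma_rep) {
  PairParams pp;
  pp.sigma = sigma; pp.rcut = r_cut; pp.eps_attr = eps_attr;
  pp.eps_rep = eps_rep; pp.sigma_rep = sigma_rep;
  pp.init();
  NumericVector out(r.size());
  for (R_xlen_t i = 0; i < r.size(); ++i) {
    if (r[i] <= 0) stop("pair potential singular at r <= 0");
    out[i] = pair_energy(r[i], pp);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Exported: system energy / forces
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_system_energy(NumericMatrix coords, int nv, NumericVector kb,
                         NumericVector A0, LogicalVector rigid, List par) {
  System S = build_system(coords, nv, kb, A0, rigid, par);
  return system_energy_impl(S);
}

// [[Rcpp::export]]
NumericMatrix cpp_system_forces(NumericMatrix coords, int nv, NumericVector kb,
                                NumericVector A0, LogicalVector rigid,
                                List par) {
  System S = build_system(coords, nv, kb, A0, rigid, par);
  std::vector<double> fx, fy;
  system_forces_impl(S, fx, fy);
  NumericMatrix f(S.ntot, 2);
  for (int i = 0; i < S.ntot; ++i) { f(i, 0) = fx[i]; f(i, 1) = fy[i]; }
  return f;
}

// ---------------------------------------------------------------------------
// Exported: overdamped Langevin integrator
// ---------------------------------------------------------------------------

// Deformable cells: per-vertex Euler-Maruyama with mobility 1/gamma.
// Rigid cells: net force and torque about the centroid drive rigid-body
// translation (mobility 1/(nv*gamma)) and rotation (mobility 1/(gamma*I),
// I = sum |r_i - r_cm|^2), with matching thermal noise.
// In athermal mode (kT == 0) a step that would increase the energy is
// retried with a halved step size (backtracking), so the energy trace is
// non-increasing.
// [[Rcpp::export]]
List cpp_run_langevin(NumericMatrix coords, int nv, NumericVector kb,
                      NumericVector A0, LogicalVector rigid, List par,
                      int n_steps, int save_every, double kT, double gamma,
                      double dt, int seed, double cap_disp = -1.0,
                      bool check_stability = true, bool backtrack = true,
                      Nullable<NumericMatrix> tether_sites = R_NilValue,
                      double k_tether = 0.0) {
  System S = build_system(coords, nv, kb, A0, rigid, par);
  const int nc = S.ncell;
  FastRng rng(static_cast<std::uint64_t>(seed) + 0x7f4a7c15ULL);
  static const Ziggurat zig;
  auto norm = [&]() { return zig.draw(rng); };

  // rigid-body bookkeeping
  std::vector<double> cmx(nc), cmy(nc), ang(nc, 0.0), inertia(nc, 0.0);
  std::vector<std::vector<double>> bx(nc), by(nc);
  for (int c = 0; c < nc; ++c) {
    double mx = 0.0, my = 0.0;
    for (int i = 0; i < nv; ++i) { mx += S.x[c * nv + i]; my += S.y[c * nv + i]; }
    cmx[c] = mx / nv; cmy[c] = my / nv;
    if (S.rigid[c]) {
      bx[c].resize(nv); by[c].resize(nv);
      for (int i = 0; i < nv; ++i) {
        bx[c][i] = S.x[c * nv + i] - cmx[c];
        by[c][i] = S.y[c * nv + i] - cmy[c];
        inertia[c] += bx[c][i] * bx[c][i] + by[c][i] * by[c][i];
      }
    }
  }

  const bool athermal = (kT == 0.0);
  const bool do_backtrack = athermal && backtrack;
  std::vector<double> fx(S.ntot), fy(S.ntot);
  std::vector<double> xs, ys;
  List traj;
  IntegerVector traj_steps;
  NumericVector traj_energy;
  double max_disp_seen = 0.0;
  double e_prev = do_backtrack ? system_energy_impl(S) : 0.0;

  // Verlet list bookkeeping: rebuild when any vertex may have moved half
  // the skin since the last build
  NeighborList nl;
  build_nlist(S, nl);
  std::vector<double> accx(S.ntot, 0.0), accy(S.ntot, 0.0);
  double acc_max2 = 0.0;
  const double half_skin2 = 0.25 * nl.skin * nl.skin;

  std::vector<double> gxb(nv), gyb(nv);
  auto compute_forces = [&]() {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    for (int c = 0; c < nc; ++c) {
      if (S.rigid[c]) continue;
      cell_grad_impl(&S.x[c * nv], &S.y[c * nv], nv, S.ks, S.l0, S.kb[c],
                     S.ka, S.A0[c], gxb.data(), gyb.data());
      for (int i = 0; i < nv; ++i) {
        fx[c * nv + i] -= gxb[i];
        fy[c * nv + i] -= gyb[i];
      }
    }
    nlist_forces(S, nl, fx, fy);
    if (k_tether > 0.0 && tether_sites.isNotNull()) {
      // soft harmonic tether of each cell centroid to a fixed site (used
      // by the packing initializer to keep the inflation homogeneous);
      // applied as a uniform per-vertex force, so rigid bodies feel no
      // spurious torque
      NumericMatrix ts(tether_sites);
      for (int c = 0; c < nc; ++c) {
        double mx = 0.0, my = 0.0;
        for (int i = 0; i < nv; ++i) { mx += S.x[c*nv+i]; my += S.y[c*nv+i]; }
        mx /= nv; my /= nv;
        double dxs = min_image(mx - ts(c, 0), S.Lx);
        double dys = min_image(my - ts(c, 1), S.Ly);
        for (int i = 0; i < nv; ++i) {
          fx[c * nv + i] -= k_tether * dxs / nv;
          fy[c * nv + i] -= k_tether * dys / nv;
        }
      }
    }
  };

  auto save_snapshot = [&](int step) {
    NumericMatrix snap(S.ntot, 2);
    for (int i = 0; i < S.ntot; ++i) {
      snap(i, 0) = wrap(S.x[i], S.Lx);
      snap(i, 1) = wrap(S.y[i], S.Ly);
    }
    traj.push_back(snap);
    traj_steps.push_back(step);
    traj_energy.push_back(system_energy_impl(S));
  };

  for (int step = 1; step <= n_steps; ++step) {
    compute_forces();
    double eff_dt = dt;
    int tries = 0;
    for (;;) {
      xs = S.x; ys = S.y; // trial state from current
      std::vector<double> cmx_t = cmx, cmy_t = cmy, ang_t = ang;
      double max_disp = 0.0;
      // pre-draw noise so retries reuse the same random numbers scaled by dt
      // (only relevant in thermal mode where no retries happen anyway)
      for (int c = 0; c < nc; ++c) {
        if (S.rigid[c]) {
          double Fx = 0.0, Fy = 0.0, tau = 0.0;
          for (int i = 0; i < nv; ++i) {
            int g = c * nv + i;
            Fx += fx[g]; Fy += fy[g];
            tau += (S.x[g] - cmx[c]) * fy[g] - (S.y[g] - cmy[c]) * fx[g];
          }
          double mob_t = 1.0 / (nv * gamma);
          double mob_r = 1.0 / (gamma * inertia[c]);
          double ddx = Fx * mob_t * eff_dt;
          double ddy = Fy * mob_t * eff_dt;
          double dth = tau * mob_r * eff_dt;
          if (!athermal) {
            ddx += std::sqrt(2.0 * kT * mob_t * eff_dt) * norm();
            ddy += std::sqrt(2.0 * kT * mob_t * eff_dt) * norm();
            dth += std::sqrt(2.0 * kT * mob_r * eff_dt) * norm();
          }
          if (cap_disp > 0.0) {
            double d = std::sqrt(ddx * ddx + ddy * ddy);
            if (d > cap_disp) { ddx *= cap_disp / d; ddy *= cap_disp / d; }
            double rim = std::sqrt(inertia[c] / nv);
            if (std::fabs(dth) * rim > cap_disp)
              dth = (dth > 0 ? 1 : -1) * cap_disp / rim;
          }
          cmx_t[c] += ddx; cmy_t[c] += ddy; ang_t[c] += dth;
          double ca = std::cos(ang_t[c]), sa = std::sin(ang_t[c]);
          for (int i = 0; i < nv; ++i) {
            int g = c * nv + i;
            double nxp = cmx_t[c] + ca * bx[c][i] - sa * by[c][i];
            double nyp = cmy_t[c] + sa * bx[c][i] + ca * by[c][i];
            double mdx = nxp - S.x[g], mdy = nyp - S.y[g];
            double d = std::sqrt(mdx * mdx + mdy * mdy);
            if (d > max_disp) max_disp = d;
            xs[g] = nxp; ys[g] = nyp;
          }
        } else {
          for (int i = 0; i < nv; ++i) {
            int g = c * nv + i;
            double ddx = fx[g] * eff_dt / gamma;
            double ddy = fy[g] * eff_dt / gamma;
            if (!athermal) {
              double amp = std::sqrt(2.0 * kT * eff_dt / gamma);
              ddx += amp * norm();
              ddy += amp * norm();
            }
            double d = std::sqrt(ddx * ddx + ddy * ddy);
            if (cap_disp > 0.0 && d > cap_disp) {
              ddx *= cap_disp / d; ddy *= cap_disp / d; d = cap_disp;
            }
            if (d > max_disp) max_disp = d;
            xs[g] = S.x[g] + ddx; ys[g] = S.y[g] + ddy;
          }
        }
      }
      if (check_stability && max_disp > 0.5 * S.pp.sigma && cap_disp <= 0.0)
        stop("unstable time step: per-step displacement %f exceeds sigma/2 "
             "at step %d", max_disp, step);
      if (do_backtrack) {
        // backtracking: accept only non-increasing energy
        std::swap(S.x, xs); std::swap(S.y, ys);
        double e_new = system_energy_impl(S);
        if (e_new <= e_prev || tries >= 30) {
          e_prev = e_new;
          cmx = cmx_t; cmy = cmy_t; ang = ang_t;
          if (max_disp > max_disp_seen) max_disp_seen = max_disp;
          break;
        }
        std::swap(S.x, xs); std::swap(S.y, ys); // reject
        eff_dt *= 0.5;
        ++tries;
      } else {
        std::swap(S.x, xs); std::swap(S.y, ys);
        cmx = cmx_t; cmy = cmy_t; ang = ang_t;
        if (max_disp > max_disp_seen) max_disp_seen = max_disp;
        break;
      }
    }
    // neighbor-list maintenance: xs holds the pre-step coordinates
    for (int i = 0; i < S.ntot; ++i) {
      accx[i] += S.x[i] - xs[i];
      accy[i] += S.y[i] - ys[i];
      double a2 = accx[i] * accx[i] + accy[i] * accy[i];
      if (a2 > acc_max2) acc_max2 = a2;
    }
    if (acc_max2 > half_skin2) {
      build_nlist(S, nl);
      std::fill(accx.begin(), accx.end(), 0.0);
      std::fill(accy.begin(), accy.end(), 0.0);
      acc_max2 = 0.0;
    }
    // re-centre cells whose centroid left the domain (keeps coordinates
    // bounded; minimum image handles interactions)
    if (step % 16 == 0 || step == n_steps) {
      for (int c = 0; c < nc; ++c) {
        double mx, my;
        if (S.rigid[c]) { mx = cmx[c]; my = cmy[c]; }
        else {
          mx = 0.0; my = 0.0;
          for (int i = 0; i < nv; ++i) { mx += S.x[c*nv+i]; my += S.y[c*nv+i]; }
          mx /= nv; my /= nv;
        }
        double sx = -S.Lx * std::floor(mx / S.Lx);
        double sy = -S.Ly * std::floor(my / S.Ly);
        if (sx != 0.0 || sy != 0.0) {
          for (int i = 0; i < nv; ++i) {
            S.x[c * nv + i] += sx; S.y[c * nv + i] += sy;
          }
          cmx[c] += sx; cmy[c] += sy;
        }
      }
    }
    if (save_every > 0 && (step % save_every == 0 || step == n_steps))
      save_snapshot(step);
    if (step % 2048 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix fin(S.ntot, 2);
  for (int i = 0; i < S.ntot; ++i) { fin(i, 0) = S.x[i]; fin(i, 1) = S.y[i]; }
  return List::create(_["trajectory"] = traj, _["steps"] = traj_steps,
                      _["energies"] = traj_energy, _["final"] = fin,
                      _["max_disp"] = max_disp_seen);
}

// ---------------------------------------------------------------------------
// Exported: diagnostics
// ---------------------------------------------------------------------------

// Minimum inter-cell vertex distance (capped at r_probe).
// [[Rcpp::export]]
double cpp_min_intercell_dist(NumericMatrix coords, int nv, double Lx,
                              double Ly, double r_probe) {
  List par = List::create(_["l0"] = 1.0, _["k_spring"] = 0.0,
                          _["k_area"] = 0.0, _["Lx"] = Lx, _["Ly"] = Ly,
                          _["sigma"] = r_probe / std::pow(2.0, 1.0 / 6.0),
                          _["r_cut"] = r_probe, _["eps_attr"] = 0.0,
                          _["eps_rep"] = 1.0,
                          _["sigma_rep"] = r_probe / std::pow(2.0, 1.0 / 6.0));
  int ncell = coords.nrow() / nv;
  NumericVector kb(ncell), A0(ncell, 1.0);
  LogicalVector rigid(ncell);
  System S = build_system(coords, nv, kb, A0, rigid, par);
  double dmin = r_probe;
  for_each_pair(S, [&](int i, int j, double, double, double r) {
    if (i / nv != j / nv && r < dmin) dmin = r;
  });
  return dmin;
}

// Cell pairs with any inter-cell vertex pair closer than r_contact.
// [[Rcpp::export]]
IntegerMatrix cpp_cell_contact_pairs(NumericMatrix coords, int nv, double Lx,
                                     double Ly, double r_contact) {
  List par = List::create(_["l0"] = 1.0, _["k_spring"] = 0.0,
                          _["k_area"] = 0.0, _["Lx"] = Lx, _["Ly"] = Ly,
                          _["sigma"] = r_contact / std::pow(2.0, 1.0 / 6.0),
                          _["r_cut"] = r_contact, _["eps_attr"] = 0.0,
                          _["eps_rep"] = 1.0,
                          _["sigma_rep"] = r_contact / std::pow(2.0, 1.0 / 6.0));
  int ncell = coords.nrow() / nv;
  NumericVector kb(ncell), A0(ncell, 1.0);
  LogicalVector rigid(ncell);
  System S = build_system(coords, nv, kb, A0, rigid, par);
  std::set<std::pair<int, int>> pairs;
  for_each_pair(S, [&](int i, int j, double, double, double r) {
    int ci = i / nv, cj = j / nv;
    if (ci != cj && r < r_contact)
      pairs.insert({std::min(ci, cj), std::max(ci, cj)});
  });
  IntegerMatrix out(pairs.size(), 2);
  int k = 0;
  for (auto& p : pairs) { out(k, 0) = p.first + 1; out(k, 1) = p.second + 1; ++k; }
  return out;
}

// ---------------------------------------------------------------------------
// Exported: rasterization and hole labeling
// ---------------------------------------------------------------------------

// Occupancy grid: a grid cell (centre at ((i+0.5)res, (j+0.5)res)) is
// occupied iff its centre lies inside any cell polygon (with periodic
// images) or within `thick` of any vertex (membrane thickness).
// coords must be ring-contiguous per cell (unwrapped rings); each cell is
// tested at the periodic images overlapping the domain.
// Rows index y, columns index x.
// [[Rcpp::export]]
IntegerMatrix cpp_rasterize(NumericMatrix coords, int nv, double Lx,
                            double Ly, double res, double thick) {
  int nx = (int)std::lround(Lx / res);
  int ny = (int)std::lround(Ly / res);
  if (nx < 1 || ny < 1) stop("resolution too coarse for domain");
  IntegerMatrix occ(ny, nx);
  int ncell = coords.nrow() / nv;
  std::vector<double> px(nv), py(nv);
  for (int c = 0; c < ncell; ++c) {
    // re-centre polygon so its centroid lies in the domain
    double mx = 0.0, my = 0.0;
    for (int i = 0; i < nv; ++i) { mx += coords(c*nv+i,0); my += coords(c*nv+i,1); }
    mx /= nv; my /= nv;
    double sx = -Lx * std::floor(mx / Lx), sy = -Ly * std::floor(my / Ly);
    double xmin = 1e300, xmax = -1e300, ymin = 1e300, ymax = -1e300;
    for (int i = 0; i < nv; ++i) {
      px[i] = coords(c * nv + i, 0) + sx;
      py[i] = coords(c * nv + i, 1) + sy;
      xmin = std::min(xmin, px[i]); xmax = std::max(xmax, px[i]);
      ymin = std::min(ymin, py[i]); ymax = std::max(ymax, py[i]);
    }
    for (int ox = -1; ox <= 1; ++ox) {
      for (int oy = -1; oy <= 1; ++oy) {
        double bx0 = xmin + ox * Lx - thick, bx1 = xmax + ox * Lx + thick;
        double by0 = ymin + oy * Ly - thick, by1 = ymax + oy * Ly + thick;
        if (bx1 < 0 || bx0 > Lx || by1 < 0 || by0 > Ly) continue;
        int i0 = std::max(0, (int)std::floor(bx0 / res));
        int i1 = std::min(nx - 1, (int)std::floor(bx1 / res));
        int j0 = std::max(0, (int)std::floor(by0 / res));
        int j1 = std::min(ny - 1, (int)std::floor(by1 / res));
        for (int gi = i0; gi <= i1; ++gi) {
          double cx = (gi + 0.5) * res - ox * Lx;
          for (int gj = j0; gj <= j1; ++gj) {
            if (occ(gj, gi)) continue;
            double cy = (gj + 0.5) * res - oy * Ly;
            // point in polygon (ray crossing)
            bool inside = false;
            for (int i = 0, j = nv - 1; i < nv; j = i++) {
              if (((py[i] > cy) != (py[j] > cy)) &&
                  (cx < (px[j] - px[i]) * (cy - py[i]) / (py[j] - py[i]) + px[i]))
                inside = !inside;
            }
            if (!inside && thick > 0.0) {
              double t2 = thick * thick;
              for (int i = 0; i < nv; ++i) {
                double ddx = px[i] - cx, ddy = py[i] - cy;
                if (ddx * ddx + ddy * ddy <= t2) { inside = true; break; }
              }
            }
            if (inside) occ(gj, gi) = 1;
          }
        }
      }
    }
  }
  return occ;
}

// Morphological closing (k-fold 4-neighbor dilation then erosion) of the
// occupied phase, periodic-aware.  Used to seal adhesive contacts so that
// the compartments between aggregated cells become separate components.
// [[Rcpp::export]]
IntegerMatrix cpp_morph_close(IntegerMatrix occ, int k, bool periodic) {
  int ny = occ.nrow(), nx = occ.ncol();
  IntegerMatrix cur = clone(occ);
  auto pass = [&](bool dilate) {
    IntegerMatrix nxt(ny, nx);
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        int self = cur(j, i);
        bool any = false, all = true;
        const int dj[4] = {0, 0, 1, -1}, di[4] = {1, -1, 0, 0};
        for (int d = 0; d < 4; ++d) {
          int jj = j + dj[d], ii = i + di[d];
          if (periodic) {
            jj = (jj + ny) % ny; ii = (ii + nx) % nx;
          } else if (jj < 0 || jj >= ny || ii < 0 || ii >= nx) {
            all = false; // outside counts as free
            continue;
          }
          if (cur(jj, ii)) any = true; else all = false;
        }
        if (dilate) nxt(j, i) = (self || any) ? 1 : 0;
        else nxt(j, i) = (self && all) ? 1 : 0;
      }
    }
    cur = nxt;
  };
  for (int r = 0; r < k; ++r) pass(true);
  for (int r = 0; r < k; ++r) pass(false);
  return cur;
}

// 4-connected labeling of free (== 0) grid cells, with optional periodic
// merging across opposite boundaries.  Returns a label matrix (0 for
// occupied cells, labels 1..K for free components).
// [[Rcpp::export]]
IntegerMatrix cpp_label_free(IntegerMatrix occ, bool periodic) {
  int ny = occ.nrow(), nx = occ.ncol(), n = nx * ny;
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[b] = a;
  };
  auto idx = [&](int j, int i) { return j * nx + i; };
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      if (occ(j, i)) continue;
      if (i + 1 < nx && !occ(j, i + 1)) unite(idx(j, i), idx(j, i + 1));
      if (j + 1 < ny && !occ(j + 1, i)) unite(idx(j, i), idx(j + 1, i));
      if (periodic && i == nx - 1 && !occ(j, 0)) unite(idx(j, i), idx(j, 0));
      if (periodic && j == ny - 1 && !occ(0, i)) unite(idx(j, i), idx(0, i));
    }
  }
  IntegerMatrix lab(ny, nx);
  std::map<int, int> relabel;
  int next = 0;
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      if (occ(j, i)) { lab(j, i) = 0; continue; }
      int r = find(idx(j, i));
      auto it = relabel.find(r);
      if (it == relabel.end()) { relabel[r] = ++next; lab(j, i) = next; }
      else lab(j, i) = it->second;
    }
  }
  return lab;
}
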