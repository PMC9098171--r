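// DPD engine kernels: soft conservative repulsions, harmonic bonds/angles,
// pairwise dissipative-random thermostat, Slater-smeared Ewald
// electrostatics, velocity-Verlet integration with optional Berendsen
// barostat. Positions are in r_c units, energies in kBT, masses 1.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Deterministic RNG (xorshift128+ seeded by splitmix64); avoids
// implementation-defined std::distribution algorithms so that equal seeds
// give bitwise-equal trajectories on any platform.
struct Rng {
  uint64_t s0, s1;
  explicit Rng(uint64_t seed) {
    uint64_t z = seed;
    uint64_t out[2];
    for (int i = 0; i < 2; i++) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      out[i] = t ^ (t >> 31);
    }
    s0 = out[0] ? out[0] : 1ULL;
    s1 = out[1] ? out[1] : 2ULL;
  }
  uint64_t next() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // zero-mean, unit-variance uniform deviate (standard choice for the DPD
  // random force; only the first two moments matter for the stationary state)
  double theta() { return (2.0 * unif() - 1.0) * 1.7320508075688772; }
  double normal() {
    double u1 = unif();
    if (u1 < 1e-300) u1 = 1e-300;
    double u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
  }
};

static inline double min_image(double d, double L) {
  if (d > 0.5 * L) d -= L;
  else if (d < -0.5 * L) d += L;
  return d;
}

static inline double wrap(double x, double L) {
  x = std::fmod(x, L);
  if (x < 0) x += L;
  return x;
}

// ---------------------------------------------------------------------------
// Pair loop over all bead pairs within `cut`, via linked cells when the box
// holds at least 3 cells per side, otherwise a double loop. Callback gets
// (i, j, dx, dy, dz, r2) with dx = xi - xj (minimum image).
template <typename F>
static void for_each_pair(const std::vector<double>& x,
                          const std::vector<double>& y,
                          const std::vector<double>& z,
                          double L, double cut, bool force_allpairs, F&& fn) {
  const int n = (int)x.size();
  const double cut2 = cut * cut;
  int ncx = (int)std::floor(L / cut);
  if (force_allpairs || ncx < 3) {
    for (int i = 0; i < n; i++)
      for (int j = i + 1; j < n; j++) {
        double dx = min_image(x[i] - x[j], L);
        double dy = min_image(y[i] - y[j], L);
        double dz = min_image(z[i] - z[j], L);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 < cut2) fn(i, j, dx, dy, dz, r2);
      }
    return;
  }
  const double cw = L / ncx;
  std::vector<std::vector<int>> cells((size_t)ncx * ncx * ncx);
  for (int i = 0; i < n; i++) {
    int cx = (int)(x[i] / cw); if (cx >= ncx) cx = ncx - 1;
    int cy = (int)(y[i] / cw); if (cy >= ncx) cy = ncx - 1;
    int cz = (int)(z[i] / cw); if (cz >= ncx) cz = ncx - 1;
    cells[(size_t)(cx * ncx + cy) * ncx + cz].push_back(i);
  }
  // 13 half-space neighbour offsets + same cell
  static const int off[13][3] = {
    {1,0,0},{0,1,0},{0,0,1},{1,1,0},{1,-1,0},{1,0,1},{1,0,-1},
    {0,1,1},{0,1,-1},{1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}};
  for (int cx = 0; cx < ncx; cx++)
    for (int cy = 0; cy < ncx; cy++)
      for (int cz = 0; cz < ncx; cz++) {
        const std::vector<int>& c0 = cells[(size_t)(cx * ncx + cy) * ncx + cz];
        const int m0 = (int)c0.size();
        for (int a = 0; a < m0; a++)
          for (int b = a + 1; b < m0; b++) {
            int i = c0[a], j = c0[b];
            double dx = min_image(x[i] - x[j], L);
            double dy = min_image(y[i] - y[j], L);
            double dz = min_image(z[i] - z[j], L);
            double r2 = dx * dx + dy * dy + dz * dz;
            if (r2 < cut2) fn(i, j, dx, dy, dz, r2);
          }
        for (int k = 0; k < 13; k++) {
          int nx = (cx + off[k][0] + ncx) % ncx;
          int ny = (cy + off[k][1] + ncx) % ncx;
          int nz = (cz + off[k][2] + ncx) % ncx;
          const std::vector<int>& c1 = cells[(size_t)(nx * ncx + ny) * ncx + nz];
          for (int a = 0; a < m0; a++)
            for (size_t b = 0; b < c1.size(); b++) {
              int i = c0[a], j = c1[b];
              double dx = min_image(x[i] - x[j], L);
              double dy = min_image(y[i] - y[j], L);
              double dz = min_image(z[i] - z[j], L);
              double r2 = dx * dx + dy * dy + dz * dz;
              if (r2 < cut2) fn(i, j, dx, dy, dz, r2);
            }
        }
      }
}

// ---------------------------------------------------------------------------
// Parameter bundle shared by the standalone evaluators and the run loop.
struct ElecParams {
  bool enabled = false;
  double gamma = 15.94, beta = 0.929, alpha = 1.0;
  double rcut = 3.0, kcut = 5.0, rcut_corr = 8.0;
};

struct Forces {
  std::vector<double> fx, fy, fz;
  double virial = 0.0, pe = 0.0;
  explicit Forces(int n) : fx(n, 0.0), fy(n, 0.0), fz(n, 0.0) {}
  void zero() {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    virial = 0.0; pe = 0.0;
  }
};

// Conservative soft repulsion + (optionally) the pairwise thermostat in a
// single pass. Random-force prefactor sig_dt = sigma/sqrt(dt); pass 0 to
// disable both dissipative and random forces.
static void soft_thermo_forces(const std::vector<double>& x,
                               const std::vector<double>& y,
                               const std::vector<double>& z,
                               const std::vector<double>& vx,
                               const std::vector<double>& vy,
                               const std::vector<double>& vz,
                               const std::vector<int>& type, int ntype,
                               const std::vector<double>& aM,
                               const std::vector<double>& RM,
                               double L, double maxR,
                               double gamma_d, double sig_dt, Rng* rng,
                               bool force_allpairs,
                               Forces& F, int* overlap_count) {
  double cut = maxR;
  bool thermo = (gamma_d > 0.0 || sig_dt > 0.0);
  if (thermo && cut < 1.0) cut = 1.0;
  for_each_pair(x, y, z, L, cut, force_allpairs,
    [&](int i, int j, double dx, double dy, double dz, double r2) {
      double r = std::sqrt(r2);
      int ti = type[i], tj = type[j];
      double Rij = RM[ti * ntype + tj];
      double fx = 0, fy = 0, fz = 0;
      if (r < Rij) {
        double a = aM[ti * ntype + tj];
        if (r < 1e-12) {
          // soft potential is finite at r = 0 but the direction is
          // undefined; count the overlap and apply no force for this pair
          if (overlap_count) (*overlap_count)++;
          F.pe += 0.5 * a * Rij;
        } else {
          double omr = 1.0 - r / Rij;
          double fmag = a * omr;            // |F| = a(1 - r/R)
          double inv = fmag / r;
          fx = inv * dx; fy = inv * dy; fz = inv * dz;
          F.pe += 0.5 * a * Rij * omr * omr;
          F.virial += fmag * r;
        }
      }
      if (thermo && r < 1.0 && r > 1e-12) {
        double w = 1.0 - r;
        double ex = dx / r, ey = dy / r, ez = dz / r;
        double dvx = vx[i] - vx[j], dvy = vy[i] - vy[j], dvz = vz[i] - vz[j];
        double ev = ex * dvx + ey * dvy + ez * dvz;
        double fd = -gamma_d * w * w * ev;
        double fr = (sig_dt > 0.0) ? sig_dt * w * rng->theta() : 0.0;
        double fm = fd + fr;
        fx += fm * ex; fy += fm * ey; fz += fm * ez;
      }
      F.fx[i] += fx; F.fy[i] += fy; F.fz[i] += fz;
      F.fx[j] -= fx; F.fy[j] -= fy; F.fz[j] -= fz;
    });
}

// Harmonic bonds and angles; energies 0.5 kb (r-r0)^2 and 0.5 ka (th-th0)^2.
static void bonded_force_eval(const std::vector<double>& x,
                              const std::vector<double>& y,
                              const std::vector<double>& z, double L,
                              const IntegerVector& bi, const IntegerVector& bj,
                              const NumericVector& br0, double kb,
                              const IntegerVector& ai, const IntegerVector& aj,
                              const IntegerVector& ak, const NumericVector& ath0,
                              double ka, Forces& F) {
  for (int b = 0; b < bi.size(); b++) {
    int i = bi[b], j = bj[b];
    double dx = min_image(x[i] - x[j], L);
    double dy = min_image(y[i] - y[j], L);
    double dz = min_image(z[i] - z[j], L);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - br0[b];
    F.pe += 0.5 * kb * dr * dr;
    if (r > 1e-12) {
      double fmag = -kb * dr;               // along r-hat on bead i
      double inv = fmag / r;
      F.fx[i] += inv * dx; F.fy[i] += inv * dy; F.fz[i] += inv * dz;
      F.fx[j] -= inv * dx; F.fy[j] -= inv * dy; F.fz[j] -= inv * dz;
      F.virial += fmag * r;
    }
  }
  for (int t = 0; t < ai.size(); t++) {
    int i = ai[t], j = aj[t], k = ak[t];
    double ax = min_image(x[i] - x[j], L);
    double ay = min_image(y[i] - y[j], L);
    double az = min_image(z[i] - z[j], L);
    double bx = min_image(x[k] - x[j], L);
    double by = min_image(y[k] - y[j], L);
    double bz = min_image(z[k] - z[j], L);
    double ra = std::sqrt(ax * ax + ay * ay + az * az);
    double rb = std::sqrt(bx * bx + by * by + bz * bz);
    if (ra < 1e-12 || rb < 1e-12) continue;
    double c = (ax * bx + ay * by + az * bz) / (ra * rb);
    if (c > 1.0) c = 1.0;
    if (c < -1.0) c = -1.0;
    double th = std::acos(c);
    double dth = th - ath0[t];
    F.pe += 0.5 * ka * dth * dth;
    double s = std::sqrt(1.0 - c * c);
    if (s < 1e-8) s = 1e-8;                 // stable small-sine branch
    double coef = ka * dth / s;             // F_i = -dE/dri = +ka dth/s dcos/dri
    // dcos/dri and dcos/drk
    double dcix = bx / (ra * rb) - c * ax / (ra * ra);
    double dciy = by / (ra * rb) - c * ay / (ra * ra);
    double dciz = bz / (ra * rb) - c * az / (ra * ra);
    double dckx = ax / (ra * rb) - c * bx / (rb * rb);
    double dcky = ay / (ra * rb) - c * by / (rb * rb);
    double dckz = az / (ra * rb) - c * bz / (rb * rb);
    double fix = coef * dcix, fiy = coef * dciy, fiz = coef * dciz;
    double fkx = coef * dckx, fky = coef * dcky, fkz = coef * dckz;
    F.fx[i] += fix; F.fy[i] += fiy; F.fz[i] += fiz;
    F.fx[k] += fkx; F.fy[k] += fky; F.fz[k] += fkz;
    F.fx[j] -= fix + fkx; F.fy[j] -= fiy + fky; F.fz[j] -= fiz + fkz;
    F.virial += ax * fix + ay * fiy + az * fiz + bx * fkx + by * fky + bz * fkz;
  }
}

// ---------------------------------------------------------------------------
// Slater-smeared Ewald electrostatics. Decomposition: point-charge Ewald
// (real erfc + reciprocal + self) plus a short-range smearing correction
// u_sl(r) - u_coul(r) = -ke q q' (1/r + beta) exp(-2 beta r), summed over
// periodic image shells out to rcut_corr so that it is converged rather
// than truncated at the (shorter) Ewald real-space cutoff.
static void ewald_eval(const std::vector<double>& x,
                       const std::vector<double>& y,
                       const std::vector<double>& z,
                       const std::vector<double>& q, double L,
                       const ElecParams& ep, Forces& F) {
  const int n = (int)x.size();
  const double ke = ep.gamma / (4.0 * M_PI);
  const double alpha = ep.alpha, beta = ep.beta;
  const double V = L * L * L;
  const double twop = 2.0 * M_PI;

  // real-space erfc part (minimum image; requires L >= 2 rcut, checked in R)
  for_each_pair(x, y, z, L, ep.rcut, false,
    [&](int i, int j, double dx, double dy, double dz, double r2) {
      double qq = q[i] * q[j];
      if (qq == 0.0) return;
      double r = std::sqrt(r2);
      if (r < 1e-12) return;
      double er = std::erfc(alpha * r);
      double e = ke * qq * er / r;
      F.pe += e;
      double fmag = ke * qq * (er / r2 +
                    2.0 * alpha / std::sqrt(M_PI) * std::exp(-alpha * alpha * r2) / r);
      double inv = fmag / r;
      F.fx[i] += inv * dx; F.fy[i] += inv * dy; F.fz[i] += inv * dz;
      F.fx[j] -= inv * dx; F.fy[j] -= inv * dy; F.fz[j] -= inv * dz;
      F.virial += fmag * r;
    });

  // smearing correction over image shells
  {
    int nsh = (int)std::ceil(ep.rcut_corr / L - 0.5);
    if (nsh < 0) nsh = 0;
    double rc2 = ep.rcut_corr * ep.rcut_corr;
    for (int i = 0; i < n; i++)
      for (int j = i; j < n; j++) {
        double qq = q[i] * q[j];
        if (qq == 0.0) continue;
        double dx0 = x[i] - x[j], dy0 = y[i] - y[j], dz0 = z[i] - z[j];
        for (int mx = -nsh; mx <= nsh; mx++)
          for (int my = -nsh; my <= nsh; my++)
            for (int mz = -nsh; mz <= nsh; mz++) {
              if (i == j && mx == 0 && my == 0 && mz == 0) continue;
              double dx = min_image(dx0, L) + mx * L;
              double dy = min_image(dy0, L) + my * L;
              double dz = min_image(dz0, L) + mz * L;
              double r2 = dx * dx + dy * dy + dz * dz;
              if (r2 > rc2 || r2 < 1e-24) continue;
              double r = std::sqrt(r2);
              double ex2 = std::exp(-2.0 * beta * r);
              double w = (i == j) ? 0.5 : 1.0;  // self-image pairs count once
              F.pe += -w * ke * qq * (1.0 / r + beta) * ex2;
              double fmag = -w * ke * qq * ex2 *
                            (1.0 / r2 + 2.0 * beta / r + 2.0 * beta * beta);
              double inv = fmag / r;
              F.fx[i] += inv * dx; F.fy[i] += inv * dy; F.fz[i] += inv * dz;
              F.fx[j] -= inv * dx; F.fy[j] -= inv * dy; F.fz[j] -= inv * dz;
              F.virial += fmag * r;
            }
      }
  }

  // self term
  double sq2 = 0.0;
  for (int i = 0; i < n; i++) sq2 += q[i] * q[i];
  F.pe += -ke * alpha / std::sqrt(M_PI) * sq2;

  // reciprocal part: k = 2 pi m / L with |k| <= kcut
  int mmax = (int)std::floor(ep.kcut * L / twop);
  if (mmax > 0) {
    double k2max = ep.kcut * ep.kcut;
    for (int mx = -mmax; mx <= mmax; mx++)
      for (int my = -mmax; my <= mmax; my++)
        for (int mz = -mmax; mz <= mmax; mz++) {
          if (mx == 0 && my == 0 && mz == 0) continue;
          double kx = twop * mx / L, ky = twop * my / L, kz = twop * mz / L;
          double k2 = kx * kx + ky * ky + kz * kz;
          if (k2 > k2max) continue;
          double Ak = std::exp(-k2 / (4.0 * alpha * alpha)) / k2;
          double Sre = 0.0, Sim = 0.0;
          for (int i = 0; i < n; i++) {
            if (q[i] == 0.0) continue;
            double ph = kx * x[i] + ky * y[i] + kz * z[i];
            Sre += q[i] * std::cos(ph);
            Sim += q[i] * std::sin(ph);
          }
          double S2 = Sre * Sre + Sim * Sim;
          double epref = ke * twop / V * Ak;
          F.pe += epref * S2;
          F.virial += epref * S2 * (1.0 - k2 / (2.0 * alpha * alpha));
          double fpref = ke * 4.0 * M_PI / V * Ak;
          for (int i = 0; i < n; i++) {
            if (q[i] == 0.0) continue;
            double ph = kx * x[i] + ky * y[i] + kz * z[i];
            double im = std::sin(ph) * Sre - std::cos(ph) * Sim;
            double f = fpref * q[i] * im;
            F.fx[i] += f * kx; F.fy[i] += f * ky; F.fz[i] += f * kz;
          }
        }
  }
}

// ---------------------------------------------------------------------------
// Standalone evaluators exposed to R

// [[Rcpp::export]]
List cpp_conservative_forces(NumericMatrix pos, IntegerVector type, double L,
                             NumericMatrix aMat, NumericMatrix RMat,
                             bool allpairs = false) {
  const int n = pos.nrow();
  const int ntype = aMat.nrow();
  std::vector<double> x(n), y(n), z(n), v0(n, 0.0);
  for (int i = 0; i < n; i++) { x[i] = pos(i,0); y[i] = pos(i,1); z[i] = pos(i,2); }
  std::vector<int> ty(type.begin(), type.end());
  std::vector<double> aM(aMat.begin(), aMat.end()), RM(RMat.begin(), RMat.end());
  // matrices arrive column-major; symmetric, so row/col order is immaterial
  double maxR = 0.0;
  for (size_t i = 0; i < RM.size(); i++) if (RM[i] > maxR) maxR = RM[i];
  Forces F(n);
  int overlaps = 0;
  soft_thermo_forces(x, y, z, v0, v0, v0, ty, ntype, aM, RM, L, maxR,
                     0.0, 0.0, nullptr, allpairs, F, &overlaps);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; i++) { out(i,0)=F.fx[i]; out(i,1)=F.fy[i]; out(i,2)=F.fz[i]; }
  return List::create(_["forces"] = out, _["virial"] = F.virial,
                      _["energy"] = F.pe, _["overlaps"] = overlaps);
}

// [[Rcpp::export]]
List cpp_bonded_forces(NumericMatrix pos, double L,
                       IntegerVector bond_i, IntegerVector bond_j,
                       NumericVector bond_r0, double kb,
                       IntegerVector ang_i, IntegerVector ang_j,
                       IntegerVector ang_k, NumericVector ang_th0, double ka) {
  const int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; i++) { x[i] = pos(i,0); y[i] = pos(i,1); z[i] = pos(i,2); }
  Forces F(n);
  bonded_force_eval(x, y, z, L, bond_i, bond_j, bond_r0, kb,
                    ang_i, ang_j, ang_k, ang_th0, ka, F);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; i++) { out(i,0)=F.fx[i]; out(i,1)=F.fy[i]; out(i,2)=F.fz[i]; }
  return List::create(_["forces"] = out, _["energy"] = F.pe,
                      _["virial"] = F.virial);
}

// [[Rcpp::export]]
List cpp_ewald(NumericMatrix pos, NumericVector charge, double L,
               double gamma, double beta, double alpha,
               double rcut, double kcut, double rcut_corr) {
  const int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n), q(charge.begin(), charge.end());
  for (int i = 0; i < n; i++) { x[i] = pos(i,0); y[i] = pos(i,1); z[i] = pos(i,2); }
  ElecParams ep;
  ep.enabled = true; ep.gamma = gamma; ep.beta = beta; ep.alpha = alpha;
  ep.rcut = rcut; ep.kcut = kcut; ep.rcut_corr = rcut_corr;
  Forces F(n);
  ewald_eval(x, y, z, q, L, ep, F);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; i++) { out(i,0)=F.fx[i]; out(i,1)=F.fy[i]; out(i,2)=F.fz[i]; }
  return List::create(_["energy"] = F.pe, _["forces"] = out,
                      _["virial"] = F.virial);
}

// ---------------------------------------------------------------------------
// Full integrator. Velocity Verlet with the dissipative force evaluated at
// half-step velocities (the common DPD-VV scheme).
// [[Rcpp::export]]
List cpp_run_dpd(NumericMatrix pos, NumericMatrix vel, IntegerVector type,
                 NumericVector charge, double L,
                 NumericMatrix aMat, NumericMatrix RMat,
                 IntegerVector bond_i, IntegerVector bond_j,
                 NumericVector bond_r0, double kb,
                 IntegerVector ang_i, IntegerVector ang_j, IntegerVector ang_k,
                 NumericVector ang_th0, double ka,
                 bool elec_on, double e_gamma, double e_beta, double e_alpha,
                 double e_rcut, double e_kcut, double e_rcut_corr,
                 double dt, int nsteps, double gamma_d, double kT,
                 int seed, int sample_every,
                 bool npt, double p_target, double tau_p,
                 double max_disp = 0.5) {
  const int n = pos.nrow();
  const int ntype = aMat.nrow();
  std::vector<double> x(n), y(n), z(n), vx(n), vy(n), vz(n);
  for (int i = 0; i < n; i++) {
    x[i] = wrap(pos(i,0), L); y[i] = wrap(pos(i,1), L); z[i] = wrap(pos(i,2), L);
    vx[i] = vel(i,0); vy[i] = vel(i,1); vz[i] = vel(i,2);
  }
  std::vector<int> ty(type.begin(), type.end());
  std::vector<double> q(charge.begin(), charge.end());
  std::vector<double> aM(aMat.begin(), aMat.end()), RM(RMat.begin(), RMat.end());
  double maxR = 0.0;
  for (size_t i = 0; i < RM.size(); i++) if (RM[i] > maxR) maxR = RM[i];
  bool any_q = false;
  for (int i = 0; i < n; i++) if (q[i] != 0.0) { any_q = true; break; }
  ElecParams ep;
  ep.enabled = elec_on && any_q;
  ep.gamma = e_gamma; ep.beta = e_beta; ep.alpha = e_alpha;
  ep.rcut = e_rcut; ep.kcut = e_kcut; ep.rcut_corr = e_rcut_corr;

  Rng rng((uint64_t)seed * 2654435761ULL + 1ULL);
  const double sigma = std::sqrt(2.0 * gamma_d * kT);
  const double sig_dt = (gamma_d > 0.0) ? sigma / std::sqrt(dt) : 0.0;

  Forces F(n);
  int overlaps = 0;
  auto eval_forces = [&](void) {
    F.zero();
    soft_thermo_forces(x, y, z, vx, vy, vz, ty, ntype, aM, RM, L, maxR,
                       gamma_d, sig_dt, &rng, false, F, &overlaps);
    bonded_force_eval(x, y, z, L, bond_i, bond_j, bond_r0, kb,
                      ang_i, ang_j, ang_k, ang_th0, ka, F);
    if (ep.enabled) ewald_eval(x, y, z, q, L, ep, F);
  };
  eval_forces();

  int nsamp = (sample_every > 0) ? nsteps / sample_every : 0;
  List frames(nsamp);
  IntegerVector fsteps(nsamp);
  NumericVector fL(nsamp), Tser(nsamp), Pser(nsamp), PEser(nsamp), KEser(nsamp);
  int isamp = 0;

  const double half = 0.5 * dt;
  for (int step = 1; step <= nsteps; step++) {
    double md2 = 0.0;
    for (int i = 0; i < n; i++) {
      vx[i] += half * F.fx[i]; vy[i] += half * F.fy[i]; vz[i] += half * F.fz[i];
      double ddx = dt * vx[i], ddy = dt * vy[i], ddz = dt * vz[i];
      double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
      if (d2 > md2) md2 = d2;
      x[i] = wrap(x[i] + ddx, L);
      y[i] = wrap(y[i] + ddy, L);
      z[i] = wrap(z[i] + ddz, L);
    }
    if (md2 > max_disp * max_disp)
      stop("integration unstable: per-step displacement %.3f r_c exceeds %.2f r_c at step %d; reduce the timestep",
           std::sqrt(md2), max_disp, step);
    eval_forces();
    for (int i = 0; i < n; i++) {
      vx[i] += half * F.fx[i]; vy[i] += half * F.fy[i]; vz[i] += half * F.fz[i];
    }

    double ke = 0.0;
    for (int i = 0; i < n; i++)
      ke += 0.5 * (vx[i]*vx[i] + vy[i]*vy[i] + vz[i]*vz[i]);
    double V = L * L * L;
    double p_inst = (2.0 * ke + F.virial) / (3.0 * V);

    if (npt) {
      double mu3 = 1.0 - dt / tau_p * (p_target - p_inst);
      if (mu3 < 0.9) mu3 = 0.9;
      if (mu3 > 1.1) mu3 = 1.1;
      double mu = std::cbrt(mu3);
      L *= mu;
      for (int i = 0; i < n; i++) { x[i] *= mu; y[i] *= mu; z[i] *= mu; }
    }

    if (sample_every > 0 && step % sample_every == 0 && isamp < nsamp) {
      NumericMatrix fr(n, 3);
      for (int i = 0; i < n; i++) { fr(i,0)=x[i]; fr(i,1)=y[i]; fr(i,2)=z[i]; }
      frames[isamp] = fr;
      fsteps[isamp] = step;
      fL[isamp] = L;
      Tser[isamp] = 2.0 * ke / (3.0 * n - 3.0);
      Pser[isamp] = p_inst;
      PEser[isamp] = F.pe;
      KEser[isamp] = ke;
      isamp++;
    }
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix pout(n, 3), vout(n, 3);
  for (int i = 0; i < n; i++) {
    pout(i,0)=x[i]; pout(i,1)=y[i]; pout(i,2)=z[i];
    vout(i,0)=vx[i]; vout(i,1)=vy[i]; vout(i,2)=vz[i];
  }
  return List::create(_["frames"] = frames, _["steps"] = fsteps, _["L"] = fL,
                      _["temperature"] = Tser, _["pressure"] = Pser,
                      _["potential"] = PEser, _["kinetic"] = KEser,
                      _["positions"] = pout, _["velocities"] = vout,
                      _["box"] = L, _["overlaps"] = overlaps);
}

// Maxwell velocities from the engine RNG (deterministic given seed).
// [[Rcpp::export]]
NumericMatrix cpp_maxwell_velocities(int n, double kT, int seed) {
  Rng rng((uint64_t)seed * 0x9e3779b97f4a7c15ULL + 7ULL);
  NumericMatrix v(n, 3);
  double sd = std::sqrt(kT);
  for (int i = 0; i < n; i++)
    for (int k = 0; k < 3; k++) v(i, k) = sd * rng.normal();
  // zero net momentum
  for (int k = 0; k < 3; k++) {
    double m = 0.0;
    for (int i = 0; i < n; i++) m += v(i, k);
    m /= n;
    for (int i = 0; i < n; i++) v(i, k) -= m;
  }
  return v;
}
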