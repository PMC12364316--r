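#ifndef EMLIG_H
#define EMLIG_H

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <unordered_set>

// Units: length Angstrom, energy kJ/mol, mass amu, time ps, charge e.
// With these, acceleration [A/ps^2] = 100 * F[kJ/mol/A] / m[amu].
static const double EM_KB = 0.0083144621;     // kJ/mol/K
static const double EM_FCOUL = 1389.35458;    // kJ/mol * A / e^2
static const double EM_ACC = 100.0;           // unit conversion, see above

struct GridGeom {
  int nx, ny, nz;
  double ox, oy, oz;   // centre of voxel (0,0,0)
  double vx, vy, vz;   // voxel spacing per axis
  inline long nvox() const { return (long)nx * ny * nz; }
  inline long idx(int i, int j, int k) const {
    return (long)i + (long)nx * ((long)j + (long)ny * (long)k);
  }
};

// Add the Gaussian density of natom atoms (positions P, column-major n x 3,
// amplitudes amp) to dens; optionally mark the support mask (voxels within
// mask_rcs * sigma of any atom). Spherical density truncation at
// rcs * sigma; peak value of a unit-amplitude atom is
// 1 / ((2 pi)^{3/2} sigma^3).
inline void em_add_density(const double* X, const double* Y, const double* Z,
                           const double* amp, int natom, const GridGeom& g,
                           double sigma, double rcs, double mask_rcs,
                           std::vector<double>* dens,
                           std::vector<unsigned char>* mask) {
  const double rcut = rcs * sigma, rcut2 = rcut * rcut;
  const double mrad = mask_rcs * sigma, mrad2 = mrad * mrad;
  const double boxr = std::max(rcut, mask ? mrad : 0.0);
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double norm = 1.0 / (std::pow(2.0 * M_PI, 1.5) * sigma * sigma * sigma);
  std::vector<double> gx, gy, gz, dx2, dy2, dz2;
  for (int a = 0; a < natom; ++a) {
    const double px = X[a], py = Y[a], pz = Z[a];
    int i0 = (int)std::ceil((px - boxr - g.ox) / g.vx);
    int i1 = (int)std::floor((px + boxr - g.ox) / g.vx);
    int j0 = (int)std::ceil((py - boxr - g.oy) / g.vy);
    int j1 = (int)std::floor((py + boxr - g.oy) / g.vy);
    int k0 = (int)std::ceil((pz - boxr - g.oz) / g.vz);
    int k1 = (int)std::floor((pz + boxr - g.oz) / g.vz);
    if (i0 < 0) i0 = 0; if (i1 > g.nx - 1) i1 = g.nx - 1;
    if (j0 < 0) j0 = 0; if (j1 > g.ny - 1) j1 = g.ny - 1;
    if (k0 < 0) k0 = 0; if (k1 > g.nz - 1) k1 = g.nz - 1;
    if (i1 < i0 || j1 < j0 || k1 < k0) continue;
    const int ni = i1 - i0 + 1, nj = j1 - j0 + 1, nk = k1 - k0 + 1;
    gx.resize(ni); dx2.resize(ni);
    gy.resize(nj); dy2.resize(nj);
    gz.resize(nk); dz2.resize(nk);
    for (int i = 0; i < ni; ++i) {
      double d = g.ox + (i0 + i) * g.vx - px;
      dx2[i] = d * d; gx[i] = std::exp(-d * d * inv2s2);
    }
    for (int j = 0; j < nj; ++j) {
      double d = g.oy + (j0 + j) * g.vy - py;
      dy2[j] = d * d; gy[j] = std::exp(-d * d * inv2s2);
    }
    for (int k = 0; k < nk; ++k) {
      double d = g.oz + (k0 + k) * g.vz - pz;
      dz2[k] = d * d; gz[k] = std::exp(-d * d * inv2s2);
    }
    const double A = amp[a] * norm;
    const double boxr2 = boxr * boxr;
    for (int k = 0; k < nk; ++k) {
      for (int j = 0; j < nj; ++j) {
        const double r2yz = dy2[j] + dz2[k];
        if (r2yz > boxr2) continue;
        const double gyz = gy[j] * gz[k];
        long base = g.idx(i0, j0 + j, k0 + k);
        for (int i = 0; i < ni; ++i) {
          const double r2 = dx2[i] + r2yz;
          if (dens && r2 <= rcut2) (*dens)[base + i] += A * gx[i] * gyz;
          if (mask && r2 <= mrad2) (*mask)[base + i] = 1;
        }
      }
    }
  }
}

struct CCStats {
  double cc, P, Qm, Qt, mbar, tbar;
  long n;
  bool meanSub;
};

// Pearson (or non-centred) correlation of model vs target over mask.
inline CCStats em_masked_cc(const std::vector<double>& m,
                            const double* t,
                            const std::vector<unsigned char>& mask,
                            bool meanSub) {
  CCStats s; s.n = 0; s.meanSub = meanSub;
  double sm = 0, st = 0;
  const long nv = (long)mask.size();
  for (long v = 0; v < nv; ++v) if (mask[v]) { sm += m[v]; st += t[v]; ++s.n; }
  if (s.n == 0) Rcpp::stop("degenerate mask: no voxels selected");
  s.mbar = meanSub ? sm / s.n : 0.0;
  s.tbar = meanSub ? st / s.n : 0.0;
  double P = 0, Qm = 0, Qt = 0;
  for (long v = 0; v < nv; ++v) {
    if (!mask[v]) continue;
    const double a = m[v] - s.mbar, b = t[v] - s.tbar;
    P += a * b; Qm += a * a; Qt += b * b;
  }
  if (Qm <= 0 || Qt <= 0)
    Rcpp::stop("degenerate mask: zero variance of %s values inside the mask",
               Qm <= 0 ? "model" : "target");
  s.P = P; s.Qm = Qm; s.Qt = Qt;
  s.cc = P / std::sqrt(Qm * Qt);
  return s;
}

// Analytic gradient of the masked cc with respect to the selected atoms'
// positions (the mask is held fixed). grad is 3 x natom column blocks
// (gx1,gy1,gz1, gx2, ...) accumulated in-place (caller zeroes).
inline void em_cc_gradient(const double* X, const double* Y, const double* Z,
                           const double* amp, int natom, const GridGeom& g,
                           double sigma, double rcs,
                           const std::vector<double>& dens, const double* t,
                           const std::vector<unsigned char>& mask,
                           const CCStats& s, double* grad) {
  const double rcut = rcs * sigma, rcut2 = rcut * rcut;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double invs2 = 1.0 / (sigma * sigma);
  const double norm = 1.0 / (std::pow(2.0 * M_PI, 1.5) * sigma * sigma * sigma);
  const double c1 = 1.0 / std::sqrt(s.Qm * s.Qt);
  const double c2 = s.cc / s.Qm;
  std::vector<double> gx, gy, gz, dx, dy, dz;
  for (int a = 0; a < natom; ++a) {
    const double px = X[a], py = Y[a], pz = Z[a];
    int i0 = (int)std::ceil((px - rcut - g.ox) / g.vx);
    int i1 = (int)std::floor((px + rcut - g.ox) / g.vx);
    int j0 = (int)std::ceil((py - rcut - g.oy) / g.vy);
    int j1 = (int)std::floor((py + rcut - g.oy) / g.vy);
    int k0 = (int)std::ceil((pz - rcut - g.oz) / g.vz);
    int k1 = (int)std::floor((pz + rcut - g.oz) / g.vz);
    if (i0 < 0) i0 = 0; if (i1 > g.nx - 1) i1 = g.nx - 1;
    if (j0 < 0) j0 = 0; if (j1 > g.ny - 1) j1 = g.ny - 1;
    if (k0 < 0) k0 = 0; if (k1 > g.nz - 1) k1 = g.nz - 1;
    if (i1 < i0 || j1 < j0 || k1 < k0) continue;
    const int ni = i1 - i0 + 1, nj = j1 - j0 + 1, nk = k1 - k0 + 1;
    gx.resize(ni); dx.resize(ni);
    gy.resize(nj); dy.resize(nj);
    gz.resize(nk); dz.resize(nk);
    for (int i = 0; i < ni; ++i) {
      double d = g.ox + (i0 + i) * g.vx - px;
      dx[i] = d; gx[i] = std::exp(-d * d * inv2s2);
    }
    for (int j = 0; j < nj; ++j) {
      double d = g.oy + (j0 + j) * g.vy - py;
      dy[j] = d; gy[j] = std::exp(-d * d * inv2s2);
    }
    for (int k = 0; k < nk; ++k) {
      double d = g.oz + (k0 + k) * g.vz - pz;
      dz[k] = d; gz[k] = std::exp(-d * d * inv2s2);
    }
    const double A = amp[a] * norm;
    double sx = 0, sy = 0, sz = 0;
    for (int k = 0; k < nk; ++k) {
      const double dz2 = dz[k] * dz[k];
      for (int j = 0; j < nj; ++j) {
        const double r2yz = dy[j] * dy[j] + dz2;
        if (r2yz > rcut2) continue;
        const double gyz = gy[j] * gz[k];
        long base = g.idx(i0, j0 + j, k0 + k);
        for (int i = 0; i < ni; ++i) {
          if (dx[i] * dx[i] + r2yz > rcut2) continue;
          long v = base + i;
          if (!mask[v]) continue;
          // d cc / d m_v, frozen mask
          const double w = c1 * (t[v] - s.tbar) - c2 * (dens[v] - s.mbar);
          // d m_v / d p = contribution * (voxel - p) / sigma^2
          const double contrib = A * gx[i] * gyz * invs2;
          const double ww = w * contrib;
          sx += ww * dx[i]; sy += ww * dy[j]; sz += ww * dz[k];
        }
      }
    }
    grad[3 * a] += sx; grad[3 * a + 1] += sy; grad[3 * a + 2] += sz;
  }
}

// ---------------------------------------------------------------------------
// Lightweight force field
// ---------------------------------------------------------------------------

// GROMACS-style force-switch constants for a potential term c * r^{-alpha}:
// the pair force is smoothly taken to zero between r1 and rc, and the
// potential is the exact integral of the modified force.
struct SwitchConst {
  double alpha, A, B, C;
  void init(double alpha_, double r1, double rc) {
    alpha = alpha_;
    const double d = rc - r1;
    A = -alpha * ((alpha + 4.0) * rc - (alpha + 1.0) * r1) /
        (std::pow(rc, alpha + 2.0) * d * d);
    B = alpha * ((alpha + 3.0) * rc - (alpha + 1.0) * r1) /
        (std::pow(rc, alpha + 2.0) * d * d * d);
    C = std::pow(rc, -alpha) - A / 3.0 * d * d * d - B / 4.0 * d * d * d * d;
  }
  // potential (per unit coefficient) and dV/dr at distance r
  inline void eval(double r, double r1, double rc, double& V, double& dV) const {
    if (r > rc) { V = 0; dV = 0; return; }
    const double rma = std::pow(r, -alpha);
    if (r <= r1) {
      V = rma - C;
      dV = -alpha * rma / r;
    } else {
      const double d = r - r1;
      V = rma - A / 3.0 * d * d * d - B / 4.0 * d * d * d * d - C;
      dV = -alpha * rma / r - A * d * d - B * d * d * d;
    }
  }
};

struct FFData {
  Rcpp::NumericMatrix bonds;    // i, j, r0, kb   (1-based indices)
  Rcpp::NumericMatrix angles;   // i, j, k, theta0, ktheta
  std::vector<double> sig, eps, q;
  std::unordered_set<long long> excl, s14;
  double scale14, dielectric, r1, rc;
  SwitchConst sw1, sw6, sw12;
  bool anyCharge;

  static long long key(int i, int j, int n) {
    return i < j ? (long long)i * n + j : (long long)j * n + i;
  }

  void init(Rcpp::NumericMatrix bonds_, Rcpp::NumericMatrix angles_,
            Rcpp::NumericVector sig_, Rcpp::NumericVector eps_,
            Rcpp::NumericVector q_, Rcpp::IntegerMatrix excl_,
            Rcpp::IntegerMatrix s14_, double scale14_, double diel_,
            double r1_, double rc_) {
    bonds = bonds_; angles = angles_;
    sig.assign(sig_.begin(), sig_.end());
    eps.assign(eps_.begin(), eps_.end());
    q.assign(q_.begin(), q_.end());
    scale14 = scale14_; dielectric = diel_; r1 = r1_; rc = rc_;
    const int n = sig.size();
    for (int r = 0; r < excl_.nrow(); ++r)
      excl.insert(key(excl_(r, 0) - 1, excl_(r, 1) - 1, n));
    for (int r = 0; r < s14_.nrow(); ++r)
      s14.insert(key(s14_(r, 0) - 1, s14_(r, 1) - 1, n));
    sw1.init(1.0, r1, rc); sw6.init(6.0, r1, rc); sw12.init(12.0, r1, rc);
    anyCharge = false;
    for (double qi : q) if (qi != 0.0) { anyCharge = true; break; }
  }
};

// One nonbonded pair (LJ + Coulomb with force switch). Returns energy terms
// and accumulates the force on atom i (fi) and j (-fi).
inline void em_nb_pair(const FFData& ff, int i, int j, double dx, double dy,
                       double dz, double scale, double& elj, double& ecoul,
                       double* F) {
  const double r2 = dx * dx + dy * dy + dz * dz;
  if (r2 > ff.rc * ff.rc) return;
  const double r = std::sqrt(r2);
  if (r < 0.1)
    Rcpp::stop("overlapping atoms %d and %d (distance %.4f A)", i + 1, j + 1, r);
  const double sij = 0.5 * (ff.sig[i] + ff.sig[j]);
  const double eij = std::sqrt(ff.eps[i] * ff.eps[j]);
  const double c6 = 4.0 * eij * std::pow(sij, 6.0);
  const double c12 = 4.0 * eij * std::pow(sij, 12.0);
  double V6, dV6, V12, dV12;
  ff.sw6.eval(r, ff.r1, ff.rc, V6, dV6);
  ff.sw12.eval(r, ff.r1, ff.rc, V12, dV12);
  double V = c12 * V12 - c6 * V6;
  double dV = c12 * dV12 - c6 * dV6;
  elj += scale * V;
  if (ff.anyCharge && ff.q[i] != 0.0 && ff.q[j] != 0.0) {
    const double cc = EM_FCOUL * ff.q[i] * ff.q[j] / ff.dielectric;
    double V1, dV1;
    ff.sw1.eval(r, ff.r1, ff.rc, V1, dV1);
    ecoul += scale * cc * V1;
    dV += cc * dV1;
  }
  const double fr = -scale * dV / r;   // force magnitude / r along (i - j)
  F[3 * i] += fr * dx; F[3 * i + 1] += fr * dy; F[3 * i + 2] += fr * dz;
  F[3 * j] -= fr * dx; F[3 * j + 1] -= fr * dy; F[3 * j + 2] -= fr * dz;
}

// Full restraint-field energy and forces (harmonic bonds and angles plus
// nonbonded with exclusions). F must be zeroed by the caller (length 3n).
inline double em_ff_energy_forces(const double* x, int n, const FFData& ff,
                                  double* F, double* elj_out = nullptr,
                                  double* ecoul_out = nullptr) {
  double ebond = 0, eangle = 0, elj = 0, ecoul = 0;
  for (int b = 0; b < ff.bonds.nrow(); ++b) {
    const int i = (int)ff.bonds(b, 0) - 1, j = (int)ff.bonds(b, 1) - 1;
    const double r0 = ff.bonds(b, 2), kb = ff.bonds(b, 3);
    const double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
                 dz = x[3 * i + 2] - x[3 * j + 2];
    const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    const double dr = r - r0;
    ebond += 0.5 * kb * dr * dr;
    const double fr = -kb * dr / std::max(r, 1e-12);
    F[3 * i] += fr * dx; F[3 * i + 1] += fr * dy; F[3 * i + 2] += fr * dz;
    F[3 * j] -= fr * dx; F[3 * j + 1] -= fr * dy; F[3 * j + 2] -= fr * dz;
  }
  for (int t = 0; t < ff.angles.nrow(); ++t) {
    const int i = (int)ff.angles(t, 0) - 1, j = (int)ff.angles(t, 1) - 1,
              k = (int)ff.angles(t, 2) - 1;
    const double th0 = ff.angles(t, 3), kt = ff.angles(t, 4);
    const double rijx = x[3 * i] - x[3 * j], rijy = x[3 * i + 1] - x[3 * j + 1],
                 rijz = x[3 * i + 2] - x[3 * j + 2];
    const double rkjx = x[3 * k] - x[3 * j], rkjy = x[3 * k + 1] - x[3 * j + 1],
                 rkjz = x[3 * k + 2] - x[3 * j + 2];
    const double nij = std::sqrt(rijx * rijx + rijy * rijy + rijz * rijz);
    const double nkj = std::sqrt(rkjx * rkjx + rkjy * rkjy + rkjz * rkjz);
    double cth = (rijx * rkjx + rijy * rkjy + rijz * rkjz) / (nij * nkj);
    if (cth > 1.0) cth = 1.0; if (cth < -1.0) cth = -1.0;
    const double th = std::acos(cth);
    const double dth = th - th0;
    eangle += 0.5 * kt * dth * dth;
    double sth = std::sqrt(1.0 - cth * cth);
    if (sth < 1e-8) sth = 1e-8;
    const double c = -kt * dth / sth;    // dV/d(cos theta) prefactor chain
    // d cos/d ri = rkj/(nij nkj) - cth * rij / nij^2
    const double gix = c * (rkjx / (nij * nkj) - cth * rijx / (nij * nij));
    const double giy = c * (rkjy / (nij * nkj) - cth * rijy / (nij * nij));
    const double giz = c * (rkjz / (nij * nkj) - cth * rijz / (nij * nij));
    const double gkx = c * (rijx / (nij * nkj) - cth * rkjx / (nkj * nkj));
    const double gky = c * (rijy / (nij * nkj) - cth * rkjy / (nkj * nkj));
    const double gkz = c * (rijz / (nij * nkj) - cth * rkjz / (nkj * nkj));
    F[3 * i] -= gix; F[3 * i + 1] -= giy; F[3 * i + 2] -= giz;
    F[3 * k] -= gkx; F[3 * k + 1] -= gky; F[3 * k + 2] -= gkz;
    F[3 * j] += gix + gkx; F[3 * j + 1] += giy + gky; F[3 * j + 2] += giz + gkz;
  }
  const int nn = n;
  for (int i = 0; i < nn; ++i) {
    for (int j = i + 1; j < nn; ++j) {
      const long long k = FFData::key(i, j, nn);
      if (ff.excl.count(k)) continue;
      const double scale = ff.s14.count(k) ? ff.scale14 : 1.0;
      em_nb_pair(ff, i, j, x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1],
                 x[3 * i + 2] - x[3 * j + 2], scale, elj, ecoul, F);
    }
  }
  if (elj_out) *elj_out = elj;
  if (ecoul_out) *ecoul_out = ecoul;
  return ebond + eangle + elj + ecoul;
}

#endif
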