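#include "emlig.h"
using namespace Rcpp;

static FFData make_ff2(List ff) {
  FFData d;
  d.init(ff["bonds"], ff["angles"], ff["ljSigma"], ff["ljEps"], ff["charges"],
         ff["exclusions"], ff["scaled14"], ff["scale14"], ff["dielectric"],
         ff["r1"], ff["rc"]);
  return d;
}

// Steepest-descent minimisation with optional per-atom harmonic positional
// restraints (k in kJ/mol/A^2) to reference coordinates.
// [[Rcpp::export]]
List cpp_minimize(NumericMatrix P, List ff, NumericVector restraintK,
                  NumericMatrix refP, int steps) {
  FFData d = make_ff2(ff);
  const int n = P.nrow();
  std::vector<double> x(3 * n), ref(3 * n), F(3 * n), xnew(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) {
      x[3 * i + c] = P(i, c);
      ref[3 * i + c] = refP(i, c);
    }
  auto energyForces = [&](const std::vector<double>& xx, std::vector<double>& FF) {
    std::fill(FF.begin(), FF.end(), 0.0);
    double e = em_ff_energy_forces(xx.data(), n, d, FF.data());
    for (int i = 0; i < n; ++i) {
      const double k = restraintK[i];
      if (k <= 0) continue;
      for (int c = 0; c < 3; ++c) {
        const double dxc = xx[3 * i + c] - ref[3 * i + c];
        e += 0.5 * k * dxc * dxc;
        FF[3 * i + c] -= k * dxc;
      }
    }
    return e;
  };
  double e = energyForces(x, F);
  double h = 0.01;                          // max displacement, Angstrom
  for (int s = 0; s < steps; ++s) {
    double fmax = 1e-12;
    for (double f : F) fmax = std::max(fmax, std::fabs(f));
    if (fmax < 1e-6) break;
    for (int i = 0; i < 3 * n; ++i) xnew[i] = x[i] + h * F[i] / fmax;
    std::vector<double> Fnew(3 * n);
    double enew = energyForces(xnew, Fnew);
    if (enew < e) {
      x.swap(xnew); F.swap(Fnew); e = enew; h = std::min(h * 1.2, 0.5);
    } else {
      h *= 0.5;
      if (h < 1e-8) break;
    }
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) out(i, c) = x[3 * i + c];
  return List::create(_["coords"] = out, _["energy"] = e);
}

struct EntitySel {
  std::vector<int> idx;        // 0-based heavy-atom indices
  std::vector<double> amp;
};

static EntitySel make_sel(IntegerVector idx1, NumericVector ampAll) {
  EntitySel s;
  s.idx.reserve(idx1.size());
  for (int i = 0; i < idx1.size(); ++i) {
    s.idx.push_back(idx1[i] - 1);
    s.amp.push_back(ampAll[idx1[i] - 1]);
  }
  return s;
}

static double entity_cc(const std::vector<double>& x, const EntitySel& sel,
                        const GridGeom& g, const double* target, double sigma,
                        double rcs, double maskR, bool meanSub,
                        std::vector<double>& dens,
                        std::vector<unsigned char>& mask) {
  const int m = sel.idx.size();
  std::vector<double> X(m), Y(m), Z(m);
  for (int a = 0; a < m; ++a) {
    X[a] = x[3 * sel.idx[a]];
    Y[a] = x[3 * sel.idx[a] + 1];
    Z[a] = x[3 * sel.idx[a] + 2];
  }
  std::fill(dens.begin(), dens.end(), 0.0);
  std::fill(mask.begin(), mask.end(), 0);
  em_add_density(X.data(), Y.data(), Z.data(), sel.amp.data(), m, g, sigma,
                 rcs, maskR, &dens, &mask);
  CCStats s = em_masked_cc(dens, target, mask, meanSub);
  return s.cc;
}

// Density-guided Langevin dynamics (BAOAB) on the restraint field, with map
// forces k * d(cc)/dx recomputed every `nint` steps and held between
// recomputations, adaptive growth of k when cc stalls, per-component force
// capping with graceful termination, and monitor-trace sampling.
// [[Rcpp::export]]
List cpp_run_flexfit(NumericMatrix P, NumericVector mass, List ff,
                     NumericVector target, IntegerVector dims,
                     NumericVector origin, NumericVector voxel, double sigma,
                     double rcs, double maskRMon, double maskRForce,
                     bool meanSub, NumericVector ampAll,
                     IntegerVector denseIdx, IntegerVector ligHeavy,
                     IntegerVector pocHeavy, IntegerVector protHeavy,
                     IntegerVector protAll, IntegerVector ligAll,
                     int nLigHeavy, double dt_fs, double temperature,
                     double gamma_ps, double k0, int nint, bool adaptive,
                     int checkInterval, double ccEps, double growth,
                     double kMax, double duration_ps, double forceCap,
                     double traceInterval_fs, double frameInterval_fs) {
  FFData d = make_ff2(ff);
  GridGeom g;
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.ox = origin[0]; g.oy = origin[1]; g.oz = origin[2];
  g.vx = voxel[0]; g.vy = voxel[1]; g.vz = voxel[2];
  const double* tv = REAL(target);

  const int n = P.nrow();
  std::vector<double> x(3 * n), v(3 * n, 0.0), Fff(3 * n), Fdens(3 * n, 0.0),
      Ftot(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = P(i, c);

  EntitySel selDens = make_sel(denseIdx, ampAll);
  EntitySel selLig = make_sel(ligHeavy, ampAll);
  EntitySel selPoc = make_sel(pocHeavy, ampAll);
  EntitySel selProt = make_sel(protHeavy, ampAll);

  std::vector<double> dens(g.nvox());
  std::vector<unsigned char> mask(g.nvox());

  const double dt = dt_fs / 1000.0;          // ps
  const long nsteps = (long)std::llround(duration_ps * 1000.0 / dt_fs);
  const long traceEvery = std::max(1L, (long)std::llround(traceInterval_fs / dt_fs));
  const long frameEvery = std::max(1L, (long)std::llround(frameInterval_fs / dt_fs));
  const double c1 = std::exp(-gamma_ps * dt);
  const double c2 = std::sqrt(1.0 - c1 * c1);
  const double kT100 = EM_KB * temperature * EM_ACC;  // for velocity sigma^2 * m

  double k = k0, ccGlobal = NA_REAL, ccRef = NA_REAL;
  long nApplied = 0;
  bool terminated = false;

  std::vector<double> trT, trL, trP, trPr, trPlie, trK;
  std::vector<double> evT; std::vector<std::string> evL;
  List frames; std::vector<double> frameT;

  auto plieNow = [&]() {
    double elj = 0, ecoul = 0;
    std::vector<double> Fd(3 * n, 0.0);
    for (int a = 0; a < protAll.size(); ++a) {
      const int i = protAll[a] - 1;
      for (int b = 0; b < ligAll.size(); ++b) {
        const int j = ligAll[b] - 1;
        em_nb_pair(d, i, j, x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1],
                   x[3 * i + 2] - x[3 * j + 2], 1.0, elj, ecoul, Fd.data());
      }
    }
    return (elj + ecoul) / std::max(1, nLigHeavy);
  };
  auto sampleTrace = [&](double t_ps) {
    trT.push_back(t_ps);
    trL.push_back(entity_cc(x, selLig, g, tv, sigma, rcs, maskRMon, meanSub,
                            dens, mask));
    trP.push_back(entity_cc(x, selPoc, g, tv, sigma, rcs, maskRMon, meanSub,
                            dens, mask));
    trPr.push_back(entity_cc(x, selProt, g, tv, sigma, rcs, maskRMon, meanSub,
                             dens, mask));
    trPlie.push_back(plieNow());
    trK.push_back(k);
  };
  auto saveFrame = [&](double t_ps) {
    NumericMatrix fr(n, 3);
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c) fr(i, c) = x[3 * i + c];
    frames.push_back(fr);
    frameT.push_back(t_ps);
  };
  auto computeDensityForce = [&]() {
    const int m = selDens.idx.size();
    std::vector<double> X(m), Y(m), Z(m);
    for (int a = 0; a < m; ++a) {
      X[a] = x[3 * selDens.idx[a]];
      Y[a] = x[3 * selDens.idx[a] + 1];
      Z[a] = x[3 * selDens.idx[a] + 2];
    }
    std::fill(dens.begin(), dens.end(), 0.0);
    std::fill(mask.begin(), mask.end(), 0);
    em_add_density(X.data(), Y.data(), Z.data(), selDens.amp.data(), m, g,
                   sigma, rcs, maskRForce, &dens, &mask);
    CCStats s = em_masked_cc(dens, tv, mask, meanSub);
    ccGlobal = s.cc;
    std::vector<double> grad(3 * m, 0.0);
    em_cc_gradient(X.data(), Y.data(), Z.data(), selDens.amp.data(), m, g,
                   sigma, rcs, dens, tv, mask, s, grad.data());
    std::fill(Fdens.begin(), Fdens.end(), 0.0);
    for (int a = 0; a < m; ++a)
      for (int c = 0; c < 3; ++c)
        Fdens[3 * selDens.idx[a] + c] = k * grad[3 * a + c];
    ++nApplied;
    if (adaptive && checkInterval > 0 && nApplied % checkInterval == 0) {
      if (!ISNA(ccRef) && ccGlobal - ccRef < ccEps)
        k = std::min(k * growth, kMax);
      ccRef = ccGlobal;
    }
  };
  // returns false on termination request (force cap breached)
  auto totalForce = [&](double t_ps) {
    std::fill(Fff.begin(), Fff.end(), 0.0);
    em_ff_energy_forces(x.data(), n, d, Fff.data());
    int nCapped = 0;
    for (int i = 0; i < n; ++i) {
      bool capped = false;
      for (int c = 0; c < 3; ++c) {
        double f = Fff[3 * i + c] + Fdens[3 * i + c];
        if (f > forceCap) { f = forceCap; capped = true; }
        if (f < -forceCap) { f = -forceCap; capped = true; }
        Ftot[3 * i + c] = f;
      }
      if (capped) ++nCapped;
    }
    if (nCapped > 0.01 * n) {
      evT.push_back(t_ps);
      evL.push_back("force_cap_exceeded");
      return false;
    }
    return true;
  };

  sampleTrace(0.0);
  saveFrame(0.0);
  bool aborted = false;
  if (nsteps > 0) {
    computeDensityForce();
    if (!totalForce(0.0)) { terminated = true; }
    for (long step = 0; step < nsteps && !terminated && !aborted; ++step) {
      const double t_ps = (step + 1) * dt;
      // B: half kick
      for (int i = 0; i < n; ++i) {
        const double am = EM_ACC / mass[i];
        for (int c = 0; c < 3; ++c)
          v[3 * i + c] += 0.5 * dt * Ftot[3 * i + c] * am;
      }
      // A: half drift
      for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
      // O: friction + noise
      if (temperature > 0) {
        for (int i = 0; i < n; ++i) {
          const double sv = std::sqrt(kT100 / mass[i]);
          for (int c = 0; c < 3; ++c)
            v[3 * i + c] = c1 * v[3 * i + c] + c2 * sv * R::norm_rand();
        }
      } else {
        for (int i = 0; i < 3 * n; ++i) v[i] = c1 * v[i];
      }
      // A: half drift
      for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
      // forces at new positions
      if ((step + 1) % nint == 0) computeDensityForce();
      if (!totalForce(t_ps)) terminated = true;
      // B: half kick
      for (int i = 0; i < n; ++i) {
        const double am = EM_ACC / mass[i];
        for (int c = 0; c < 3; ++c)
          v[3 * i + c] += 0.5 * dt * Ftot[3 * i + c] * am;
      }
      for (int i = 0; i < 3 * n; ++i)
        if (!std::isfinite(x[i])) {
          evT.push_back(t_ps);
          evL.push_back("non_finite_coordinates");
          aborted = true;
          break;
        }
      if (aborted) break;
      const bool last = terminated || step + 1 == nsteps;
      if ((step + 1) % traceEvery == 0 || last) sampleTrace(t_ps);
      if ((step + 1) % frameEvery == 0 || last) saveFrame(t_ps);
      if ((step + 1) % 2000 == 0) Rcpp::checkUserInterrupt();
    }
  }

  NumericMatrix xOut(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) xOut(i, c) = x[3 * i + c];
  return List::create(
      _["trace"] = DataFrame::create(
          _["time_ps"] = trT, _["cc_ligand"] = trL, _["cc_pocket"] = trP,
          _["cc_protein"] = trPr, _["plie_per_heavy_atom"] = trPlie,
          _["k_current"] = trK),
      _["frames"] = frames, _["frame_times"] = frameT,
      _["event_times"] = evT, _["event_labels"] = wrap(evL),
      _["coords"] = xOut, _["k_final"] = k, _["terminated"] = terminated,
      _["aborted"] = aborted);
}
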