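#include "emlig.h"
using namespace Rcpp;

static GridGeom make_geom(IntegerVector dims, NumericVector origin,
                          NumericVector voxel) {
  GridGeom g;
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.ox = origin[0]; g.oy = origin[1]; g.oz = origin[2];
  g.vx = voxel[0]; g.vy = voxel[1]; g.vz = voxel[2];
  return g;
}

// [[Rcpp::export]]
NumericVector cpp_min_dist2(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      const double dx = A(i, 0) - B(j, 0), dy = A(i, 1) - B(j, 1),
                   dz = A(i, 2) - B(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = best;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_simulate_density(NumericMatrix P, NumericVector amp,
                                   IntegerVector dims, NumericVector origin,
                                   NumericVector voxel, double sigma,
                                   double rcs) {
  GridGeom g = make_geom(dims, origin, voxel);
  std::vector<double> dens(g.nvox(), 0.0);
  const int n = P.nrow();
  std::vector<double> X(n), Y(n), Z(n);
  for (int i = 0; i < n; ++i) { X[i] = P(i, 0); Y[i] = P(i, 1); Z[i] = P(i, 2); }
  em_add_density(X.data(), Y.data(), Z.data(), REAL(amp), n, g, sigma, rcs,
                 0.0, &dens, nullptr);
  NumericVector out(dens.begin(), dens.end());
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_support_mask(NumericMatrix P, IntegerVector dims,
                               NumericVector origin, NumericVector voxel,
                               double sigma, double rcs) {
  GridGeom g = make_geom(dims, origin, voxel);
  std::vector<unsigned char> mask(g.nvox(), 0);
  const int n = P.nrow();
  std::vector<double> X(n), Y(n), Z(n), amp(n, 1.0);
  for (int i = 0; i < n; ++i) { X[i] = P(i, 0); Y[i] = P(i, 1); Z[i] = P(i, 2); }
  em_add_density(X.data(), Y.data(), Z.data(), amp.data(), n, g, sigma, rcs,
                 rcs, nullptr, &mask);
  LogicalVector out(mask.size());
  for (size_t v = 0; v < mask.size(); ++v) out[v] = mask[v] != 0;
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export]]
List cpp_masked_cc(NumericVector model, NumericVector target,
                   LogicalVector mask, bool meanSub) {
  const long nv = model.size();
  if (target.size() != nv || mask.size() != nv)
    stop("grids and mask must have identical dimensions");
  std::vector<double> m(REAL(model), REAL(model) + nv);
  std::vector<unsigned char> mk(nv);
  for (long v = 0; v < nv; ++v) mk[v] = mask[v] ? 1 : 0;
  CCStats s = em_masked_cc(m, REAL(target), mk, meanSub);
  return List::create(_["cc"] = s.cc, _["n"] = (double)s.n);
}

// cc of a model density simulated from P against target, over the
// model-support mask (or a caller-frozen mask), plus the analytic gradient.
// [[Rcpp::export]]
List cpp_cc_and_gradient(NumericMatrix P, NumericVector amp,
                         NumericVector target, IntegerVector dims,
                         NumericVector origin, NumericVector voxel,
                         double sigma, double rcs, double maskR,
                         bool meanSub, bool wantGradient,
                         Nullable<LogicalVector> frozenMask = R_NilValue) {
  GridGeom g = make_geom(dims, origin, voxel);
  if (target.size() != g.nvox()) stop("target does not match grid dims");
  const int n = P.nrow();
  std::vector<double> X(n), Y(n), Z(n);
  for (int i = 0; i < n; ++i) { X[i] = P(i, 0); Y[i] = P(i, 1); Z[i] = P(i, 2); }
  std::vector<double> dens(g.nvox(), 0.0);
  std::vector<unsigned char> mask(g.nvox(), 0);
  em_add_density(X.data(), Y.data(), Z.data(), REAL(amp), n, g, sigma, rcs,
                 maskR, &dens, &mask);
  if (frozenMask.isNotNull()) {
    LogicalVector fm(frozenMask);
    if (fm.size() != g.nvox()) stop("frozen mask does not match grid dims");
    for (long v = 0; v < g.nvox(); ++v) mask[v] = fm[v] ? 1 : 0;
  }
  CCStats s = em_masked_cc(dens, REAL(target), mask, meanSub);
  List out = List::create(_["cc"] = s.cc, _["n"] = (double)s.n);
  if (wantGradient) {
    NumericMatrix grad(3, n);
    std::fill(grad.begin(), grad.end(), 0.0);
    em_cc_gradient(X.data(), Y.data(), Z.data(), REAL(amp), n, g, sigma, rcs,
                   dens, REAL(target), mask, s, REAL(grad));
    out["gradient"] = grad;
  }
  return out;
}

// Trilinear resampling of src at the voxel centres of the reference grid;
// points outside the source extent get 0.
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector src, IntegerVector sdims,
                           NumericVector sorigin, NumericVector svoxel,
                           IntegerVector rdims, NumericVector rorigin,
                           NumericVector rvoxel) {
  GridGeom gs = make_geom(sdims, sorigin, svoxel);
  GridGeom gr = make_geom(rdims, rorigin, rvoxel);
  NumericVector out((long)gr.nx * gr.ny * gr.nz);
  const double* sv = REAL(src);
  long nInside = 0;
  for (int k = 0; k < gr.nz; ++k) {
    const double z = gr.oz + k * gr.vz;
    const double fz = (z - gs.oz) / gs.vz;
    for (int j = 0; j < gr.ny; ++j) {
      const double y = gr.oy + j * gr.vy;
      const double fy = (y - gs.oy) / gs.vy;
      for (int i = 0; i < gr.nx; ++i) {
        const double x = gr.ox + i * gr.vx;
        const double fx = (x - gs.ox) / gs.vx;
        double val = 0.0;
        const double eps = 1e-9;   // tolerate float round-off at the edges
        if (fx >= -eps && fx <= gs.nx - 1 + eps && fy >= -eps &&
            fy <= gs.ny - 1 + eps && fz >= -eps && fz <= gs.nz - 1 + eps) {
          int i0 = (int)std::floor(fx), j0 = (int)std::floor(fy),
              k0 = (int)std::floor(fz);
          if (i0 == gs.nx - 1) --i0;
          if (j0 == gs.ny - 1) --j0;
          if (k0 == gs.nz - 1) --k0;
          if (i0 < 0) i0 = 0; if (j0 < 0) j0 = 0; if (k0 < 0) k0 = 0;
          const double tx = fx - i0, ty = fy - j0, tz = fz - k0;
          double c = 0;
          for (int dk = 0; dk < 2; ++dk)
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di) {
                const double w = (di ? tx : 1 - tx) * (dj ? ty : 1 - ty) *
                                 (dk ? tz : 1 - tz);
                c += w * sv[gs.idx(i0 + di, j0 + dj, k0 + dk)];
              }
          val = c;
          ++nInside;
        }
        out[gr.idx(i, j, k)] = val;
      }
    }
  }
  if (nInside == 0) stop("grids do not overlap; cannot resample");
  out.attr("dim") = rdims;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_min_dist2_self(NumericMatrix A) {
  const int n = A.nrow();
  NumericVector out(n, R_PosInf);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      const double dx = A(i, 0) - A(j, 0), dy = A(i, 1) - A(j, 1),
                   dz = A(i, 2) - A(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < out[i]) out[i] = d2;
      if (d2 < out[j]) out[j] = d2;
    }
  return out;
}

// all pairs (i < j) with distance below cutoff; columns i, j, dist^2
// [[Rcpp::export]]
NumericMatrix cpp_all_pairs_within(NumericMatrix A, double cutoff) {
  const int n = A.nrow();
  const double c2 = cutoff * cutoff;
  std::vector<double> rows;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      const double dx = A(i, 0) - A(j, 0), dy = A(i, 1) - A(j, 1),
                   dz = A(i, 2) - A(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < c2) { rows.push_back(i + 1); rows.push_back(j + 1); rows.push_back(d2); }
    }
  const int np = rows.size() / 3;
  NumericMatrix out(np, 3);
  for (int r = 0; r < np; ++r)
    for (int c = 0; c < 3; ++c) out(r, c) = rows[3 * r + c];
  return out;
}
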