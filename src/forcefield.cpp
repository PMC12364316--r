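#include "emlig.h"
using namespace Rcpp;

static FFData make_ff(List ff) {
  FFData d;
  d.init(ff["bonds"], ff["angles"], ff["ljSigma"], ff["ljEps"], ff["charges"],
         ff["exclusions"], ff["scaled14"], ff["scale14"], ff["dielectric"],
         ff["r1"], ff["rc"]);
  return d;
}

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix P, List ff) {
  FFData d = make_ff(ff);
  const int n = P.nrow();
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = P(i, c);
  NumericMatrix F(3, n);
  std::fill(F.begin(), F.end(), 0.0);
  double elj = 0, ecoul = 0;
  const double e = em_ff_energy_forces(x.data(), n, d, REAL(F), &elj, &ecoul);
  return List::create(_["energy"] = e, _["forces"] = F, _["lj"] = elj,
                      _["coulomb"] = ecoul);
}

// Protein-ligand nonbonded interaction energy: LJ + Coulomb over cross
// pairs only, with the same force switch as the restraint field.
// [[Rcpp::export]]
List cpp_plie(NumericMatrix P, List ff, IntegerVector protIdx,
              IntegerVector ligIdx) {
  FFData d = make_ff(ff);
  std::vector<double> F(3 * (size_t)P.nrow(), 0.0);
  double elj = 0, ecoul = 0;
  for (int a = 0; a < protIdx.size(); ++a) {
    const int i = protIdx[a] - 1;
    for (int b = 0; b < ligIdx.size(); ++b) {
      const int j = ligIdx[b] - 1;
      em_nb_pair(d, i, j, P(i, 0) - P(j, 0), P(i, 1) - P(j, 1),
                 P(i, 2) - P(j, 2), 1.0, elj, ecoul, F.data());
    }
  }
  return List::create(_["lj"] = elj, _["coulomb"] = ecoul,
                      _["total"] = elj + ecoul);
}
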