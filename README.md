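# emligfit

Building a small-molecule ligand into a cryo-EM map is routinely harder than
building the protein around it: the ligand density is local, often worse than
the nominal map resolution, and standard refinement tools are tuned for
polypeptides. `emligfit` implements, as a self-contained R toolkit, the
core of a pipeline that addresses this by combining externally produced
candidate models of a protein–ligand complex (e.g. AlphaFold3-class
predictions) with density-guided molecular dynamics:

1. **Score and rank** candidate complexes by masked model-to-map
   cross-correlation of the ligand after rigid-body alignment into the map.
2. **Rigid-body fit** by gradient ascent of the global cross-correlation
   over rotations and translations (quaternion parameterisation, seeded
   multi-start).
3. **Flexibly fit** the best candidate with Langevin dynamics: every heavy
   atom feels a force `k · ∂CC/∂x` along the gradient of the similarity
   between a density simulated from the moving model and the experimental
   map, on top of a lightweight structure-native restraint field (harmonic
   bonds/angles at their observed values, elastic-network native contacts,
   Lennard-Jones with a GROMACS-style force switch at 10/12 Å). The force
   constant (default `k = 10³ kJ/mol`, applied every `N = 2` steps of a 2 fs
   integrator at 310 K) grows adaptively whenever the fit stalls.
4. **Evaluate** with per-entity (ligand / pocket / whole protein)
   cross-correlations, the accuracy metric
   `accuracy (%) = (1 − |CC_model − CC_ground-truth| / CC_max) × 100`
   with `CC_max = 1`, and a protein–ligand interaction energy (PLIE,
   kJ/mol per ligand heavy atom) as a chemical-plausibility monitor.

Density is simulated as a sum of atom-centred Gaussians whose FWHM equals
the nominal resolution, with atomic-number amplitudes; cross-correlations
are Pearson correlations over a tight model-support mask (1.5 σ around the
selection's heavy atoms). A fully synthetic, seeded fixture generator
(`makeFixture()`) builds a solenoidal pseudo-protein with a concave pocket,
a ring-plus-tail ligand, a simulated target map at 2.7–3.7 Å-like
resolution, and graded perturbed candidates — so the entire pipeline is
testable offline.

## Worked example

```r
library(emligfit)

spec <- fixtureSpec(seed = 0)        # 3.2 A map, 5 candidates, 3 A ligand error
fx   <- makeFixture(spec)
prm  <- mapSimParams(3.2)

rk <- rankCandidates(fx@candidates, fx@targetMap, prm, nRestarts = 1, seed = 0)
rk$table[1, ]
#>            id ligand_cc pocket_cc rank
#> 1 candidate_1 0.4558707 0.7479855    1

best <- candidateModels(rk$models)[[rk$bestId]]
fit  <- runFlexFit(best, fx@targetMap,
                   fitConfig(duration = 50, seed = 0, preRelaxSteps = 500),
                   prm)
td <- traceData(fit$trace)
round(td[c(1, nrow(td)), c("time_ps", "cc_ligand", "cc_protein",
                           "plie_per_heavy_atom")], 3)
#>      time_ps cc_ligand cc_protein plie_per_heavy_atom
#> 1          0     0.522      0.996              -4.298
#> 1001      50     0.946      0.987              -3.756
```

The ligand cross-correlation rises from 0.52 to 0.95 — against a
ground-truth self-correlation of 0.96 — while the protein stays in its
density and the PLIE stays favourable (negative); the final ligand pose is
0.56 Å RMSD from the ground truth that generated the map. `buildReport()`
turns such runs into the per-entity accuracy table, with the fitted value
taken from the final frame or averaged over the last 20 frames.

The package also ships the published ten-system benchmark table
(`benchmarkCC()`): per-entity CCs of the best AI prediction, the flexibly
fitted model and the deposited structure for ten drug-target complexes
(two kinases, two GPCRs, six solute transporters), plus curation-filter
predicates (`curationFilter()`) of the kind used to assemble such
benchmarks (cryo-EM, monomeric, QED ≥ 0.7, ≤ 1200 residues, conclusive
pocket contacts, non-covalent, 2022–2024 release window).

## Acceptance script

`scripts/acceptance.R` recomputes the benchmark's headline accuracy
figures from scratch with the installed package — it loads the benchmark
CC table, applies the package's accuracy metric, and reduces to the
documented group minima — and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
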