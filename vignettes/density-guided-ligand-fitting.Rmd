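---
title: "Density-guided ligand fitting: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-guided ligand fitting: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(emligfit)
```

This vignette is the package's own account of the science it implements:
the density model, the similarity functional and its gradient, the
restraint field, the Langevin fitting engine, the evaluation metrics, and
the synthetic world the tests run in — together with the numerical choices
that were genuinely open and how they were settled.

## The problem

Cryo-EM reconstructions of drug–target complexes routinely resolve the
protein better than the bound small molecule, and AI structure predictors
(AlphaFold3-class models) often predict the protein fold well while
misplacing or misorienting the ligand. The pipeline implemented here takes
*candidate models* of the complex from any source, selects the one whose
ligand best explains the experimental density, and then lets the whole
model relax under forces derived from the map itself, so that ligand pose
and pocket conformation are refined simultaneously. The deposited
experimental structure, when available, is used only for *evaluation* —
never during fitting.

## Density simulation

A model's density is a sum of isotropic 3-D Gaussians over its heavy
atoms, evaluated at voxel centres:

$$\rho(\mathbf{v}) = \sum_i A_i\,
  \frac{1}{(2\pi)^{3/2}\sigma^3}
  \exp\!\left(-\frac{\lVert\mathbf{v}-\mathbf{x}_i\rVert^2}{2\sigma^2}\right),
  \qquad \sigma = \frac{d}{2\sqrt{2\ln 2}},$$

so that the Gaussian FWHM equals the nominal map resolution $d$ — the
standard convention when a tool must pick one width per map.
Amplitudes $A_i$ default to the atomic number (approximating scattering
mass); a uniform mode exists for tests. Contributions are truncated
spherically at 4σ (relative error ≤ 3·10⁻⁴); voxel values are point
evaluations, not volume integrals, because the correlation normalisation
absorbs the difference. Hydrogens never contribute: maps at 2.7–3.7 Å
carry no hydrogen signal.

## Masked cross-correlation and its gradient

Fit quality is the Pearson correlation between simulated and experimental
density restricted to a mask (the no-mean-subtraction dialect is available
via `mapSimParams(meanSubtract = FALSE)`, since external CC tools support
both). Mean subtraction makes the score invariant to affine rescaling of
either map.

**Two mask radii are used, deliberately.** Scoring masks
(`entityCC()`, ranking, the monitor traces) cover voxels within
1.5 σ of the selection's heavy atoms. Wide masks (the full 4σ support)
are used for the rigid-body objective and the density force. The reason is
empirical and structural: with a full-complex map, a 4σ ball around a
16-atom ligand includes the entire first shell of protein density, and the
correlation of a ligand-only simulated density with that neighbourhood is
dominated by protein the model does not contain — on the synthetic fixture
the ground-truth ligand's own self-correlation collapses from ≈ 0.99
(1.0 σ mask) to 0.07 (4 σ mask), destroying all pose sensitivity. The
1.5 σ default mimics the threshold masks of standard CC tools (which keep
voxels where the simulated map is non-negligible) while retaining a
ground-truth ligand self-cc of ≈ 0.95–0.97 and a dynamic range of ≈ 0.9
between correct and 3 Å-displaced poses. Conversely the *force* needs a
capture range of several Å, so it keeps the wide support.

A consequence worth stating: even a perfect ligand model does not reach
cc = 1 against a full-complex map, because neighbouring protein density
bleeds into any finite mask. This is why pose-recovery outcomes are
normalised by the *ground-truth self-correlation* rather than by 1, and
why the whole-model correlation (which contains everything) is the
quantity that equals 1 exactly on a noiseless self-map.

The gradient of the masked cc with respect to atom positions is analytic:
with $a_v, b_v$ the mean-centred model and target values over the mask,
$P=\sum a_v b_v$, $Q_m=\sum a_v^2$, $Q_t=\sum b_v^2$,

$$\frac{\partial\,\mathrm{cc}}{\partial m_v}
  = \frac{b_v}{\sqrt{Q_mQ_t}} - \mathrm{cc}\,\frac{a_v}{Q_m},
\qquad
\frac{\partial m_v}{\partial \mathbf{x}_i}
  = \rho_i(\mathbf{v})\,\frac{\mathbf{v}-\mathbf{x}_i}{\sigma^2},$$

with the mask held fixed during differentiation (it is recomputed at every
evaluation, so the frozen-mask gradient is exact almost everywhere; the
finite-difference oracles in the tests freeze the same mask). The hard 4σ
truncation makes the objective discontinuous at the e⁻⁸ level; the
gradient-correctness tests therefore use truncation 7σ, which exercises
the same code path with the boundary pushed below the finite-difference
scale.

## Rigid-body fitting

`fitRigid()` performs gradient ascent on the wide-mask global cc over a
unit quaternion (rotation about the model centroid) and a translation. The
rotational gradient is the torque identity
$\tau = \sum_i (\mathbf{x}_i - \bar{\mathbf{x}}) \times \mathbf{g}_i$
applied to the per-atom cc gradients, preconditioned by the mean squared
radius so rotational and translational steps are commensurate. The line
search backtracks until improvement and then doubles while improvement
continues (a quasi-exact search); convergence is declared after three
successive iterations improving cc by less than `ccTol`. The default
`ccTol = 1e-8` is deliberately tighter than a "visually converged" 1e-6:
on smooth synthetic maps the cc landscape near the optimum is shallow
(curvature ≈ 3·10⁻³ per Å²), and a 1e-6 stall rule stops a systematic
0.1 Å / 1° short of the optimum. Restarts add seeded uniformly random
orientations (Shoemake quaternions); ties break to the earliest restart,
and the identity restart guarantees the ascent contract
`ccAfter ≥ ccBefore`.

## The structure-native restraint field

During flexible fitting the model needs internal forces that preserve
stereochemistry without asserting thermodynamics — the map force is meant
to dominate. `deriveParams()` builds, from a reference geometry:

* **bonds** between atoms closer than 1.3 × the sum of covalent radii
  (never across the protein/ligand boundary; complexes here are
  non-covalent), harmonic ($\tfrac12 k_b (r-r_0)^2$, $k_b$ = 2000
  kJ mol⁻¹ Å⁻²) at the *observed* length;
* **angles** for every bonded triple, harmonic ($k_\theta$ = 200
  kJ mol⁻¹ rad⁻²) at the observed angle;
* **elastic-network contacts**: every non-bonded same-molecule pair
  within 7 Å restrained to its observed distance with
  $k$ = 10 kJ mol⁻¹ Å⁻². This term is not decorative. Bonds + angles + LJ
  alone leave a vacuum structure free to compact under net LJ attraction:
  on the synthetic pseudo-protein, damped relaxation at $T=0$ without map
  forces degraded the whole-protein cc from 0.99 to 0.06 within 10 ps;
  with the contact network it stays at ≈ 0.99. Weak pairwise networks of
  this kind are the standard restraint device in flexible fitting; because
  contacts never cross the protein–ligand boundary, the ligand remains
  free to move through the pocket.
* **Lennard-Jones** per-element parameters with Lorentz–Berthelot
  combination, and opt-in cutoff **Coulomb** (charges default to zero;
  relative dielectric 15 stands in for solvent screening). Both use the
  GROMACS-style force switch between 10 and 12 Å, so the pair force goes
  smoothly to zero at the cutoff and the potential is its exact integral —
  the reported forces are the exact negative gradient of the reported
  energy, which the finite-difference tests assert at 10⁻⁵ relative.
  1-2/1-3 pairs are excluded, 1-4 pairs scaled by 0.5. No dihedral terms:
  the angle terms plus contacts restrain torsions sufficiently for
  ligands with few rotatable bonds.

PLIE — the protein–ligand interaction energy monitor — is the LJ + Coulomb
sum over cross pairs only, with the same switch, normalised per ligand
heavy atom. It is a plausibility monitor (favourable packing, no clashes),
*not* a free energy; with the default zero charges and this element-level
LJ table its absolute values are not comparable to those from a
solvent-screened all-atom force field, so only its sign and trend are
meaningful.

## The Langevin fitting engine

`runFlexFit()` integrates BAOAB Langevin dynamics (2 fs step, 310 K,
friction 1 ps⁻¹, velocities started at zero) in vacuum — no barostat, no
solvent; the solvent's only mechanical role here (screening and friction)
is played by the dielectric and the thermostat. Before dynamics, an
optional restrained steepest-descent minimisation (default 5000 steps)
relieves contacts, with positional restraints of 400 kJ mol⁻¹ nm⁻² on
backbone atoms and 40 on everything else, mirroring common
pre-equilibration practice.

The density force on heavy atom $i$ is $k\,\partial\mathrm{cc}/
\partial\mathbf{x}_i$ over the wide whole-model support, recomputed every
$N = 2$ steps and held constant in between (a zero-order hold; the
alternative impulse convention multiplies by $N$ instead — the hold gives
the same average force with less shot noise). Hydrogens, if present, feel
only the restraint field.

**Adaptive force scaling.** Every 50 force applications (200 fs), if the
global cc improved by less than 10⁻⁵, $k$ grows by 5% up to 100 × its
start value; $k$ never decreases. The starting $k$ = 10³ kJ/mol matches
the production protocol this engine emulates, but that number is
calibrated to a different similarity functional: Pearson-cc gradients are
small (the whole objective spans [−1, 1]), so on desk-scale systems the
initial force is comparable to thermal noise and the escalation schedule
must act within picoseconds. A timid schedule (1% per 100 applications)
provably cannot raise $k$ more than ×3.5 in a 50 ps run and left the
synthetic ligand stuck at cc ≈ 0.6; the 5%/50 schedule recovers it to
≈ 0.95. Runs destined for nanoseconds can restore gentler growth through
`fitConfig()`.

Safety rails: per-component forces are capped (default 10⁴ kJ mol⁻¹ Å⁻¹);
if more than 1% of atoms hit the cap the run terminates gracefully with a
`force_cap_exceeded` event and the last valid frame saved — the analogue
of a production engine aborting on excessive density forces — and
non-finite coordinates abort with a diagnostic frame. The monitor trace
(ligand/pocket/protein cc with scoring masks, PLIE, current $k$) is
sampled every 50 fs; trajectory frames every 1 ps. The pocket selection is
fixed at the input pose: a moving pocket definition would fold selection
changes into the monitored signal. All stochasticity flows from
`fitConfig(seed=)` through R's RNG, so traces are bit-reproducible.

The default duration (50 ps) is a desk-scale setting for toy systems;
production-scale refinements of real complexes run nanoseconds and are
reached by configuration, not code.

## Evaluation

`accuracy()` implements
$(1 - |v_\mathrm{model} - v_\mathrm{GT}|/v_\mathrm{max})\times 100$ with
$v_\mathrm{max} = 1$ for cc-based accuracies — the only reading under
which the shipped benchmark table's cc values reproduce its printed
accuracy ranges. `rankCandidates()` sorts by ligand cc (ties: pocket cc,
then input order). `buildReport()` assembles the per-entity table; the
"fitted" value is the final frame by default, with a last-20-frame mean
(± standard error) as the alternative reducer, since published tables are
ambiguous between the two. `curationFilter()` encodes the benchmark
assembly predicates; the binding-site contact bound is read as *strict*
(`min_contact < 4 Å` passes) — the source wording supports either reading,
so the choice is documented and configurable.

## The synthetic world

`makeFixture()` builds everything the tests need, deterministically from a
seed:

* a **pseudo-protein**: 60 four-atom residues (N, CA, C, O with realistic
  in-plane offsets) on a solenoidal backbone of radius 6 Å, ≈ 3.8 Å arc
  per residue — a concave cylindrical cavity with no side chains, enough
  to define pocket/backbone classes while keeping 50 ps runs under a
  minute;
* a **ligand**: a hexagonal ring (1.4 Å sides) plus a zigzag tail
  (1.5 Å bonds) on the cavity axis, 16 heavy atoms by default (the small
  end of the 16–30 drug-like range), a few nitrogens/oxygens among the
  carbons, placed with ≥ 3 protein contacts under 4 Å and no contact
  below ≈ 3 Å;
* a **target map**: all-heavy-atom density at 3.2 Å resolution on 1 Å
  voxels (the centre of the 2.7–3.7 Å benchmark range), optionally with
  seeded Gaussian voxel noise scaled to the map peak;
* **candidates**: five perturbed copies. Candidate $i$'s ligand is
  rigidly rotated and displaced to hit a target RMSD tuned by bisection
  (±10% contract, ±2% achieved), with clashing draws rejected and redrawn
  deterministically; the per-candidate targets are graded by multipliers
  0.6–1.4 around the spec'd 3 Å so that candidate 1 is always the
  expected ranking winner by a margin larger than the tuning tolerance,
  while still starting below 0.7 ligand cc — the regime where refinement
  is genuinely needed. A calibration sweep (cc vs ligand RMSD at 3.2 Å:
  ≈ 0.96 at 0 Å, ≈ 0.45 at 1.8 Å, ≈ 0.1 at 3 Å, ≈ 0 at 4 Å) fixed these
  choices once. Protein deformation, when requested, is a hinge rotation
  plus a smooth low-frequency displacement field tuned to a backbone RMSD
  target; a `flip` mode rotates the ligand 180° about its long principal
  axis, emulating the hardest error mode (a flipped pose that local
  refinement cannot fix).

What a green test does **not** establish: the fixture has no side chains,
no solvent, no CTF-like noise structure, no B-factor heterogeneity, and
its ligand is nearly rigid — so passing pose recovery here demonstrates
the mechanics of ranking and density-guided refinement, not performance on
experimental maps. Absolute PLIE values and absolute cc levels of real
systems are likewise outside what the synthetic world can certify.

## Known limitations

* mmCIF support is read-only and minimal (`atom_site` loop); PDB is the
  write format, which limits coordinate round-trips to 10⁻³ Å.
* The density force uses the cc gradient; engines built on other
  similarity functionals (inner product, relative entropy) scale their
  force constants differently, so $k$ values are not transferable.
* Maps must be orthogonal-cell MRC mode 2; no Fourier-space sharpening,
  FSC, or B-factor-dependent spreading.
* The restraint field is structure-native: it preserves the input
  stereochemistry, so a chemically wrong input geometry is preserved too.
* No symmetry-aware or FFT-exhaustive rigid search: `fitRigid()` is a
  local method with random-restart coverage.
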