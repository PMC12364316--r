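#' @import methods
NULL

# ---------------------------------------------------------------------------
# Structure: an atomic model
# ---------------------------------------------------------------------------

#' Atomic structure container
#'
#' A `Structure` holds an ordered atom table (one row per atom) plus free-form
#' metadata. Coordinates are in Angstrom throughout the package; masses in
#' atomic mass units; charges in elementary charge (default 0).
#'
#' The atom table columns are: `serial` (integer, unique), `name`, `element`
#' (recognised chemical symbol), `resname`, `resseq` (integer), `chain`,
#' `x`, `y`, `z`, `occupancy`, `hetero` (logical), `mass`, `charge`.
#'
#' @slot atoms data.frame with one row per atom (columns above).
#' @slot metadata named list of free-form annotations.
#' @aliases Structure
#' @exportClass Structure
setClass("Structure",
         representation(atoms = "data.frame", metadata = "list"),
         prototype(metadata = list()))

.STRUCTURE_COLS <- c("serial", "name", "element", "resname", "resseq",
                     "chain", "x", "y", "z", "occupancy", "hetero",
                     "mass", "charge")

setValidity("Structure", function(object) {
  a <- object@atoms
  msg <- character(0)
  if (!all(.STRUCTURE_COLS %in% names(a)))
    msg <- c(msg, paste("atom table must have columns:",
                        paste(setdiff(.STRUCTURE_COLS, names(a)), collapse = ", ")))
  else {
    if (nrow(a) < 1L) msg <- c(msg, "structure must contain at least one atom")
    if (anyDuplicated(a$serial)) msg <- c(msg, "atom serials must be unique")
    if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
      msg <- c(msg, "atom positions must be finite")
    if (!all(.isKnownElement(a$element)))
      msg <- c(msg, paste("unknown element(s):",
                          paste(unique(a$element[!.isKnownElement(a$element)]),
                                collapse = ", ")))
    else if (!all(a$mass > 0)) msg <- c(msg, "atom masses must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Structure from an atom table
#'
#' @param atoms data.frame of atom records; `mass` is filled from the element
#'   table when absent, `charge` defaults to 0, `occupancy` to 1.
#' @param metadata named list of annotations.
#' @return A [Structure-class] object.
#' @export
Structure <- function(atoms, metadata = list()) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  if (is.null(atoms$charge)) atoms$charge <- 0
  if (is.null(atoms$hetero)) atoms$hetero <- FALSE
  if (is.null(atoms$chain)) atoms$chain <- "A"
  if (is.null(atoms$mass)) atoms$mass <- elementMass(atoms$element)
  atoms$serial <- as.integer(atoms$serial)
  atoms$resseq <- as.integer(atoms$resseq)
  atoms$element <- toupper(atoms$element)
  rownames(atoms) <- NULL
  new("Structure", atoms = atoms[, .STRUCTURE_COLS], metadata = metadata)
}

#' @describeIn Structure Number of atoms.
#' @param x,object a `Structure`.
#' @export
nAtoms <- function(x) nrow(x@atoms)

#' Atom table accessor
#' @param x a [Structure-class].
#' @return data.frame of atom records.
#' @export
atoms <- function(x) x@atoms

#' Coordinate accessors
#'
#' `coords()` returns the n x 3 coordinate matrix (Angstrom);
#' `coords<-` replaces it.
#' @param x a [Structure-class].
#' @param value n x 3 numeric matrix.
#' @return `coords()` an n x 3 matrix with columns x, y, z.
#' @export
coords <- function(x) {
  m <- as.matrix(x@atoms[, c("x", "y", "z")])
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

#' @rdname coords
#' @export
`coords<-` <- function(x, value) {
  stopifnot(is.matrix(value), ncol(value) == 3, nrow(value) == nAtoms(x))
  x@atoms$x <- value[, 1]; x@atoms$y <- value[, 2]; x@atoms$z <- value[, 3]
  x
}

setMethod("show", "Structure", function(object) {
  a <- object@atoms
  cat("Structure with", nrow(a), "atoms:",
      sum(!a$hetero), "polymer,", sum(a$hetero), "hetero;",
      length(unique(paste(a$chain, a$resseq, a$resname))), "residues\n")
  if (length(object@metadata))
    cat("metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# Selection
# ---------------------------------------------------------------------------

#' Atom selection
#'
#' An ordered set of atom indices into a [Structure-class], tagged with a
#' role label (`ligand`, `pocket`, `protein` or `custom`).
#'
#' @slot indices integer vector of 1-based atom indices (unique).
#' @slot label character scalar.
#' @exportClass Selection
setClass("Selection",
         representation(indices = "integer", label = "character"))

setValidity("Selection", function(object) {
  msg <- character(0)
  if (anyDuplicated(object@indices)) msg <- c(msg, "indices must be unique")
  if (length(object@indices) && any(object@indices < 1L))
    msg <- c(msg, "indices must be positive")
  if (length(object@label) != 1L ||
      !object@label %in% c("ligand", "pocket", "protein", "custom"))
    msg <- c(msg, "label must be one of ligand/pocket/protein/custom")
  if (length(msg)) msg else TRUE
})

#' @param indices integer vector of atom indices.
#' @param label selection role.
#' @rdname Selection-class
#' @export
Selection <- function(indices, label = "custom") {
  new("Selection", indices = as.integer(indices), label = label)
}

#' @export
#' @rdname Selection-class
#' @param x a `Selection`.
selectionIndices <- function(x) x@indices

setMethod("show", "Selection", function(object) {
  cat(sprintf("Selection '%s': %d atoms\n", object@label,
              length(object@indices)))
})

setMethod("length", "Selection", function(x) length(x@indices))

# ---------------------------------------------------------------------------
# DensityGrid
# ---------------------------------------------------------------------------

#' Voxelised density map
#'
#' Scalar field on a regular orthogonal grid. `origin` is the position (in
#' Angstrom) of the centre of voxel `[1, 1, 1]`; voxel `[i, j, k]` is centred
#' at `origin + (i-1, j-1, k-1) * voxelSize`. Values are stored as a
#' column-major R array indexed `[x, y, z]`, matching an MRC file with axis
#' order 1,2,3.
#'
#' @slot origin numeric 3-vector, Angstrom.
#' @slot voxel numeric 3-vector of per-axis voxel spacing, Angstrom.
#' @slot values 3-d numeric array.
#' @slot resolution nominal map resolution in Angstrom (`NA` if unknown).
#' @exportClass DensityGrid
setClass("DensityGrid",
         representation(origin = "numeric", voxel = "numeric",
                        values = "array", resolution = "numeric"),
         prototype(resolution = NA_real_))

setValidity("DensityGrid", function(object) {
  msg <- character(0)
  if (length(object@origin) != 3L) msg <- c(msg, "origin must be length 3")
  if (length(object@voxel) != 3L || any(object@voxel <= 0))
    msg <- c(msg, "voxel sizes must be 3 positive values")
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3-d array")
  else if (!all(is.finite(object@values)))
    msg <- c(msg, "grid values must be finite")
  if (length(msg)) msg else TRUE
})

#' @param values 3-d array of densities.
#' @param origin position of the first voxel centre (Angstrom).
#' @param voxel per-axis voxel spacing (scalar recycled to 3).
#' @param resolution nominal resolution in Angstrom.
#' @rdname DensityGrid-class
#' @export
DensityGrid <- function(values, origin = c(0, 0, 0), voxel = c(1, 1, 1),
                        resolution = NA_real_) {
  if (length(voxel) == 1L) voxel <- rep(voxel, 3)
  new("DensityGrid", origin = as.numeric(origin), voxel = as.numeric(voxel),
      values = values, resolution = as.numeric(resolution))
}

#' @export
#' @rdname DensityGrid-class
#' @param x a `DensityGrid`.
gridValues <- function(x) x@values

#' @export
#' @rdname DensityGrid-class
gridOrigin <- function(x) x@origin

#' @export
#' @rdname DensityGrid-class
voxelSize <- function(x) x@voxel

#' @export
#' @rdname DensityGrid-class
gridDims <- function(x) dim(x@values)

#' @export
#' @rdname DensityGrid-class
nominalResolution <- function(x) x@resolution

setMethod("show", "DensityGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("DensityGrid %d x %d x %d, voxel %.3g x %.3g x %.3g A",
              d[1], d[2], d[3], object@voxel[1], object@voxel[2],
              object@voxel[3]))
  if (!is.na(object@resolution))
    cat(sprintf(", nominal resolution %.2f A", object@resolution))
  cat(sprintf("\nvalue range [%.4g, %.4g]\n",
              min(object@values), max(object@values)))
})

# ---------------------------------------------------------------------------
# MapSimParams
# ---------------------------------------------------------------------------

#' Parameters for simulating density from an atomic model
#'
#' Each heavy atom contributes an isotropic 3-d Gaussian of width
#' `sigma = resolution / (2 sqrt(2 ln 2))`, so the Gaussian FWHM equals the
#' nominal resolution. Amplitudes are either the atomic number
#' (`"atomic_number"`, default -- approximates scattering mass) or 1
#' (`"uniform"`). Contributions are truncated at `truncationRadius * sigma`.
#'
#' @slot resolution nominal resolution, Angstrom (> 0).
#' @slot sigma derived Gaussian width, Angstrom.
#' @slot amplitudeMode `"atomic_number"` or `"uniform"`.
#' @slot truncationRadius truncation radius in multiples of sigma (>= 2).
#' @slot maskRadius model-support mask radius for cc scoring, in multiples
#'   of sigma (default 1.5; a tight mask keeps a small entity's correlation
#'   from being swamped by neighbouring density, mimicking the
#'   simulated-map threshold masks of standard cc tools).
#' @slot gridSpec a [DensityGrid-class] giving the geometry to rasterise
#'   onto, or `NULL` to derive a grid from the selection bounding box.
#' @slot meanSubtract logical; use Pearson (mean-subtracted) correlation.
#' @exportClass MapSimParams
setClass("MapSimParams",
         representation(resolution = "numeric", sigma = "numeric",
                        amplitudeMode = "character",
                        truncationRadius = "numeric", maskRadius = "numeric",
                        gridSpec = "ANY", meanSubtract = "logical"))

setValidity("MapSimParams", function(object) {
  msg <- character(0)
  if (object@resolution <= 0) msg <- c(msg, "resolution must be > 0")
  if (object@truncationRadius < 2) msg <- c(msg, "truncationRadius must be >= 2")
  if (object@maskRadius <= 0) msg <- c(msg, "maskRadius must be > 0")
  if (!object@amplitudeMode %in% c("uniform", "atomic_number"))
    msg <- c(msg, "amplitudeMode must be 'uniform' or 'atomic_number'")
  if (!is.null(object@gridSpec) && !is(object@gridSpec, "DensityGrid"))
    msg <- c(msg, "gridSpec must be NULL or a DensityGrid")
  if (length(msg)) msg else TRUE
})

#' @param resolution nominal resolution in Angstrom.
#' @param amplitudeMode `"atomic_number"` (default) or `"uniform"`.
#' @param truncationRadius truncation radius in sigma multiples (default 4).
#' @param maskRadius scoring-mask radius in sigma multiples (default 1.5).
#' @param gridSpec optional reference [DensityGrid-class] geometry.
#' @param meanSubtract use mean-subtracted (Pearson) correlation (default
#'   `TRUE`); `FALSE` gives the no-mean-subtraction dialect.
#' @rdname MapSimParams-class
#' @export
mapSimParams <- function(resolution, amplitudeMode = "atomic_number",
                         truncationRadius = 4, maskRadius = 1.5,
                         gridSpec = NULL, meanSubtract = TRUE) {
  new("MapSimParams", resolution = resolution,
      sigma = resolution / (2 * sqrt(2 * log(2))),
      amplitudeMode = amplitudeMode, truncationRadius = truncationRadius,
      maskRadius = maskRadius, gridSpec = gridSpec,
      meanSubtract = meanSubtract)
}

setMethod("show", "MapSimParams", function(object) {
  cat(sprintf(
    "MapSimParams: resolution %.2f A (sigma %.3f A), %s amplitudes, %g sigma truncation\n",
    object@resolution, object@sigma, object@amplitudeMode,
    object@truncationRadius))
})

# ---------------------------------------------------------------------------
# SimilarityResult
# ---------------------------------------------------------------------------

#' Masked model-to-map cross-correlation result
#'
#' @slot cc Pearson correlation in \[-1, 1\].
#' @slot maskVoxels number of voxels in the mask (> 0).
#' @slot entity one of ligand/pocket/protein/global.
#' @exportClass SimilarityResult
setClass("SimilarityResult",
         representation(cc = "numeric", maskVoxels = "integer",
                        entity = "character"))

setValidity("SimilarityResult", function(object) {
  msg <- character(0)
  if (abs(object@cc) > 1 + 1e-9) msg <- c(msg, "cc must lie in [-1, 1]")
  if (object@maskVoxels <= 0L) msg <- c(msg, "mask must be non-empty")
  if (length(msg)) msg else TRUE
})

#' @export
#' @rdname SimilarityResult-class
#' @param x a `SimilarityResult`.
ccValue <- function(x) x@cc

#' @export
#' @rdname SimilarityResult-class
maskVoxels <- function(x) x@maskVoxels

setMethod("show", "SimilarityResult", function(object) {
  cat(sprintf("SimilarityResult [%s]: cc = %.4f over %d voxels\n",
              object@entity, object@cc, object@maskVoxels))
})

# ---------------------------------------------------------------------------
# RigidTransform
# ---------------------------------------------------------------------------

#' Rigid-body transform
#'
#' Rotation (unit quaternion, scalar-first) about `center`, followed by a
#' translation: `p -> R (p - center) + center + translation`.
#'
#' @slot quaternion numeric 4-vector (w, x, y, z), unit norm.
#' @slot translation numeric 3-vector, Angstrom.
#' @slot center numeric 3-vector, Angstrom; the rotation centre.
#' @exportClass RigidTransform
setClass("RigidTransform",
         representation(quaternion = "numeric", translation = "numeric",
                        center = "numeric"))

setValidity("RigidTransform", function(object) {
  msg <- character(0)
  if (length(object@quaternion) != 4L ||
      abs(sqrt(sum(object@quaternion^2)) - 1) > 1e-9)
    msg <- c(msg, "quaternion must be unit norm (within 1e-9)")
  if (length(object@translation) != 3L) msg <- c(msg, "translation must be length 3")
  if (length(object@center) != 3L) msg <- c(msg, "center must be length 3")
  if (length(msg)) msg else TRUE
})

#' @param quaternion numeric 4-vector (w, x, y, z); normalised on input.
#' @param translation numeric 3-vector (Angstrom).
#' @param center rotation centre (Angstrom).
#' @rdname RigidTransform-class
#' @export
rigidTransform <- function(quaternion = c(1, 0, 0, 0),
                           translation = c(0, 0, 0),
                           center = c(0, 0, 0)) {
  q <- quaternion / sqrt(sum(quaternion^2))
  new("RigidTransform", quaternion = q,
      translation = as.numeric(translation), center = as.numeric(center))
}

setMethod("show", "RigidTransform", function(object) {
  ang <- 2 * acos(pmin(1, abs(object@quaternion[1]))) * 180 / pi
  cat(sprintf(
    "RigidTransform: rotation %.3f deg, translation (%.3f, %.3f, %.3f) A\n",
    ang, object@translation[1], object@translation[2], object@translation[3]))
})

# ---------------------------------------------------------------------------
# RigidFitResult
# ---------------------------------------------------------------------------

#' Result of rigid-body map fitting
#'
#' @slot transform best [RigidTransform-class] found.
#' @slot ccBefore global cc of the input pose.
#' @slot ccAfter global cc after fitting (`>= ccBefore - 1e-9`).
#' @slot nRestartsUsed restarts actually evaluated.
#' @slot converged logical.
#' @exportClass RigidFitResult
setClass("RigidFitResult",
         representation(transform = "RigidTransform", ccBefore = "numeric",
                        ccAfter = "numeric", nRestartsUsed = "integer",
                        converged = "logical"))

setValidity("RigidFitResult", function(object) {
  if (object@ccAfter < object@ccBefore - 1e-9)
    "ccAfter must be >= ccBefore - 1e-9" else TRUE
})

setMethod("show", "RigidFitResult", function(object) {
  cat(sprintf("RigidFitResult: cc %.4f -> %.4f (%d restarts, %s)\n",
              object@ccBefore, object@ccAfter, object@nRestartsUsed,
              if (object@converged) "converged" else "not converged"))
})

# ---------------------------------------------------------------------------
# FFParams
# ---------------------------------------------------------------------------

#' Structure-native restraint-field parameters
#'
#' A lightweight molecular-mechanics parameter set: harmonic bonds and angles
#' whose reference values are taken from an input geometry, a per-atom
#' Lennard-Jones table, optional point charges, and the bonded exclusion
#' lists. It preserves stereochemistry during density-guided fitting; it is
#' not a transferable force field.
#'
#' Energies are kJ/mol, lengths Angstrom, angles radians. Bond energy is
#' `0.5 kb (r - r0)^2`, angle energy `0.5 ktheta (theta - theta0)^2`.
#'
#' @slot bonds numeric matrix, columns (i, j, r0, kb).
#' @slot angles numeric matrix, columns (i, j, k, theta0, ktheta).
#' @slot contacts numeric matrix, columns (i, j, r0, k): weak harmonic
#'   native-contact (elastic-network) restraints at observed distances,
#'   never across the protein/ligand boundary; they hold the fold together
#'   in vacuum while staying soft against collective deformation.
#' @slot ljSigma,ljEps per-atom LJ parameters (Angstrom, kJ/mol).
#' @slot charges per-atom charges (elementary charge).
#' @slot exclusions integer matrix of excluded pairs (1-2 and 1-3), columns (i, j).
#' @slot scaled14 integer matrix of 1-4 pairs, columns (i, j).
#' @slot scale14 nonbonded scale factor for 1-4 pairs.
#' @slot dielectric relative dielectric for cutoff Coulomb.
#' @exportClass FFParams
setClass("FFParams",
         representation(bonds = "matrix", angles = "matrix",
                        contacts = "matrix",
                        ljSigma = "numeric", ljEps = "numeric",
                        charges = "numeric", exclusions = "matrix",
                        scaled14 = "matrix", scale14 = "numeric",
                        dielectric = "numeric"))

setValidity("FFParams", function(object) {
  msg <- character(0)
  if (nrow(object@bonds) && (any(object@bonds[, 3] <= 0) || any(object@bonds[, 4] < 0)))
    msg <- c(msg, "bond r0 must be > 0 and kb >= 0")
  if (nrow(object@angles) && any(object@angles[, 5] < 0))
    msg <- c(msg, "angle ktheta must be >= 0")
  if (any(object@ljSigma <= 0) || any(object@ljEps < 0))
    msg <- c(msg, "LJ sigma must be > 0 and epsilon >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FFParams", function(object) {
  cat(sprintf(
    "FFParams: %d bonds, %d angles, %d contacts, %d atoms, %d exclusions, %d 1-4 pairs (dielectric %g)\n",
    nrow(object@bonds), nrow(object@angles), nrow(object@contacts),
    length(object@ljSigma), nrow(object@exclusions), nrow(object@scaled14),
    object@dielectric))
})

# ---------------------------------------------------------------------------
# InteractionEnergy
# ---------------------------------------------------------------------------

#' Protein-ligand interaction energy (PLIE)
#'
#' Nonbonded (LJ + Coulomb) energy summed over protein-ligand atom pairs,
#' reported both in total and per ligand heavy atom. A plausibility monitor,
#' not a free energy.
#'
#' @slot total,lj,coulomb energies, kJ/mol.
#' @slot perHeavyAtom total / ligand heavy-atom count, kJ/mol.
#' @slot nHeavy ligand heavy-atom count used for normalisation.
#' @exportClass InteractionEnergy
setClass("InteractionEnergy",
         representation(total = "numeric", lj = "numeric",
                        coulomb = "numeric", perHeavyAtom = "numeric",
                        nHeavy = "integer"))

setValidity("InteractionEnergy", function(object) {
  if (object@nHeavy > 0L &&
      abs(object@perHeavyAtom - object@total / object@nHeavy) > 1e-9)
    "perHeavyAtom must equal total / nHeavy" else TRUE
})

setMethod("show", "InteractionEnergy", function(object) {
  cat(sprintf(
    "InteractionEnergy: %.3f kJ/mol (LJ %.3f, Coulomb %.3f); %.3f kJ/mol per heavy atom (%d)\n",
    object@total, object@lj, object@coulomb, object@perHeavyAtom,
    object@nHeavy))
})

# ---------------------------------------------------------------------------
# FitConfig
# ---------------------------------------------------------------------------

#' Flexible-fitting configuration
#'
#' Houses every knob of the density-guided Langevin engine. Defaults follow
#' the production protocol this package emulates: 2 fs timestep, 310 K,
#' density forces applied every `densityForceInterval = 2` steps with scaling
#' factor `forceConstant = 1e3` kJ/mol combined with adaptive force scaling,
#' and a restrained pre-relaxation (5000 minimisation steps, backbone /
#' side-chain positional restraints of 400 / 40 kJ mol^-1 nm^-2).
#'
#' @slot timestep integration step, fs.
#' @slot temperature thermostat temperature, K.
#' @slot friction Langevin friction, 1/ps.
#' @slot forceConstant density-force scaling factor k, kJ/mol.
#' @slot densityForceInterval apply density forces every N steps.
#' @slot adaptiveScaling logical; grow k when cc stalls.
#' @slot checkInterval adaptive-scaling check interval, in force applications.
#' @slot ccEpsilon minimum cc improvement per check window.
#' @slot growthFactor multiplicative k growth on stall.
#' @slot kMax adaptive-scaling cap on k, kJ/mol.
#' @slot duration run length, ps.
#' @slot seed RNG seed (all stochasticity flows from it).
#' @slot forceCap per-component force cap, kJ/mol/Angstrom.
#' @slot preRelaxSteps restrained minimisation steps before dynamics (0 = off).
#' @slot backboneRestraint,sidechainRestraint pre-relax positional restraints,
#'   kJ/mol/Angstrom^2 (4 and 0.4 = the conventional 400/40 kJ/mol/nm^2).
#' @slot traceInterval trace sampling interval, fs.
#' @slot frameInterval trajectory frame interval, fs.
#' @exportClass FitConfig
setClass("FitConfig",
         representation(timestep = "numeric", temperature = "numeric",
                        friction = "numeric", forceConstant = "numeric",
                        densityForceInterval = "integer",
                        adaptiveScaling = "logical", checkInterval = "integer",
                        ccEpsilon = "numeric", growthFactor = "numeric",
                        kMax = "numeric", duration = "numeric",
                        seed = "integer", forceCap = "numeric",
                        preRelaxSteps = "integer",
                        backboneRestraint = "numeric",
                        sidechainRestraint = "numeric",
                        traceInterval = "numeric", frameInterval = "numeric"))

setValidity("FitConfig", function(object) {
  msg <- character(0)
  if (object@timestep <= 0) msg <- c(msg, "timestep must be > 0")
  if (object@forceConstant < 0) msg <- c(msg, "forceConstant must be >= 0")
  if (object@densityForceInterval < 1L)
    msg <- c(msg, "densityForceInterval must be >= 1")
  if (object@kMax < object@forceConstant)
    msg <- c(msg, "kMax must be >= forceConstant")
  if (object@duration < 0) msg <- c(msg, "duration must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param timestep fs (default 2).
#' @param temperature K (default 310).
#' @param friction 1/ps (default 1).
#' @param forceConstant density-force scaling k in kJ/mol (default 1e3).
#' @param densityForceInterval steps between density-force applications
#'   (default 2).
#' @param adaptiveScaling enable adaptive force scaling (default `TRUE`).
#' @param checkInterval,ccEpsilon,growthFactor,kMax adaptive-scaling knobs:
#'   every `checkInterval` force applications (default 50 = 200 fs at the
#'   default timestep and interval), if the global cc improved by less than
#'   `ccEpsilon`, k grows by `growthFactor` (default 1.05) up to `kMax`
#'   (default 100 * k). With a correlation-type similarity the per-atom
#'   gradients are small, so stalls must escalate k within picoseconds for
#'   desk-scale runs to finish.
#' @param duration run length in ps (default 50; a desk-scale default --
#'   production runs of 2 ns are reached by setting `duration = 2000`).
#' @param seed integer RNG seed.
#' @param forceCap per-component cap in kJ/mol/Angstrom (default 1e4).
#' @param preRelaxSteps restrained minimisation steps (default 5000).
#' @param backboneRestraint,sidechainRestraint kJ/mol/Angstrom^2 (defaults 4
#'   and 0.4).
#' @param traceInterval trace sampling interval in fs (default 50).
#' @param frameInterval trajectory frame interval in fs (default 1000).
#' @rdname FitConfig-class
#' @export
fitConfig <- function(timestep = 2, temperature = 310, friction = 1,
                      forceConstant = 1e3, densityForceInterval = 2L,
                      adaptiveScaling = TRUE, checkInterval = 50L,
                      ccEpsilon = 1e-5, growthFactor = 1.05,
                      kMax = 100 * forceConstant, duration = 50,
                      seed = 0L, forceCap = 1e4, preRelaxSteps = 5000L,
                      backboneRestraint = 4, sidechainRestraint = 0.4,
                      traceInterval = 50, frameInterval = 1000) {
  new("FitConfig", timestep = timestep, temperature = temperature,
      friction = friction, forceConstant = forceConstant,
      densityForceInterval = as.integer(densityForceInterval),
      adaptiveScaling = adaptiveScaling,
      checkInterval = as.integer(checkInterval), ccEpsilon = ccEpsilon,
      growthFactor = growthFactor, kMax = kMax, duration = duration,
      seed = as.integer(seed), forceCap = forceCap,
      preRelaxSteps = as.integer(preRelaxSteps),
      backboneRestraint = backboneRestraint,
      sidechainRestraint = sidechainRestraint,
      traceInterval = traceInterval, frameInterval = frameInterval)
}

setMethod("show", "FitConfig", function(object) {
  cat(sprintf(
    "FitConfig: %.0f ps at %.1f fs/step, %g K, k = %g kJ/mol every %d steps (%s), seed %d\n",
    object@duration, object@timestep, object@temperature,
    object@forceConstant, object@densityForceInterval,
    if (object@adaptiveScaling) "adaptive" else "fixed", object@seed))
})

# ---------------------------------------------------------------------------
# Trace and Trajectory
# ---------------------------------------------------------------------------

#' Fitting monitor trace
#'
#' Time series sampled during flexible fitting: per-entity cross-correlations,
#' PLIE per ligand heavy atom, and the current density-force constant; plus a
#' table of labelled events (warnings, early termination).
#'
#' @slot data data.frame with columns `time_ps`, `cc_ligand`, `cc_pocket`,
#'   `cc_protein`, `plie_per_heavy_atom`, `k_current`.
#' @slot events data.frame with columns `time_ps`, `label`.
#' @exportClass Trace
setClass("Trace",
         representation(data = "data.frame", events = "data.frame"))

setValidity("Trace", function(object) {
  msg <- character(0)
  need <- c("time_ps", "cc_ligand", "cc_pocket", "cc_protein",
            "plie_per_heavy_atom", "k_current")
  if (!all(need %in% names(object@data)))
    msg <- c(msg, "trace data missing required columns")
  else if (nrow(object@data) > 1L && any(diff(object@data$time_ps) <= 0))
    msg <- c(msg, "trace time must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' @export
#' @rdname Trace-class
#' @param x a `Trace`.
traceData <- function(x) x@data

#' @export
#' @rdname Trace-class
traceEvents <- function(x) x@events

setMethod("show", "Trace", function(object) {
  n <- nrow(object@data)
  cat(sprintf("Trace: %d samples over %.3f ps", n,
              if (n) max(object@data$time_ps) else 0))
  if (n) cat(sprintf("; final cc(ligand) = %.4f", object@data$cc_ligand[n]))
  cat(sprintf("; %d event(s)\n", nrow(object@events)))
})

#' Trajectory of saved frames
#'
#' @slot frames list of n x 3 coordinate matrices (Angstrom).
#' @slot times frame timestamps, ps.
#' @slot template the [Structure-class] whose atom table all frames share.
#' @slot saveInterval frame interval in steps.
#' @exportClass Trajectory
setClass("Trajectory",
         representation(frames = "list", times = "numeric",
                        template = "Structure", saveInterval = "integer"))

setValidity("Trajectory", function(object) {
  if (length(object@frames) != length(object@times))
    "frames and times must have equal length" else TRUE
})

#' @export
#' @rdname Trajectory-class
#' @param x a `Trajectory`.
nFrames <- function(x) length(x@frames)

#' Extract one frame of a trajectory as a Structure
#' @param x a [Trajectory-class].
#' @param i frame index (negative counts from the end; `-1` = final frame).
#' @return A [Structure-class].
#' @export
trajectoryFrame <- function(x, i = -1L) {
  n <- length(x@frames)
  if (i < 0L) i <- n + 1L + i
  stopifnot(i >= 1L, i <= n)
  s <- x@template
  coords(s) <- x@frames[[i]]
  s
}

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d frames of %d atoms over %.3f ps\n",
              length(object@frames), nAtoms(object@template),
              if (length(object@times)) max(object@times) else 0))
})

# ---------------------------------------------------------------------------
# CandidateSet, FixtureSpec, Fixture
# ---------------------------------------------------------------------------

#' Set of candidate models for one target
#'
#' Ordered candidate structures (e.g. independent AI predictions of the same
#' complex) sharing one target map; `ligandCC` is filled by
#' [rankCandidates()].
#'
#' @slot models named list of [Structure-class] objects (unique ids).
#' @slot ligandCC numeric per-model ligand cc (NA until ranked).
#' @slot sourceNote free-form provenance text.
#' @exportClass CandidateSet
setClass("CandidateSet",
         representation(models = "list", ligandCC = "numeric",
                        sourceNote = "character"))

setValidity("CandidateSet", function(object) {
  msg <- character(0)
  if (length(object@models) < 1L) msg <- c(msg, "at least one model required")
  if (is.null(names(object@models)) || anyDuplicated(names(object@models)))
    msg <- c(msg, "model ids must be unique and named")
  if (length(msg)) msg else TRUE
})

#' @param models named list of [Structure-class] candidates.
#' @param sourceNote provenance note.
#' @rdname CandidateSet-class
#' @export
CandidateSet <- function(models, sourceNote = "") {
  if (is.null(names(models)))
    names(models) <- paste0("model_", seq_along(models))
  new("CandidateSet", models = models,
      ligandCC = rep(NA_real_, length(models)), sourceNote = sourceNote)
}

#' @export
#' @rdname CandidateSet-class
#' @param x a `CandidateSet`.
candidateModels <- function(x) x@models

setMethod("show", "CandidateSet", function(object) {
  cat(sprintf("CandidateSet: %d models (%s)\n", length(object@models),
              paste(names(object@models), collapse = ", ")))
})

setMethod("length", "CandidateSet", function(x) length(x@models))

#' Synthetic fixture specification
#'
#' The stated world of the synthetic benchmark: a helical pseudo-protein with
#' a concave pocket binding a rigid ring-plus-tail ligand, a target map
#' simulated at cryo-EM-like resolution (default 3.2 Angstrom, 1 Angstrom
#' voxels, matching the middle of the 2.7-3.7 Angstrom range typical of
#' drug-target reconstructions), and candidate models perturbed by controlled
#' amounts (default ligand displacement 3 Angstrom RMSD) mimicking a spread
#' of AI predictions.
#'
#' @slot nResidues pseudo-residues on the helical backbone (default 60).
#' @slot ligandHeavyAtoms ligand heavy-atom count (default 16; drug-like
#'   ligands span roughly 16-30).
#' @slot mapResolution Angstrom (default 3.2).
#' @slot voxelSize Angstrom (default 1).
#' @slot noiseSigma voxel noise s.d. as a fraction of the map peak (default 0).
#' @slot ligandRmsdTarget,proteinRmsdTarget perturbation targets, Angstrom.
#' @slot flip apply a 180-degree flip about the ligand long axis first.
#' @slot nCandidates number of perturbed candidate models (default 5).
#' @slot seed master seed; all fixture randomness flows from it.
#' @exportClass FixtureSpec
setClass("FixtureSpec",
         representation(nResidues = "integer", ligandHeavyAtoms = "integer",
                        mapResolution = "numeric", voxelSize = "numeric",
                        noiseSigma = "numeric", ligandRmsdTarget = "numeric",
                        proteinRmsdTarget = "numeric", flip = "logical",
                        nCandidates = "integer", seed = "integer"))

setValidity("FixtureSpec", function(object) {
  msg <- character(0)
  if (object@nResidues < 20L) msg <- c(msg, "need at least 20 residues")
  if (object@ligandHeavyAtoms < 1L) msg <- c(msg, "ligandHeavyAtoms must be > 0")
  if (object@ligandRmsdTarget < 0 || object@proteinRmsdTarget < 0)
    msg <- c(msg, "RMSD targets must be >= 0")
  if (object@nCandidates < 1L) msg <- c(msg, "nCandidates must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param nResidues,ligandHeavyAtoms,mapResolution,voxelSize,noiseSigma see slots.
#' @param ligandRmsdTarget,proteinRmsdTarget,flip,nCandidates,seed see slots.
#' @rdname FixtureSpec-class
#' @export
fixtureSpec <- function(nResidues = 60L, ligandHeavyAtoms = 16L,
                        mapResolution = 3.2, voxelSize = 1,
                        noiseSigma = 0, ligandRmsdTarget = 3,
                        proteinRmsdTarget = 0, flip = FALSE,
                        nCandidates = 5L, seed = 0L) {
  new("FixtureSpec", nResidues = as.integer(nResidues),
      ligandHeavyAtoms = as.integer(ligandHeavyAtoms),
      mapResolution = mapResolution, voxelSize = voxelSize,
      noiseSigma = noiseSigma, ligandRmsdTarget = ligandRmsdTarget,
      proteinRmsdTarget = proteinRmsdTarget, flip = flip,
      nCandidates = as.integer(nCandidates), seed = as.integer(seed))
}

setMethod("show", "FixtureSpec", function(object) {
  cat(sprintf(
    "FixtureSpec: %d residues + %d-heavy-atom ligand, %.2f A map, %d candidates (ligand %.1f A, protein %.1f A%s), seed %d\n",
    object@nResidues, object@ligandHeavyAtoms, object@mapResolution,
    object@nCandidates, object@ligandRmsdTarget, object@proteinRmsdTarget,
    if (object@flip) ", flipped" else "", object@seed))
})

#' A complete synthetic benchmark fixture
#'
#' @slot groundTruth the generating [Structure-class].
#' @slot targetMap the simulated [DensityGrid-class] (optionally noisy).
#' @slot candidates perturbed [CandidateSet-class].
#' @slot provenance the [FixtureSpec-class] that generated everything.
#' @exportClass Fixture
setClass("Fixture",
         representation(groundTruth = "Structure", targetMap = "DensityGrid",
                        candidates = "CandidateSet",
                        provenance = "FixtureSpec"))

setMethod("show", "Fixture", function(object) {
  cat("Synthetic fixture\n  ground truth: ")
  show(object@groundTruth)
  cat("  target map:   ")
  show(object@targetMap)
  cat("  candidates:   ")
  show(object@candidates)
})
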