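# Structure-native restraint field: harmonic bonds/angles whose reference
# values come from an input geometry, an element Lennard-Jones table, and an
# optional cutoff-Coulomb term. Its job is to preserve stereochemistry during
# density-guided fitting while the map force does the work -- dependence on a
# transferable force field is deliberately minimal.

.DEFAULT_KB <- 2000     # kJ/mol/A^2
.DEFAULT_KTHETA <- 200  # kJ/mol/rad^2

# pairs within the element-dependent covalent cutoff; bonds never cross the
# polymer/hetero boundary (complexes here are non-covalent)
.inferBonds <- function(structure, tolerance = 1.3) {
  p <- coords(structure)
  el <- structure@atoms$element
  het <- structure@atoms$hetero
  rcov <- elementCovalentRadius(el)
  n <- nrow(p)
  out <- matrix(numeric(0), 0, 3)
  if (n < 2) return(out)
  maxcut <- tolerance * 2 * max(rcov)
  d2 <- cpp_all_pairs_within(p, maxcut)
  if (nrow(d2) == 0) return(out)
  i <- d2[, 1]; j <- d2[, 2]; r <- sqrt(d2[, 3])
  keep <- r < tolerance * (rcov[i] + rcov[j]) & het[i] == het[j]
  cbind(i, j, r)[keep, , drop = FALSE]
}

#' Derive restraint-field parameters from a reference geometry
#'
#' Bonds are inferred by element-dependent distance cutoffs on the reference
#' geometry (`dist < 1.3 * (rcov_i + rcov_j)`, never across the polymer/hetero
#' boundary); angles connect every bonded triple. Reference values `r0` /
#' `theta0` are the observed ones, so the bonded energy of the reference
#' geometry is exactly zero. Force constants and LJ parameters come from the
#' element table; charges are zero unless supplied (Coulomb is opt-in).
#'
#' @param structure the [Structure-class] the parameters will act on.
#' @param referenceGeometry [Structure-class] supplying reference bond
#'   lengths/angles (defaults to `structure` itself).
#' @param kb,ktheta harmonic force constants (kJ/mol/A^2, kJ/mol/rad^2).
#' @param contactCutoff,kContact elastic-network native-contact restraints:
#'   every non-bonded pair within `contactCutoff` (Angstrom, default 7) of
#'   the same molecule (never protein-to-ligand) is restrained to its
#'   observed distance with force constant `kContact` (default 10
#'   kJ/mol/A^2; 0 disables). These hold the fold together in vacuum --
#'   soft against hinge-like deformation, stiff against collapse.
#' @param charges optional per-atom charges (e).
#' @param dielectric relative dielectric for cutoff Coulomb (default 15,
#'   damping bare charges in lieu of solvent screening).
#' @param switchDist,cutoff nonbonded force-switch bounds, Angstrom
#'   (defaults 10 and 12).
#' @param scale14 1-4 nonbonded scale factor (default 0.5).
#' @return An [FFParams-class]. Atoms with no bonds (and not ions) are noted
#'   in a `"disconnected"` attribute.
#' @export
deriveParams <- function(structure, referenceGeometry = structure,
                         kb = .DEFAULT_KB, ktheta = .DEFAULT_KTHETA,
                         charges = NULL, dielectric = 15,
                         switchDist = 10, cutoff = 12, scale14 = 0.5,
                         contactCutoff = 7, kContact = 10) {
  stopifnot(nAtoms(structure) == nAtoms(referenceGeometry))
  p <- coords(referenceGeometry)
  n <- nrow(p)
  mind <- if (n > 1) sqrt(min(cpp_min_dist2_self(p))) else Inf
  if (mind < 0.7)
    stop(sprintf("reference geometry has overlapping atoms (min distance %.3f A)",
                 mind))
  b <- .inferBonds(referenceGeometry)
  bonds <- cbind(b[, 1], b[, 2], b[, 3], rep(kb, nrow(b)))
  colnames(bonds) <- c("i", "j", "r0", "kb")
  # adjacency for angles and exclusions
  adj <- vector("list", n)
  for (r in seq_len(nrow(b))) {
    i <- b[r, 1]; j <- b[r, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  ang <- list()
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) >= 2) {
      cmb <- utils::combn(sort(nb), 2)
      for (c0 in seq_len(ncol(cmb))) {
        i <- cmb[1, c0]; k <- cmb[2, c0]
        v1 <- p[i, ] - p[j, ]; v2 <- p[k, ] - p[j, ]
        th <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                  sqrt(sum(v1^2) * sum(v2^2)))))
        ang[[length(ang) + 1L]] <- c(i, j, k, th, ktheta)
      }
    }
  }
  angles <- if (length(ang)) do.call(rbind, ang) else matrix(numeric(0), 0, 5)
  colnames(angles) <- c("i", "j", "k", "theta0", "ktheta")
  # exclusions: 1-2 and 1-3; scaled 1-4
  excl <- unique(rbind(
    if (nrow(bonds)) cbind(pmin(bonds[, 1], bonds[, 2]),
                           pmax(bonds[, 1], bonds[, 2])),
    if (nrow(angles)) cbind(pmin(angles[, 1], angles[, 3]),
                            pmax(angles[, 1], angles[, 3]))))
  if (is.null(excl)) excl <- matrix(numeric(0), 0, 2)
  s14 <- list()
  if (nrow(angles)) {
    for (r in seq_len(nrow(angles))) {
      i <- angles[r, 1]; k <- angles[r, 3]
      for (l in adj[[k]]) if (l != angles[r, 2] && l != i)
        s14[[length(s14) + 1L]] <- c(min(i, l), max(i, l))
      for (l in adj[[i]]) if (l != angles[r, 2] && l != k)
        s14[[length(s14) + 1L]] <- c(min(k, l), max(k, l))
    }
  }
  s14 <- if (length(s14)) unique(do.call(rbind, s14)) else matrix(numeric(0), 0, 2)
  # drop 1-4 pairs that are also 1-2/1-3 (rings)
  if (nrow(s14) && nrow(excl)) {
    key <- function(m) paste(m[, 1], m[, 2])
    s14 <- s14[!key(s14) %in% key(excl), , drop = FALSE]
  }
  # elastic-network contacts: non-bonded same-molecule pairs at native range
  contacts <- matrix(numeric(0), 0, 4)
  if (kContact > 0) {
    het <- structure@atoms$hetero
    cp <- cpp_all_pairs_within(p, contactCutoff)
    if (nrow(cp)) {
      keyOf <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
      bonded <- c(if (nrow(excl)) keyOf(excl), if (nrow(b)) keyOf(b))
      keep <- het[cp[, 1]] == het[cp[, 2]] & !(keyOf(cp) %in% bonded)
      cp <- cp[keep, , drop = FALSE]
      contacts <- cbind(cp[, 1], cp[, 2], sqrt(cp[, 3]),
                        rep(kContact, nrow(cp)))
    }
  }
  colnames(contacts) <- c("i", "j", "r0", "k")
  el <- structure@atoms$element
  if (is.null(charges)) charges <- structure@atoms$charge
  disconnected <- setdiff(which(lengths(adj) == 0L),
                          which(toupper(structure@atoms$resname) %in% .ION_NAMES))
  if (length(disconnected))
    warning(sprintf("%d non-ion atom(s) have no inferred bonds (first: serial %d)",
                    length(disconnected),
                    structure@atoms$serial[disconnected[1]]))
  out <- new("FFParams", bonds = bonds, angles = angles,
             contacts = contacts,
             ljSigma = .elementField(el, "lj_sigma"),
             ljEps = .elementField(el, "lj_eps"),
             charges = as.numeric(charges),
             exclusions = matrix(as.integer(excl), ncol = 2),
             scaled14 = matrix(as.integer(s14), ncol = 2),
             scale14 = scale14, dielectric = dielectric)
  attr(out, "disconnected") <- disconnected
  attr(out, "switchDist") <- switchDist
  attr(out, "cutoff") <- cutoff
  out
}

# plain-list view consumed by the C++ kernels; elastic-network contacts are
# harmonic distance terms, so they ride along with the bond list
.ffList <- function(params, switchDist = NULL, cutoff = NULL) {
  list(bonds = rbind(params@bonds, params@contacts), angles = params@angles,
       ljSigma = params@ljSigma, ljEps = params@ljEps,
       charges = params@charges, exclusions = params@exclusions,
       scaled14 = params@scaled14, scale14 = params@scale14,
       dielectric = params@dielectric,
       r1 = switchDist %||% attr(params, "switchDist") %||% 10,
       rc = cutoff %||% attr(params, "cutoff") %||% 12)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Restraint-field energy and forces
#'
#' Harmonic bonds and angles plus Lennard-Jones and (opt-in) Coulomb with a
#' GROMACS-style force switch between `switchDist` and `cutoff`; the
#' returned forces are the exact negative gradient of the returned energy.
#'
#' @param structure a [Structure-class].
#' @param params an [FFParams-class] from [deriveParams()].
#' @param switchDist,cutoff force-switch bounds in Angstrom (default 10 / 12).
#' @return List with `energy` (kJ/mol), `forces` (nAtoms x 3, kJ/mol/A),
#'   `lj` and `coulomb` components.
#' @export
energyForces <- function(structure, params, switchDist = NULL, cutoff = NULL) {
  r <- cpp_energy_forces(coords(structure),
                         .ffList(params, switchDist, cutoff))
  list(energy = r$energy, forces = t(r$forces), lj = r$lj,
       coulomb = r$coulomb)
}

#' Protein-ligand interaction energy (PLIE)
#'
#' Nonbonded (LJ + Coulomb) energy over protein-ligand atom pairs only, with
#' the same force switch as [energyForces()], normalised per ligand heavy
#' atom. A plausibility monitor, not a free energy.
#'
#' @param structure a [Structure-class].
#' @param protein,ligand disjoint [Selection-class] objects.
#' @param params an [FFParams-class].
#' @param switchDist,cutoff force-switch bounds in Angstrom.
#' @return An [InteractionEnergy-class].
#' @export
plie <- function(structure, protein, ligand, params, switchDist = NULL,
                 cutoff = NULL) {
  if (length(intersect(protein@indices, ligand@indices)))
    stop("protein and ligand selections overlap")
  r <- cpp_plie(coords(structure), .ffList(params, switchDist, cutoff),
                protein@indices, ligand@indices)
  nH <- length(heavyAtoms(ligand, structure))
  new("InteractionEnergy", total = r$total, lj = r$lj, coulomb = r$coulomb,
      perHeavyAtom = if (nH > 0) r$total / nH else 0,
      nHeavy = as.integer(nH))
}

#' Write / read restraint-field parameters as JSON
#' @param params an [FFParams-class].
#' @param path file path.
#' @return `writeFFParams` invisibly returns `path`; `readFFParams` an
#'   [FFParams-class].
#' @export
writeFFParams <- function(params, path) {
  jsonlite::write_json(
    list(bonds = params@bonds, angles = params@angles,
         contacts = params@contacts,
         lj_sigma = params@ljSigma, lj_eps = params@ljEps,
         charges = params@charges, exclusions = params@exclusions,
         scaled14 = params@scaled14, scale14 = params@scale14,
         dielectric = params@dielectric,
         switch_dist = attr(params, "switchDist") %||% 10,
         cutoff = attr(params, "cutoff") %||% 12),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeFFParams
#' @export
readFFParams <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  asm <- function(x, nc) {
    m <- if (length(x)) as.matrix(x) else matrix(numeric(0), 0, nc)
    if (ncol(m) != nc) m <- matrix(m, ncol = nc)
    m
  }
  out <- new("FFParams", bonds = asm(j$bonds, 4), angles = asm(j$angles, 5),
             contacts = asm(j$contacts, 4),
             ljSigma = j$lj_sigma, ljEps = j$lj_eps, charges = j$charges,
             exclusions = matrix(as.integer(asm(j$exclusions, 2)), ncol = 2),
             scaled14 = matrix(as.integer(asm(j$scaled14, 2)), ncol = 2),
             scale14 = j$scale14, dielectric = j$dielectric)
  attr(out, "switchDist") <- j$switch_dist
  attr(out, "cutoff") <- j$cutoff
  out
}
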