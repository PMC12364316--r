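# Seeded synthetic protein-ligand fixtures: a solenoidal pseudo-protein
# (4-atom backbone residues: N, CA, C, O) wrapped around an axial
# ring-plus-tail ligand, a simulated target map at cryo-EM-like resolution,
# and perturbed candidate models emulating the spread of AI predictions.

.withSeed <- function(seed, expr) {
  oldSeed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, .GlobalEnv))
  set.seed(seed)
  force(expr)
}

#' Root-mean-square deviation between two conformations
#'
#' Positional RMSD (no superposition) over a selection, heavy atoms only.
#'
#' @param a,b [Structure-class] objects with identical atom tables.
#' @param selection a [Selection-class] (default: all atoms).
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, selection = NULL) {
  stopifnot(nAtoms(a) == nAtoms(b))
  if (is.null(selection)) selection <- Selection(seq_len(nAtoms(a)), "custom")
  sel <- heavyAtoms(selection, a)
  d <- coords(a)[sel@indices, , drop = FALSE] -
       coords(b)[sel@indices, , drop = FALSE]
  sqrt(mean(rowSums(d^2)))
}

# backbone (N, CA, C, O polymer atoms) selection
.backboneSelection <- function(structure) {
  a <- structure@atoms
  Selection(which(!a$hetero & a$name %in% c("N", "CA", "C", "O")), "custom")
}

#' Build a synthetic protein-ligand complex
#'
#' Deterministic given `spec@seed`: a solenoidal pseudo-protein of
#' `nResidues` backbone-only residues (N, CA, C, O) coiled around a concave
#' axial cavity, plus a rigid ring-plus-tail ligand of
#' `ligandHeavyAtoms` heavy atoms placed on the axis with at least 3
#' protein contacts under 4 Angstrom and no clashes.
#'
#' @param spec a [FixtureSpec-class].
#' @return A [Structure-class] (ligand residue name `"LIG"`).
#' @export
makeComplex <- function(spec) {
  stopifnot(is(spec, "FixtureSpec"))
  validObject(spec)
  .withSeed(spec@seed, {
    n <- spec@nResidues
    # solenoid anchors: radius 6 A, ~3.8 A arc per residue, pitch 0.65 A/res
    phi <- (seq_len(n) - 1) * 0.633
    zz <- (seq_len(n) - 1) * 0.65
    anchor <- cbind(6 * cos(phi), 6 * sin(phi), zz)
    # local frames: tangent e, outward radial m
    e <- rbind(anchor[2:n, ] - anchor[1:(n - 1), ],
               anchor[n, ] - anchor[n - 1, ])
    e <- e / sqrt(rowSums(e^2))
    m <- cbind(cos(phi), sin(phi), 0)
    # in-plane offsets (along e, along m) giving realistic pseudo-peptide
    # spacings: N-CA 1.46, CA-C 1.52, C-N(next) ~1.36, C=O 1.23
    off <- list(N = c(0, 0), CA = c(1.196, 0.837), C = c(2.441, -0.035),
                O = c(2.121, -1.223))
    els <- c(N = "N", CA = "C", C = "C", O = "O")
    rows <- vector("list", 4L * n)
    for (t in seq_len(n)) {
      for (w in seq_along(off)) {
        nm <- names(off)[w]
        p <- anchor[t, ] + off[[nm]][1] * e[t, ] + off[[nm]][2] * m[t, ]
        rows[[4L * (t - 1L) + w]] <- data.frame(
          name = nm, element = els[[nm]], resname = "GLY", resseq = t,
          chain = "A", x = p[1], y = p[2], z = p[3], hetero = FALSE,
          stringsAsFactors = FALSE)
      }
    }
    prot <- do.call(rbind, rows)
    # small seeded jitter breaks exact symmetry
    jit <- matrix(stats::rnorm(3L * nrow(prot), sd = 0.05), ncol = 3)
    prot$x <- prot$x + jit[, 1]; prot$y <- prot$y + jit[, 2]
    prot$z <- prot$z + jit[, 3]

    # ligand: hexagonal ring (side 1.4) in the xz-plane on the axis, plus a
    # zigzag tail along +z (bond 1.5); a few N/O among the carbons
    nl <- spec@ligandHeavyAtoms
    zmid <- mean(range(zz)) - 1
    lig <- matrix(0, nl, 3)
    nring <- min(6L, nl)
    th <- (seq_len(nring) - 1) * 2 * pi / 6
    lig[seq_len(nring), ] <- cbind(1.4 * sin(th), 0, zmid + 1.4 * cos(th))
    if (nl > 6L) {
      for (k in seq_len(nl - 6L)) {
        sgn <- if (k %% 2 == 0) -0.375 else 0.375   # zigzag, 1.5 A bonds
        lig[6L + k, ] <- c(sgn, 0, zmid + 1.4 + 1.3 * k)
      }
    }
    ligEl <- rep("C", nl)
    if (nl >= 4L) ligEl[4L] <- "N"
    if (nl >= 9L) ligEl[9L] <- "O"
    if (nl >= 14L) ligEl[14L] <- "N"
    ligdf <- data.frame(
      name = paste0(ligEl, seq_len(nl)), element = ligEl, resname = "LIG",
      resseq = 1L, chain = "L", x = lig[, 1], y = lig[, 2], z = lig[, 3],
      hetero = TRUE, stringsAsFactors = FALSE)
    jl <- matrix(stats::rnorm(3L * nl, sd = 0.03), ncol = 3)
    ligdf$x <- ligdf$x + jl[, 1]; ligdf$y <- ligdf$y + jl[, 2]
    ligdf$z <- ligdf$z + jl[, 3]

    all <- rbind(prot, ligdf)
    all$serial <- seq_len(nrow(all))
    s <- Structure(all, metadata = list(generator = "makeComplex",
                                        seed = spec@seed))
    # construction contract: pocket non-empty, ligand in contact, no clash
    ligSel <- selectLigand(s, "LIG")
    d2 <- cpp_min_dist2(coords(s)[ligSel@indices, , drop = FALSE],
                        coords(s)[-ligSel@indices, , drop = FALSE])
    if (sum(d2 < 16) < 3L || min(d2) < 2.0)
      stop("fixture construction failed its contact contract; try another seed")
    s
  })
}

#' Simulate the target map of a fixture
#'
#' Density of all heavy atoms at `spec@mapResolution` on a grid of
#' `spec@voxelSize` voxels padded past the model support, plus (optionally)
#' independent seeded Gaussian voxel noise with s.d. `noiseSigma * peak`.
#'
#' @param complex the ground-truth [Structure-class].
#' @param spec a [FixtureSpec-class].
#' @return A [DensityGrid-class].
#' @export
makeTargetMap <- function(complex, spec) {
  params <- mapSimParams(spec@mapResolution)
  allSel <- Selection(seq_len(nAtoms(complex)), "custom")
  grid <- .autoGrid(complex, heavyAtoms(allSel, complex), params,
                    voxel = spec@voxelSize)
  params@gridSpec <- grid
  map <- simulateDensity(complex, allSel, params)
  if (spec@noiseSigma > 0) {
    noise <- .withSeed(spec@seed + 500009L,
                       stats::rnorm(length(map@values),
                                    sd = spec@noiseSigma * max(map@values)))
    map@values <- map@values + array(noise, dim(map@values))
  }
  map@resolution <- spec@mapResolution
  map
}

# scalable deformation used by perturbCandidate: s = 1 is the raw draw
.ligandPerturbation <- function(P, s, draw) {
  ctr <- colMeans(P)
  q <- .axisAngleQuat(draw$axis, s * draw$angle)
  R <- .quatToMatrix(q)
  sweep(sweep(P, 2, ctr) %*% t(R), 2, ctr + s * draw$shift, "+")
}

.proteinPerturbation <- function(P, s, draw, resseq) {
  n <- nrow(P)
  # hinge: rotate residues past the hinge about an axis through the hinge
  hingeAt <- P[draw$hingeAtom, ]
  R <- .quatToMatrix(.axisAngleQuat(draw$axis, s * draw$angle))
  past <- resseq > draw$hingeRes
  Q <- P
  Q[past, ] <- sweep(sweep(P[past, , drop = FALSE], 2, hingeAt) %*% t(R),
                     2, hingeAt, "+")
  # smooth low-frequency displacement field along the chain
  t01 <- (resseq - min(resseq)) / max(1, diff(range(resseq)))
  for (c0 in 1:3) {
    w <- draw$amp[, c0]
    Q[, c0] <- Q[, c0] + s * (w[1] * sin(2 * pi * t01 + draw$ph[1, c0]) +
                              w[2] * sin(4 * pi * t01 + draw$ph[2, c0]))
  }
  Q
}

#' Perturb a fixture complex into a candidate model
#'
#' Emulates AI-prediction error modes: a rigid ligand displacement plus
#' rotation tuned (by bisection on the perturbation magnitude) to hit
#' `ligandRmsdTarget`, a protein hinge-plus-smooth-field deformation tuned
#' to `proteinRmsdTarget` (backbone RMSD), and optionally a 180-degree flip
#' of the ligand about its long principal axis applied before tuning.
#' Deterministic given `candidateSeed`.
#'
#' @param complex the ground-truth [Structure-class].
#' @param spec a [FixtureSpec-class] (perturbation targets, tolerance 10%).
#' @param candidateSeed integer seed for this candidate's random draws.
#' @param ligandScale,proteinScale optional multipliers on the spec targets.
#' @return A perturbed [Structure-class].
#' @export
perturbCandidate <- function(complex, spec, candidateSeed,
                             ligandScale = 1, proteinScale = 1) {
  ligTarget <- spec@ligandRmsdTarget * ligandScale
  protTarget <- spec@proteinRmsdTarget * proteinScale
  .withSeed(candidateSeed, {
    out <- complex
    ligSel <- selectLigand(complex, "LIG")
    li <- ligSel@indices
    P <- coords(complex)

    if (spec@flip) {
      L <- P[li, , drop = FALSE]
      ctr <- colMeans(L)
      pc <- prcomp(L, center = TRUE)$rotation[, 1]
      R <- .quatToMatrix(.axisAngleQuat(pc, pi))
      P[li, ] <- sweep(sweep(L, 2, ctr) %*% t(R), 2, ctr, "+")
    }

    measureLig <- function(Pnew) {
      sqrt(mean(rowSums((Pnew[li, , drop = FALSE] -
                         coords(complex)[li, , drop = FALSE])^2)))
    }
    base <- measureLig(P)
    if (ligTarget > 0 || spec@flip) {
      if (ligTarget < base * 0.999 && base > ligTarget * 1.1)
        stop(sprintf(
          "ligand RMSD target %.2f A unreachable: flip alone gives %.2f A",
          ligTarget, base))
      accepted <- FALSE
      for (attempt in 1:100) {
        draw <- list(axis = stats::rnorm(3), angle = stats::runif(1, 0.3, 0.9),
                     shift = {
                       u <- stats::rnorm(3); u / sqrt(sum(u^2)) *
                         stats::runif(1, 2, 4)
                     })
        f <- function(s) {
          Q <- P
          Q[li, ] <- .ligandPerturbation(P[li, , drop = FALSE], s, draw)
          measureLig(Q)
        }
        if (ligTarget < base * 0.999) {
          s <- 0
        } else {
          lo <- 0; hi <- 1
          tries <- 0L
          while (f(hi) < ligTarget && tries < 100L) {
            hi <- hi * 1.6; tries <- tries + 1L
          }
          if (f(hi) < ligTarget)
            stop(sprintf(
              "ligand RMSD target %.2f A unreachable (achieved %.2f A)",
              ligTarget, f(hi)))
          for (it in 1:100) {
            s <- (lo + hi) / 2
            if (f(s) < ligTarget) lo <- s else hi <- s
          }
          s <- (lo + hi) / 2
        }
        ligNew <- .ligandPerturbation(P[li, , drop = FALSE], s, draw)
        # candidates must stay physically plausible: no hard clashes
        clash <- sqrt(min(cpp_min_dist2(ligNew,
                                        P[-li, , drop = FALSE])))
        if (clash >= 1.5) {
          P[li, ] <- ligNew
          accepted <- TRUE
          break
        }
      }
      if (!accepted)
        stop("could not draw a clash-free ligand perturbation in 100 attempts")
    }

    if (protTarget > 0) {
      a <- complex@atoms
      pi0 <- which(!a$hetero)
      bbSel <- .backboneSelection(complex)
      resseq <- a$resseq[pi0]
      hingeRes <- sample(round(spec@nResidues * c(0.35, 0.65)), 1L)
      hingeAtom <- which(a$resseq[pi0] == hingeRes & a$name[pi0] == "CA")[1]
      draw <- list(axis = stats::rnorm(3), angle = stats::runif(1, 0.1, 0.25),
                   hingeRes = hingeRes, hingeAtom = hingeAtom,
                   amp = matrix(stats::rnorm(6, sd = 1.2), 2, 3),
                   ph = matrix(stats::runif(6, 0, 2 * pi), 2, 3))
      Pp <- P[pi0, , drop = FALSE]
      bbLocal <- match(bbSel@indices, pi0)
      measureProt <- function(Q) {
        sqrt(mean(rowSums((Q[bbLocal, , drop = FALSE] -
                           coords(complex)[bbSel@indices, , drop = FALSE])^2)))
      }
      fp <- function(s) measureProt(.proteinPerturbation(Pp, s, draw, resseq))
      lo <- 0; hi <- 1
      tries <- 0L
      while (fp(hi) < protTarget && tries < 100L) { hi <- hi * 1.6; tries <- tries + 1L }
      if (fp(hi) < protTarget)
        stop(sprintf("protein RMSD target %.2f A unreachable (achieved %.2f A)",
                     protTarget, fp(hi)))
      for (it in 1:100) {
        s <- (lo + hi) / 2
        if (fp(s) < protTarget) lo <- s else hi <- s
      }
      P[pi0, ] <- .proteinPerturbation(Pp, (lo + hi) / 2, draw, resseq)
    }

    coords(out) <- P
    out@metadata$candidate_seed <- candidateSeed
    out
  })
}

#' Generate a complete synthetic fixture
#'
#' Ground-truth complex, simulated target map, and `nCandidates` perturbed
#' candidate models. Candidate i's perturbation targets are scaled by a
#' graded multiplier (evenly spaced over 0.6-1.4 around the spec targets),
#' emulating the spread of independent AI predictions of one complex; the
#' least-perturbed candidate is always candidate 1. Fully reproducible from
#' the spec.
#'
#' @param spec a [FixtureSpec-class].
#' @return A [Fixture-class].
#' @export
makeFixture <- function(spec) {
  gt <- makeComplex(spec)
  map <- makeTargetMap(gt, spec)
  mult <- if (spec@nCandidates == 1L) 1
          else seq(0.6, 1.4, length.out = spec@nCandidates)
  models <- lapply(seq_len(spec@nCandidates), function(i) {
    perturbCandidate(gt, spec, candidateSeed = spec@seed + 7919L * i,
                     ligandScale = mult[i], proteinScale = mult[i])
  })
  names(models) <- sprintf("candidate_%d", seq_len(spec@nCandidates))
  new("Fixture", groundTruth = gt, targetMap = map,
      candidates = CandidateSet(models, sourceNote = "synthetic fixture"),
      provenance = spec)
}

#' Write / read a fixture as plain files
#'
#' Writes `ground_truth.pdb`, `target_map.mrc`, `candidate_<i>.pdb` and a
#' JSON spec into a directory; `readFixture` reconstructs the
#' [Fixture-class] from them.
#'
#' @param fixture a [Fixture-class].
#' @param dir directory (created if missing).
#' @return `writeFixture` invisibly returns `dir`; `readFixture` a
#'   [Fixture-class].
#' @export
writeFixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeStructure(fixture@groundTruth, file.path(dir, "ground_truth.pdb"))
  writeMap(fixture@targetMap, file.path(dir, "target_map.mrc"))
  for (i in seq_along(fixture@candidates@models))
    writeStructure(fixture@candidates@models[[i]],
                   file.path(dir, sprintf("candidate_%d.pdb", i)))
  s <- fixture@provenance
  jsonlite::write_json(
    list(n_residues = s@nResidues, ligand_heavy_atoms = s@ligandHeavyAtoms,
         map_resolution = s@mapResolution, voxel_size = s@voxelSize,
         noise_sigma = s@noiseSigma, ligand_rmsd_target = s@ligandRmsdTarget,
         protein_rmsd_target = s@proteinRmsdTarget, flip = s@flip,
         n_candidates = s@nCandidates, seed = s@seed),
    file.path(dir, "fixture_spec.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeFixture
#' @export
readFixture <- function(dir) {
  j <- jsonlite::read_json(file.path(dir, "fixture_spec.json"),
                           simplifyVector = TRUE)
  spec <- fixtureSpec(j$n_residues, j$ligand_heavy_atoms, j$map_resolution,
                      j$voxel_size, j$noise_sigma, j$ligand_rmsd_target,
                      j$protein_rmsd_target, j$flip, j$n_candidates, j$seed)
  gt <- readStructure(file.path(dir, "ground_truth.pdb"))
  map <- readMap(file.path(dir, "target_map.mrc"))
  map@resolution <- spec@mapResolution
  models <- lapply(seq_len(spec@nCandidates), function(i)
    readStructure(file.path(dir, sprintf("candidate_%d.pdb", i))))
  names(models) <- sprintf("candidate_%d", seq_len(spec@nCandidates))
  new("Fixture", groundTruth = gt, targetMap = map,
      candidates = CandidateSet(models, sourceNote = paste("read from", dir)),
      provenance = spec)
}
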