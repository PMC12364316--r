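# Restraint-field derivation, energies/forces, and the PLIE monitor.

test_that("a water-like 3-atom toy yields 2 bonds and 1 angle at rest", {
  s <- Structure(data.frame(
    name = c("O", "H1", "H2"), element = c("O", "H", "H"), resname = "HOH",
    resseq = 1L,
    x = c(0, 0.9572, 0.9572 * cos(104.5 * pi / 180)),
    y = c(0, 0, 0.9572 * sin(104.5 * pi / 180)), z = 0, hetero = TRUE))
  p <- deriveParams(s, kContact = 0)
  expect_equal(nrow(p@bonds), 2L)
  expect_equal(nrow(p@angles), 1L)
  expect_equal(unname(p@angles[1, "theta0"]), 104.5 * pi / 180,
               tolerance = 1e-6)
  # reference geometry => bonded energy exactly zero (no nonbonded pairs left)
  ef <- energyForces(s, p)
  expect_equal(ef$energy, 0, tolerance = 1e-12)
})

test_that("bond inference equals an exhaustive cutoff scan", {
  s <- chainToy(20L, seed = 9L)
  p <- deriveParams(s, kContact = 0)
  rcov <- emligfit:::elementCovalentRadius(atoms(s)$element)
  pc <- coords(s)
  oracle <- list()
  for (i in 1:19) for (j in (i + 1):20) {
    if (sqrt(sum((pc[i, ] - pc[j, ])^2)) < 1.3 * (rcov[i] + rcov[j]))
      oracle[[length(oracle) + 1L]] <- c(i, j)
  }
  oracle <- do.call(rbind, oracle)
  expect_equal(nrow(p@bonds), nrow(oracle))
  expect_setequal(paste(p@bonds[, 1], p@bonds[, 2]),
                  paste(oracle[, 1], oracle[, 2]))
})

test_that("overlapping atoms are rejected with the pair named", {
  s <- Structure(data.frame(name = c("C1", "C2"), element = "C",
                            resname = "LIG", resseq = 1L,
                            x = c(0, 0.05), y = 0, z = 0, hetero = TRUE))
  expect_error(deriveParams(s), "overlapping")
  ok <- Structure(data.frame(name = c("C1", "C2"), element = "C",
                             resname = "LIG", resseq = 1L,
                             x = c(0, 5), y = 0, z = 0, hetero = TRUE))
  p <- suppressWarnings(deriveParams(ok, kContact = 0))
  cm <- coords(ok); cm[2, 1] <- 0.05; coords(ok) <- cm
  expect_error(energyForces(ok, p), "atoms 1 and 2")
})

test_that("two neutral atoms at the LJ minimum have energy -eps, force 0", {
  sig <- 3.4; eps <- 0.36
  s <- Structure(data.frame(name = c("C1", "C2"), element = "C",
                            resname = "LIG", resseq = 1:2,
                            x = c(0, 2^(1 / 6) * sig), y = 0, z = 0,
                            hetero = TRUE))
  p <- suppressWarnings(deriveParams(s, kContact = 0))
  r <- energyForces(s, p)
  expect_equal(r$energy, -eps, tolerance = 5e-3)   # force-switch shift ~0.3%
  expect_lt(max(abs(r$forces)), 1e-10)
  # beyond the 12 A cutoff everything vanishes, charges included
  cm <- coords(s); cm[2, 1] <- 12.5; coords(s) <- cm
  p2 <- suppressWarnings(deriveParams(s, charges = c(0.5, -0.5), kContact = 0))
  r2 <- energyForces(s, p2)
  expect_identical(r2$energy, 0)
  expect_true(all(r2$forces == 0))
})

test_that("forces are the exact negative gradient of the energy", {
  s <- chainToy(15L, seed = 12L)
  withr::with_seed(13, q <- rnorm(15, 0, 0.2))
  p <- deriveParams(s, charges = q)   # bonds+angles+contacts+LJ+Coulomb
  ef <- energyForces(s, p)
  h <- 1e-5
  for (i in c(1L, 5L, 11L, 15L)) {
    for (c0 in 1:3) {
      sp <- s
      cm <- coords(s)
      cm[i, c0] <- cm[i, c0] + h; coords(sp) <- cm
      up <- energyForces(sp, p)$energy
      cm[i, c0] <- cm[i, c0] - 2 * h; coords(sp) <- cm
      dn <- energyForces(sp, p)$energy
      fd <- -(up - dn) / (2 * h)
      expect_equal(ef$forces[i, c0], fd, tolerance = 1e-5)
    }
  }
})

test_that("energy is invariant under rigid motion; net force/torque vanish", {
  s <- chainToy(12L, seed = 14L)
  p <- deriveParams(s)
  e0 <- energyForces(s, p)
  tf <- rigidTransform(c(0.8, 0.36, -0.3, 0.37), translation = c(3, -2, 7),
                       center = colMeans(coords(s)))
  e1 <- energyForces(applyTransform(s, tf), p)
  expect_equal(e1$energy, e0$energy, tolerance = 1e-9)
  expect_lt(max(abs(colSums(e0$forces))), 1e-9)
  rel <- sweep(coords(s), 2, colMeans(coords(s)))
  torque <- c(sum(rel[, 2] * e0$forces[, 3] - rel[, 3] * e0$forces[, 2]),
              sum(rel[, 3] * e0$forces[, 1] - rel[, 1] * e0$forces[, 3]),
              sum(rel[, 1] * e0$forces[, 2] - rel[, 2] * e0$forces[, 1]))
  expect_lt(max(abs(torque)), 1e-9)
})

test_that("PLIE equals an independent pairwise double loop", {
  fx <- defaultFixture()
  s <- fx@groundTruth
  prot <- selectProtein(s)
  lig <- selectLigand(s)
  withr::with_seed(15, q <- rnorm(nAtoms(s), 0, 0.1))
  p <- deriveParams(s, charges = q)
  r <- plie(s, prot, lig, p)
  # naive oracle with the same switched potentials, evaluated pair by pair
  oracle <- 0
  pc <- coords(s)
  for (i in selectionIndices(prot)) for (j in selectionIndices(lig)) {
    two <- Structure(atoms(s)[c(i, j), ])
    pp <- p
    pp@ljSigma <- p@ljSigma[c(i, j)]; pp@ljEps <- p@ljEps[c(i, j)]
    pp@charges <- p@charges[c(i, j)]
    pp@bonds <- matrix(numeric(0), 0, 4); pp@angles <- matrix(numeric(0), 0, 5)
    pp@contacts <- matrix(numeric(0), 0, 4)
    pp@exclusions <- matrix(integer(0), 0, 2)
    pp@scaled14 <- matrix(integer(0), 0, 2)
    oracle <- oracle + energyForces(two, pp)$energy
  }
  expect_equal(r@total, oracle, tolerance = 1e-9)
  expect_equal(r@perHeavyAtom, r@total / 16)
  expect_equal(r@nHeavy, 16L)
  # symmetric in selection order; overlapping selections rejected
  expect_equal(plie(s, prot, lig, p)@total,
               {
                 sw <- plie(s, lig, prot, p)   # per-heavy differs, total same
                 sw@total
               })
  expect_error(plie(s, prot, Selection(selectionIndices(prot)[1:4]), p),
               "overlap")
})

test_that("a far-displaced ligand has exactly zero PLIE", {
  fx <- defaultFixture()
  s <- fx@groundTruth
  lig <- selectLigand(s)
  cm <- coords(s)
  cm[selectionIndices(lig), ] <- cm[selectionIndices(lig), ] + 40
  coords(s) <- cm
  p <- deriveParams(s)
  r <- plie(s, selectProtein(s), lig, p)
  expect_identical(r@total, 0)
  expect_identical(r@perHeavyAtom, 0)
})

test_that("parameters survive a JSON round trip", {
  s <- chainToy(10L, seed = 16L)
  p <- deriveParams(s, charges = rep(c(0.1, -0.1), 5))
  f <- withr::local_tempfile(fileext = ".json")
  writeFFParams(p, f)
  p2 <- readFFParams(f)
  expect_equal(p2@bonds, p@bonds, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(p2@angles, p@angles, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(p2@contacts, p@contacts, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(energyForces(s, p2)$energy, energyForces(s, p)$energy,
               tolerance = 1e-12)
})
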