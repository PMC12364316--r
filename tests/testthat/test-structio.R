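# Structure and map I/O, element resolution, altloc policy, selections.

test_that("PDB reading resolves records, elements and altlocs", {
  f <- writeMiniPDB(withr::local_tempfile(fileext = ".pdb"))
  s <- readStructure(f)
  expect_equal(nAtoms(s), 3L)
  expect_setequal(atoms(s)$element, c("N", "C", "O"))
  expect_equal(coords(s)[1, ], c(x = 1, y = 2, z = 3))

  # altloc: A at occupancy 0.6 beats B at 0.4; element inferred from name
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AGLY A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      2  CA BGLY A   1       9.000   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CB  GLY A   1       2.500   0.000   0.000  1.00  0.00",
    "END"), f2)
  s2 <- readStructure(f2)
  expect_equal(nAtoms(s2), 2L)
  expect_equal(atoms(s2)$x[1], 1)          # highest occupancy retained
  expect_equal(atoms(s2)$element[2], "C")  # inferred from atom name

  expect_error(readStructure(withr::local_tempfile(fileext = ".pdb")),
               "not found")
})

test_that("unknown elements are reported with the offending atom", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  Q7  UNK A   1       1.000   2.000   3.000  1.00  0.00",
    "END"), f)
  expect_error(readStructure(f), "unknown element.*serial 1")
})

test_that("structure write/read round-trips coordinates to format precision", {
  fx <- defaultFixture()
  s <- fx@groundTruth
  f <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(s, f)
  s2 <- readStructure(f)
  expect_equal(nAtoms(s2), nAtoms(s))
  expect_equal(atoms(s2)$name, atoms(s)$name)
  expect_equal(atoms(s2)$resseq, atoms(s)$resseq)
  expect_lt(max(abs(coords(s2) - coords(s))), 1e-3)

  one <- Structure(data.frame(name = "C1", element = "C", resname = "LIG",
                              resseq = 1L, x = 0, y = 0, z = 0, hetero = TRUE))
  f1 <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(one, f1)
  recs <- grep("^(ATOM|HETATM)", readLines(f1), value = TRUE)
  expect_length(recs, 1L)
  expect_match(recs, "^HETATM")
})

test_that("multi-character chain ids are refused on write", {
  s <- Structure(data.frame(name = "C1", element = "C", resname = "LIG",
                            resseq = 1L, chain = "AB", x = 0, y = 0, z = 0,
                            hetero = TRUE))
  expect_error(writeStructure(s, withr::local_tempfile(fileext = ".pdb")),
               "single character")
})

test_that("minimal mmCIF atom_site loops read equivalently to PDB", {
  f <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_toy", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
    "_atom_site.Cartn_z", "_atom_site.occupancy",
    "ATOM 1 N N . GLY A 1 1.000 2.000 3.000 1.00",
    "ATOM 2 C CA . GLY A 1 2.400 2.100 3.200 1.00",
    "HETATM 3 O O1 . LIG L 1 3.100 3.500 3.100 1.00",
    "#"), f)
  s <- readStructure(f)
  expect_equal(nAtoms(s), 3L)
  expect_equal(atoms(s)$element, c("N", "C", "O"))
  expect_equal(atoms(s)$hetero, c(FALSE, FALSE, TRUE))
  expect_equal(unname(coords(s)[3, 3]), 3.1)
})

test_that("MRC maps round-trip values, origin and voxel size", {
  withr::with_seed(7, {
    g <- DensityGrid(array(rnorm(8 * 10 * 12), c(8, 10, 12)),
                     origin = c(-3.5, 2, 11), voxel = c(1.1, 1.3, 0.9))
  })
  f <- withr::local_tempfile(fileext = ".mrc")
  writeMap(g, f)
  g2 <- readMap(f)
  expect_equal(dim(gridValues(g2)), dim(gridValues(g)))
  expect_lt(max(abs(gridValues(g2) - gridValues(g))), 1e-6)  # float32
  expect_equal(gridOrigin(g2), gridOrigin(g), tolerance = 1e-6)
  expect_equal(voxelSize(g2), voxelSize(g), tolerance = 1e-6)
  # header statistics consistent with the values
  con <- file(f, "rb"); seek(con, 76)
  stats <- readBin(con, "numeric", 3, size = 4, endian = "little")
  close(con)
  expect_equal(stats, c(min(gridValues(g)), max(gridValues(g)),
                        mean(gridValues(g))), tolerance = 1e-6)
})

test_that("nxstart-encoded origins shift by start times voxel", {
  vox <- c(0.5, 0.5, 0.5)
  g <- DensityGrid(array(seq_len(27), c(3, 3, 3)),
                   origin = c(2, -1.5, 3) * vox, voxel = vox)
  f <- withr::local_tempfile(fileext = ".mrc")
  expect_error(emligfit:::.writeMRC(g, f, originAsStart = TRUE),
               "integer multiple")
  g@origin <- c(2, -2, 3) * vox
  emligfit:::.writeMRC(g, f, originAsStart = TRUE)
  g2 <- readMap(f)
  # independent header arithmetic: origin = nstart * voxel
  con <- file(f, "rb"); seek(con, 16)
  nstart <- readBin(con, "integer", 3, size = 4, endian = "little")
  close(con)
  expect_equal(gridOrigin(g2), nstart * vox)
  expect_equal(gridOrigin(g2), g@origin)
})

test_that("permuted axis order is normalised to x,y,z", {
  withr::with_seed(8, {
    g <- DensityGrid(array(rnorm(4 * 5 * 6), c(4, 5, 6)), voxel = 1)
  })
  for (ord in list(c(2L, 1L, 3L), c(3L, 1L, 2L), c(2L, 3L, 1L))) {
    f <- withr::local_tempfile(fileext = ".mrc")
    emligfit:::.writeMRC(g, f, axisOrder = ord)
    g2 <- readMap(f)
    expect_lt(max(abs(gridValues(g2) - gridValues(g))), 1e-6)
  }
})

test_that("map writing refuses NaN; reading refuses wrong modes", {
  g <- DensityGrid(array(1, c(4, 4, 4)))
  g@values[1] <- NaN
  expect_error(writeMap(g, withr::local_tempfile(fileext = ".mrc")), "NaN")
  # corrupt the mode field of a valid file
  g@values[1] <- 0
  f <- withr::local_tempfile(fileext = ".mrc")
  writeMap(g, f)
  con <- file(f, "r+b"); seek(con, 12, rw = "write")
  writeBin(1L, con, size = 4, endian = "little"); close(con)
  expect_error(readMap(f), "mode 1")
  # non-orthogonal cell
  writeMap(g, f)
  con <- file(f, "r+b"); seek(con, 52, rw = "write")
  writeBin(c(90, 90, 120), con, size = 4, endian = "little"); close(con)
  expect_error(readMap(f), "non-orthogonal")
})

test_that("ligand selection picks named or largest hetero residue", {
  fx <- defaultFixture()
  s <- fx@groundTruth
  lig <- selectLigand(s, "LIG")
  expect_equal(length(lig), 16L)
  expect_selection_equal(lig, selectLigand(s, "auto"))
  expect_error(selectLigand(s, "XYZ"), "LIG")
  # waters and ions are never auto-selected
  a <- atoms(s)
  wat <- data.frame(name = "O", element = "O", resname = "HOH",
                    resseq = 99L, chain = "W", x = 50, y = 50, z = 50,
                    occupancy = 1, hetero = TRUE, mass = 15.999, charge = 0,
                    serial = max(a$serial) + 1L)
  s2 <- Structure(rbind(a, wat[names(a)]))
  expect_selection_equal(selectLigand(s2, "auto"), lig)
})

test_that("pocket selection matches a brute-force residue scan", {
  fx <- defaultFixture()
  s <- fx@groundTruth
  lig <- selectLigand(s)
  for (cutoff in c(0, 3.5, 4, 6)) {
    poc <- selectPocket(s, lig, cutoff = cutoff)
    # oracle: exhaustive all-pairs double loop over residues
    a <- atoms(s)
    pc <- coords(s)
    lc <- pc[selectionIndices(lig), , drop = FALSE]
    keep <- integer(0)
    for (rs in unique(a$resseq[!a$hetero])) {
      idx <- which(!a$hetero & a$resseq == rs)
      dmin <- min(vapply(idx, function(i)
        min(sqrt(colSums((t(lc) - pc[i, ])^2))), numeric(1)))
      if (dmin < cutoff) keep <- c(keep, idx)
    }
    expect_setequal(selectionIndices(poc), keep)
  }
  # ligand and pocket partition: no shared atoms
  poc <- selectPocket(s, lig)
  expect_length(intersect(selectionIndices(poc), selectionIndices(lig)), 0L)
})

test_that("pocket threshold is strict and heavyAtoms drops hydrogens", {
  # one protein residue at 3.9 A (in), one at 4.1 A (out)
  s <- Structure(data.frame(
    name = c("C1", "CA", "CA"), element = "C",
    resname = c("LIG", "GLY", "GLY"), resseq = c(1L, 1L, 2L),
    chain = c("L", "A", "A"), x = c(0, 3.9, 4.1), y = 0, z = 0,
    hetero = c(TRUE, FALSE, FALSE)))
  lig <- selectLigand(s, "LIG")
  expect_equal(atoms(s)$resseq[selectionIndices(selectPocket(s, lig, 4))], 1L)
  expect_length(selectPocket(s, lig, cutoff = 0), 0L)

  sh <- Structure(data.frame(
    name = c("C1", "H1", "H2"), element = c("C", "H", "H"), resname = "LIG",
    resseq = 1L, x = 0:2, y = 0, z = 0, hetero = TRUE))
  all3 <- Selection(1:3)
  expect_equal(selectionIndices(heavyAtoms(all3, sh)), 1L)
  expect_length(heavyAtoms(Selection(2:3), sh), 0L)
})
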