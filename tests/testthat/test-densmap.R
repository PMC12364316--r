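# Density simulation, masked cross-correlation, analytic gradient, resampling.

test_that("a single atom reproduces the closed-form Gaussian peak", {
  s <- Structure(data.frame(name = "C1", element = "C", resname = "LIG",
                            resseq = 1L, x = 5, y = 5, z = 5, hetero = TRUE))
  grid <- DensityGrid(array(0, c(11, 11, 11)), voxel = 1)
  p <- mapSimParams(3.2, amplitudeMode = "uniform", gridSpec = grid)
  d <- simulateDensity(s, Selection(1L, "ligand"), p)
  sig <- 3.2 / (2 * sqrt(2 * log(2)))
  expect_equal(gridValues(d)[6, 6, 6], 1 / ((2 * pi)^1.5 * sig^3),
               tolerance = 1e-6)
  # normalisation: integral ~ amplitude at 4 sigma truncation
  expect_equal(sum(gridValues(d)) * prod(voxelSize(d)), 1, tolerance = 0.01)
  # atomic-number amplitudes scale the field by Z
  pz <- mapSimParams(3.2, gridSpec = grid)
  dz <- simulateDensity(s, Selection(1L, "ligand"), pz)
  expect_equal(gridValues(dz), 6 * gridValues(d), tolerance = 1e-12)
})

test_that("density is additive and translation-equivariant", {
  grid <- DensityGrid(array(0, c(14, 14, 14)), voxel = 1)
  p <- mapSimParams(3.0, gridSpec = grid)
  two <- Structure(data.frame(name = c("C1", "O2"), element = c("C", "O"),
                              resname = "LIG", resseq = 1L,
                              x = c(5, 7.3), y = c(6, 5.2), z = c(6.5, 7),
                              hetero = TRUE))
  d12 <- simulateDensity(two, Selection(1:2, "ligand"), p)
  d1 <- simulateDensity(two, Selection(1L, "ligand"), p)
  d2 <- simulateDensity(two, Selection(2L, "ligand"), p)
  expect_equal(gridValues(d12), gridValues(d1) + gridValues(d2),
               tolerance = 1e-12)
  # exact whole-voxel shift equivariance
  shifted <- two
  coords(shifted) <- coords(two) + matrix(rep(c(2, 1, 0), each = 2), 2)
  ds <- simulateDensity(shifted, Selection(1:2, "ligand"), p)
  v0 <- gridValues(d12)[3:10, 3:10, 3:10]
  v1 <- gridValues(ds)[5:12, 4:11, 3:10]
  expect_equal(v1, v0, tolerance = 1e-12)
})

test_that("masked cc matches a naive R implementation and its invariants", {
  fx <- defaultFixture()
  p <- defaultParams()
  gt <- fx@groundTruth
  sel <- selectLigand(gt)
  pg <- mapSimParams(3.2, gridSpec = fx@targetMap)
  model <- simulateDensity(gt, sel, pg)
  # self and anti correlation
  expect_equal(ccValue(crossCorrelation(model, model)), 1)
  anti <- model; anti@values <- -anti@values
  expect_equal(ccValue(crossCorrelation(model, anti)), -1)
  # naive oracle on the displaced-copy example
  disp <- gt
  coords(disp) <- coords(gt) + 2
  model2 <- simulateDensity(disp, sel, pg)
  msk <- supportMask(disp, sel, fx@targetMap, p)
  r <- crossCorrelation(model2, fx@targetMap, mask = msk)
  m <- gridValues(model2)[msk]; t0 <- gridValues(fx@targetMap)[msk]
  naive <- sum((m - mean(m)) * (t0 - mean(t0))) /
    sqrt(sum((m - mean(m))^2) * sum((t0 - mean(t0))^2))
  expect_equal(ccValue(r), naive, tolerance = 1e-12)
  expect_equal(maskVoxels(r), sum(msk))
  # affine invariance of either map under mean subtraction
  aff <- fx@targetMap; aff@values <- 3.7 * aff@values + 0.21
  expect_equal(ccValue(crossCorrelation(model2, aff, mask = msk)),
               ccValue(r), tolerance = 1e-10)
  # degenerate masks are flagged
  expect_error(crossCorrelation(model2, fx@targetMap,
                                mask = array(FALSE, dim(msk))), "mask")
})

test_that("entity cc separates ligand misfit from protein fit", {
  fx <- defaultFixture()
  p <- defaultParams()
  gt <- fx@groundTruth
  lig <- selectLigand(gt)
  protCC0 <- ccValue(entityCC(gt, selectProtein(gt), fx@targetMap, p))
  ligCC0 <- ccValue(entityCC(gt, lig, fx@targetMap, p))
  expect_gt(protCC0, 0.99)
  expect_gt(ligCC0, 0.9)
  # ligand displaced far outside its density: ligand cc ~ 0, protein cc same
  far <- gt
  cm <- coords(gt)
  cm[selectionIndices(lig), 1] <- cm[selectionIndices(lig), 1] + 12
  coords(far) <- cm
  expect_lt(abs(ccValue(entityCC(far, lig, fx@targetMap, p))), 0.35)
  expect_equal(ccValue(entityCC(far, selectProtein(far), fx@targetMap, p)),
               protCC0, tolerance = 1e-12)
})

test_that("cc gradient matches central finite differences", {
  toy <- randomToy(10L, seed = 4L)
  target <- randomToy(10L, seed = 5L)
  grid <- DensityGrid(array(0, c(16, 16, 16)), origin = c(-2, -2, -2),
                      voxel = 1)
  # truncation 7 sigma keeps the truncation boundary far below the FD scale
  p <- mapSimParams(3.0, truncationRadius = 7, gridSpec = grid)
  tmap <- simulateDensity(target, Selection(1:10, "ligand"), p)
  sel <- Selection(1:10, "ligand")
  res <- ccGradient(toy, sel, tmap, p)
  msk <- supportMask(toy, sel, tmap, p)
  h <- 1e-4
  for (i in c(1L, 3L, 6L, 10L)) {
    for (c0 in 1:3) {
      cm <- coords(toy)
      tp <- toy
      cm[i, c0] <- cm[i, c0] + h; coords(tp) <- cm
      up <- ccGradient(tp, sel, tmap, p, frozenMask = msk)$cc
      cm[i, c0] <- cm[i, c0] - 2 * h; coords(tp) <- cm
      dn <- ccGradient(tp, sel, tmap, p, frozenMask = msk)$cc
      fd <- (up - dn) / (2 * h)
      expect_equal(res$gradient[i, c0], fd, tolerance = 1e-4)
    }
  }
  # stationarity at the perfect fit
  perfect <- ccGradient(target, sel, tmap, p)
  expect_equal(perfect$cc, 1)
  expect_lt(max(abs(perfect$gradient)), 1e-6)
  # unselected atoms get zero rows
  part <- ccGradient(toy, Selection(1:4, "ligand"), tmap, p)
  expect_true(all(part$gradient[5:10, ] == 0))
})

test_that("a rigid offset along +x feels a restoring (-x) net gradient", {
  target <- randomToy(8L, seed = 6L)
  grid <- DensityGrid(array(0, c(18, 16, 16)), origin = c(-2, -2, -2),
                      voxel = 1)
  p <- mapSimParams(3.0, gridSpec = grid)
  tmap <- simulateDensity(target, Selection(1:8, "ligand"), p)
  off <- target
  coords(off) <- coords(target) + matrix(rep(c(1.5, 0, 0), each = 8), 8)
  g <- ccGradient(off, Selection(1:8, "ligand"), tmap, p,
                  maskRadius = p@truncationRadius)
  expect_lt(sum(g$gradient[, 1]), 0)
})

test_that("resampling is identity on itself and exact on constants", {
  withr::with_seed(11, {
    g <- DensityGrid(array(rnorm(6 * 7 * 8), c(6, 7, 8)),
                     origin = c(1, 2, 3), voxel = c(1.2, 1, 0.8))
  })
  expect_equal(gridValues(resampleOnto(g, g)), gridValues(g),
               tolerance = 1e-12)
  const <- DensityGrid(array(2.5, c(6, 7, 8)), origin = c(1, 2, 3), voxel = 1)
  ref <- DensityGrid(array(0, c(5, 5, 5)), origin = c(2.3, 3.1, 4.7),
                     voxel = 0.7)
  expect_true(all(abs(gridValues(resampleOnto(const, ref)) - 2.5) < 1e-12))
  # no-overlap error
  farRef <- DensityGrid(array(0, c(3, 3, 3)), origin = c(100, 100, 100))
  expect_error(resampleOnto(g, farRef), "overlap")
})

test_that("downsample-then-upsample of a smooth field has small RMS error", {
  s <- Structure(data.frame(name = "C1", element = "C", resname = "LIG",
                            resseq = 1L, x = 8, y = 8, z = 8, hetero = TRUE))
  fine <- DensityGrid(array(0, c(33, 33, 33)), voxel = 0.5)
  p <- mapSimParams(4, amplitudeMode = "uniform", gridSpec = fine)
  d <- simulateDensity(s, Selection(1L, "ligand"), p)
  coarse <- DensityGrid(array(0, c(17, 17, 17)), voxel = 1)
  down <- resampleOnto(d, coarse)
  back <- resampleOnto(down, fine)
  inner <- gridValues(d)[5:29, 5:29, 5:29]
  innerB <- gridValues(back)[5:29, 5:29, 5:29]
  expect_lt(sqrt(mean((innerB - inner)^2)), 0.02 * max(gridValues(d)))
})
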