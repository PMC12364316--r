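# Density forces, adaptive scaling, the Langevin engine, trace reducers.

test_that("density forces scale linearly in k and vanish at the optimum", {
  fx <- defaultFixture()
  gt <- fx@groundTruth
  p <- defaultParams()
  sel <- Selection(seq_len(nAtoms(gt)), "custom")
  f1 <- densityForce(gt, sel, fx@targetMap, p, k = 1000)
  f2 <- densityForce(gt, sel, fx@targetMap, p, k = 2000)
  expect_equal(f2, 2 * f1, tolerance = 1e-12)
  # the ground truth generated the map: forces are (numerically) zero
  expect_lt(max(abs(f1)), 1e-3)
  # capping clips components exactly
  cand <- candidateModels(fx@candidates)[[3]]
  fr <- densityForce(cand, sel, fx@targetMap, p, k = 1e9, forceCap = 5)
  expect_lte(max(abs(fr)), 5)
})

test_that("adaptive scaling grows k only on stalls and caps at kMax", {
  cfg <- fitConfig(forceConstant = 1000, growthFactor = 1.01,
                   ccEpsilon = 1e-5, kMax = 1010)
  expect_equal(adaptiveScale(c(0.5, 0.5), 1000, cfg), 1010)        # stall
  expect_equal(adaptiveScale(c(0.5, 0.51), 1000, cfg), 1000)       # improving
  k <- 1000
  for (i in 1:10) k <- adaptiveScale(c(0.5, 0.5), k, cfg)
  expect_equal(k, 1010)                                            # capped
  off <- fitConfig(adaptiveScaling = FALSE)
  expect_equal(adaptiveScale(c(0.5, 0.5), 1000, off), 1000)
})

test_that("zero-duration runs return the initial state only", {
  fx <- defaultFixture()
  cfg <- fitConfig(duration = 0, preRelaxSteps = 0L, seed = 0)
  fit <- runFlexFit(fx@groundTruth, fx@targetMap, cfg, defaultParams())
  expect_equal(nFrames(fit$trajectory), 1L)
  expect_equal(nrow(traceData(fit$trace)), 1L)
  expect_equal(coords(trajectoryFrame(fit$trajectory, 1)),
               coords(fx@groundTruth))
  expect_gt(traceData(fit$trace)$cc_ligand[1], 0.9)
})

test_that("identical seeds give bit-identical traces; k never decreases", {
  fx <- defaultFixture()
  cand <- candidateModels(fx@candidates)[[1]]
  cfg <- fitConfig(duration = 2, seed = 42, preRelaxSteps = 100L)
  f1 <- runFlexFit(cand, fx@targetMap, cfg, defaultParams())
  f2 <- runFlexFit(cand, fx@targetMap, cfg, defaultParams())
  expect_identical(traceData(f1$trace), traceData(f2$trace))
  expect_identical(f1$trajectory@frames, f2$trajectory@frames)
  expect_true(all(diff(traceData(f1$trace)$k_current) >= 0))
  # different seed diverges
  f3 <- runFlexFit(cand, fx@targetMap, fitConfig(duration = 2, seed = 43,
                                                 preRelaxSteps = 100L),
                   defaultParams())
  expect_false(identical(traceData(f1$trace)$cc_ligand,
                         traceData(f3$trace)$cc_ligand))
})

test_that("with k = 0 and T = 0 the dynamics dissipates energy", {
  fx <- defaultFixture()
  gt <- fx@groundTruth
  ffp <- deriveParams(gt)
  cfg <- fitConfig(duration = 4, seed = 0, temperature = 0,
                   forceConstant = 0, kMax = 1, preRelaxSteps = 0L,
                   frameInterval = 100)
  fit <- runFlexFit(gt, fx@targetMap, cfg, defaultParams(), ffParams = ffp)
  pe <- vapply(seq_len(nFrames(fit$trajectory)), function(i)
    energyForces(trajectoryFrame(fit$trajectory, i), ffp)$energy, numeric(1))
  expect_lt(pe[length(pe)], pe[1])
  # started at rest, dissipation bounds every later potential energy by the
  # initial one (kinetic/potential exchange makes PE itself non-monotone)
  expect_true(all(pe <= pe[1] + abs(pe[1]) * 0.01 + 1e-6))
})

test_that("with k = 0 there is no systematic pull toward the density", {
  fx <- defaultFixture()
  cand <- candidateModels(fx@candidates)[[3]]
  runFinal <- function(sd, k) {
    cfg <- fitConfig(duration = 1.5, seed = sd, forceConstant = k,
                     kMax = max(k, 1), adaptiveScaling = FALSE,
                     preRelaxSteps = 0L)
    td <- traceData(runFlexFit(cand, fx@targetMap, cfg, defaultParams())$trace)
    td$cc_ligand[nrow(td)]
  }
  finalNull <- vapply(0:4, runFinal, numeric(1), k = 0)
  finalForced <- vapply(0:4, runFinal, numeric(1), k = 5000)
  # unforced thermal wandering never approaches recovery; the density force
  # systematically does better in every seeded pair
  expect_true(all(finalNull < 0.6))
  expect_true(all(finalForced > finalNull))
  expect_gt(mean(finalForced), mean(finalNull) + 0.15)
})

test_that("the monitor trace improves the pose on a short recovery run", {
  fx <- defaultFixture()
  cand <- candidateModels(fx@candidates)[[1]]
  cfg <- fitConfig(duration = 15, seed = 0, preRelaxSteps = 200L)
  fit <- runFlexFit(cand, fx@targetMap, cfg, defaultParams())
  td <- traceData(fit$trace)
  expect_gt(td$cc_ligand[nrow(td)], td$cc_ligand[1])
  expect_true(all(diff(td$time_ps) > 0))
  lig <- selectLigand(fx@groundTruth)
  expect_lt(rmsd(trajectoryFrame(fit$trajectory, -1), fx@groundTruth, lig),
            rmsd(cand, fx@groundTruth, lig))
})

test_that("last-n mean matches a two-pass computation and warns when short", {
  td <- data.frame(time_ps = seq(0, 10, by = 0.5))
  withr::with_seed(30, td$cc_ligand <- runif(nrow(td)))
  td$cc_pocket <- td$cc_protein <- td$plie_per_heavy_atom <- 0
  td$k_current <- 1000
  tr <- new("Trace", data = td,
            events = data.frame(time_ps = numeric(0), label = character(0)))
  tmpl <- randomToy(3L)
  traj <- new("Trajectory",
              frames = rep(list(coords(tmpl)), 21), times = td$time_ps,
              template = tmpl, saveInterval = 1L)
  r <- lastNMean(tr, traj, n = 20L, field = "cc_ligand")
  v <- utils::tail(td$cc_ligand, 20)
  expect_equal(r[["mean"]], mean(v))
  expect_equal(r[["se"]], sd(v) / sqrt(20))
  # constant series: zero standard error
  td$cc_ligand <- 0.7
  trc <- new("Trace", data = td, events = tr@events)
  expect_equal(lastNMean(trc, traj, 20L)[["se"]], 0)
  # 1..20 over the final 20 -> mean 10.5
  td$cc_ligand <- c(0, seq_len(20))
  expect_equal(lastNMean(new("Trace", data = td, events = tr@events),
                         traj, 20L)[["mean"]], 10.5)
  short <- new("Trajectory", frames = rep(list(coords(tmpl)), 5),
               times = td$time_ps[1:5], template = tmpl, saveInterval = 1L)
  expect_warning(lastNMean(tr, short, 20L), "using all")
})

test_that("traces round-trip through CSV including events", {
  td <- data.frame(time_ps = c(0, 1), cc_ligand = c(0.2, 0.3),
                   cc_pocket = c(0.4, 0.5), cc_protein = c(0.6, 0.7),
                   plie_per_heavy_atom = c(-3, -4), k_current = c(1e3, 2e3))
  ev <- data.frame(time_ps = 1, label = "force_cap_exceeded",
                   stringsAsFactors = FALSE)
  tr <- new("Trace", data = td, events = ev)
  f <- withr::local_tempfile(fileext = ".csv")
  writeTrace(tr, f)
  tr2 <- readTrace(f)
  expect_equal(traceData(tr2), td)
  expect_equal(traceEvents(tr2), ev)
})

test_that("runaway forces trigger graceful termination with an event", {
  fx <- defaultFixture()
  cand <- candidateModels(fx@candidates)[[5]]
  # a pathologically low force cap trips the >1%-of-atoms rule immediately
  cfg <- fitConfig(duration = 5, seed = 0, preRelaxSteps = 0L,
                   forceCap = 1e-4)
  fit <- runFlexFit(cand, fx@targetMap, cfg, defaultParams())
  ev <- traceEvents(fit$trace)
  expect_true("force_cap_exceeded" %in% ev$label)
  expect_lt(max(traceData(fit$trace)$time_ps), 5)
  expect_gte(nFrames(fit$trajectory), 1L)
})
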