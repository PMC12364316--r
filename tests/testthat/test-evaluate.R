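# Accuracy metric, candidate ranking, curation filter, report assembly.

test_that("the accuracy formula reproduces published benchmark arithmetic", {
  # worked cases from the ten-system benchmark table (max possible cc = 1)
  expect_equal(accuracy(0.2, 0.8), 40)     # weakest predicted ligand pose
  expect_equal(accuracy(0.46, 0.71), 75)   # predicted whole-protein case
  expect_equal(accuracy(0.74, 0.8), 94)    # fitted whole-protein case
  expect_equal(accuracy(0.35, 0.76), 59)
  # identity, symmetry and scale consistency
  expect_equal(accuracy(0.42, 0.42, 0.9), 100)
  expect_equal(accuracy(0.3, 0.7), accuracy(0.7, 0.3))
  expect_equal(accuracy(3, 7, 10), accuracy(0.3, 0.7, 1))
  expect_error(accuracy(0.5, 0.6, 0), "maxPossible")
})

test_that("the shipped benchmark table is complete and self-consistent", {
  b <- benchmarkCC()
  expect_equal(nrow(b), 10L)
  expect_equal(sum(b$needed_refinement), 7L)
  expect_true(all(b$ligand_cc_gt >= b$ligand_cc_pred - 0.2))
  # the published headline: fitted ligand accuracy of the refined systems
  fit <- accuracy(b$ligand_cc_fitted[b$needed_refinement],
                  b$ligand_cc_gt[b$needed_refinement])
  expect_true(all(fit >= 82 & fit <= 95))
})

test_that("candidates rank by ligand cc with documented tie-breaks", {
  fx <- defaultFixture()
  p <- defaultParams()
  r <- rankCandidates(fx@candidates, fx@targetMap, p, rigidFit = FALSE)
  expect_equal(r$bestId, "candidate_1")
  expect_equal(r$table$id[order(r$table$rank)], r$table$id)
  expect_true(all(diff(r$table$ligand_cc) <= 1e-12))
  # duplicating a candidate cannot change who wins; earlier input order wins
  dupModels <- c(candidateModels(fx@candidates)[1],
                 candidateModels(fx@candidates))
  names(dupModels) <- paste0("model_", seq_along(dupModels))
  dup <- CandidateSet(dupModels)
  r2 <- rankCandidates(dup, fx@targetMap, p, rigidFit = FALSE)
  expect_equal(ccValue(entityCC(candidateModels(dup)[[r2$bestId]],
                                selectLigand(candidateModels(dup)[[r2$bestId]]),
                                fx@targetMap, p)),
               r2$table$ligand_cc[1])
  expect_equal(r2$table$id[1], "model_1")
  # single candidate returns itself; empty set errors
  single <- CandidateSet(candidateModels(fx@candidates)[3])
  expect_equal(rankCandidates(single, fx@targetMap, p,
                              rigidFit = FALSE)$bestId, "candidate_3")
  expect_error(new("CandidateSet", models = list(), ligandCC = numeric(0),
                   sourceNote = ""), "at least one")
})

test_that("curation filter equals an independent predicate conjunction", {
  mk <- function(method = "cryo-EM", date = "2023-05-01",
                 olig = "monomeric", qed = 0.8, cov = FALSE, len = 500L,
                 contact = 3.5, chim = FALSE) {
    data.frame(determination_method = method, release_date = date,
               oligomeric_state = olig, ligand_qed = qed, is_covalent = cov,
               seq_length = len, min_contact = contact, is_chimeric = chim,
               stringsAsFactors = FALSE)
  }
  # boundary cases forced by the thresholds
  r <- curationFilter(rbind(
    mk(),                        # pass
    mk(qed = 0.69),              # fail: qed below threshold
    mk(qed = 0.7),               # pass: inclusive threshold
    mk(len = 1194L),             # pass (largest accepted target class)
    mk(len = 1201L),             # fail: length
    mk(contact = 4.0),           # fail: strict contact boundary
    mk(method = "X-ray diffraction"),
    mk(date = "2021-11-30"),     # before the window
    mk(olig = "dimeric", cov = TRUE)))
  expect_equal(r$pass,
               c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(r$reasons[2], "qed")
  expect_equal(r$reasons[6], "contact")
  expect_setequal(strsplit(r$reasons[9], ",")[[1]],
                  c("oligomeric", "covalent"))
  # missing fields fail with the stable "incomplete" code
  bad <- mk(); bad$ligand_qed <- NA
  expect_equal(curationFilter(bad)$reasons, "incomplete")

  # randomized records against an independently coded conjunction
  withr::with_seed(33, {
    n <- 60
    rec <- data.frame(
      determination_method = sample(c("cryo-EM", "X-ray", "NMR"), n, TRUE),
      release_date = as.Date("2021-06-01") + sample.int(1500, n),
      oligomeric_state = sample(c("monomeric", "dimeric"), n, TRUE),
      ligand_qed = round(runif(n, 0.5, 1), 2),
      is_covalent = sample(c(TRUE, FALSE), n, TRUE),
      seq_length = sample.int(1500, n),
      min_contact = round(runif(n, 2, 6), 2),
      is_chimeric = sample(c(TRUE, FALSE), n, TRUE),
      stringsAsFactors = FALSE)
  })
  got <- curationFilter(rec)$pass
  oracle <- grepl("cryo", rec$determination_method) &
    rec$release_date >= as.Date("2022-01-01") &
    rec$release_date <= as.Date("2024-06-30") &
    rec$oligomeric_state == "monomeric" & !rec$is_covalent &
    rec$ligand_qed >= 0.7 & rec$seq_length <= 1200 &
    rec$min_contact < 4 & !rec$is_chimeric
  expect_equal(got, oracle)
})

test_that("reports score a ground-truth 'fit' at 100% accuracy", {
  fx <- defaultFixture()
  p <- defaultParams()
  gt <- fx@groundTruth
  cfg <- fitConfig(duration = 0, preRelaxSteps = 0L)
  fit <- runFlexFit(gt, fx@targetMap, cfg, p)
  gtCC <- c(ligand = ccValue(entityCC(gt, selectLigand(gt), fx@targetMap, p)),
            pocket = ccValue(entityCC(gt, selectPocket(gt, selectLigand(gt)),
                                      fx@targetMap, p)),
            protein = ccValue(entityCC(gt, selectProtein(gt), fx@targetMap, p)))
  rep <- buildReport(gt, fit, fx@targetMap, p, groundTruthCC = gtCC)
  expect_equal(rep$predicted_accuracy, rep(100, 3))
  expect_equal(rep$fitted_accuracy, rep(100, 3))
  expect_equal(rep$entity, c("ligand", "pocket", "protein"))
  expect_length(attr(rep, "plie"), 2L)
  # without ground truth, accuracy columns are absent
  rep2 <- buildReport(gt, fit, fx@targetMap, p)
  expect_false("predicted_accuracy" %in% names(rep2))
  # empty trace errors
  emptyFit <- list(trajectory = new("Trajectory", frames = list(),
                                    times = numeric(0), template = gt,
                                    saveInterval = 1L),
                   trace = fit$trace)
  expect_error(buildReport(gt, emptyFit, fx@targetMap, p), "empty")
})
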