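# Candidate ranking, the accuracy metric, curation filter predicates, and
# report assembly.

#' Model accuracy relative to ground truth
#'
#' `accuracy = (1 - |model - groundTruth| / maxPossible) * 100` (percent).
#' For cross-correlation-based accuracies the maximum possible value is 1.
#' Symmetric in model and ground truth; no rounding is applied.
#'
#' @param modelValue metric value of the model under evaluation.
#' @param groundTruthValue the same metric for the deposited ground truth.
#' @param maxPossible maximum possible value of the metric (default 1).
#' @return Accuracy in percent. Vectorised.
#' @export
accuracy <- function(modelValue, groundTruthValue, maxPossible = 1) {
  if (any(maxPossible <= 0)) stop("maxPossible must be > 0")
  (1 - abs(modelValue - groundTruthValue) / maxPossible) * 100
}

#' Published cryo-EM protein-ligand benchmark table
#'
#' Per-system model-to-map cross-correlations (ligand, pocket, whole
#' protein) for the best AI prediction, the flexibly fitted model, and the
#' deposited ground-truth structure, plus PLIE per ligand heavy atom, for
#' ten drug-target complexes (two kinases, two GPCRs, six solute
#' transporters).
#'
#' @return data.frame with one row per system.
#' @export
benchmarkCC <- function() {
  utils::read.csv(system.file("extdata", "benchmark_cc.csv",
                              package = "emligfit"),
                  stringsAsFactors = FALSE)
}

#' Rank candidate models by ligand cross-correlation
#'
#' Rigid-body fits every candidate into the target map, scores the ligand
#' entity cc of each fitted pose, and sorts descending (ties: pocket cc,
#' then input order). The top-ranked model is the one taken forward to
#' flexible fitting.
#'
#' @param candidates a [CandidateSet-class].
#' @param targetMap the reference [DensityGrid-class].
#' @param params a [MapSimParams-class].
#' @param ligandName ligand residue name or `"auto"`.
#' @param rigidFit rigid-fit each candidate first (default `TRUE`).
#' @param nRestarts,seed passed to [fitRigid()].
#' @return List with `bestId`, `table` (data.frame id / ligand_cc /
#'   pocket_cc / rank), and `models` (the fitted [CandidateSet-class]).
#' @export
rankCandidates <- function(candidates, targetMap, params, ligandName = "auto",
                           rigidFit = TRUE, nRestarts = 4L, seed = 0L) {
  stopifnot(is(candidates, "CandidateSet"))
  if (length(candidates) == 0L) stop("empty candidate set")
  ids <- names(candidates@models)
  fitted <- candidates@models
  ligCC <- pocCC <- numeric(length(ids))
  for (i in seq_along(ids)) {
    s <- fitted[[i]]
    if (rigidFit) {
      fr <- fitRigid(s, targetMap, params, nRestarts = nRestarts,
                     seed = seed + i - 1L)
      s <- applyTransform(s, fr@transform)
      fitted[[i]] <- s
    }
    lig <- selectLigand(s, ligandName)
    poc <- selectPocket(s, lig)
    ligCC[i] <- ccValue(entityCC(s, lig, targetMap, params))
    pocCC[i] <- if (length(poc)) ccValue(entityCC(s, poc, targetMap, params))
                else NA_real_
  }
  ord <- order(-ligCC, -ifelse(is.na(pocCC), -Inf, pocCC), seq_along(ids))
  tab <- data.frame(id = ids[ord], ligand_cc = ligCC[ord],
                    pocket_cc = pocCC[ord], rank = seq_along(ids),
                    stringsAsFactors = FALSE)
  out <- new("CandidateSet", models = fitted, ligandCC = ligCC,
             sourceNote = candidates@sourceNote)
  list(bestId = tab$id[1], table = tab, models = out)
}

.CURATION_FIELDS <- c("determination_method", "release_date",
                      "oligomeric_state", "ligand_qed", "is_covalent",
                      "seq_length", "min_contact", "is_chimeric")

#' Benchmark curation filter
#'
#' Applies the conjunction of predicates used to assemble a desk benchmark
#' of recent drug-like cryo-EM complexes: cryo-EM determination, monomeric,
#' release date inside the window, non-covalent drug-like ligand
#' (QED >= 0.7), sequence length <= 1200, a conclusive binding site
#' (minimum protein contact strictly under 4 Angstrom), and no chimeric
#' construct. Records with missing fields fail with reason `"incomplete"`;
#' other failures carry every violated reason code.
#'
#' @param records data.frame with columns `determination_method`,
#'   `release_date` (Date or "YYYY-MM-DD"), `oligomeric_state`,
#'   `ligand_qed`, `is_covalent`, `seq_length`, `min_contact`,
#'   `is_chimeric`.
#' @param qedMin QED threshold (default 0.7, inclusive).
#' @param maxLength maximum sequence length (default 1200, inclusive).
#' @param contactMax binding-site contact bound in Angstrom (default 4,
#'   strict: a record passes only if `min_contact < contactMax`).
#' @param dateWindow length-2 date window (default 2022-01-01 to
#'   2024-06-30, inclusive).
#' @return `records` with added logical `pass` and character `reasons`
#'   (comma-separated stable codes, empty when passing).
#' @export
curationFilter <- function(records, qedMin = 0.7, maxLength = 1200L,
                           contactMax = 4,
                           dateWindow = as.Date(c("2022-01-01",
                                                  "2024-06-30"))) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missingCols <- setdiff(.CURATION_FIELDS, names(records))
  for (mc in missingCols) records[[mc]] <- NA
  dateWindow <- as.Date(dateWindow)
  n <- nrow(records)
  pass <- logical(n)
  reasons <- character(n)
  for (i in seq_len(n)) {
    r <- records[i, ]
    vals <- lapply(.CURATION_FIELDS, function(f) r[[f]])
    if (any(vapply(vals, function(v) is.null(v) || is.na(v), logical(1)))) {
      pass[i] <- FALSE
      reasons[i] <- "incomplete"
      next
    }
    codes <- character(0)
    if (!grepl("cryo", tolower(r$determination_method)) &&
        !grepl("electron microscopy", tolower(r$determination_method)))
      codes <- c(codes, "method")
    rd <- as.Date(r$release_date)
    if (is.na(rd) || rd < dateWindow[1] || rd > dateWindow[2])
      codes <- c(codes, "date")
    if (tolower(r$oligomeric_state) != "monomeric")
      codes <- c(codes, "oligomeric")
    if (isTRUE(as.logical(r$is_covalent))) codes <- c(codes, "covalent")
    if (r$ligand_qed < qedMin) codes <- c(codes, "qed")
    if (r$seq_length > maxLength) codes <- c(codes, "length")
    if (!(r$min_contact < contactMax)) codes <- c(codes, "contact")
    if (isTRUE(as.logical(r$is_chimeric))) codes <- c(codes, "chimeric")
    pass[i] <- length(codes) == 0L
    reasons[i] <- paste(codes, collapse = ",")
  }
  records$pass <- pass
  records$reasons <- reasons
  records
}

#' Assemble a per-entity accuracy report
#'
#' Computes ligand / pocket / whole-protein cross-correlations for the
#' predicted model and the fitted result (final frame or mean over the
#' last-20-frame window, per `reducer`), and -- when ground-truth entity ccs
#' are supplied -- the accuracy of each (maximum possible cc = 1). PLIE per
#' ligand heavy atom is reported for both models.
#'
#' @param predicted the best predicted [Structure-class] (rigid-fitted).
#' @param fitted list with `trajectory` and `trace` from [runFlexFit()].
#' @param targetMap the reference [DensityGrid-class].
#' @param params a [MapSimParams-class].
#' @param groundTruthCC optional named numeric,
#'   `c(ligand = , pocket = , protein = )`: entity ccs of the deposited
#'   structure. When absent, accuracy fields are omitted.
#' @param reducer `"final_frame"` (default) or `"last20_mean"`.
#' @param ligandName ligand residue name or `"auto"`.
#' @return data.frame with one row per entity (ligand, pocket, protein):
#'   predicted / fitted ccs and accuracies, plus a `plie` attribute with the
#'   predicted and fitted PLIE per heavy atom.
#' @export
buildReport <- function(predicted, fitted, targetMap, params,
                        groundTruthCC = NULL, reducer = c("final_frame",
                                                          "last20_mean"),
                        ligandName = "auto") {
  reducer <- match.arg(reducer)
  if (nFrames(fitted$trajectory) < 1L || nrow(traceData(fitted$trace)) < 1L)
    stop("fitted trajectory/trace is empty")
  entCC <- function(s) {
    lig <- selectLigand(s, ligandName)
    poc <- selectPocket(s, lig)
    prot <- selectProtein(s)
    c(ligand = ccValue(entityCC(s, lig, targetMap, params)),
      pocket = if (length(poc)) ccValue(entityCC(s, poc, targetMap, params))
               else NA_real_,
      protein = ccValue(entityCC(s, prot, targetMap, params)))
  }
  predCC <- entCC(predicted)
  finalS <- trajectoryFrame(fitted$trajectory, -1L)
  fitCC <- if (reducer == "final_frame") {
    entCC(finalS)
  } else {
    td <- traceData(fitted$trace)
    c(ligand = lastNMean(fitted$trace, fitted$trajectory, 20L, "cc_ligand")[["mean"]],
      pocket = lastNMean(fitted$trace, fitted$trajectory, 20L, "cc_pocket")[["mean"]],
      protein = lastNMean(fitted$trace, fitted$trajectory, 20L, "cc_protein")[["mean"]])
  }
  rep <- data.frame(entity = c("ligand", "pocket", "protein"),
                    predicted_cc = as.numeric(predCC),
                    fitted_cc = as.numeric(fitCC),
                    stringsAsFactors = FALSE)
  if (!is.null(groundTruthCC)) {
    gt <- as.numeric(groundTruthCC[rep$entity])
    rep$ground_truth_cc <- gt
    rep$predicted_accuracy <- accuracy(rep$predicted_cc, gt)
    rep$fitted_accuracy <- accuracy(rep$fitted_cc, gt)
  }
  ffp <- deriveParams(predicted)
  pliePred <- {
    lig <- selectLigand(predicted, ligandName)
    plie(predicted, selectProtein(predicted), lig, ffp)@perHeavyAtom
  }
  plieFit <- {
    lig <- selectLigand(finalS, ligandName)
    plie(finalS, selectProtein(finalS), lig, deriveParams(finalS))@perHeavyAtom
  }
  attr(rep, "plie") <- c(predicted = pliePred, fitted = plieFit)
  attr(rep, "reducer") <- reducer
  rep
}
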