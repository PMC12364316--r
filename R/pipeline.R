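# End-to-end orchestration: rigid-fit all candidates -> rank by ligand cc ->
# flexibly fit the best -> evaluate against ground truth when available.
# All intermediates are persisted; a JSON manifest records config, seeds and
# output checksums.

#' Run the full fitting pipeline
#'
#' Stages, in order: rigid-body fit every candidate into the map; rank by
#' ligand cross-correlation; density-guided flexible fitting of the best
#' candidate; report assembly (with accuracies when a ground truth is
#' given). Deterministic given the seeds in `config`.
#'
#' @param candidates a [CandidateSet-class], or a character vector of
#'   PDB/mmCIF paths.
#' @param targetMap a [DensityGrid-class], or an MRC file path.
#' @param outDir output directory (created; intermediates persisted here).
#' @param params a [MapSimParams-class]; defaults to the map's nominal
#'   resolution (which must then be set).
#' @param config a [FitConfig-class] (defaults: [fitConfig()]).
#' @param groundTruth optional [Structure-class] or PDB path, used only for
#'   evaluation, never during fitting.
#' @param ligandName ligand residue name or `"auto"`.
#' @param reducer `"final_frame"` or `"last20_mean"` for the fitted column.
#' @return List with `report`, `manifest`, `trace`, `trajectory`, `ranking`.
#' @export
runPipeline <- function(candidates, targetMap, outDir,
                        params = NULL, config = fitConfig(),
                        groundTruth = NULL, ligandName = "auto",
                        reducer = "final_frame") {
  t0 <- Sys.time()
  if (is.character(targetMap)) {
    if (!file.exists(targetMap)) stop("map file not found: ", targetMap)
    targetMap <- readMap(targetMap)
  }
  if (is.character(candidates)) {
    missing <- candidates[!file.exists(candidates)]
    if (length(missing)) stop("candidate file(s) not found: ",
                              paste(missing, collapse = ", "))
    models <- lapply(candidates, readStructure)
    names(models) <- tools::file_path_sans_ext(basename(candidates))
    candidates <- CandidateSet(models)
  }
  if (is.character(groundTruth)) groundTruth <- readStructure(groundTruth)
  if (is.null(params)) {
    if (is.na(targetMap@resolution))
      stop("params not given and the map has no nominal resolution")
    params <- mapSimParams(targetMap@resolution)
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  note <- function(stage) {
    stages <<- c(stages, sprintf("%s @ %.2fs", stage,
                                 as.numeric(Sys.time() - t0, units = "secs")))
  }

  ranking <- rankCandidates(candidates, targetMap, params,
                            ligandName = ligandName, seed = config@seed)
  note("align+rank")
  utils::write.csv(ranking$table, file.path(outDir, "ranking.csv"),
                   row.names = FALSE)
  best <- ranking$models@models[[ranking$bestId]]
  writeStructure(best, file.path(outDir, "best_prediction.pdb"))

  fit <- runFlexFit(best, targetMap, config, params, ligandName = ligandName)
  note("flexfit")
  writeTrace(fit$trace, file.path(outDir, "trace.csv"))
  writeTrajectory(fit$trajectory, file.path(outDir, "trajectory.pdb"))
  fitted <- trajectoryFrame(fit$trajectory, -1L)
  writeStructure(fitted, file.path(outDir, "fitted_model.pdb"))

  gtCC <- NULL
  if (!is.null(groundTruth)) {
    lig <- selectLigand(groundTruth, ligandName)
    poc <- selectPocket(groundTruth, lig)
    gtCC <- c(ligand = ccValue(entityCC(groundTruth, lig, targetMap, params)),
              pocket = if (length(poc))
                ccValue(entityCC(groundTruth, poc, targetMap, params))
                else NA_real_,
              protein = ccValue(entityCC(groundTruth,
                                         selectProtein(groundTruth),
                                         targetMap, params)))
  }
  report <- buildReport(best, fit, targetMap, params, groundTruthCC = gtCC,
                        reducer = reducer, ligandName = ligandName)
  note("evaluate")
  utils::write.csv(report, file.path(outDir, "report.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(entities = report, plie = as.list(attr(report, "plie")),
         reducer = reducer),
    file.path(outDir, "report.json"), dataframe = "rows", auto_unbox = TRUE,
    digits = NA)

  files <- setdiff(list.files(outDir), "manifest.json")
  manifest <- list(
    created = format(t0, "%Y-%m-%d %H:%M:%S"),
    seeds = list(pipeline = config@seed),
    config = list(timestep_fs = config@timestep,
                  temperature_K = config@temperature,
                  friction_per_ps = config@friction,
                  force_constant = config@forceConstant,
                  density_force_interval = config@densityForceInterval,
                  adaptive_scaling = config@adaptiveScaling,
                  duration_ps = config@duration,
                  resolution = params@resolution,
                  reducer = reducer),
    versions = list(emligfit = as.character(utils::packageVersion("emligfit")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    stages = stages,
    outputs = lapply(stats::setNames(files, files), function(f)
      unname(tools::md5sum(file.path(outDir, f)))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(report = report, manifest = manifest, trace = fit$trace,
       trajectory = fit$trajectory, ranking = ranking)
}
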