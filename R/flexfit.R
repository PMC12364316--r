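# Density-guided flexible fitting: Langevin dynamics on the structure-native
# restraint field plus map-similarity forces k * d(cc)/dx, recomputed every N
# steps, with adaptive growth of k when the fit stalls.

#' Density force on the selected atoms
#'
#' Force on atom i is `k * d(cc)/dx_i` (the ascent direction of the masked
#' model-to-map cross-correlation), capped per component at `forceCap`.
#' Non-selected atoms and hydrogens get zero.
#'
#' @inheritParams entityCC
#' @param k density-force scaling factor, kJ/mol.
#' @param forceCap per-component cap, kJ/mol/Angstrom (default `Inf`).
#' @param maskRadius mask radius in sigma multiples; the engine default is
#'   the wide truncation-radius support, giving the force a capture range
#'   of several Angstrom.
#' @return nAtoms x 3 matrix of forces (kJ/mol/Angstrom).
#' @export
densityForce <- function(structure, selection, targetMap, params, k,
                         forceCap = Inf,
                         maskRadius = params@truncationRadius) {
  g <- ccGradient(structure, selection, targetMap, params,
                  maskRadius = maskRadius)
  f <- k * g$gradient
  f[f > forceCap] <- forceCap
  f[f < -forceCap] <- -forceCap
  f
}

#' Adaptive force scaling rule
#'
#' If the cc improvement over the supplied window is below
#' `config@ccEpsilon`, the force constant grows by `config@growthFactor`, up
#' to `config@kMax`; otherwise it is unchanged. k never decreases.
#'
#' @param traceWindow numeric vector of cc samples (one check window).
#' @param kCurrent current force constant, kJ/mol.
#' @param config a [FitConfig-class].
#' @return Updated force constant, kJ/mol.
#' @export
adaptiveScale <- function(traceWindow, kCurrent, config) {
  if (!config@adaptiveScaling || length(traceWindow) < 2L) return(kCurrent)
  if (traceWindow[length(traceWindow)] - traceWindow[1] < config@ccEpsilon)
    min(kCurrent * config@growthFactor, config@kMax)
  else kCurrent
}

#' Run density-guided flexible fitting
#'
#' Optional restrained pre-relaxation (steepest-descent minimisation with
#' positional restraints on backbone and side-chain/ligand atoms), then
#' Langevin (BAOAB) integration of the restraint field with density forces on
#' all heavy atoms recomputed every `densityForceInterval` steps and held
#' between recomputations. Ligand / pocket / whole-protein cross-correlations
#' and PLIE are sampled onto the monitor trace on a fixed time grid. The
#' pocket selection is computed once from the input pose and held fixed.
#'
#' If more than 1% of atoms hit the per-component force cap the run
#' terminates gracefully with a `force_cap_exceeded` event and the final
#' valid frame saved; non-finite coordinates abort with a
#' `non_finite_coordinates` event. Deterministic given `config@seed`.
#'
#' @param structure the rigid-fitted [Structure-class] to refine.
#' @param targetMap the reference [DensityGrid-class].
#' @param config a [FitConfig-class].
#' @param params a [MapSimParams-class].
#' @param ffParams optional [FFParams-class]; derived from `structure`
#'   (structure-native restraints) when missing.
#' @param ligandName ligand residue name or `"auto"`.
#' @return List with `trajectory` ([Trajectory-class]) and `trace`
#'   ([Trace-class]).
#' @export
runFlexFit <- function(structure, targetMap, config, params,
                       ffParams = NULL, ligandName = "auto") {
  stopifnot(is(config, "FitConfig"), is(params, "MapSimParams"))
  validObject(config)
  if (is.null(ffParams)) ffParams <- deriveParams(structure)
  a <- structure@atoms

  lig <- selectLigand(structure, ligandName)
  poc <- selectPocket(structure, lig)
  prot <- selectProtein(structure)
  if (length(poc) == 0L)
    poc <- prot   # degenerate fixture: fall back to whole protein
  allSel <- Selection(seq_len(nAtoms(structure)), "custom")
  dense <- heavyAtoms(allSel, structure)
  ligH <- heavyAtoms(lig, structure)
  pocH <- heavyAtoms(poc, structure)
  protH <- heavyAtoms(prot, structure)

  # pre-relaxation: restrained minimisation (backbone vs side-chain classes)
  if (config@preRelaxSteps > 0L) {
    rk <- rep(config@sidechainRestraint, nAtoms(structure))
    backbone <- !a$hetero & a$name %in% c("N", "CA", "C", "O")
    rk[backbone] <- config@backboneRestraint
    mn <- cpp_minimize(coords(structure), .ffList(ffParams), rk,
                       coords(structure), config@preRelaxSteps)
    coords(structure) <- mn$coords
  }

  amp <- if (params@amplitudeMode == "atomic_number")
    as.numeric(elementZ(a$element)) else rep(1, nAtoms(structure))

  oldSeed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, .GlobalEnv))
  set.seed(config@seed)
  r <- cpp_run_flexfit(
    coords(structure), a$mass, .ffList(ffParams),
    targetMap@values, dim(targetMap@values), targetMap@origin,
    targetMap@voxel, params@sigma, params@truncationRadius,
    params@maskRadius, params@truncationRadius, params@meanSubtract, amp,
    dense@indices, ligH@indices, pocH@indices, protH@indices,
    prot@indices, lig@indices, length(ligH),
    config@timestep, config@temperature, config@friction,
    config@forceConstant, config@densityForceInterval,
    config@adaptiveScaling, config@checkInterval, config@ccEpsilon,
    config@growthFactor, config@kMax, config@duration, config@forceCap,
    config@traceInterval, config@frameInterval)

  events <- data.frame(time_ps = as.numeric(r$event_times),
                       label = as.character(r$event_labels),
                       stringsAsFactors = FALSE)
  trace <- new("Trace", data = as.data.frame(r$trace), events = events)
  traj <- new("Trajectory", frames = lapply(r$frames, identity),
              times = as.numeric(r$frame_times), template = structure,
              saveInterval = as.integer(round(config@frameInterval /
                                              config@timestep)))
  if (isTRUE(r$aborted)) {
    diag <- structure
    coords(diag) <- r$coords
    warning("dynamics aborted on non-finite coordinates; diagnostic frame attached")
    attr(traj, "diagnostic") <- diag
  }
  list(trajectory = traj, trace = trace)
}

#' Mean and standard error over the final n frames
#'
#' @param trace a [Trace-class].
#' @param trajectory the matching [Trajectory-class] (frame grid defines
#'   "frames"; trace samples co-sampled at those times are used).
#' @param n number of final frames (default 20).
#' @param field trace column name (default `"cc_ligand"`).
#' @return Named numeric vector `c(mean, se)`. If fewer than `n` frames are
#'   available, all are used with a warning.
#' @export
lastNMean <- function(trace, trajectory, n = 20L, field = "cc_ligand") {
  td <- trace@data
  stopifnot(field %in% names(td))
  ft <- trajectory@times
  if (length(ft) < n) {
    warning(sprintf("only %d frames available; using all", length(ft)))
    n <- length(ft)
  }
  keep <- utils::tail(ft, n)
  # trace samples nearest to each retained frame time
  idx <- vapply(keep, function(t) which.min(abs(td$time_ps - t)), integer(1))
  v <- td[[field]][idx]
  c(mean = mean(v), se = stats::sd(v) / sqrt(length(v)))
}

#' Write / read a monitor trace as CSV
#' @param trace a [Trace-class].
#' @param path file path.
#' @return `writeTrace` invisibly returns `path`; `readTrace` a
#'   [Trace-class] (events are stored in a matching `*.events.csv` when
#'   present).
#' @export
writeTrace <- function(trace, path) {
  utils::write.csv(trace@data, path, row.names = FALSE)
  if (nrow(trace@events))
    utils::write.csv(trace@events, paste0(path, ".events.csv"),
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrace
#' @export
readTrace <- function(path) {
  d <- utils::read.csv(path)
  evPath <- paste0(path, ".events.csv")
  ev <- if (file.exists(evPath)) utils::read.csv(evPath, stringsAsFactors = FALSE)
        else data.frame(time_ps = numeric(0), label = character(0))
  new("Trace", data = d, events = ev)
}
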