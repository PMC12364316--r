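# Density simulation from atomic models, masked model-to-map
# cross-correlation, and its analytic gradient -- the engine behind both
# pose scoring and the density force of flexible fitting.

.selectionAmplitudes <- function(structure, selection, params) {
  el <- structure@atoms$element[selection@indices]
  if (params@amplitudeMode == "atomic_number") as.numeric(elementZ(el))
  else rep(1, length(el))
}

# grid geometry covering the selection bounding box plus truncation padding
.autoGrid <- function(structure, selection, params, voxel = NULL) {
  if (is.null(voxel)) voxel <- params@resolution / 3
  pc <- coords(structure)[selection@indices, , drop = FALSE]
  pad <- params@truncationRadius * params@sigma + voxel
  lo <- apply(pc, 2, min) - pad
  hi <- apply(pc, 2, max) + pad
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / voxel)) + 1L)
  DensityGrid(array(0, dims), origin = lo, voxel = rep(voxel, 3),
              resolution = params@resolution)
}

#' Simulate density from an atomic model
#'
#' Each selected heavy atom contributes an isotropic 3-d Gaussian of width
#' `sigma` (see [mapSimParams()]) evaluated at voxel centres, truncated
#' spherically at `truncationRadius * sigma`; contributions sum. Hydrogens in
#' the selection are ignored. If `params@gridSpec` is `NULL` a grid covering
#' the selection bounding box (padded by the truncation radius) is created;
#' atoms outside a supplied grid are clipped at its edges.
#'
#' @param structure a [Structure-class].
#' @param selection a non-empty [Selection-class].
#' @param params a [MapSimParams-class].
#' @return A [DensityGrid-class].
#' @export
simulateDensity <- function(structure, selection, params) {
  stopifnot(is(params, "MapSimParams"))
  validObject(params)
  sel <- heavyAtoms(selection, structure)
  if (length(sel) == 0L) stop("selection contains no heavy atoms")
  grid <- if (is.null(params@gridSpec)) .autoGrid(structure, sel, params)
          else params@gridSpec
  vals <- cpp_simulate_density(
    coords(structure)[sel@indices, , drop = FALSE],
    .selectionAmplitudes(structure, sel, params),
    dim(grid@values), grid@origin, grid@voxel, params@sigma,
    params@truncationRadius)
  DensityGrid(vals, origin = grid@origin, voxel = grid@voxel,
              resolution = params@resolution)
}

#' Model-support mask of a selection on a grid
#'
#' Logical array marking voxels within `maskRadius * sigma` (default; any
#' radius can be passed) of any heavy atom of the selection.
#'
#' @inheritParams simulateDensity
#' @param grid the [DensityGrid-class] supplying the geometry.
#' @param maskRadius mask radius in sigma multiples (default
#'   `params@maskRadius`).
#' @return A logical array with the grid's dimensions.
#' @export
supportMask <- function(structure, selection, grid, params,
                        maskRadius = params@maskRadius) {
  sel <- heavyAtoms(selection, structure)
  if (length(sel) == 0L) stop("selection contains no heavy atoms")
  cpp_support_mask(coords(structure)[sel@indices, , drop = FALSE],
                   dim(grid@values), grid@origin, grid@voxel, params@sigma,
                   maskRadius)
}

.sameGeometry <- function(a, b) {
  identical(dim(a@values), dim(b@values)) &&
    max(abs(a@origin - b@origin)) < 1e-6 &&
    max(abs(a@voxel - b@voxel)) < 1e-6
}

#' Masked cross-correlation of two density grids
#'
#' Pearson correlation (mean-subtracted by default) of the two value sets
#' restricted to a mask. The grids must share geometry; [resampleOnto()]
#' first if they do not. The mask may be a logical array, a vector of voxel
#' indices, or `"model-support"`, which uses the support of `structure` /
#' `selection` when given and otherwise the non-zero support of `modelMap`.
#'
#' @param modelMap,targetMap [DensityGrid-class] objects on one geometry.
#' @param mask `"model-support"` (default), a logical array, or voxel indices.
#' @param structure,selection optional: define the model-support mask from
#'   atoms (voxels within the truncation radius of any selected heavy atom).
#' @param params [MapSimParams-class]; required with `structure`.
#' @param meanSubtract override the Pearson mean subtraction (defaults to
#'   `params@meanSubtract`, or `TRUE` without `params`).
#' @return A [SimilarityResult-class] with entity `"global"`.
#' @export
crossCorrelation <- function(modelMap, targetMap, mask = "model-support",
                             structure = NULL, selection = NULL,
                             params = NULL, meanSubtract = NULL) {
  if (!.sameGeometry(modelMap, targetMap))
    stop("grid geometries differ; resampleOnto() one of them first")
  if (is.null(meanSubtract))
    meanSubtract <- if (!is.null(params)) params@meanSubtract else TRUE
  if (identical(mask, "model-support")) {
    mask <- if (!is.null(structure)) {
      supportMask(structure, selection, targetMap, params)
    } else {
      m <- modelMap@values != 0
      dim(m) <- dim(modelMap@values)
      m
    }
  } else if (is.numeric(mask)) {
    idx <- as.integer(mask)
    mask <- array(FALSE, dim(modelMap@values))
    mask[idx] <- TRUE
  }
  if (!any(mask)) stop("degenerate mask: no voxels selected")
  r <- cpp_masked_cc(modelMap@values, targetMap@values, mask, meanSubtract)
  new("SimilarityResult", cc = r$cc, maskVoxels = as.integer(r$n),
      entity = "global")
}

#' Per-entity model-to-map cross-correlation
#'
#' Simulates density from the selection and correlates it against the target
#' map over the selection's model-support mask -- the quantity used to score
#' ligand, pocket and whole-protein fits.
#'
#' @param structure a [Structure-class].
#' @param selection a non-empty [Selection-class].
#' @param targetMap the reference [DensityGrid-class].
#' @param params a [MapSimParams-class].
#' @return A [SimilarityResult-class] (entity = the selection label).
#' @export
entityCC <- function(structure, selection, targetMap, params) {
  sel <- heavyAtoms(selection, structure)
  if (length(sel) == 0L) stop("selection contains no heavy atoms")
  r <- cpp_cc_and_gradient(
    coords(structure)[sel@indices, , drop = FALSE],
    .selectionAmplitudes(structure, sel, params),
    targetMap@values, dim(targetMap@values), targetMap@origin,
    targetMap@voxel, params@sigma, params@truncationRadius,
    params@maskRadius, params@meanSubtract, FALSE)
  new("SimilarityResult", cc = r$cc, maskVoxels = as.integer(r$n),
      entity = selection@label)
}

#' Gradient of the masked cross-correlation
#'
#' Analytic partial derivatives of the masked model-to-map cc with respect to
#' each selected heavy atom's coordinates (units 1/Angstrom); all other atoms
#' get zero. The mask is the selection's model-support at the input
#' positions, held fixed for the differentiation (pass `frozenMask` to reuse
#' a mask, e.g. for finite-difference checks).
#'
#' @inheritParams entityCC
#' @param frozenMask optional logical array to use as the mask.
#' @param maskRadius mask radius in sigma multiples (default
#'   `params@maskRadius`).
#' @return List with `cc` (numeric) and `gradient` (nAtoms x 3 matrix).
#' @export
ccGradient <- function(structure, selection, targetMap, params,
                       frozenMask = NULL, maskRadius = params@maskRadius) {
  sel <- heavyAtoms(selection, structure)
  if (length(sel) == 0L) stop("selection contains no heavy atoms")
  r <- cpp_cc_and_gradient(
    coords(structure)[sel@indices, , drop = FALSE],
    .selectionAmplitudes(structure, sel, params),
    targetMap@values, dim(targetMap@values), targetMap@origin,
    targetMap@voxel, params@sigma, params@truncationRadius, maskRadius,
    params@meanSubtract, TRUE, frozenMask)
  grad <- matrix(0, nAtoms(structure), 3)
  grad[sel@indices, ] <- t(r$gradient)
  list(cc = r$cc, gradient = grad)
}

#' Resample a grid onto a reference geometry
#'
#' Trilinear interpolation of `grid` values at the voxel centres of
#' `reference`; voxels outside the source extent are set to 0.
#'
#' @param grid source [DensityGrid-class].
#' @param reference [DensityGrid-class] supplying the output geometry.
#' @return A [DensityGrid-class] on the reference geometry.
#' @export
resampleOnto <- function(grid, reference) {
  vals <- cpp_resample(grid@values, dim(grid@values), grid@origin,
                       grid@voxel, dim(reference@values), reference@origin,
                       reference@voxel)
  DensityGrid(vals, origin = reference@origin, voxel = reference@voxel,
              resolution = grid@resolution)
}
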