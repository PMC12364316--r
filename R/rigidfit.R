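# Rigid-body alignment into a density map by gradient ascent on the global
# masked cross-correlation, with seeded random-rotation restarts.

.quatToMatrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

.quatMultiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

.axisAngleQuat <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-15) return(c(1, 0, 0, 0))
  c(cos(angle / 2), sin(angle / 2) * axis / n)
}

.randomQuat <- function() {
  # Shoemake's uniform random rotation
  u <- stats::runif(3)
  c(sqrt(u[1]) * cos(2 * pi * u[3]),
    sqrt(1 - u[1]) * sin(2 * pi * u[2]),
    sqrt(1 - u[1]) * cos(2 * pi * u[2]),
    sqrt(u[1]) * sin(2 * pi * u[3]))
}

#' Rotation angle of a transform, degrees
#' @param transform a [RigidTransform-class].
#' @return Rotation magnitude in degrees.
#' @export
rotationAngle <- function(transform) {
  2 * acos(pmin(1, abs(transform@quaternion[1]))) * 180 / pi
}

#' Apply a rigid transform to a structure
#'
#' Rotates every atom about the transform's centre, then translates;
#' internal geometry is preserved exactly.
#'
#' @param structure a [Structure-class].
#' @param transform a [RigidTransform-class].
#' @return The transformed [Structure-class].
#' @export
applyTransform <- function(structure, transform) {
  validObject(transform)
  R <- .quatToMatrix(transform@quaternion)
  p <- coords(structure)
  p <- sweep(p, 2, transform@center) %*% t(R)
  p <- sweep(p, 2, transform@center + transform@translation, "+")
  coords(structure) <- p
  structure
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `first`, then `second`
#' (centre at the origin).
#'
#' @param second,first [RigidTransform-class] objects.
#' @return A [RigidTransform-class].
#' @export
composeTransforms <- function(second, first) {
  M <- transformMatrix(second) %*% transformMatrix(first)
  transformFromMatrix(M)
}

#' 4x4 homogeneous matrix of a transform
#' @param transform a [RigidTransform-class].
#' @return 4 x 4 numeric matrix.
#' @export
transformMatrix <- function(transform) {
  R <- .quatToMatrix(transform@quaternion)
  c0 <- transform@center
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- c0 + transform@translation - R %*% c0
  M
}

#' Build a transform from a 4x4 homogeneous matrix
#' @param M 4 x 4 rigid-motion matrix.
#' @return A [RigidTransform-class] with centre at the origin.
#' @export
transformFromMatrix <- function(M) {
  R <- M[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0)
    stop("matrix is not a proper rotation")
  w <- sqrt(max(0, 1 + R[1, 1] + R[2, 2] + R[3, 3])) / 2
  if (w > 1e-6) {
    q <- c(w, (R[3, 2] - R[2, 3]) / (4 * w), (R[1, 3] - R[3, 1]) / (4 * w),
           (R[2, 1] - R[1, 2]) / (4 * w))
  } else {
    # 180-degree rotation: recover axis from the diagonal
    x <- sqrt(max(0, 1 + R[1, 1] - R[2, 2] - R[3, 3])) / 2
    y <- sqrt(max(0, 1 - R[1, 1] + R[2, 2] - R[3, 3])) / 2
    z <- sqrt(max(0, 1 - R[1, 1] - R[2, 2] + R[3, 3])) / 2
    if (x >= y && x >= z) { y <- R[1, 2] / (4 * x); z <- R[1, 3] / (4 * x) }
    else if (y >= z) { x <- R[1, 2] / (4 * y); z <- R[2, 3] / (4 * y) }
    else { x <- R[1, 3] / (4 * z); y <- R[2, 3] / (4 * z) }
    q <- c(w, x, y, z)
  }
  rigidTransform(q, translation = M[1:3, 4], center = c(0, 0, 0))
}

#' Write / read a transform as a 4x4 row-major text file
#' @param transform a [RigidTransform-class].
#' @param path file path.
#' @return `writeTransform` invisibly returns `path`; `readTransform` a
#'   [RigidTransform-class].
#' @export
writeTransform <- function(transform, path) {
  M <- transformMatrix(transform)
  writeLines(apply(M, 1, function(r) paste(sprintf("%.10g", r), collapse = " ")),
             path)
  invisible(path)
}

#' @rdname writeTransform
#' @export
readTransform <- function(path) {
  M <- as.matrix(utils::read.table(path))
  stopifnot(all(dim(M) == c(4, 4)))
  dimnames(M) <- NULL
  transformFromMatrix(M)
}

# whole-model cc and gradient over the wide (truncation-radius) support --
# the wide mask gives the ascent a capture range of several Angstrom
.globalCCGrad <- function(P, amp, targetMap, params, wantGradient = TRUE) {
  cpp_cc_and_gradient(P, amp, targetMap@values, dim(targetMap@values),
                      targetMap@origin, targetMap@voxel, params@sigma,
                      params@truncationRadius, params@truncationRadius,
                      params@meanSubtract, wantGradient)
}

# ascent over (rotation about centroid, translation) from one starting pose;
# converged when the cc improvement stays below ccTol for 3 iterations
.ascendPose <- function(P0, amp, targetMap, params, maxIter = 500L,
                        ccTol = 1e-8) {
  centr <- colMeans(P0)
  q <- c(1, 0, 0, 0)
  tr <- c(0, 0, 0)
  pose <- function(q, tr) {
    R <- .quatToMatrix(q)
    sweep(sweep(P0, 2, centr) %*% t(R), 2, centr + tr, "+")
  }
  P <- P0
  safeGrad <- function(P) {
    # a trial pose thrown fully outside the map is a rejected step, not an error
    tryCatch(.globalCCGrad(P, amp, targetMap, params),
             error = function(e) NULL)
  }
  r <- safeGrad(P)
  if (is.null(r))
    return(list(q = q, tr = tr, cc = -Inf, centr = centr, converged = FALSE))
  cc <- r$cc
  Rbar2 <- mean(rowSums(sweep(P, 2, centr)^2))
  s <- 1
  stall <- 0L
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    gmat <- r$gradient                          # 3 x n
    Fsum <- rowSums(gmat)
    rel <- sweep(P, 2, colMeans(P))
    tau <- c(sum(rel[, 2] * gmat[3, ] - rel[, 3] * gmat[2, ]),
             sum(rel[, 3] * gmat[1, ] - rel[, 1] * gmat[3, ]),
             sum(rel[, 1] * gmat[2, ] - rel[, 2] * gmat[1, ]))
    gnorm2 <- sum(Fsum^2) / nrow(P) + sum(tau^2) / (nrow(P) * Rbar2)
    if (gnorm2 < 1e-18) { converged <- TRUE; break }
    evalAt <- function(sv) {
      dtr <- sv * Fsum / nrow(P)
      dang <- sv * tau / (nrow(P) * Rbar2)
      qNew <- .quatMultiply(.axisAngleQuat(dang, sqrt(sum(dang^2))), q)
      qNew <- qNew / sqrt(sum(qNew^2))
      trNew <- tr + dtr
      Pnew <- pose(qNew, trNew)
      rNew <- safeGrad(Pnew)
      if (is.null(rNew)) return(NULL)
      list(q = qNew, tr = trNew, P = Pnew, r = rNew, cc = rNew$cc)
    }
    # backtrack until the step improves ...
    cand <- NULL
    for (bt in 1:25) {
      cand <- evalAt(s)
      if (!is.null(cand) && cand$cc > cc) break
      cand <- NULL
      s <- s / 4
    }
    if (is.null(cand)) { converged <- TRUE; break }
    # ... then expand while doubling still helps (quasi-exact line search)
    repeat {
      cand2 <- evalAt(s * 2)
      if (!is.null(cand2) && cand2$cc > cand$cc) {
        s <- s * 2; cand <- cand2
      } else break
    }
    dcc <- cand$cc - cc
    q <- cand$q; tr <- cand$tr; P <- cand$P; r <- cand$r; cc <- cand$cc
    stall <- if (dcc < ccTol) stall + 1L else 0L
    if (stall >= 3L) { converged <- TRUE; break }
  }
  list(q = q, tr = tr, cc = cc, centr = centr, converged = converged)
}

#' Rigid-body fit of a model into a density map
#'
#' Local gradient ascent on the global masked cross-correlation over
#' rotation and translation, starting from the input pose plus
#' `nRestarts - 1` seeded random rotations about the model centroid; the
#' best-scoring restart wins (ties: earliest restart). The ascent never
#' decreases cc, so `ccAfter >= ccBefore`. Deterministic given `seed`.
#'
#' @param structure a [Structure-class]; all heavy atoms are used.
#' @param targetMap the reference [DensityGrid-class].
#' @param params a [MapSimParams-class].
#' @param nRestarts number of starting orientations (default 12).
#' @param seed RNG seed for the random restarts.
#' @param maxIter ascent iterations per restart.
#' @param ccTol convergence tolerance: stop after 3 successive iterations
#'   improving cc by less than this (default 1e-8; loose tolerances stop
#'   visibly short of the optimum on smooth synthetic maps).
#' @return A [RigidFitResult-class].
#' @export
fitRigid <- function(structure, targetMap, params, nRestarts = 12L,
                     seed = 0L, maxIter = 500L, ccTol = 1e-8) {
  sel <- heavyAtoms(Selection(seq_len(nAtoms(structure)), "custom"), structure)
  P0 <- coords(structure)[sel@indices, , drop = FALSE]
  amp <- .selectionAmplitudes(structure, sel, params)
  # overlap check: any support voxel inside the map extent
  msk <- cpp_support_mask(P0, dim(targetMap@values), targetMap@origin,
                          targetMap@voxel, params@sigma,
                          params@truncationRadius)
  if (!any(msk))
    stop("model does not overlap the map extent; cannot rigid-fit")
  ccBefore <- .globalCCGrad(P0, amp, targetMap, params, FALSE)$cc
  best <- NULL
  bestIdx <- 0L
  oldSeed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, .GlobalEnv))
  set.seed(seed)
  centr <- colMeans(P0)
  for (rst in seq_len(max(1L, nRestarts))) {
    qStart <- if (rst == 1L) c(1, 0, 0, 0) else .randomQuat()
    Pstart <- if (rst == 1L) P0
              else sweep(sweep(P0, 2, centr) %*% t(.quatToMatrix(qStart)),
                         2, centr, "+")
    res <- .ascendPose(Pstart, amp, targetMap, params, maxIter, ccTol)
    # fold the restart pre-rotation into the reported transform
    qTot <- .quatMultiply(res$q, qStart)
    if (is.null(best) || res$cc > best$cc + 1e-12) {
      best <- res
      best$qTot <- qTot
      bestIdx <- rst
    }
  }
  tf <- rigidTransform(best$qTot, translation = best$tr, center = best$centr)
  new("RigidFitResult", transform = tf,
      ccBefore = ccBefore, ccAfter = max(best$cc, ccBefore),
      nRestartsUsed = as.integer(max(1L, nRestarts)),
      converged = isTRUE(best$converged))
}
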