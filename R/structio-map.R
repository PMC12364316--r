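# MRC/CCP4 (2014 standard) map I/O, mode 2 (32-bit float), orthogonal cells
# only. Values are stored internally as an R array indexed [x, y, z] with the
# origin at the centre of voxel [1, 1, 1].

#' Read an MRC/CCP4 density map
#'
#' Supports mode-2 (32-bit real) maps with orthogonal cells. Axis order is
#' normalised to x, y, z regardless of the header's mapc/mapr/maps
#' permutation. The origin is taken from the MRC2014 origin header if
#' non-zero, otherwise from `nxstart/nystart/nzstart * voxel`.
#'
#' @param path file path.
#' @return A [DensityGrid-class].
#' @export
readMap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  i32 <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  f32 <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  nxyz <- i32(3)                      # columns, rows, sections
  mode <- i32(1)
  nstart <- i32(3)
  m <- i32(3)                         # sampling along cell x, y, z
  cella <- f32(3)
  cellb <- f32(3)
  mapcrs <- i32(3)
  f32(3)                              # dmin dmax dmean
  i32(1)                              # ispg
  nsymbt <- i32(1)
  seek(con, 196)
  orig <- f32(3)
  maptag <- rawToChar(readBin(con, "raw", 4))
  if (!startsWith(maptag, "MAP"))
    stop("not an MRC 2014 map (missing MAP tag): ", path)
  if (mode != 2L)
    stop(sprintf("unsupported MRC mode %d (only mode 2, 32-bit real, is supported)",
                 mode))
  if (any(abs(cellb - 90) > 1e-3))
    stop("non-orthogonal cell angles are not supported: ",
         paste(sprintf("%.2f", cellb), collapse = ", "))
  if (any(nxyz <= 0) || any(m <= 0)) stop("invalid grid dimensions in ", path)
  if (!all(sort(mapcrs) == 1:3)) stop("invalid axis order in header of ", path)
  seek(con, 1024 + nsymbt)
  vals <- f32(prod(nxyz))
  if (length(vals) != prod(nxyz)) stop("truncated map data in ", path)
  a <- array(vals, dim = nxyz)
  perm <- match(1:3, mapcrs)          # data dim holding crystal axis i
  a <- aperm(a, perm)
  voxel <- cella / m
  origin <- if (any(orig != 0)) orig else nstart[perm] * voxel
  DensityGrid(a, origin = origin, voxel = voxel)
}

#' Write an MRC/CCP4 density map
#'
#' Writes a standard MRC2014 mode-2 file that round-trips with [readMap()].
#' Anisotropic voxel sizes are permitted; NaN values are an error.
#'
#' @param grid a [DensityGrid-class].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeMap <- function(grid, path) {
  .writeMRC(grid, path)
}

# internal writer; axisOrder and originAsStart exist so tests can produce
# permuted-axis and nstart-origin headers.
.writeMRC <- function(grid, path, axisOrder = c(1L, 2L, 3L),
                      originAsStart = FALSE) {
  stopifnot(is(grid, "DensityGrid"))
  v <- grid@values
  if (anyNA(v) || !all(is.finite(v)))
    stop("grid contains NaN or non-finite values; refusing to write")
  stopifnot(all(sort(axisOrder) == 1:3))
  voxel <- grid@voxel
  dims <- dim(v)
  nstart <- c(0L, 0L, 0L)
  orig <- grid@origin
  if (originAsStart) {
    nstart <- as.integer(round(grid@origin / voxel))
    if (max(abs(nstart * voxel - grid@origin)) > 1e-6)
      stop("origin is not an integer multiple of the voxel size; cannot encode as nstart")
    orig <- c(0, 0, 0)
  }
  # data layout: columns fastest along crystal axis axisOrder[1]
  a <- aperm(v, axisOrder)
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("cannot open for writing: ", path, " (", conditionMessage(e), ")"))
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(dim(a))                          # nx ny nz (columns/rows/sections)
  wi(2L)                              # mode 2
  wi(nstart[axisOrder])               # starts, in column/row/section order
  wi(dims)                            # mx my mz (cell sampling, x,y,z order)
  wf(dims * voxel)                    # cella
  wf(c(90, 90, 90))                   # cellb
  wi(axisOrder)                       # mapc mapr maps
  wf(c(min(v), max(v), mean(v)))      # dmin dmax dmean
  wi(1L)                              # ispg
  wi(0L)                              # nsymbt
  wi(c(0L, 0L, 0L, 20140L, rep(0L, 21)))  # extra words 25-49, nversion at 28
  wf(orig)                            # origin x y z (words 50-52)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(as.numeric(v)) * sqrt((length(v) - 1) / length(v)))  # rms
  wi(1L)                              # nlabl
  lab <- sprintf("%-80s", "emligfit density grid")
  writeBin(charToRaw(lab), con)
  writeBin(raw(800 - 80), con)
  wf(as.numeric(a))
  invisible(path)
}
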