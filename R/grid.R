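## GridSpec constructor, accessors and coordinate helpers.

#' Create a rectilinear grid specification
#'
#' @param origin numeric(3), centre of the first voxel, Angstrom.
#' @param step per-axis spacing in Angstrom; a single number is recycled to
#'   all three axes.
#' @param counts per-axis voxel counts (>= 2); a single number is recycled.
#' @return a [GridSpec-class] object.
#' @examples
#' g <- GridSpec(origin = c(-2, -2, -2), step = 0.5, counts = 9)
#' voxelVolume(g)
#' @export
GridSpec <- function(origin = c(0, 0, 0), step = 0.4, counts = 2L) {
  if (length(step) == 1L) step <- rep(step, 3L)
  if (length(counts) == 1L) counts <- rep(counts, 3L)
  new("GridSpec", origin = as.numeric(origin), step = as.numeric(step),
      counts = as.integer(counts))
}

#' @rdname GridSpec
#' @param grid a [GridSpec-class].
#' @export
gridOrigin <- function(grid) grid@origin

#' @rdname GridSpec
#' @export
gridStep <- function(grid) grid@step

#' @rdname GridSpec
#' @export
gridCounts <- function(grid) grid@counts

gridDim <- function(grid) grid@counts

#' Voxel volume of a grid
#'
#' @param grid a [GridSpec-class].
#' @return product of the per-axis steps, Angstrom^3.
#' @export
voxelVolume <- function(grid) prod(grid@step)

#' Voxel-centre coordinates along one axis
#'
#' @param grid a [GridSpec-class].
#' @param axis 1, 2 or 3 (x, y, z).
#' @return numeric vector of voxel-centre positions, Angstrom.
#' @export
axisCoords <- function(grid, axis) {
  stopifnot(axis %in% 1:3)
  grid@origin[axis] + (seq_len(grid@counts[axis]) - 1L) * grid@step[axis]
}

#' All voxel-centre coordinates of a grid
#'
#' Returns the voxel centres as an (nx*ny*nz) x 3 matrix in the same linear
#' order as the values array of a [VolumetricField-class] (x fastest).
#'
#' @param grid a [GridSpec-class].
#' @return numeric matrix with columns x, y, z (Angstrom).
#' @export
gridCoordinates <- function(grid) {
  cx <- axisCoords(grid, 1); cy <- axisCoords(grid, 2); cz <- axisCoords(grid, 3)
  n <- prod(grid@counts)
  cbind(x = rep(cx, times = n / length(cx)),
        y = rep(rep(cy, each = length(cx)), times = length(cz)),
        z = rep(cz, each = length(cx) * length(cy)))
}

#' Compare two grids for compatibility
#'
#' Two grids are compatible when origin, steps and counts agree, positions
#' to within 1e-8 Angstrom. Fields on incompatible grids are never silently
#' resampled: operations combining them raise an error instead, because
#' interpolation silently corrupts finite-differenced densities.
#'
#' @param a,b [GridSpec-class] objects.
#' @return logical scalar.
#' @export
gridsCompatible <- function(a, b, tol = 1e-8) {
  identical(a@counts, b@counts) &&
    all(abs(a@origin - b@origin) < tol) &&
    all(abs(a@step - b@step) < tol)
}

#' Build a grid covering a set of points with a margin
#'
#' Mirrors the grid-construction convention used for the densities: the box
#' boundary sits `margin` Angstrom beyond the extreme atom positions, with
#' the stated lateral and vertical steps.
#'
#' @param points n x 3 matrix of positions (Angstrom).
#' @param margin box margin beyond the extreme positions, default 3 Angstrom.
#' @param stepXY lateral (x, y) step, default 0.4 Angstrom.
#' @param stepZ vertical step, default 0.1 Angstrom.
#' @return a [GridSpec-class].
#' @export
boundingGrid <- function(points, margin = 3, stepXY = 0.4, stepZ = 0.1) {
  points <- rbind(points, deparse.level = 0)  # tolerate a single 3-vector
  lo <- apply(points, 2L, min) - margin
  hi <- apply(points, 2L, max) + margin
  step <- c(stepXY, stepXY, stepZ)
  counts <- pmax(2L, as.integer(ceiling((hi - lo) / step)) + 1L)
  GridSpec(origin = lo, step = step, counts = counts)
}

setMethod("show", "GridSpec", function(object) {
  cat("GridSpec:", paste(object@counts, collapse = " x "), "voxels\n")
  cat("  origin :", paste(sprintf("%.4f", object@origin), collapse = ", "),
      "Angstrom\n")
  cat("  step   :", paste(sprintf("%.4f", object@step), collapse = ", "),
      "Angstrom  (voxel volume", sprintf("%.6g", voxelVolume(object)),
      "A^3)\n")
})
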