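#' Image grid: world-space geometry of a voxel lattice
#'
#' World coordinates follow the LPS convention (x to patient left, y to
#' posterior, z to superior), in millimetres. Voxel indices are 0-based and
#' `origin` is the world position of the *center* of voxel (0,0,0).
#'
#' @param shape integer 3-vector of voxel counts per axis.
#' @param spacing numeric 3-vector, mm per voxel per axis (all > 0).
#' @param origin numeric 3-vector, world coordinates (mm) of voxel (0,0,0).
#' @param direction 3x3 orthonormal direction-cosine matrix (columns are the
#'   world directions of the voxel axes).
#' @return An object of class `image_grid`.
#' @export
image_grid <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       direction = diag(3)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  direction <- matrix(as.numeric(direction), 3, 3)
  if (length(shape) != 3L || any(shape < 1L))
    cbct_stop("cbct_argument_error", "grid shape must be 3 positive integers")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    cbct_stop("cbct_argument_error", "grid spacing must be 3 positive reals")
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6)
    cbct_stop("cbct_argument_error", "direction matrix is not orthonormal")
  structure(list(shape = shape, spacing = spacing, origin = origin,
                 direction = direction),
            class = "image_grid")
}

#' @export
format.image_grid <- function(x, ...) {
  sprintf("<image_grid %s @ %s mm>", paste(x$shape, collapse = "x"),
          paste(signif(x$spacing, 4), collapse = "x"))
}

#' @export
print.image_grid <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

# voxel-index -> world affine, 3x3 linear part (A) with origin as offset
grid_affine <- function(grid) grid$direction %*% diag(grid$spacing, 3, 3)

#' Convert 0-based voxel indices to world coordinates (mm)
#' @param grid an [image_grid].
#' @param idx numeric matrix (n x 3) of 0-based voxel indices (may be fractional).
#' @return n x 3 matrix of world coordinates.
#' @export
voxel_to_world <- function(grid, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  t(grid_affine(grid) %*% t(idx) + grid$origin)
}

#' Convert world coordinates (mm) to continuous 0-based voxel indices
#' @inheritParams voxel_to_world
#' @param pts numeric matrix (n x 3) of world coordinates.
#' @return n x 3 matrix of continuous voxel indices.
#' @export
world_to_voxel <- function(grid, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  A <- grid_affine(grid)
  t(solve(A, t(pts) - grid$origin))
}

grids_equal <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol &&
    max(abs(a$direction - b$direction)) < tol
}

default_padding <- function(unit) {
  switch(unit, HU = -1000, MU_RELATIVE = 0, RATIO = 1, DENSITY = 0,
         cbct_stop("cbct_argument_error", paste("unknown intensity unit:", unit)))
}

VOLUME_UNITS <- c("HU", "MU_RELATIVE", "RATIO", "DENSITY")

#' Volumetric image with world geometry
#'
#' The carrier type for planning CT, CBCT, ratio, density, and corrected
#' volumes: a 3-D voxel array plus an [image_grid] and an intensity unit.
#'
#' @param voxels 3-D numeric array whose `dim` equals `grid$shape`.
#' @param grid an [image_grid].
#' @param unit one of `"HU"`, `"MU_RELATIVE"`, `"RATIO"`, `"DENSITY"`.
#' @param padding scalar reported for out-of-support voxels; defaults to
#'   -1000 for HU, 1 for RATIO, 0 otherwise.
#' @return An object of class `cbct_volume` with fields `voxels`, `grid`,
#'   `unit`, `padding` (and, after resampling, `support`).
#' @export
cbct_volume <- function(voxels, grid, unit = "HU", padding = default_padding(unit)) {
  unit <- match.arg(unit, VOLUME_UNITS)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    cbct_stop("cbct_argument_error", "voxels must be a 3-D array")
  if (!identical(as.integer(dim(voxels)), grid$shape))
    cbct_stop("cbct_argument_error", "voxel array shape does not match grid shape")
  structure(list(voxels = voxels, grid = grid, unit = unit,
                 padding = as.numeric(padding), support = NULL),
            class = "cbct_volume")
}

#' @export
format.cbct_volume <- function(x, ...) {
  sprintf("<cbct_volume %s %s @ %s mm, range [%.6g, %.6g]>",
          x$unit, paste(x$grid$shape, collapse = "x"),
          paste(signif(x$grid$spacing, 4), collapse = "x"),
          min(x$voxels), max(x$voxels))
}

#' @export
print.cbct_volume <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

# same-grid check used throughout the pipeline
check_same_grid <- function(a, b) {
  if (!grids_equal(a$grid, b$grid))
    cbct_stop("cbct_argument_error", "images are not defined on the same grid")
  invisible(TRUE)
}
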