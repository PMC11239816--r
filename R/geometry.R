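#' Volume geometry
#'
#' World geometry of a regular 3D voxel grid. The axis convention is
#' anatomical and fixed: x runs left--right, y anterior--posterior and
#' z superior--inferior, so "axial plane" always means the plane
#' perpendicular to z regardless of file layout. The world position of
#' the centre of voxel `(i, j, k)` (1-based) is
#' `origin + (i - 1, j - 1, k - 1) * spacing`, in millimetres.
#'
#' @param dims Integer vector of length 3, voxels per axis (all >= 1).
#' @param spacing Numeric vector of length 3, voxel edge lengths in mm
#'   (all > 0).
#' @param origin Numeric vector of length 3, world position (mm) of the
#'   centre of the first voxel. Defaults to `c(0, 0, 0)`.
#' @return An object of class `vol_geometry`.
#' @examples
#' vol_geometry(c(96, 96, 120), c(1, 1, 1.5))
#' @export
vol_geometry <- function(dims, spacing, origin = c(0, 0, 0)) {
  dims <- as.integer(dims)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(dims) == 3, length(spacing) == 3, length(origin) == 3)
  if (any(is.na(dims)) || any(dims < 1L)) {
    stop("`dims` must be three integers >= 1", call. = FALSE)
  }
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three positive reals (mm)", call. = FALSE)
  }
  if (any(!is.finite(origin))) {
    stop("`origin` must be finite (mm)", call. = FALSE)
  }
  structure(list(dims = dims, spacing = spacing, origin = origin),
            class = "vol_geometry")
}

#' @export
print.vol_geometry <- function(x, ...) {
  cat(sprintf("<vol_geometry> %d x %d x %d voxels, spacing %g x %g x %g mm, origin (%g, %g, %g) mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @export
format.vol_geometry <- function(x, ...) {
  sprintf("%dx%dx%d @ %g/%g/%g mm", x$dims[1], x$dims[2], x$dims[3],
          x$spacing[1], x$spacing[2], x$spacing[3])
}

geom_equal <- function(a, b) {
  identical(a$dims, b$dims) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-12)) &&
    isTRUE(all.equal(a$origin, b$origin, tolerance = 1e-12))
}

#' World extent of a geometry
#'
#' Returns the voxel-centre bounding box: a 2 x 3 matrix with the world
#' coordinates (mm) of the first and last voxel centres per axis.
#'
#' @param geometry A [vol_geometry()].
#' @return A numeric 2 x 3 matrix with rows `min` and `max`.
#' @export
world_extent <- function(geometry) {
  lo <- geometry$origin
  hi <- geometry$origin + (geometry$dims - 1L) * geometry$spacing
  matrix(c(lo, hi), nrow = 2, byrow = TRUE,
         dimnames = list(c("min", "max"), c("x", "y", "z")))
}

# Per-axis world coordinates of voxel centres.
axis_coords <- function(geometry, axis) {
  geometry$origin[axis] +
    (seq_len(geometry$dims[axis]) - 1) * geometry$spacing[axis]
}

# N x 3 matrix of world coordinates for every voxel centre, x fastest
# (column-major order of the voxel array).
grid_points <- function(geometry) {
  d <- geometry$dims
  cbind(rep(axis_coords(geometry, 1), times = d[2] * d[3]),
        rep(rep(axis_coords(geometry, 2), each = d[1]), times = d[3]),
        rep(axis_coords(geometry, 3), each = d[1] * d[2]))
}

# Round half toward negative infinity; fixed cross-platform tie-break
# for nearest-neighbour index snapping.
round_half_down <- function(x) ceiling(x - 0.5)
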