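#' Planar control-point lattices
#'
#' Each anatomical direction owns an independent regular lattice of
#' cubic B-spline control points whose displacements are constrained to
#' that direction's plane: axial control points (plane perpendicular to
#' z) move only in x/y, sagittal (perpendicular to x) only in y/z,
#' coronal (perpendicular to y) only in x/z. The out-of-plane component
#' is structurally zero, so each lattice contributes a deformation
#' field with a vanishing out-of-plane component, and editing one
#' lattice never touches the other two.
#'
#' `make_lattice()` builds a resting (all-zero) lattice covering the
#' target extent plus the margin cubic-spline support requires: one
#' control point beyond each face, and enough points past the far face
#' that every voxel has a full 4-point support per axis.
#'
#' @param plane `"axial"`, `"sagittal"` or `"coronal"`.
#' @param spacing_mm Positive control-point spacing in mm (same on all
#'   axes; the finest grid used in practice is 20 mm).
#' @param target_geometry The [vol_geometry()] the lattice must cover.
#' @return An object of class `planar_lattice` with fields `plane`,
#'   `spacing`, `origin`, `dims` and a `dims x 3`-shaped displacement
#'   array (`disp`, mm).
#' @examples
#' g <- vol_geometry(c(101, 101, 101), c(1, 1, 1))
#' lat <- make_lattice("axial", 20, g)
#' lat$dims
#' @export
make_lattice <- function(plane = c("axial", "sagittal", "coronal"),
                         spacing_mm, target_geometry) {
  plane <- match.arg(plane)
  stopifnot(inherits(target_geometry, "vol_geometry"))
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1 ||
      !is.finite(spacing_mm) || spacing_mm <= 0) {
    stop("`spacing_mm` must be a positive real", call. = FALSE)
  }
  ext <- world_extent(target_geometry)
  origin <- ext["min", ] - spacing_mm
  # farthest voxel sits at local coordinate u_max; cubic support needs
  # control indices floor(u)-1 .. floor(u)+2 in range for all samples
  u_max <- (ext["max", ] - origin) / spacing_mm
  dims <- as.integer(floor(u_max + 1e-9)) + 3L
  structure(list(plane = plane,
                 spacing = rep(as.numeric(spacing_mm), 3),
                 origin = as.numeric(origin),
                 dims = dims,
                 disp = array(0, c(dims, 3L))),
            class = "planar_lattice")
}

# in-plane axes and the (structurally zero) normal axis per plane
plane_axes <- function(plane) {
  switch(plane,
         axial    = list(inplane = c(1L, 2L), normal = 3L),
         sagittal = list(inplane = c(2L, 3L), normal = 1L),
         coronal  = list(inplane = c(1L, 3L), normal = 2L),
         stop("unknown plane: ", plane, call. = FALSE))
}

#' @export
print.planar_lattice <- function(x, ...) {
  cat(sprintf("<planar_lattice> %s, %g mm spacing, %d x %d x %d control points\n",
              x$plane, x$spacing[1], x$dims[1], x$dims[2], x$dims[3]))
  invisible(x)
}

#' Set one control point's in-plane displacement
#'
#' Stores the two in-plane millimetre components at control point
#' `index`; the out-of-plane component is zero by construction and
#' cannot be set. All other control points — in this lattice and in the
#' other two lattices — are untouched.
#'
#' @param lattice A [make_lattice()] result.
#' @param index Integer triple, 1-based control-point index.
#' @param in_plane Numeric length-2: displacement (mm) along the
#'   plane's two in-plane axes, in canonical axis order (axial: x,y;
#'   sagittal: y,z; coronal: x,z).
#' @return The modified lattice.
#' @examples
#' g <- vol_geometry(c(40, 40, 40), c(1, 1, 1))
#' lat <- make_lattice("sagittal", 20, g)
#' lat <- set_control_displacement(lat, c(2, 2, 2), c(4, 1))
#' lat$disp[2, 2, 2, ]  # (0, 4, 1)
#' @export
set_control_displacement <- function(lattice, index, in_plane) {
  stopifnot(inherits(lattice, "planar_lattice"))
  index <- as.integer(index)
  if (length(index) != 3 || anyNA(index) ||
      any(index < 1L) || any(index > lattice$dims)) {
    stop("control-point index out of range", call. = FALSE)
  }
  in_plane <- as.numeric(in_plane)
  if (length(in_plane) != 2 || any(!is.finite(in_plane))) {
    stop("`in_plane` must be two finite displacement components (mm)",
         call. = FALSE)
  }
  ax <- plane_axes(lattice$plane)
  vec <- c(0, 0, 0)
  vec[ax$inplane] <- in_plane
  lattice$disp[index[1], index[2], index[3], ] <- vec
  lattice
}

# Raw-array variant (used by deserialization and scripted deformation
# generators): the stored 3-vectors must already respect the plane
# constraint — a nonzero out-of-plane component is rejected, never
# silently zeroed.
set_lattice_displacements <- function(lattice, disp) {
  disp <- array(as.numeric(disp), c(lattice$dims, 3L))
  ax <- plane_axes(lattice$plane)
  normal_comp <- disp[, , , ax$normal]
  if (any(normal_comp != 0)) {
    stop("out-of-plane displacement component must be exactly 0 for a ",
         lattice$plane, " lattice", call. = FALSE)
  }
  if (any(!is.finite(disp))) stop("displacements must be finite", call. = FALSE)
  lattice$disp <- disp
  lattice
}

lattice_is_zero <- function(lattice) all(lattice$disp == 0)

# world coordinates of control points along one axis
lattice_axis_coords <- function(lattice, axis) {
  lattice$origin[axis] + (seq_len(lattice$dims[axis]) - 1) * lattice$spacing[axis]
}
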