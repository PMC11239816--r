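#' Dense deformation fields
#'
#' A deformation field stores a per-voxel displacement 3-vector (mm) on
#' a sampling grid (normally the target-image grid). Fields are
#' backward (pull) maps: the content of output point `x` is sampled
#' from `x + displacement(x)` in the source. This convention makes
#' label resampling single-pass and hole-free.
#'
#' @param geometry The sampling-grid [vol_geometry()].
#' @param disp 4D numeric array `c(dims, 3)` of displacements in mm, or
#'   `NULL` for the zero field.
#' @return An object of class `deformation_field`.
#' @export
deformation_field <- function(geometry, disp = NULL) {
  stopifnot(inherits(geometry, "vol_geometry"))
  if (is.null(disp)) disp <- array(0, c(geometry$dims, 3L))
  if (!identical(dim(disp), c(geometry$dims, 3L))) {
    stop("displacement array must have dim c(geometry$dims, 3)", call. = FALSE)
  }
  if (any(!is.finite(disp))) stop("displacements must be finite", call. = FALSE)
  structure(list(geometry = geometry, disp = disp),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  mx <- max(abs(x$disp))
  cat(sprintf("<deformation_field> %s, max |displacement| %.3g mm\n",
              format(x$geometry), mx))
  invisible(x)
}

# Uniform cubic B-spline basis, local coordinate t in [0, 1].
bspline3_weights <- function(t) {
  t2 <- t * t; t3 <- t2 * t
  cbind((1 - t)^3 / 6,
        (3 * t3 - 6 * t2 + 4) / 6,
        (-3 * t3 + 3 * t2 + 3 * t + 1) / 6,
        t3 / 6)
}

# n_samples x n_control dense weight matrix along one axis.
bspline_axis_weights <- function(coords, lat_origin, lat_spacing, n_ctrl) {
  u <- (coords - lat_origin) / lat_spacing
  if (any(u < 1 - 1e-6) || any(u > n_ctrl - 2 + 1e-6)) {
    stop("sampling geometry lies outside the lattice support", call. = FALSE)
  }
  i0 <- pmin(pmax(floor(u), 1), n_ctrl - 3)
  t <- u - i0
  B <- bspline3_weights(t)
  W <- matrix(0, length(coords), n_ctrl)
  for (m in 0:3) W[cbind(seq_along(coords), i0 + m)] <- B[, m + 1]
  W
}

# multiply W (n x d[mode]) along one mode of a 3D array
mode_prod <- function(A, W, mode) {
  d <- dim(A)
  perm <- c(mode, setdiff(1:3, mode))
  M <- W %*% matrix(aperm(A, perm), d[mode])
  aperm(array(M, c(nrow(W), d[perm[2]], d[perm[3]])), order(perm))
}

#' Evaluate a lattice's deformation field
#'
#' Tensor-product uniform cubic B-spline interpolation of the control
#' displacements, sampled at every voxel centre of `geometry`. The
#' out-of-plane component is exactly zero (the lattice never stores
#' one). By the spline's partition of unity, uniformly translated
#' control points reproduce a constant field exactly.
#'
#' @param lattice A [make_lattice()] result.
#' @param geometry The sampling [vol_geometry()] (must lie inside the
#'   lattice support).
#' @return A [deformation_field()].
#' @export
evaluate_field <- function(lattice, geometry) {
  stopifnot(inherits(lattice, "planar_lattice"),
            inherits(geometry, "vol_geometry"))
  if (lattice_is_zero(lattice)) {
    return(deformation_field(geometry))
  }
  W <- lapply(1:3, function(a) {
    bspline_axis_weights(axis_coords(geometry, a), lattice$origin[a],
                         lattice$spacing[a], lattice$dims[a])
  })
  disp <- array(0, c(geometry$dims, 3L))
  for (comp in plane_axes(lattice$plane)$inplane) {
    D <- lattice$disp[, , , comp]
    if (all(D == 0)) next
    disp[, , , comp] <-
      mode_prod(mode_prod(mode_prod(D, W[[1]], 1), W[[2]], 2), W[[3]], 3)
  }
  deformation_field(geometry, disp)
}

# displacement vectors (N x 3) of `field` at arbitrary world points,
# trilinear with edge clamping
sample_field <- function(field, points) {
  n <- nrow(points)
  out <- matrix(0, n, 3)
  d <- field$geometry$dims
  for (comp in 1:3) {
    comp_arr <- field$disp[, , , comp]
    dim(comp_arr) <- d
    out[, comp] <- sample_trilinear_clamped(comp_arr, field$geometry, points)
  }
  out
}

field_as_matrix <- function(field) {
  matrix(field$disp, prod(field$geometry$dims), 3)
}

#' Compose two backward deformation fields
#'
#' Returns the field of the map `outer(inner(x))`: output point `x`
#' first follows `inner`'s displacement, then `outer`'s displacement
#' looked up (trilinear, edge-clamped) at the displaced position.
#'
#' @param outer,inner [deformation_field()]s on the same geometry.
#' @return A [deformation_field()] on the shared geometry.
#' @export
compose_fields <- function(outer, inner) {
  stopifnot(inherits(outer, "deformation_field"),
            inherits(inner, "deformation_field"))
  if (!geom_equal(outer$geometry, inner$geometry)) {
    stop("deformation fields must share one geometry", call. = FALSE)
  }
  g <- inner$geometry
  X <- grid_points(g)
  y <- X + field_as_matrix(inner)
  disp <- (y + sample_field(outer, y)) - X
  deformation_field(g, array(disp, c(g$dims, 3L)))
}

#' Compose the three planar fields into the whole field
#'
#' The whole deformation is the product of the axial, sagittal and
#' coronal factors, applied to the shape in the fixed order coronal,
#' then sagittal, then axial. As backward maps that order is realised
#' as `B(x) = B_coronal(B_sagittal(B_axial(x)))`: sampling the template
#' through `B` reproduces the forward sequence. Changing the order
#' changes the result for non-commuting fields, which is why the order
#' is fixed throughout the package.
#'
#' @param axial,sagittal,coronal [deformation_field()]s sharing one
#'   geometry (each usually from [evaluate_field()]).
#' @return The whole-field [deformation_field()].
#' @export
compose_whole <- function(axial, sagittal, coronal) {
  for (f in list(axial, sagittal, coronal)) {
    stopifnot(inherits(f, "deformation_field"))
  }
  if (!geom_equal(axial$geometry, sagittal$geometry) ||
      !geom_equal(axial$geometry, coronal$geometry)) {
    stop("the three deformation fields must share one geometry", call. = FALSE)
  }
  g <- axial$geometry
  X <- grid_points(g)
  y <- X + field_as_matrix(axial)        # innermost factor, exact on grid
  y <- y + sample_field(sagittal, y)
  y <- y + sample_field(coronal, y)
  deformation_field(g, array(y - X, c(g$dims, 3L)))
}

#' Minimum Jacobian determinant of a deformation
#'
#' Central finite-difference Jacobian of the map `x -> x +
#' displacement(x)` at every interior voxel. A positive minimum means
#' the sampled map is locally invertible everywhere — the operational
#' check that the deformation preserved the template's topology. The
#' identity and any pure translation give exactly 1 everywhere.
#'
#' @param field A [deformation_field()] with at least 3 voxels per axis.
#' @return The minimum determinant (numeric scalar) with attribute
#'   `voxel`: the 1-based interior voxel index attaining it.
#' @export
jacobian_min <- function(field) {
  stopifnot(inherits(field, "deformation_field"))
  d <- field$geometry$dims
  if (any(d < 3L)) {
    stop("jacobian_min needs at least 3 voxels per axis", call. = FALSE)
  }
  h <- field$geometry$spacing
  ii <- 2:(d[1] - 1); jj <- 2:(d[2] - 1); kk <- 2:(d[3] - 1)
  J <- vector("list", 9)
  dim_int <- c(length(ii), length(jj), length(kk))
  idx <- 0
  for (comp in 1:3) {
    D <- field$disp[, , , comp]
    dim(D) <- d
    grads <- list(
      (D[ii + 1, jj, kk] - D[ii - 1, jj, kk]) / (2 * h[1]),
      (D[ii, jj + 1, kk] - D[ii, jj - 1, kk]) / (2 * h[2]),
      (D[ii, jj, kk + 1] - D[ii, jj, kk - 1]) / (2 * h[3])
    )
    for (ax in 1:3) {
      idx <- idx + 1
      g <- grads[[ax]]
      if (comp == ax) g <- g + 1
      J[[idx]] <- as.vector(g)
    }
  }
  # J[[3*(comp-1)+ax]] = d(map_comp)/d(x_ax)
  a11 <- J[[1]]; a12 <- J[[2]]; a13 <- J[[3]]
  a21 <- J[[4]]; a22 <- J[[5]]; a23 <- J[[6]]
  a31 <- J[[7]]; a32 <- J[[8]]; a33 <- J[[9]]
  det <- a11 * (a22 * a33 - a23 * a32) -
         a12 * (a21 * a33 - a23 * a31) +
         a13 * (a21 * a32 - a22 * a31)
  w <- which.min(det)
  vox <- arrayInd(w, dim_int)[1, ] + 1L  # interior offset
  structure(min(det), voxel = vox)
}
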