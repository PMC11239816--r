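# Point-sampling kernels shared by resampling and warping.
#
# `points` is an N x 3 matrix of world coordinates (mm). Values sampled
# outside the source voxel-centre bounding box are background: 0 for
# labels, 0.0 for intensities — deformation near the volume edge must
# never invent anatomy.

sample_nearest <- function(voxels, geometry, points) {
  d <- geometry$dims
  idx <- matrix(0L, nrow(points), 3)
  inside <- rep(TRUE, nrow(points))
  for (a in 1:3) {
    f <- (points[, a] - geometry$origin[a]) / geometry$spacing[a] + 1
    i <- round_half_down(f)
    inside <- inside & i >= 1L & i <= d[a]
    idx[, a] <- pmin(pmax(i, 1L), d[a])
  }
  lin <- idx[, 1] + (idx[, 2] - 1L) * d[1] + (idx[, 3] - 1L) * d[1] * d[2]
  out <- voxels[lin]
  out[!inside] <- if (is.integer(voxels)) 0L else 0
  out
}

sample_trilinear <- function(voxels, geometry, points, outside = 0) {
  d <- geometry$dims
  f <- matrix(0, nrow(points), 3)
  inside <- rep(TRUE, nrow(points))
  for (a in 1:3) {
    fa <- (points[, a] - geometry$origin[a]) / geometry$spacing[a] + 1
    inside <- inside & fa >= 1 & fa <= d[a]
    # clamp so corner gathers stay in range; weights handle the rest
    f[, a] <- pmin(pmax(fa, 1), d[a])
  }
  i0 <- pmin(pmax(floor(f), 1), pmax(d[col(f)] - 1, 1))
  i0 <- matrix(as.integer(i0), nrow(points), 3)
  t <- f - i0
  n1 <- d[1]; n12 <- d[1] * d[2]
  step <- c(1L, n1, n12) * as.integer(d > 1L)  # degenerate axes collapse
  base <- i0[, 1] + (i0[, 2] - 1L) * n1 + (i0[, 3] - 1L) * n12
  acc <- numeric(nrow(points))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- (if (cx) t[, 1] else 1 - t[, 1]) *
         (if (cy) t[, 2] else 1 - t[, 2]) *
         (if (cz) t[, 3] else 1 - t[, 3])
    lin <- base + cx * step[1] + cy * step[2] + cz * step[3]
    acc <- acc + w * voxels[lin]
  }
  acc[!inside] <- outside
  acc
}

# Trilinear with edge clamping (no outside zeroing) — used when
# composing deformation fields, where the nearest edge displacement is
# a better extrapolant than an abrupt zero.
sample_trilinear_clamped <- function(voxels, geometry, points) {
  d <- geometry$dims
  f <- matrix(0, nrow(points), 3)
  for (a in 1:3) {
    fa <- (points[, a] - geometry$origin[a]) / geometry$spacing[a] + 1
    f[, a] <- pmin(pmax(fa, 1), d[a])
  }
  i0 <- pmin(pmax(floor(f), 1), pmax(d[col(f)] - 1, 1))
  i0 <- matrix(as.integer(i0), nrow(points), 3)
  t <- f - i0
  n1 <- d[1]; n12 <- d[1] * d[2]
  step <- c(1L, n1, n12) * as.integer(d > 1L)
  base <- i0[, 1] + (i0[, 2] - 1L) * n1 + (i0[, 3] - 1L) * n12
  acc <- numeric(nrow(points))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- (if (cx) t[, 1] else 1 - t[, 1]) *
         (if (cy) t[, 2] else 1 - t[, 2]) *
         (if (cz) t[, 3] else 1 - t[, 3])
    lin <- base + cx * step[1] + cy * step[2] + cz * step[3]
    acc <- acc + w * voxels[lin]
  }
  acc
}

#' Resample a volume onto a new grid
#'
#' Places `vol` onto `target_geometry` by sampling at the target voxel
#' centres. Label volumes require nearest-neighbour mode so no label
#' value is ever invented; points outside the source extent become
#' background (0). Used, e.g., to put the 1 mm template onto the
#' anisotropic 1.0 x 1.0 x 1.5 mm MR grid.
#'
#' @param vol A [label_volume()] or [intensity_volume()].
#' @param target_geometry A [vol_geometry()] describing the output grid.
#' @param mode `"nearest"` or `"linear"`. Labels must use `"nearest"`.
#' @return A volume of the same class as `vol` on `target_geometry`.
#' @export
resample_volume <- function(vol, target_geometry,
                            mode = c("nearest", "linear")) {
  mode <- match.arg(mode)
  stopifnot(inherits(vol, "ffd_volume"), inherits(target_geometry, "vol_geometry"))
  is_label <- inherits(vol, "label_volume")
  if (is_label && mode == "linear") {
    stop("linear interpolation is not defined for label volumes; use mode = \"nearest\"",
         call. = FALSE)
  }
  if (geom_equal(vol$geometry, target_geometry)) {
    out <- vol
    out$geometry <- target_geometry
    return(out)
  }
  pts <- grid_points(target_geometry)
  vals <- if (mode == "nearest") {
    sample_nearest(vol$voxels, vol$geometry, pts)
  } else {
    sample_trilinear(vol$voxels, vol$geometry, pts)
  }
  arr <- array(vals, target_geometry$dims)
  if (is_label) {
    label_volume(arr, target_geometry, table = vol$table)
  } else {
    intensity_volume(arr, target_geometry)
  }
}
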