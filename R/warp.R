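#' Warp a label volume through a deformation field
#'
#' Backward warping: each output voxel at world position `x` takes the
#' template label nearest to `x + displacement(x)`. The output grid is
#' the field's grid. Nearest-neighbour sampling guarantees the output
#' label set is a subset of the template's (plus background); sample
#' points falling outside the template become background. Half-integer
#' index ties round toward negative infinity, fixed across platforms.
#'
#' @param template A [label_volume()].
#' @param field A [deformation_field()] defining the output grid.
#' @return A [label_volume()] on the field's geometry.
#' @export
warp_labels <- function(template, field) {
  stopifnot(inherits(template, "label_volume"),
            inherits(field, "deformation_field"))
  pts <- warp_sample_points(field)
  vals <- sample_nearest(template$voxels, template$geometry, pts)
  label_volume(array(vals, field$geometry$dims), field$geometry,
               table = template$table)
}

#' Warp an intensity volume through a deformation field
#'
#' As [warp_labels()] but with trilinear interpolation; sample points
#' outside the source read 0.
#'
#' @param image An [intensity_volume()].
#' @param field A [deformation_field()] defining the output grid.
#' @return An [intensity_volume()] on the field's geometry.
#' @export
warp_image <- function(image, field) {
  stopifnot(inherits(image, "intensity_volume"),
            inherits(field, "deformation_field"))
  pts <- warp_sample_points(field)
  vals <- sample_trilinear(image$voxels, image$geometry, pts)
  intensity_volume(array(vals, field$geometry$dims), field$geometry)
}

# where each output voxel samples from (output grid + displacement);
# the zero field short-circuits to the exact grid coordinates
warp_sample_points <- function(field) {
  X <- grid_points(field$geometry)
  if (all(field$disp == 0)) X else X + field_as_matrix(field)
}
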