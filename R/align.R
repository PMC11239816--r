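#' Similarity alignment of the template
#'
#' The initial, global placement of the template over the target:
#' isotropic scale and rotation about the template's world centre,
#' followed by translation. Rotation angles are Euler angles in
#' degrees, applied z, then y, then x. This is the scripted stand-in
#' for the interactive "rough alignment" step of the workflow; it is
#' composed as the innermost (template-side) factor, before any
#' free-form deformation.
#'
#' @param translation Numeric length-3, mm.
#' @param rotation Numeric length-3, degrees (z, y, x order of
#'   application).
#' @param scale Positive isotropic scale factor.
#' @return An object of class `similarity_alignment`.
#' @export
similarity_alignment <- function(translation = c(0, 0, 0),
                                 rotation = c(0, 0, 0),
                                 scale = 1) {
  translation <- as.numeric(translation)
  rotation <- as.numeric(rotation)
  stopifnot(length(translation) == 3, length(rotation) == 3,
            length(scale) == 1)
  if (!is.finite(scale) || scale <= 0) {
    stop("`scale` must be a positive real", call. = FALSE)
  }
  if (any(!is.finite(translation)) || any(!is.finite(rotation))) {
    stop("alignment parameters must be finite", call. = FALSE)
  }
  structure(list(translation = translation, rotation = rotation,
                 scale = as.numeric(scale)),
            class = "similarity_alignment")
}

is_identity_alignment <- function(a) {
  all(a$translation == 0) && all(a$rotation == 0) && a$scale == 1
}

rotation_matrix_zyx <- function(deg) {
  r <- deg * pi / 180
  cz <- cos(r[1]); sz <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cx <- cos(r[3]); sx <- sin(r[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Rx %*% Ry %*% Rz  # z applied first
}

# map world sample points back into template coordinates:
# forward A(p) = s * R (p - c) + c + t  =>  p = R^-1((y - c - t)/s) + c
invert_alignment_points <- function(alignment, points, center) {
  if (is_identity_alignment(alignment)) return(points)
  R <- rotation_matrix_zyx(alignment$rotation)
  y <- sweep(points, 2, center + alignment$translation)
  p <- (y / alignment$scale) %*% R  # y %*% R == t(R^T y^T)^T = R^-1 applied rowwise
  sweep(p, 2, center, "+")
}

volume_center <- function(geometry) {
  geometry$origin + (geometry$dims - 1L) * geometry$spacing / 2
}
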