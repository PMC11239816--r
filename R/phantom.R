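#' Phantom specification
#'
#' Describes a synthetic limb-like volume used to exercise the whole
#' pipeline without patient data: a central bone (label 1) whose radius
#' varies smoothly along z, surrounded by an annulus of `n_muscles`
#' angular-sector muscles (labels 2..n_muscles+1), a bright fat rim and
#' dark background (both label 0). The default grid copies the MR
#' acquisition geometry (1.0 x 1.0 x 1.5 mm, anisotropic) so that
#' resampling paths are exercised; intensity class means are separated
#' by well over twice the noise sd so segmentation difficulty stays
#' controlled.
#'
#' @param dims Voxels per axis (default `c(96, 96, 120)`).
#' @param spacing Voxel size mm (default `c(1, 1, 1.5)`).
#' @param n_muscles Number of muscle sectors (>= 1, default 8).
#' @param bone_radius Mean bone radius mm (default 10).
#' @param limb_radius Mean outer limb radius mm (default 38).
#' @param rim_mm Fat rim thickness mm (default 4).
#' @param means Named intensities for `background`, `bone`, `muscle`,
#'   `fat`.
#' @param noise_sd Gaussian noise sd added to the intensity image.
#' @param seed Integer RNG seed; generation is fully deterministic per
#'   seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(96, 96, 120), spacing = c(1, 1, 1.5),
                         n_muscles = 8, bone_radius = 10, limb_radius = 38,
                         rim_mm = 4,
                         means = c(background = 10, bone = 40,
                                   muscle = 110, fat = 200),
                         noise_sd = 10, seed = 1L) {
  if (n_muscles < 1 || n_muscles + 2 > 255) {
    stop("`n_muscles` must be in 1..253", call. = FALSE)
  }
  if (bone_radius <= 0 || limb_radius <= bone_radius + rim_mm) {
    stop("degenerate radii: need 0 < bone_radius < limb_radius - rim_mm",
         call. = FALSE)
  }
  need <- c("background", "bone", "muscle", "fat")
  if (!all(need %in% names(means))) {
    stop("`means` must name background, bone, muscle and fat", call. = FALSE)
  }
  structure(list(dims = as.integer(dims), spacing = as.numeric(spacing),
                 n_muscles = as.integer(n_muscles),
                 bone_radius = bone_radius, limb_radius = limb_radius,
                 rim_mm = rim_mm, means = means, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a synthetic limb phantom
#'
#' @param spec A [phantom_spec()].
#' @return A list with `labels` (a [label_volume()]) and `image` (an
#'   [intensity_volume()]) on the spec's grid.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- vol_geometry(spec$dims, spec$spacing)
  d <- g$dims
  cx <- (d[1] - 1) * g$spacing[1] / 2
  cy <- (d[2] - 1) * g$spacing[2] / 2
  x <- axis_coords(g, 1) - cx
  y <- axis_coords(g, 2) - cy
  z <- axis_coords(g, 3)
  zn <- (z - min(z)) / max(z[length(z)] - z[1], 1e-9)   # 0..1 along the limb

  # smooth radius profiles along z: a gentle mid-limb bulge for the
  # muscle compartment and a mild taper for the bone
  r_limb <- spec$limb_radius * (0.88 + 0.12 * sin(pi * zn))
  r_bone <- spec$bone_radius * (0.95 + 0.10 * cos(2 * pi * zn) * 0.5)
  r_musc <- r_limb - spec$rim_mm

  rx <- matrix(x, d[1], d[2])
  ry <- matrix(y, d[1], d[2], byrow = TRUE)
  rad2 <- rx^2 + ry^2
  theta <- atan2(ry, rx)                                # (-pi, pi]
  sector <- pmin(floor((theta + pi) / (2 * pi) * spec$n_muscles),
                 spec$n_muscles - 1)

  labels <- array(0L, d)
  for (k in seq_len(d[3])) {
    sl <- integer(d[1] * d[2])
    in_musc <- rad2 <= r_musc[k]^2
    sl[in_musc] <- 2L + as.integer(sector[in_musc])
    sl[rad2 <= r_bone[k]^2] <- 1L
    labels[, , k] <- sl
  }

  withr_seed <- spec$seed
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_seed(old), add = TRUE)
  set.seed(withr_seed)

  intens <- array(spec$means[["background"]], d)
  for (k in seq_len(d[3])) {
    sl <- matrix(spec$means[["background"]], d[1], d[2])
    sl[rad2 <= r_limb[k]^2] <- spec$means[["fat"]]
    sl[rad2 <= r_musc[k]^2] <- spec$means[["muscle"]]
    sl[rad2 <= r_bone[k]^2] <- spec$means[["bone"]]
    intens[, , k] <- sl
  }
  intens <- intens + array(stats::rnorm(prod(d), 0, spec$noise_sd), d)
  intens <- smooth3(intens)

  table <- label_table(seq_len(spec$n_muscles + 1L),
                       c("bone", sprintf("muscle_%02d", seq_len(spec$n_muscles))))
  list(labels = label_volume(labels, g, table = table),
       image = intensity_volume(intens, g))
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# light separable 1-2-1 smoothing with edge replication
smooth3 <- function(a) {
  for (axis in 1:3) {
    lo <- shift_array(a, axis, -1L)
    hi <- shift_array(a, axis, +1L)
    a <- (lo + 2 * a + hi) / 4
  }
  a
}

# shift along an axis by one voxel, replicating the edge slice
shift_array <- function(a, axis, by) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  src <- pmin(pmax(idx[[axis]] - by, 1L), d[axis])
  idx[[axis]] <- src
  do.call(`[`, c(list(a), idx))
}

#' Ground-truth deformation specification
#'
#' Parameters of the smooth random tri-planar deformation that turns
#' the phantom into a simulated "participant": a coarse lattice
#' spacing, a bound on the in-plane displacement components, and a
#' seed. Displacements are band-limited by construction (drawn on the
#' coarse control grid and smoothed), honouring the premise that the
#' tool's deformations preserve topology; keeping the bound at or
#' below 0.4 x spacing keeps the composed field's Jacobian positive.
#'
#' @param lattice_spacing_mm Control spacing of the generating
#'   lattices, mm (default 40).
#' @param max_disp_mm Bound on each in-plane displacement component,
#'   mm (default `0.4 * lattice_spacing_mm`).
#' @param smooth_passes Smoothing passes applied to the raw draws
#'   (default 2).
#' @param seed Integer RNG seed.
#' @return An object of class `deformation_spec`.
#' @export
deformation_spec <- function(lattice_spacing_mm = 40,
                             max_disp_mm = 0.4 * lattice_spacing_mm,
                             smooth_passes = 2, seed = 1L) {
  if (lattice_spacing_mm <= 0) stop("lattice spacing must be > 0", call. = FALSE)
  if (max_disp_mm < 0) stop("`max_disp_mm` must be >= 0", call. = FALSE)
  structure(list(lattice_spacing_mm = lattice_spacing_mm,
                 max_disp_mm = max_disp_mm,
                 smooth_passes = as.integer(smooth_passes),
                 seed = as.integer(seed)),
            class = "deformation_spec")
}

#' Draw a random tri-planar lattice triple
#'
#' @param dspec A [deformation_spec()].
#' @param geometry The target [vol_geometry()] the lattices must cover.
#' @return A named list of three [make_lattice()] results (`axial`,
#'   `sagittal`, `coronal`) with smooth random in-plane displacements,
#'   each component bounded by `max_disp_mm`.
#' @export
generate_deformation <- function(dspec, geometry) {
  stopifnot(inherits(dspec, "deformation_spec"))
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_seed(old), add = TRUE)
  set.seed(dspec$seed)
  triple <- lattice_triple(dspec$lattice_spacing_mm, geometry)
  if (dspec$max_disp_mm == 0) return(triple)
  for (p in names(triple)) {
    lat <- triple[[p]]
    ax <- plane_axes(p)
    disp <- array(0, c(lat$dims, 3L))
    for (comp in ax$inplane) {
      raw <- array(stats::rnorm(prod(lat$dims)), lat$dims)
      for (s in seq_len(dspec$smooth_passes)) raw <- smooth3(raw)
      peak <- max(abs(raw))
      if (peak > 0) raw <- raw / peak * dspec$max_disp_mm
      disp[, , , comp] <- raw
    }
    triple[[p]] <- set_lattice_displacements(lat, disp)
  }
  triple
}

#' Simulate a participant from the phantom
#'
#' Warps the phantom labels and image through the identical composed
#' tri-planar field, so the returned ground truth is exactly
#' recoverable: replaying `triple` in an annotation session on the
#' original template reproduces `ground_truth` bit-exactly (Dice 1 on
#' every label), because [make_target()] and [apply_session()] share
#' one warp implementation.
#'
#' @param labels Phantom [label_volume()] (the template).
#' @param image Phantom [intensity_volume()].
#' @param triple Lattice triple from [generate_deformation()].
#' @return A list with `target` (warped [intensity_volume()]),
#'   `ground_truth` (warped [label_volume()]) and `field` (the composed
#'   [deformation_field()]).
#' @export
make_target <- function(labels, image, triple) {
  stopifnot(inherits(labels, "label_volume"),
            inherits(image, "intensity_volume"))
  if (!geom_equal(labels$geometry, image$geometry)) {
    stop("phantom labels and image must share one geometry", call. = FALSE)
  }
  check_lattice_triple(triple)
  field <- triple_whole_field(triple, labels$geometry)
  list(target = warp_image(image, field),
       ground_truth = warp_labels(labels, field),
       field = field)
}
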