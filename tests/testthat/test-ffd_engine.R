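test_that("lattices cover the target extent with a one-point margin", {
  g <- vol_geometry(c(101, 101, 101), c(1, 1, 1))  # 100 mm extent
  lat <- make_lattice("axial", 20, g)
  lo <- lat$origin
  hi <- lat$origin + (lat$dims - 1) * lat$spacing
  expect_true(all(lo <= -20 + 1e-9))
  expect_true(all(hi >= 120 - 1e-9))
  expect_true(all(lat$disp == 0))
  expect_error(make_lattice("axial", 0, g), "positive")
  expect_error(make_lattice("axial", -5, g), "positive")
})

test_that("in-plane constraint holds by construction for every plane", {
  g <- tiny_geom()
  cases <- list(
    list(plane = "axial", in_plane = c(3, -2), stored = c(3, -2, 0)),
    list(plane = "sagittal", in_plane = c(4, 1), stored = c(0, 4, 1)),
    list(plane = "coronal", in_plane = c(-1, 6), stored = c(-1, 0, 6))
  )
  for (cs in cases) {
    lat <- make_lattice(cs$plane, 20, g)
    lat <- set_control_displacement(lat, c(2, 2, 2), cs$in_plane)
    expect_equal(lat$disp[2, 2, 2, ], cs$stored)
    # and the evaluated field has an exactly zero out-of-plane component
    f <- evaluate_field(lat, g)
    normal <- ffdseg:::plane_axes(cs$plane)$normal
    expect_true(all(f$disp[, , , normal] == 0))
  }
  lat <- make_lattice("axial", 20, g)
  expect_error(set_control_displacement(lat, c(-1, 1, 1), c(1, 1)), "range")
  expect_error(set_control_displacement(lat, c(99, 1, 1), c(1, 1)), "range")
  expect_error(ffdseg:::set_lattice_displacements(
    lat, array(1, c(lat$dims, 3))), "out-of-plane")
})

test_that("resting lattices evaluate to the exact zero field", {
  g <- tiny_geom()
  for (p in c("axial", "sagittal", "coronal")) {
    f <- evaluate_field(make_lattice(p, 25, g), g)
    expect_true(all(f$disp == 0))
  }
})

test_that("uniform control translation reproduces a constant field (affine precision)", {
  g <- vol_geometry(c(30, 25, 20), c(2, 2.5, 3), c(-7, 3, 11))
  lat <- make_lattice("axial", 35, g)
  d <- array(0, c(lat$dims, 3)); d[, , , 1] <- 2; d[, , , 2] <- -1.25
  lat <- ffdseg:::set_lattice_displacements(lat, d)
  f <- evaluate_field(lat, g)
  expect_lt(max(abs(f$disp[, , , 1] - 2)), 1e-9)
  expect_lt(max(abs(f$disp[, , , 2] + 1.25)), 1e-9)
  expect_true(all(f$disp[, , , 3] == 0))
})

test_that("evaluate_field matches brute-force basis summation", {
  g <- vol_geometry(c(21, 21, 21), c(5, 5, 5))
  lat <- make_lattice("axial", 20, g)
  lat <- set_control_displacement(lat, c(3, 3, 3), c(10, 0))
  # sample coincident with the displaced control point: weight (2/3)^3
  f <- evaluate_field(lat, g)
  expect_equal(f$disp[5, 5, 5, ], c(10 * (2 / 3)^3, 0, 0), tolerance = 1e-12)
  # random lattice against the full-support sum at random points
  set.seed(42)
  d <- array(0, c(lat$dims, 3))
  d[, , , 1] <- runif(prod(lat$dims), -8, 8)
  d[, , , 2] <- runif(prod(lat$dims), -8, 8)
  lat <- ffdseg:::set_lattice_displacements(lat, d)
  for (q in 1:20) {
    p <- runif(3, 0, 100)
    expect_equal(eval_disp_at(lat, p), bf_bspline_disp(lat, p),
                 tolerance = 1e-11)
  }
  expect_error(evaluate_field(lat, vol_geometry(c(5, 5, 5), c(100, 1, 1))),
               "outside the lattice support")
})

test_that("editing one plane's lattice leaves the other lattices untouched", {
  g <- tiny_geom()
  triple <- ffdseg:::lattice_triple(30, g)
  before_sag <- triple$sagittal
  before_cor <- triple$coronal
  triple$axial <- set_control_displacement(triple$axial, c(2, 3, 2), c(5, -4))
  expect_identical(triple$sagittal, before_sag)
  expect_identical(triple$coronal, before_cor)
})

test_that("constant backward fields compose additively; zero fields are neutral", {
  g <- tiny_geom()
  zero <- deformation_field(g)
  const <- function(v) deformation_field(
    g, array(rep(v, each = prod(g$dims)), c(g$dims, 3)))
  w0 <- compose_whole(zero, zero, zero)
  expect_true(all(w0$disp == 0))
  w1 <- compose_whole(const(c(2, 0, 0)), zero, zero)
  expect_equal(ffdseg:::field_as_matrix(w1),
               matrix(rep(c(2, 0, 0), each = prod(g$dims)), ncol = 3),
               tolerance = 1e-12)
  w2 <- compose_whole(const(c(2, 0, 0)), zero, const(c(0, 0, 3)))
  expect_equal(ffdseg:::field_as_matrix(w2),
               matrix(rep(c(2, 0, 3), each = prod(g$dims)), ncol = 3),
               tolerance = 1e-6)
  g2 <- vol_geometry(c(5, 5, 5), c(1, 1, 1))
  expect_error(compose_whole(deformation_field(g2), zero, zero), "geometry")
})

test_that("composition order matters for non-commuting fields", {
  g <- vol_geometry(c(24, 24, 24), c(4, 4, 4))
  set.seed(7)
  mk <- function(plane, seed) {
    lat <- make_lattice(plane, 40, g)
    set.seed(seed)
    d <- array(0, c(lat$dims, 3))
    for (comp in ffdseg:::plane_axes(plane)$inplane) {
      d[, , , comp] <- runif(prod(lat$dims), -12, 12)
    }
    evaluate_field(ffdseg:::set_lattice_displacements(lat, d), g)
  }
  fa <- mk("axial", 1); fs <- mk("sagittal", 2); fc <- mk("coronal", 3)
  canonical <- compose_whole(fa, fs, fc)
  permuted <- compose_whole(fc, fs, fa)  # axial applied first to the shape
  expect_gt(max(abs(canonical$disp - permuted$disp)), 0.1)
})

test_that("warping labels follows the index-shift oracle and never invents labels", {
  g <- tiny_geom()  # 2 mm spacing
  tpl <- random_label_volume(g, n_labels = 2, seed = 5)
  # zero field on the template grid: identity
  expect_identical(warp_labels(tpl, deformation_field(g))$voxels, tpl$voxels)
  # constant one-voxel shift along y (backward +2 mm: sample from j+1)
  shift <- deformation_field(
    g, array(rep(c(0, 2, 0), each = prod(g$dims)), c(g$dims, 3)))
  out <- warp_labels(tpl, shift)
  expect_identical(out$voxels[, 1:11, ], tpl$voxels[, 2:12, ])
  expect_true(all(out$voxels[, 12, ] == 0L))  # vacated slab is background
  # arbitrary smooth field: label closure
  lat <- make_lattice("coronal", 12, g)
  set.seed(6)
  d <- array(0, c(lat$dims, 3))
  d[, , , 1] <- runif(prod(lat$dims), -4, 4)
  d[, , , 3] <- runif(prod(lat$dims), -4, 4)
  f <- evaluate_field(ffdseg:::set_lattice_displacements(lat, d), g)
  out2 <- warp_labels(tpl, f)
  expect_true(all(out2$voxels %in% c(0L, tpl$table$id)))
})

test_that("warping images interpolates trilinearly and matches integer shifts", {
  g <- tiny_geom()
  set.seed(8)
  img <- intensity_volume(array(rnorm(prod(g$dims)), g$dims), g)
  expect_identical(warp_image(img, deformation_field(g))$voxels, img$voxels)
  cst <- intensity_volume(array(3.5, g$dims), g)
  shift <- deformation_field(
    g, array(rep(c(0, 0, 2), each = prod(g$dims)), c(g$dims, 3)))
  expect_true(all(abs(warp_image(cst, shift)$voxels[, , 1:11] - 3.5) < 1e-12))
  out <- warp_image(img, shift)
  expect_equal(out$voxels[, , 1:11], img$voxels[, , 2:12], tolerance = 1e-12)
  expect_true(all(out$voxels[, , 12] == 0))
})

test_that("jacobian_min certifies identity, translation and linear maps", {
  g <- tiny_geom()
  expect_equal(as.numeric(jacobian_min(deformation_field(g))), 1.0)
  tr <- deformation_field(
    g, array(rep(c(5, -3, 2), each = prod(g$dims)), c(g$dims, 3)))
  expect_equal(as.numeric(jacobian_min(tr)), 1.0)
  # d(x) = (0.1 x, 0, 0): det(J) = 1.1 exactly, central differences are
  # exact for linear fields
  X <- ffdseg:::grid_points(g)
  lin <- deformation_field(
    g, array(c(0.1 * X[, 1], numeric(nrow(X)), numeric(nrow(X))),
             c(g$dims, 3)))
  expect_equal(as.numeric(jacobian_min(lin)), 1.1, tolerance = 1e-12)
  expect_error(jacobian_min(deformation_field(vol_geometry(c(2, 5, 5), c(1, 1, 1)))),
               "3 voxels")
})

test_that("bounded random deformations keep a positive Jacobian", {
  g <- vol_geometry(c(32, 32, 24), c(2, 2, 2))
  for (seed in 1:5) {
    triple <- generate_deformation(
      deformation_spec(lattice_spacing_mm = 32, seed = seed), g)
    f <- ffdseg:::triple_whole_field(triple, g)
    expect_gt(as.numeric(jacobian_min(f)), 0)
  }
})

test_that("refine halves the spacing down the 80/40/20 ladder and bakes losslessly", {
  g <- tiny_geom(c(16, 16, 16), c(4, 4, 4))
  triple <- ffdseg:::lattice_triple(80, g)
  r1 <- refine(triple, g)
  expect_equal(r1$lattices$axial$spacing[1], 40)
  expect_true(all(r1$base$disp == 0))
  r2 <- refine(r1$lattices, g, r1$base)
  expect_equal(vapply(r2$lattices, function(l) l$spacing[1], numeric(1)),
               c(axial = 20, sagittal = 20, coronal = 20))
  # nonzero triple: warp before == warp after refine, bit-identical
  tpl <- random_label_volume(g, seed = 9)
  triple$axial <- set_control_displacement(triple$axial, c(2, 2, 2), c(9, -6))
  triple$coronal <- set_control_displacement(triple$coronal, c(2, 3, 2), c(4, 7))
  before_field <- ffdseg:::triple_whole_field(triple, g)
  before <- warp_labels(tpl, before_field)
  r <- refine(triple, g)
  after_field <- ffdseg:::triple_whole_field(r$lattices, g)  # zero
  total <- if (all(after_field$disp == 0)) r$base else
    compose_fields(r$base, after_field)
  after <- warp_labels(tpl, total)
  expect_identical(before$voxels, after$voxels)
  expect_error(refine(list(axial = triple$axial), g), "named list")
})
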