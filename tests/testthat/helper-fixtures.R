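# Shared fixtures and independent oracles. Everything here is built in
# code at test time; the oracles deliberately avoid the code paths they
# check.

tiny_geom <- function(dims = c(12, 12, 12), spacing = c(2, 2, 2),
                      origin = c(0, 0, 0)) {
  vol_geometry(dims, spacing, origin)
}

random_label_volume <- function(geom = tiny_geom(), n_labels = 3, seed = 1) {
  set.seed(seed)
  label_volume(array(sample(0:n_labels, prod(geom$dims), TRUE), geom$dims),
               geom)
}

# Brute-force FFD oracle: displacement at world point p as the full sum
# over every control point of the centred cubic B-spline basis.
bf_bspline_disp <- function(lattice, p) {
  b3 <- function(r) {
    r <- abs(r)
    if (r >= 2) 0
    else if (r >= 1) (2 - r)^3 / 6
    else (3 * r^3 - 6 * r^2 + 4) / 6
  }
  s <- c(0, 0, 0)
  for (a in seq_len(lattice$dims[1]))
    for (b in seq_len(lattice$dims[2]))
      for (cc in seq_len(lattice$dims[3])) {
        w <- 1
        for (ax in 1:3) {
          u <- (p[ax] - lattice$origin[ax]) / lattice$spacing[ax]
          w <- w * b3(u - (c(a, b, cc)[ax] - 1))
          if (w == 0) break
        }
        if (w != 0) s <- s + w * lattice$disp[a, b, cc, ]
      }
  s
}

# field evaluated at one arbitrary world point via the package (single
# sample voxel)
eval_disp_at <- function(lattice, p) {
  g1 <- vol_geometry(c(1, 1, 1), c(1, 1, 1), p)
  evaluate_field(lattice, g1)$disp[1, 1, 1, ]
}

# Exact two-sided signed-rank p by enumerating all 2^n sign
# assignments (doubling convention, capped at 1).
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
  w_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# 26-connected component count by iterated min-label propagation.
count_components_26 <- function(mask) {
  d <- dim(mask)
  comp <- array(NA_real_, d)
  comp[mask] <- which(mask)
  shifts <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  shifts <- shifts[rowSums(shifts != 0) > 0, ]
  shift1 <- function(a, s) {
    out <- array(NA_real_, d)
    src <- list(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
    dst <- src
    for (ax in 1:3) {
      k <- s[[ax]]
      if (k == 1) { dst[[ax]] <- 2:d[ax]; src[[ax]] <- 1:(d[ax] - 1) }
      if (k == -1) { dst[[ax]] <- 1:(d[ax] - 1); src[[ax]] <- 2:d[ax] }
    }
    out[dst$x, dst$y, dst$z] <- a[src$x, src$y, src$z]
    out
  }
  repeat {
    prev <- comp
    for (i in seq_len(nrow(shifts))) {
      sh <- shift1(comp, as.list(shifts[i, ]))
      take <- mask & !is.na(sh) & (is.na(comp) | sh < comp)
      comp[take] <- sh[take]
    }
    if (identical(prev, comp)) break
  }
  length(unique(comp[mask]))
}

# small, fast phantom used by most tests (the full-size default grid is
# exercised in the acceptance suite)
small_phantom_spec <- function(seed = 1) {
  phantom_spec(dims = c(48, 48, 32), spacing = c(1, 1, 1.5),
               n_muscles = 6, bone_radius = 6, limb_radius = 19,
               rim_mm = 3, seed = seed)
}
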