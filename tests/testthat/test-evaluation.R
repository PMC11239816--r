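mask_volume <- function(positions, g = vol_geometry(c(6, 6, 6), c(1, 1, 1))) {
  vox <- array(0L, g$dims)
  vox[positions] <- 1L
  label_volume(vox, g)
}

test_that("dice handles identity, disjoint, hand-counted and empty masks", {
  a <- mask_volume(1:8)
  expect_identical(as.numeric(dice(a, a, 1)), 1.0)
  b <- mask_volume(9:12)
  expect_identical(as.numeric(dice(a, b, 1)), 0.0)
  # |A| = 8, |B| = 4, |A intersect B| = 2 -> 2*2/12
  c <- mask_volume(7:10)
  expect_equal(as.numeric(dice(a, c, 1)), 1 / 3, tolerance = 1e-12)
  # symmetry
  expect_identical(dice(a, c, 1), dice(c, a, 1))
  # both masks empty: 1.0 with a flag
  d0 <- dice(a, a, 99)
  expect_identical(as.numeric(d0), 1.0)
  expect_true(attr(d0, "both_empty"))
  g2 <- vol_geometry(c(6, 6, 6), c(2, 1, 1))
  expect_error(dice(a, mask_volume(1:8, g2), 1), "geometry")
})

test_that("element volumes honour anisotropic voxel size", {
  g1 <- vol_geometry(c(10, 10, 10), c(1, 1, 1))
  v1 <- label_volume(array(c(rep(1L, 1000)), g1$dims), g1)
  expect_equal(volume_cm3(v1, 1), 1.0)
  g2 <- vol_geometry(c(10, 10, 10), c(1, 1, 1.5))
  v2 <- label_volume(array(c(rep(1L, 1000)), g2$dims), g2)
  expect_equal(volume_cm3(v2, 1), 1.5)
  expect_equal(volume_cm3(v2, 7), 0.0)  # absent label
})

test_that("volume error is absolute, symmetric and triangle-consistent", {
  g <- vol_geometry(c(20, 20, 20), c(1, 1, 1))
  mk <- function(n) {
    vox <- array(0L, g$dims); vox[seq_len(n)] <- 1L
    label_volume(vox, g)
  }
  a <- mk(5000); b <- mk(2500); c <- mk(4000)
  expect_equal(volume_error(a, a, 1), 0)
  expect_equal(volume_error(a, b, 1), 2.5)
  expect_identical(volume_error(a, b, 1), volume_error(b, a, 1))
  expect_lte(volume_error(a, b, 1),
             volume_error(a, c, 1) + volume_error(c, b, 1))
})

test_that("participant summaries are plain unweighted means", {
  rows <- dplyr::bind_rows(
    tibble::tibble(participant = "p1", label = 1:2, name = c("a", "b"),
                   dice = c(0.8, 0.6), vol_pred_cm3 = 1, vol_truth_cm3 = 1,
                   vol_err_cm3 = c(0.5, 0.1)),
    tibble::tibble(participant = "p2", label = 1:2, name = c("a", "b"),
                   dice = c(1.0, 1.0), vol_pred_cm3 = 1, vol_truth_cm3 = 1,
                   vol_err_cm3 = c(0, 0)))
  ps <- participant_summary(rows)
  expect_equal(ps$mean_dice, c(0.7, 1.0))
  expect_equal(ps$mean_vol_err_cm3, c(0.3, 0.0))
  # re-average a random report with a brute-force loop
  set.seed(10)
  big <- tidyr::crossing(participant = sprintf("p%02d", 1:6), label = 1:5)
  big$name <- sprintf("el%d", big$label)
  big$dice <- runif(nrow(big))
  big$vol_pred_cm3 <- runif(nrow(big))
  big$vol_truth_cm3 <- runif(nrow(big))
  big$vol_err_cm3 <- abs(big$vol_pred_cm3 - big$vol_truth_cm3)
  ps2 <- participant_summary(big)
  for (p in unique(big$participant)) {
    expect_equal(ps2$mean_dice[ps2$participant == p],
                 mean(big$dice[big$participant == p]))
  }
  expect_error(participant_summary(rows[-1, ]), "missing element rows")
})

test_that("signed-rank p-values match exact enumeration", {
  # all-positive differences 1..6: p = 2/64
  r <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6, 7), rep(1, 6))
  expect_equal(r$p_value, 0.03125)
  expect_identical(r$method, "exact")
  expect_equal(r$statistic, 21)
  # perfect sign symmetry: p = 1
  r2 <- suppressWarnings(
    wilcoxon_signed_rank(c(1, -1, 2, -2), c(0, 0, 0, 0)))
  expect_equal(r2$p_value, 1.0)
  # degenerate: all differences zero
  expect_error(wilcoxon_signed_rank(1:6, 1:6), "zero")
  expect_error(wilcoxon_signed_rank(1:3, 1:2), "equal length")
})

test_that("signed-rank agrees with the reference implementation and its own exact path", {
  set.seed(20)
  for (rep in 1:10) {
    n <- sample(8:12, 1)
    x <- round(rnorm(n, 0.3), 3)
    y <- round(rnorm(n), 3)
    if (any(x == y)) next
    ours_exact <- wilcoxon_signed_rank(x, y, exact = TRUE)
    ours_normal <- wilcoxon_signed_rank(x, y, exact = FALSE)
    # independent enumeration oracle
    expect_equal(ours_exact$p_value, enumerate_signed_rank_p(x - y))
    # normal approximation close to exact for 8 <= n <= 12
    expect_lt(abs(ours_normal$p_value - ours_exact$p_value), 0.02)
    # stats::wilcox.test as external cross-check of the normal path
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                              correct = TRUE)
    expect_equal(ours_normal$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("bonferroni multiplies and caps", {
  expect_equal(bonferroni(0.01, m = 3), 0.03)
  expect_equal(bonferroni(0.5, m = 3), 1.0)
  expect_equal(bonferroni(0.011, m = 3), 0.033)
  expect_equal(bonferroni(c(0.02, 0.9), m = 3), c(0.06, 1.0))
  expect_error(bonferroni(1.2, m = 3), "\\[0, 1\\]")
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "at least")
})

test_that("k-fold grouping partitions ids into near-equal, seeded folds", {
  ids <- sprintf("p%02d", 1:20)
  f <- kfold_split(ids, 5, seed = 42)
  expect_setequal(f$id, ids)
  expect_identical(sort(unique(f$fold)), 1:5)
  expect_true(all(table(f$fold) == 4L))
  expect_identical(kfold_split(ids, 5, seed = 42), f)
  expect_false(identical(kfold_split(ids, 5, seed = 43)$fold, f$fold))
  # uneven split: sizes differ by at most one
  f2 <- kfold_split(sprintf("q%d", 1:22), 5, seed = 1)
  expect_lte(diff(range(table(f2$fold))), 1)
  expect_error(kfold_split(ids, 21, seed = 1), "exceed")
})

test_that("per-fold training sets reproduce the benchmark cohort sizes", {
  ids <- sprintf("p%02d", 1:20)
  folds <- kfold_split(ids, 5, seed = 7)
  tr <- cohort_train_sets(folds)
  expect_length(tr, 5)
  expect_true(all(lengths(tr) == 16L))
  extra <- sprintf("x%02d", 1:67)
  tr2 <- cohort_train_sets(folds, extra)
  expect_true(all(lengths(tr2) == 83L))
  for (k in 1:5) {
    held <- folds$id[folds$fold == k]
    expect_length(held, 4L)
    expect_length(intersect(tr2[[paste0("fold_", k)]], held), 0L)
  }
  expect_error(cohort_train_sets(folds, ids[1]), "disjoint")
})

test_that("metrics reports are tidy and CSV output is byte-deterministic", {
  ph <- generate_phantom(small_phantom_spec(seed = 8))
  triple <- generate_deformation(deformation_spec(seed = 8),
                                 ph$labels$geometry)
  tg <- make_target(ph$labels, ph$image, triple)
  pred <- warp_labels(ph$labels,
                      ffdseg:::triple_whole_field(triple, ph$labels$geometry))
  rep_rows <- metrics_report(pred, tg$ground_truth, participant = "p1")
  expect_s3_class(rep_rows, "ffd_metrics")
  expect_identical(rep_rows$label, tg$ground_truth$table$id)
  expect_true(all(rep_rows$dice >= 0 & rep_rows$dice <= 1))
  expect_true(all(rep_rows$vol_err_cm3 >= 0))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  j1 <- withr::local_tempfile(fileext = ".json")
  write_report(rep_rows, f1, json = j1)
  write_report(rep_rows, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  js <- jsonlite::read_json(j1, simplifyVector = TRUE)
  expect_equal(nrow(js$rows), nrow(rep_rows))
})

test_that("report plots build without error", {
  rows <- tibble::tibble(participant = rep(c("p1", "p2"), each = 2),
                         label = rep(1:2, 2), name = rep(c("a", "b"), 2),
                         dice = c(0.9, 0.8, 0.85, 0.75),
                         vol_pred_cm3 = 1, vol_truth_cm3 = 1,
                         vol_err_cm3 = 0.1)
  class(rows) <- c("ffd_metrics", class(rows))
  expect_s3_class(autoplot(rows), "ggplot")
  expect_s3_class(plot_participant_dice(rows), "ggplot")
  g <- tiny_geom(c(8, 8, 8))
  expect_s3_class(plot_field_slice(deformation_field(g)), "ggplot")
})
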