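#' Dice coefficient for one label
#'
#' `2 |A ∩ B| / (|A| + |B|)` over the binary masks of `label` in
#' the two volumes. When both masks are empty the overlap is perfect by
#' convention and 1 is returned with a warning attribute
#' (`attr(x, "both_empty")`), avoiding NaN propagation in per-element
#' means.
#'
#' @param a,b [label_volume()]s on the identical geometry.
#' @param label Label id.
#' @return Dice in `[0, 1]`.
#' @export
dice <- function(a, b, label) {
  stopifnot(inherits(a, "label_volume"), inherits(b, "label_volume"))
  if (!geom_equal(a$geometry, b$geometry)) {
    stop("volumes must share one geometry", call. = FALSE)
  }
  ma <- a$voxels == label
  mb <- b$voxels == label
  na <- sum(ma); nb <- sum(mb)
  if (na + nb == 0L) {
    return(structure(1, both_empty = TRUE))
  }
  2 * sum(ma & mb) / (na + nb)
}

#' Element volume in cubic centimetres
#'
#' Voxel count of `label` times the voxel volume (mm^3) over 1000.
#' An absent label has volume 0.
#'
#' @param vol A [label_volume()].
#' @param label Label id.
#' @return Volume in cm^3.
#' @export
volume_cm3 <- function(vol, label) {
  stopifnot(inherits(vol, "label_volume"))
  sum(vol$voxels == label) * prod(vol$geometry$spacing) / 1000
}

#' Absolute element volume error
#'
#' `|volume_cm3(a, label) - volume_cm3(b, label)|`, the per-element
#' volume discrepancy between two segmentations of the same grid;
#' symmetric in its arguments.
#'
#' @inheritParams dice
#' @return Non-negative volume error in cm^3.
#' @export
volume_error <- function(a, b, label) {
  if (!geom_equal(a$geometry, b$geometry)) {
    stop("volumes must share one geometry", call. = FALSE)
  }
  abs(volume_cm3(a, label) - volume_cm3(b, label))
}

#' Per-element metrics for one participant
#'
#' Computes Dice, the two element volumes and the absolute volume
#' error for every requested element, returned as one tidy row per
#' element.
#'
#' @param pred,truth [label_volume()]s on the identical geometry.
#' @param elements Integer ids to evaluate; defaults to the truth
#'   volume's table ids.
#' @param participant Participant identifier recorded in the rows.
#' @return A tibble of class `ffd_metrics` with columns `participant`,
#'   `label`, `name`, `dice`, `vol_pred_cm3`, `vol_truth_cm3`,
#'   `vol_err_cm3`.
#' @export
metrics_report <- function(pred, truth, elements = NULL,
                           participant = "p1") {
  stopifnot(inherits(pred, "label_volume"), inherits(truth, "label_volume"))
  if (!geom_equal(pred$geometry, truth$geometry)) {
    stop("volumes must share one geometry", call. = FALSE)
  }
  if (is.null(elements)) elements <- truth$table$id
  names_lut <- stats::setNames(truth$table$name, truth$table$id)
  rows <- lapply(elements, function(lab) {
    va <- volume_cm3(pred, lab)
    vb <- volume_cm3(truth, lab)
    tibble::tibble(participant = as.character(participant),
                   label = as.integer(lab),
                   name = unname(names_lut[as.character(lab)]) %||%
                     sprintf("label_%d", lab),
                   dice = as.numeric(dice(pred, truth, lab)),
                   vol_pred_cm3 = va, vol_truth_cm3 = vb,
                   vol_err_cm3 = abs(va - vb))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ffd_metrics", class(out))
  out
}

#' Per-participant means over elements
#'
#' Unweighted mean Dice and volume error over a fixed element list,
#' one row per participant; errors if any participant is missing any
#' element row.
#'
#' @param report An `ffd_metrics` tibble ([metrics_report()] rows,
#'   possibly several participants bound together).
#' @param elements Integer element ids to average over; defaults to all
#'   labels present in the report.
#' @return A tibble with columns `participant`, `n_elements`,
#'   `mean_dice`, `mean_vol_err_cm3`.
#' @export
participant_summary <- function(report, elements = NULL) {
  stopifnot(is.data.frame(report))
  if (is.null(elements)) elements <- sort(unique(report$label))
  sub <- dplyr::filter(report, .data$label %in% elements)
  counts <- dplyr::count(sub, .data$participant)
  if (any(counts$n != length(elements))) {
    bad <- counts$participant[counts$n != length(elements)]
    stop("participant(s) missing element rows: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  dplyr::summarise(dplyr::group_by(sub, .data$participant),
                   n_elements = dplyr::n(),
                   mean_dice = mean(.data$dice),
                   mean_vol_err_cm3 = mean(.data$vol_err_cm3),
                   .groups = "drop")
}

#' Grand mean and sd over participants
#'
#' One-row summary (grand mean and sd of the per-participant means),
#' the aggregate reported alongside benchmark box plots.
#'
#' @inheritParams participant_summary
#' @return A one-row tibble with `n_participants`, `mean_dice`,
#'   `sd_dice`, `mean_vol_err_cm3`, `sd_vol_err_cm3`.
#' @export
summarize_report <- function(report, elements = NULL) {
  ps <- participant_summary(report, elements)
  tibble::tibble(n_participants = nrow(ps),
                 mean_dice = mean(ps$mean_dice),
                 sd_dice = stats::sd(ps$mean_dice),
                 mean_vol_err_cm3 = mean(ps$mean_vol_err_cm3),
                 sd_vol_err_cm3 = stats::sd(ps$mean_vol_err_cm3))
}

#' Wilcoxon signed-rank test (paired, two-sided)
#'
#' Paired nonparametric comparison as used for benchmark contrasts.
#' Zero differences are dropped; tied absolute differences receive
#' midranks. The Z statistic always comes from the normal
#' approximation with tie-corrected variance and a 0.5 continuity
#' correction. The p-value is computed by exact enumeration of all
#' `2^n` sign assignments when `n <= 12` (doubling convention, capped
#' at 1), otherwise from the normal approximation; `exact` overrides
#' the automatic choice.
#'
#' @param x,y Equal-length paired numeric vectors.
#' @param exact `NA` (auto: exact when `n <= 12`), `TRUE` or `FALSE`.
#' @return A one-row tibble with `n` (pairs after dropping zero
#'   differences), `statistic` (W+, the positive-rank sum), `z`,
#'   `p_value` and `method` (`"exact"` or `"normal"`).
#' @examples
#' wilcoxon_signed_rank(c(2, 3, 4, 5, 6, 7), c(1, 1, 1, 1, 1, 1))
#' @export
wilcoxon_signed_rank <- function(x, y, exact = NA) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length (paired data)", call. = FALSE)
  }
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    stop("all paired differences are zero; the signed-rank test is undefined",
         call. = FALSE)
  }
  if (n < 5L) {
    warning("fewer than 5 nonzero differences; the test has very little power")
  }
  r <- rank(abs(d))                      # midranks for ties
  w_pos <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  cc <- 0.5 * sign(w_pos - mu)
  z <- if (sigma2 > 0) (w_pos - mu - cc) / sqrt(sigma2) else 0
  use_exact <- if (is.na(exact)) n <= 12L else isTRUE(exact)
  if (use_exact) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- as.vector(signs %*% r)
    p <- min(1, 2 * min(mean(w_all <= w_pos), mean(w_all >= w_pos)))
    method <- "exact"
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  tibble::tibble(n = n, statistic = w_pos, z = z, p_value = p,
                 method = method)
}

#' Bonferroni correction
#'
#' Multiplies each raw p-value by the number of comparisons `m`,
#' capping at 1.
#'
#' @param p Numeric raw p-values in `[0, 1]`.
#' @param m Number of comparisons (>= `length(p)`).
#' @return Corrected p-values.
#' @examples
#' bonferroni(c(0.011, 0.4), m = 3)
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (m < length(p)) {
    stop("`m` must be at least the number of p-values", call. = FALSE)
  }
  pmin(1, p * m)
}

#' Seeded k-fold participant grouping
#'
#' Shuffles the ids with the given seed and deals them round-robin
#' into `k` folds, so fold sizes differ by at most one (20 ids into 5
#' folds gives five held-out groups of 4).
#'
#' @param ids Character or integer participant ids.
#' @param k Number of folds (<= number of ids).
#' @param seed Integer seed; the same seed always yields the same
#'   assignment.
#' @return A tibble with columns `id` and `fold` (1..k).
#' @export
kfold_split <- function(ids, k, seed = 1L) {
  if (k > length(ids)) stop("`k` cannot exceed the number of ids", call. = FALSE)
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  perm <- sample(ids)
  fold <- integer(length(ids))
  fold[match(perm, ids)] <- rep_len(seq_len(k), length(ids))
  tibble::tibble(id = ids, fold = fold)
}

#' Per-fold training sets
#'
#' For each fold, the training set is every evaluation id outside the
#' held-out fold plus all the extra ids (which never enter any held-out
#' fold). With 20 evaluation ids, 5 folds and no extras the training
#' sets have 16 ids; adding 67 extras gives 83.
#'
#' @param folds A [kfold_split()] tibble over the evaluation ids.
#' @param extra_ids Ids added to every training set; must be disjoint
#'   from the evaluation ids.
#' @return A list of per-fold character/integer id vectors, named
#'   `fold_1` .. `fold_k`.
#' @export
cohort_train_sets <- function(folds, extra_ids = NULL) {
  stopifnot(is.data.frame(folds), all(c("id", "fold") %in% names(folds)))
  if (length(intersect(extra_ids, folds$id))) {
    stop("`extra_ids` must be disjoint from the evaluation ids", call. = FALSE)
  }
  ks <- sort(unique(folds$fold))
  out <- lapply(ks, function(f) {
    c(folds$id[folds$fold != f], extra_ids)
  })
  names(out) <- paste0("fold_", ks)
  out
}

#' Write a metrics report to CSV (and optionally JSON)
#'
#' Deterministic, byte-stable output: per-element rows followed by an
#' aggregate block (per-participant means and the grand mean/sd).
#'
#' @param report An `ffd_metrics` tibble.
#' @param csv Path for the CSV report.
#' @param json Optional path for a JSON mirror.
#' @param elements Element ids for the aggregate block.
#' @return `csv`, invisibly.
#' @export
write_report <- function(report, csv, json = NULL, elements = NULL) {
  rows <- as.data.frame(report)
  rows$dice <- sprintf("%.6f", rows$dice)
  rows$vol_pred_cm3 <- sprintf("%.6f", rows$vol_pred_cm3)
  rows$vol_truth_cm3 <- sprintf("%.6f", rows$vol_truth_cm3)
  rows$vol_err_cm3 <- sprintf("%.6f", rows$vol_err_cm3)
  con <- file(csv, "wb")  # binary mode: byte-identical across platforms
  on.exit(close(con))
  writeLines(paste(names(rows), collapse = ","), con)
  writeLines(do.call(paste, c(unname(rows), sep = ",")), con)
  ps <- participant_summary(report, elements)
  agg <- summarize_report(report, elements)
  writeLines("", con)
  writeLines("# per-participant means", con)
  writeLines(paste(names(ps), collapse = ","), con)
  writeLines(sprintf("%s,%d,%.6f,%.6f", ps$participant, ps$n_elements,
                     ps$mean_dice, ps$mean_vol_err_cm3), con)
  writeLines("# grand aggregate", con)
  writeLines(paste(names(agg), collapse = ","), con)
  writeLines(sprintf("%d,%.6f,%.6f,%.6f,%.6f", agg$n_participants,
                     agg$mean_dice, agg$sd_dice, agg$mean_vol_err_cm3,
                     agg$sd_vol_err_cm3), con)
  if (!is.null(json)) {
    jsonlite::write_json(list(rows = report, participants = ps,
                              aggregate = agg),
                         json, dataframe = "rows", digits = NA)
  }
  invisible(csv)
}
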