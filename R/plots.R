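#' Plot per-element Dice from a metrics report
#'
#' Bar chart of Dice per element (averaged over participants when the
#' report covers several), the standard at-a-glance view of multi-label
#' segmentation agreement.
#'
#' @param object An `ffd_metrics` tibble ([metrics_report()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ffd_metrics <- function(object, ...) {
  by_label <- dplyr::summarise(
    dplyr::group_by(object, .data$label, .data$name),
    dice = mean(.data$dice), .groups = "drop")
  ggplot2::ggplot(by_label,
                  ggplot2::aes(x = stats::reorder(.data$name, .data$label),
                               y = .data$dice)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Dice coefficient") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Box plot of per-participant mean Dice
#'
#' @param report An `ffd_metrics` tibble with one or more participants.
#' @param elements Element ids averaged per participant.
#' @return A ggplot object.
#' @export
plot_participant_dice <- function(report, elements = NULL) {
  ps <- participant_summary(report, elements)
  ggplot2::ggplot(ps, ggplot2::aes(x = "", y = .data$mean_dice)) +
    ggplot2::geom_boxplot(width = 0.3, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "mean Dice over elements") +
    ggplot2::theme_minimal()
}

#' Quiver-style slice view of a deformation field
#'
#' Shows the in-plane displacement components on one axial slice as
#' arrows, subsampled for legibility; useful when eyeballing a
#' generated or composed field.
#'
#' @param field A [deformation_field()].
#' @param k Axial slice index (1-based; default mid-volume).
#' @param stride Arrow subsampling stride in voxels.
#' @return A ggplot object.
#' @export
plot_field_slice <- function(field, k = NULL,
                             stride = max(field$geometry$dims[1] %/% 24, 1)) {
  g <- field$geometry
  if (is.null(k)) k <- (g$dims[3] + 1) %/% 2
  ii <- seq(1, g$dims[1], by = stride)
  jj <- seq(1, g$dims[2], by = stride)
  df <- expand.grid(i = ii, j = jj)
  df$x <- axis_coords(g, 1)[df$i]
  df$y <- axis_coords(g, 2)[df$j]
  df$dx <- field$disp[cbind(df$i, df$j, k, 1L)]
  df$dy <- field$disp[cbind(df$i, df$j, k, 2L)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$x + .data$dx,
                                       yend = .data$y + .data$dy),
                          arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm")),
                          linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("axial slice k = %d", k)) +
    ggplot2::theme_minimal()
}
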