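# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a scalp topography frame
#'
#' Filled interpolated map over the head disc with electrode positions
#' overlaid, nose up.
#'
#' @param object A `topography_frame` from [interpolate_scalp()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot topography_frame
#' @export
autoplot.topography_frame <- function(object, ...) {
  df <- expand.grid(x = object$gx, y = object$gy)
  df$value <- as.vector(object$grid)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value), na.rm = TRUE) +
    ggplot2::annotate("path",
                      x = cos(seq(0, 2 * pi, length.out = 200)),
                      y = sin(seq(0, 2 * pi, length.out = 200))) +
    ggplot2::geom_point(data = object$layout,
                        ggplot2::aes(x = .data$x, y = .data$y),
                        shape = 21, fill = "white", size = 2) +
    ggplot2::scale_fill_viridis_c(limits = object$scale,
                                  oob = scales_squish, na.value = NA,
                                  name = "power") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = if (is.na(object$t_rel)) NULL else
      sprintf("t = %+d s from onset", object$t_rel)) +
    ggplot2::theme_void()
}

# clamp out-of-bounds values into the colour scale (avoids a scales dep)
scales_squish <- function(x, range = c(0, 1)) {
  pmin(pmax(x, range[1]), range[2])
}

#' Time-course plots of mean power or mean PLV
#'
#' Line plot of a per-epoch summary (`mean_power`, `plv_mean` or
#' `extent`) against time relative to seizure onset, coloured by state.
#'
#' @param tc Output of [mean_psd_timecourse()], [mean_plv_timecourse()]
#'   or the diffusion table of [run_analysis()].
#' @param value Column to plot; auto-detected by default.
#' @return A ggplot object.
#' @export
plot_timecourse <- function(tc, value = NULL) {
  value <- value %||%
    intersect(c("mean_power", "plv_mean", "extent"), names(tc))[1]
  ggplot2::ggplot(tc, ggplot2::aes(x = .data$t_rel,
                                   y = .data[[value]])) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$state)) +
    ggplot2::labs(x = "time from seizure onset (s)", y = value,
                  colour = "state") +
    ggplot2::theme_minimal()
}

#' Boxplots of a feature across states, per rhythm
#'
#' The three-state comparison view: one panel per band, boxes for
#' inter-ictal, pre-ictal and ictal observations.
#'
#' @param features [band_power_table()] or [plv_table()] output.
#' @param value_col `"power"` or `"plv"`; auto-detected.
#' @return A ggplot object.
#' @export
plot_state_comparison <- function(features, value_col = NULL) {
  value_col <- value_col %||%
    intersect(c("power", "plv"), names(features))[1]
  features$state <- factor(features$state,
                           levels = c("inter_ictal", "pre_ictal", "ictal"))
  features <- features[!is.na(features$state), , drop = FALSE]
  ggplot2::ggplot(features,
                  ggplot2::aes(x = .data$state, y = .data[[value_col]],
                               fill = .data$state)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, show.legend = FALSE) +
    ggplot2::facet_wrap(~band, scales = "free_y") +
    ggplot2::labs(x = NULL, y = value_col) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x =
                     ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot a binary synchronization network over the montage
#'
#' Draws the thresholded PLV network's edges between electrode positions
#' on the head disc.
#'
#' @param object A `binary_network` from [binarize()].
#' @param layout Electrode layout, default [montage_layout()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot binary_network
#' @export
autoplot.binary_network <- function(object, layout = montage_layout(),
                                    ...) {
  adj <- unclass(object)
  idx <- which(adj == 1 & upper.tri(adj), arr.ind = TRUE)
  edges <- tibble::tibble(
    x = layout$x[idx[, 1]], y = layout$y[idx[, 1]],
    xend = layout$x[idx[, 2]], yend = layout$y[idx[, 2]]
  )
  ggplot2::ggplot() +
    ggplot2::annotate("path",
                      x = cos(seq(0, 2 * pi, length.out = 200)),
                      y = sin(seq(0, 2 * pi, length.out = 200)),
                      colour = "grey40") +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend,
                                       yend = .data$yend),
                          colour = "steelblue", alpha = 0.7) +
    ggplot2::geom_point(data = layout,
                        ggplot2::aes(x = .data$x, y = .data$y), size = 2) +
    ggplot2::geom_text(data = layout,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$channel),
                       vjust = -1, size = 2.5) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%d edges (PLV > %g)",
                                  sum(adj) / 2, attr(object, "tau"))) +
    ggplot2::theme_void()
}
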