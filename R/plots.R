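#' Plot per-class detection metrics
#'
#' Bar chart of per-class AP and AR from a `metric_report`, with the
#' macro means as dashed lines.
#'
#' @param object A `metric_report` from [evaluate_detections()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot metric_report
#' @export
autoplot.metric_report <- function(object, ...) {
  d <- tidyr::pivot_longer(object$per_class, c("ap", "ar"),
                           names_to = "metric", values_to = "value")
  d$metric <- toupper(d$metric)
  ref <- tibble::tibble(metric = c("AP", "AR"),
                        value = c(object$mAP, object$mAR))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$label, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(data = ref,
                        ggplot2::aes(yintercept = .data$value),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Detection metrics (AP@%.2f)",
                                  object$iou_threshold)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heat map of the displacement kernel density
#'
#' @param object A `displacement_stats` object.
#' @param ... Unused.
#' @return A ggplot object (density heat map with the mode marked).
#' @method autoplot displacement_stats
#' @export
autoplot.displacement_stats <- function(object, ...) {
  if (is.null(object$kde)) stop("KDE was not computed (fewer than 2 pairs)")
  d <- tidyr::expand_grid(dh = object$kde$x, dv = object$kde$y)
  d$z <- as.vector(t(object$kde$z))  # kde z[i, j] pairs x[i] with y[j]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$dh, y = .data$dv,
                                  fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::annotate("point", x = object$mode[1], y = object$mode[2],
                      colour = "red", shape = 4, size = 3) +
    ggplot2::scale_fill_viridis_c(name = "density") +
    ggplot2::labs(x = "horizontal displacement Dh (fraction of width)",
                  y = "vertical displacement Dv (fraction of height)") +
    ggplot2::theme_minimal()
}

#' Heat map of an AGC shift-magnitude sweep
#'
#' @param sweep Result of [sweep_agc()].
#' @param metric Which column to display.
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep, metric = "target_mAP") {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$kh_mag, y = .data$kv_mag,
                                      fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data[[metric]])), colour = "white") +
    ggplot2::scale_fill_viridis_c(name = metric) +
    ggplot2::labs(x = "|Kh| (cells)", y = "|Kv| (cells)") +
    ggplot2::theme_minimal()
}

#' Sketch a synthetic scene
#'
#' Draws ground-truth boxes, candidate-region bounding boxes and
#' (optionally) detections of one frame in frame coordinates, y axis
#' pointing down as on screen.
#'
#' @param scene A `camcrm_scene`.
#' @param detections Optional detection tibble for the same frame.
#' @return A ggplot object.
#' @export
plot_scene <- function(scene, detections = NULL) {
  rect <- function(d, col, lt) {
    ggplot2::geom_rect(data = d,
                       ggplot2::aes(xmin = .data$x0, xmax = .data$x1,
                                    ymin = .data$y0, ymax = .data$y1),
                       colour = col, fill = NA, linetype = lt)
  }
  p <- ggplot2::ggplot()
  if (!is.null(scene$gt)) p <- p + rect(scene$gt, "black", "solid")
  if (nrow(scene$regions)) {
    p <- p + rect(scene$regions, "steelblue", "dotted")
  }
  if (!is.null(detections) && nrow(detections)) {
    p <- p + rect(detections, "red", "dashed")
  }
  p +
    ggplot2::scale_y_reverse(limits = c(scene$frame_size[1], 0)) +
    ggplot2::scale_x_continuous(limits = c(0, scene$frame_size[2])) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = scene$frame_id,
                  subtitle = "black: GT, dotted blue: regions, dashed red: detections") +
    ggplot2::theme_minimal()
}
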