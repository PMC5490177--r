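#' Overlay plot of a wing with key points and arcs
#'
#' @param image intensity matrix.
#' @param keypoints optional key point tibble to overlay.
#' @param polylines optional named list of arc polylines.
#' @return a ggplot object.
#' @export
plot_wing <- function(image, keypoints = NULL, polylines = NULL) {
  h <- nrow(image); w <- ncol(image)
  p <- ggplot2::ggplot() +
    ggplot2::annotation_raster(
      grDevices::as.raster(image / 255),
      xmin = -0.5, xmax = w - 0.5, ymin = -(h - 0.5), ymax = 0.5
    ) +
    ggplot2::coord_fixed(xlim = c(-0.5, w - 0.5),
                         ylim = c(-(h - 0.5), 0.5), expand = FALSE) +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::scale_y_continuous(labels = function(v) -v)
  if (!is.null(polylines)) {
    df <- purrr::imap_dfr(polylines, function(m, nm) {
      tibble::tibble(arc = nm, x = m[, 1], y = -m[, 2])
    })
    p <- p + ggplot2::geom_path(
      data = df, ggplot2::aes(x = .data$x, y = .data$y,
                              colour = .data$arc), linewidth = 0.6)
  }
  if (!is.null(keypoints)) {
    kd <- dplyr::mutate(keypoints, y = -.data$y)
    p <- p +
      ggplot2::geom_point(data = kd,
                          ggplot2::aes(x = .data$x, y = .data$y),
                          colour = "red", size = 1.2) +
      ggplot2::geom_text(data = kd,
                         ggplot2::aes(x = .data$x, y = .data$y,
                                      label = .data$label),
                         colour = "red", vjust = -0.8, size = 3)
  }
  p
}

#' @rdname plot_wing
#' @param object an [annotated_wing()] with its image loaded.
#' @param ... unused.
#' @method autoplot annotated_wing
#' @export
autoplot.annotated_wing <- function(object, ...) {
  if (is.null(object$image)) abort("wing image not loaded")
  plot_wing(object$image, object$keypoints)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Accuracy report bar chart
#'
#' @param report output of [accuracy_report()].
#' @return a ggplot object.
#' @export
plot_accuracy_report <- function(report) {
  ggplot2::ggplot(report,
                  ggplot2::aes(x = .data$label, y = .data$pct_within_2sd)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 100, linetype = 2) +
    ggplot2::labs(x = "key point", y = "% within 2 sd") +
    ggplot2::ylim(0, 105)
}
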