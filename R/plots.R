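#' Plot detections over an image
#'
#' @param object A detections tibble from [detect_objects()].
#' @param image Optional background image matrix.
#' @param ... Unused.
#' @return A ggplot object. The first image axis (`x`) is drawn vertically,
#'   matching matrix orientation.
#' @export
autoplot.lodestar_detections <- function(object, image = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(image)) {
    df <- tibble::tibble(
      row = rep(0:(nrow(image) - 1), times = ncol(image)),
      col = rep(0:(ncol(image) - 1), each = nrow(image)),
      value = as.vector(image))
    p <- p + ggplot2::geom_raster(data = df,
      ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
      ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none")
  }
  p + ggplot2::geom_point(data = object,
        ggplot2::aes(x = .data$y, y = .data$x),
        colour = "orange", shape = 1, size = 3, stroke = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "y (px)", y = "x (px)")
}

#' Mark a detections tibble for autoplotting
#' @param detections Tibble from [detect_objects()].
#' @return The tibble with class `lodestar_detections`.
#' @export
as_detections <- function(detections) {
  class(detections) <- c("lodestar_detections", class(detections))
  detections
}

#' Plot a training loss history
#'
#' @param fit A `lodestar_fit`.
#' @param ... Unused.
#' @return A ggplot of the two loss components against training step.
#' @export
autoplot.lodestar_fit <- function(fit, ...) {
  h <- tidyr_longer(fit$history)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$step, y = .data$value,
                                  colour = .data$component)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "mini-batch", y = "loss (log scale)", colour = NULL)
}

# minimal long-format reshape (avoids a tidyr dependency for one call)
tidyr_longer <- function(h) {
  dplyr::bind_rows(
    tibble::tibble(step = h$step, component = "consistency", value = h$loss_a),
    tibble::tibble(step = h$step, component = "internal", value = h$loss_b))
}
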