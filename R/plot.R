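# ggplot2 display helpers for scenes and pipeline results.

image_annotation <- function(img) {
  H <- dim(img)[1]; W <- dim(img)[2]
  ras <- grDevices::as.raster(img / 255)
  list(
    ggplot2::annotation_raster(ras, xmin = -0.5, xmax = W - 0.5,
                               ymin = -(H - 0.5), ymax = 0.5),
    ggplot2::scale_y_continuous(labels = function(b) -b),
    ggplot2::coord_fixed(xlim = c(-0.5, W - 0.5), ylim = c(-(H - 0.5), 0.5),
                         expand = FALSE),
    ggplot2::labs(x = "x (px)", y = "y (px)")
  )
}

circle_path <- function(circles, n = 72) {
  if (nrow(circles) == 0) {
    return(tibble(px = double(), py = double(), circle = integer()))
  }
  th <- seq(0, 2 * pi, length.out = n)
  dplyr::bind_rows(lapply(seq_len(nrow(circles)), function(i) {
    tibble(px = circles$x[i] + circles$r[i] * cos(th),
           py = circles$y[i] + circles$r[i] * sin(th), circle = i)
  }))
}

#' Plot detected circles over an image
#'
#' @param image H x W x 3 array (0-255).
#' @param circles Detections tibble (`x`, `y`, `r`).
#' @return A ggplot object.
#' @export
plot_detections <- function(image, circles) {
  cp <- circle_path(circles)
  ggplot2::ggplot() +
    image_annotation(image) +
    ggplot2::geom_path(
      data = cp,
      ggplot2::aes(x = .data$px, y = -.data$py, group = .data$circle),
      colour = "yellow", linewidth = 0.6
    ) +
    ggplot2::theme_minimal()
}

#' Plot a pipeline result
#'
#' Draws the left image with the fused circle detections, the merged
#' cluster labels coloured by category, and the cluster centres.
#'
#' @param object A `litchi_result`.
#' @param image The left image the result was computed from.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.litchi_result <- function(object, image, ...) {
  cl <- object$clusters
  cp <- circle_path(object$detections$fused)
  ggplot2::ggplot() +
    image_annotation(image) +
    ggplot2::geom_path(
      data = cp,
      ggplot2::aes(x = .data$px, y = -.data$py, group = .data$circle),
      colour = "white", linewidth = 0.4, alpha = 0.8
    ) +
    ggplot2::geom_rect(
      data = cl,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -.data$ymax, ymax = -.data$ymin,
                   colour = .data$category),
      fill = NA, linewidth = 0.8
    ) +
    ggplot2::geom_point(
      data = cl,
      ggplot2::aes(x = .data$u, y = -.data$v, colour = .data$category),
      shape = 3, size = 2
    ) +
    ggplot2::scale_colour_manual(
      values = c(A = "#00d0ff", B = "#ffe000", C = "#ff4dd2"),
      drop = FALSE
    ) +
    ggplot2::theme_minimal()
}

#' Plot a synthetic scene with its ground truth
#'
#' @param object A `litchi_scene`.
#' @param side `"left"` or `"right"`.
#' @param ... Unused.
#' @return A ggplot object showing the image with true fruit circles and
#'   cluster boxes.
#' @export
autoplot.litchi_scene <- function(object, side = c("left", "right"), ...) {
  side <- match.arg(side)
  img <- object[[side]]
  fr <- object$truth$fruits
  if (side == "right") fr <- dplyr::mutate(fr, x = .data$x_right)
  cp <- circle_path(fr)
  ggplot2::ggplot() +
    image_annotation(img) +
    ggplot2::geom_path(
      data = cp,
      ggplot2::aes(x = .data$px, y = -.data$py, group = .data$circle),
      colour = "white", linetype = "22", linewidth = 0.4
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
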