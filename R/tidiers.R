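#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trained segmentation network
#'
#' @param x a `mito_segnet`.
#' @param ... unused.
#' @return tibble with one row per epoch: `epoch`, `loss` (mean per-pixel
#'   cross entropy) and `lr`.
#' @export
tidy.mito_segnet <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble::tibble(epoch = integer(0), loss = numeric(0),
                          lr = numeric(0)))
  }
  x$history
}

#' One-row summary of a trained segmentation network
#'
#' @param x a `mito_segnet`.
#' @param ... unused.
#' @return tibble: `levels`, `channels`, `classes`, `wavelet`, `n_params`,
#'   `epochs`, `final_loss`.
#' @export
glance.mito_segnet <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    levels = x$config$levels,
    channels = paste(x$config$channels, collapse = "/"),
    classes = x$config$classes,
    wavelet = x$config$wavelet_name,
    n_params = segnet_n_params(x),
    epochs = if (is.null(h)) 0L else nrow(h),
    final_loss = if (is.null(h)) NA_real_ else h$loss[nrow(h)])
}

#' Tidy a trained detector
#'
#' @param x a `mito_detector`.
#' @param ... unused.
#' @return tibble with one row per minibatch step: `step`, `loss`, `lr`.
#' @export
tidy.mito_detector <- function(x, ...) x$history

#' One-row summary of a trained detector
#'
#' @param x a `mito_detector`.
#' @param ... unused.
#' @return tibble: `classifier`, `channels`, `warp_size`, `steps`,
#'   `final_loss`.
#' @export
glance.mito_detector <- function(x, ...) {
  tibble::tibble(
    classifier = x$cfg$classifier,
    channels = paste(x$cfg$channels, collapse = "/"),
    warp_size = x$cfg$warp_size,
    steps = nrow(x$history),
    final_loss = x$history$loss[nrow(x$history)])
}

#' Plot the training loss curve of a fitted network
#'
#' @param object a `mito_segnet` or `mito_detector`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mito_segnet <- function(object, ...) {
  h <- tidy(object)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean pixelwise cross entropy",
                  title = "Segmentation training loss") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.mito_segnet
#' @export
autoplot.mito_detector <- function(object, ...) {
  h <- tidy(object)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$step, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "minibatch step", y = "classification loss",
                  title = "Detector training loss") +
    ggplot2::theme_minimal()
}

#' Plot a synthetic tile with its annotations
#'
#' Renders the RGB tile with ground-truth boxes and weak-label centre
#' points; optionally overlays detections.
#'
#' @param object a `synth_tile`.
#' @param detections optional tibble of detections to overlay.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.synth_tile <- function(object, detections = NULL, ...) {
  img <- object$image
  H <- dim(img)[1]; W <- dim(img)[2]
  df <- expand.grid(y = seq_len(H) - 1, x = seq_len(W) - 1)
  df$fill <- grDevices::rgb(img[, , 1], img[, , 2], img[, , 3])
  p <- ggplot2::ggplot() +
    ggplot2::geom_raster(data = df,
                         ggplot2::aes(x = .data$x, y = .data$y,
                                      fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (nrow(object$boxes)) {
    p <- p + ggplot2::geom_rect(
      data = object$boxes,
      ggplot2::aes(xmin = .data$x0 - 0.5, xmax = .data$x1 - 0.5,
                   ymin = .data$y0 - 0.5, ymax = .data$y1 - 0.5),
      fill = NA, colour = "yellow", linewidth = 0.4)
  }
  if (nrow(object$weak_labels)) {
    p <- p + ggplot2::geom_point(
      data = object$weak_labels,
      ggplot2::aes(x = .data$x, y = .data$y),
      colour = "cyan", size = 0.8)
  }
  if (!is.null(detections) && nrow(detections)) {
    p <- p + ggplot2::geom_rect(
      data = detections,
      ggplot2::aes(xmin = .data$x0 - 0.5, xmax = .data$x1 - 0.5,
                   ymin = .data$y0 - 0.5, ymax = .data$y1 - 0.5),
      fill = NA, colour = "red", linewidth = 0.4)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
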