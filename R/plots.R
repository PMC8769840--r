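#' Plot an RGB image or mask overlay
#'
#' Renders the image with ggplot2; if a mask is supplied its boundary pixels
#' are drawn on top, which is the quickest visual check of a segmentation.
#'
#' @param img `H x W x 3` RGB array (0--255).
#' @param mask Optional logical mask of matching shape.
#' @param boundary_color Color of the overlaid mask boundary.
#' @return A ggplot object.
#' @export
plot_smear <- function(img, mask = NULL, boundary_color = "yellow") {
  img <- validate_rgb(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  df <- tibble::tibble(
    x = rep(seq_len(w), each = h),
    y = rep(seq_len(h), w),
    fill = grDevices::rgb(as.vector(img[, , 1]) / 255,
                          as.vector(img[, , 2]) / 255,
                          as.vector(img[, , 3]) / 255)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::theme_void()
  if (!is.null(mask)) {
    b <- extract_boundary(mask)
    if (nrow(b) > 0L) {
      bdf <- tibble::tibble(x = b[, "col"] + 1L, y = b[, "row"] + 1L)
      p <- p + ggplot2::geom_point(data = bdf, color = boundary_color,
                                   size = 0.2)
    }
  }
  p
}

#' Plot SIFT keypoints over an image
#'
#' Keypoint circles scale with `sigma`; the radial segment shows the
#' assigned orientation.
#'
#' @param img Grayscale matrix in `[0, 1]` or RGB array (0--255).
#' @param keypoints Tibble from [sift_extract()].
#' @return A ggplot object.
#' @export
plot_keypoints <- function(img, keypoints) {
  gray <- as_gray(img)
  h <- nrow(gray); w <- ncol(gray)
  df <- tibble::tibble(x = rep(seq_len(w), each = h),
                       y = rep(seq_len(h), w),
                       v = as.vector(gray))
  kp <- dplyr::mutate(keypoints,
                      xe = .data$x + 1 + 2 * .data$sigma * cos(.data$orientation),
                      ye = .data$y + 1 + 2 * .data$sigma * sin(.data$orientation))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$v)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::geom_point(data = kp,
                        ggplot2::aes(x = .data$x + 1, y = .data$y + 1,
                                     size = .data$sigma),
                        shape = 1, color = "red") +
    ggplot2::geom_segment(data = kp,
                          ggplot2::aes(x = .data$x + 1, y = .data$y + 1,
                                       xend = .data$xe, yend = .data$ye),
                          color = "red", linewidth = 0.3) +
    ggplot2::scale_size_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::theme_void()
}

#' @export
autoplot.wbc_cnn_fit <- function(object, ...) {
  ggplot2::ggplot(object$loss, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean crossentropy",
                  title = "CNN training loss") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.wbc_cv <- function(object, ...) {
  df <- tibble::as_tibble(object$confusion)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), color = "white") +
    ggplot2::scale_fill_viridis_c(guide = "none") +
    ggplot2::labs(title = sprintf("Confusion matrix (accuracy %.3f)",
                                  object$accuracy)) +
    ggplot2::theme_minimal()
}

#' Plot a batch segmentation metric report
#'
#' One panel per metric, one point per image; the long tail of any metric is
#' immediately visible.
#'
#' @param report Tibble from [evaluate_mask_set()] or
#'   `run_pipeline()$metrics` (columns `ts`, `rde`, `or`, `ur`, `er`).
#' @return A ggplot object.
#' @export
plot_metric_report <- function(report) {
  long <- tidyr::pivot_longer(report, dplyr::any_of(c("ts", "rde", "or",
                                                      "ur", "er")),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Segmentation metrics per image") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
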