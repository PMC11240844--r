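#' Plot a segmentation result
#'
#' Raster plot of the crisp label map, one fill level per cluster.
#'
#' @param object A `segmentation_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.segmentation_result <- function(object, ...) {
  df <- label_map_df(object$labels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = factor(.data$label))) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_d(name = "cluster") +
    ggplot2::labs(title = paste0(object$algorithm, " segmentation"),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-segment evaluation metrics
#'
#' Bar chart of Dice similarity, false positive ratio and true positive
#' ratio per matched segment.
#'
#' @param object An `evaluation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evaluation_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$per_segment[, c("segment", "similarity", "fpr", "tpr")],
    cols = c("similarity", "fpr", "tpr"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$segment),
                                     y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "segment", y = NULL,
                  subtitle = sprintf("overall accuracy %.4f",
                                     object$overall_accuracy)) +
    ggplot2::theme_minimal()
}

#' Plot a phantom benchmark
#'
#' Overall segmentation accuracy per algorithm across seeds (points) with
#' the per-algorithm mean (crossbar).
#'
#' @param object A `phantom_benchmark`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phantom_benchmark <- function(object, ...) {
  ord <- c("fcm", "ifcm", "csfcm", "csifcm")
  df <- object$overall
  df$algorithm <- factor(df$algorithm,
                         levels = intersect(ord, unique(df$algorithm)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$algorithm,
                                   y = .data$overall_accuracy)) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "red3") +
    ggplot2::labs(x = NULL, y = "overall segmentation accuracy") +
    ggplot2::theme_minimal()
}

#' Plot an image or label matrix
#'
#' Convenience raster plot for normalized intensity images and label maps.
#'
#' @param image Numeric matrix (intensities) or integer matrix (labels).
#' @param labels Logical; treat values as discrete labels.
#' @return A ggplot object.
#' @export
plot_image <- function(image, labels = FALSE) {
  df <- label_map_df(image)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  if (labels)
    p + ggplot2::geom_raster(ggplot2::aes(fill = factor(.data$label))) +
      ggplot2::scale_fill_viridis_d(name = "label")
  else
    p + ggplot2::geom_raster(ggplot2::aes(fill = .data$label)) +
      ggplot2::scale_fill_gradient(low = "black", high = "white",
                                   name = "intensity")
}

label_map_df <- function(m) {
  tibble::tibble(row = rep(seq_len(nrow(m)), times = ncol(m)),
                 col = rep(seq_len(ncol(m)), each = nrow(m)),
                 label = as.vector(m))
}
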