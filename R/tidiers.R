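#' @method tidy segmentation_result
#' @export
tidy.segmentation_result <- function(x, ...) {
  tibble(method = x$method, foreground_px = sum(x$mask),
         degenerate = x$degenerate,
         threshold = x$threshold %||% NA_integer_)
}

#' @method tidy roi_partition
#' @export
tidy.roi_partition <- function(x, ...) {
  tibble(layer = x$layer,
         region = c("center", "pizhang"),
         pixels = c(sum(x$center_mask), sum(x$pizhang_mask)))
}

#' @method glance two_layer_classifier
#' @export
glance.two_layer_classifier <- function(x, ...) {
  tibble(seg_method = x$seg_method,
         layer1 = x$layer1$spec$algorithm,
         selector = x$selector$method,
         n_selected = length(x$selector$selected),
         layer2 = x$layer2$spec$algorithm)
}

#' Plot a selection result's importance scores
#'
#' @param object a `selection_result`.
#' @param ... unused.
#' @return A ggplot bar chart of per-feature scores, selected features
#'   highlighted.
#' @method autoplot selection_result
#' @export
autoplot.selection_result <- function(object, ...) {
  df <- dplyr::mutate(object$scores,
                      feature = factor(.data$feature, levels = .data$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature, y = .data$score,
                                   fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(title = paste(object$method, "feature importance"),
                  x = NULL, y = "score") +
    ggplot2::theme_minimal()
}

#' Plot a synthetic Daqu image
#'
#' @param object a `daqu_image`.
#' @param ... unused.
#' @return A ggplot raster of the RGB image.
#' @method autoplot daqu_image
#' @export
autoplot.daqu_image <- function(object, ...) {
  px <- object$pixels
  df <- tidyr::expand_grid(col = seq_len(dim(px)[2]), row = seq_len(dim(px)[1]))
  df$hex <- grDevices::rgb(px[, , 1] / 255, px[, , 2] / 255, px[, , 3] / 255)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$hex)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("grade %s (seed %d)", object$grade, object$seed),
                  x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Plot an ROC curve
#'
#' @param roc the result of [roc_auc()].
#' @return A ggplot line plot of the ROC curve with the chance diagonal.
#' @export
plot_roc <- function(roc) {
  ggplot2::ggplot(roc$roc_points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, color = "gray60") +
    ggplot2::geom_path(linewidth = 0.8, color = "#2c7fb8") +
    ggplot2::labs(title = sprintf("ROC (AUC = %.3f)", roc$auc),
                  x = "False positive rate", y = "True positive rate") +
    ggplot2::theme_minimal()
}
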