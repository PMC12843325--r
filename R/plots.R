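## ggplot2 views of the core result types ------------------------------------

#' Plot a gait template
#'
#' Grayscale raster of the template on its canvas, image orientation (row 1
#' at the top).
#'
#' @param object A [gait_template].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gait_template <- function(object, ...) {
  px <- object$pixels
  df <- data.frame(
    u = rep(seq_len(ncol(px)) - 0.5, each = nrow(px)),
    v = rep(seq_len(nrow(px)) - 0.5, times = ncol(px)),
    value = as.vector(px))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s template (%d frames)", object$variant,
                                  object$n_frames),
                  x = "u (px)", y = "v (px)", fill = "energy") +
    ggplot2::theme_minimal()
}

#' @export
plot.gait_template <- function(x, ...) print(autoplot.gait_template(x, ...))

#' Plot a cross-view identification report
#'
#' Heatmap of rank-1 accuracy per gallery-view x probe-view cell, faceted by
#' covariate condition.
#'
#' @param object An `identification_report` from
#'   [evaluate_gallery_probe()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.identification_report <- function(object, ...) {
  ggplot2::ggplot(object$cells,
                  ggplot2::aes(x = factor(.data$probe_view),
                               y = factor(.data$gallery_view),
                               fill = .data$rank1)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.0f", .data$rank1)),
                       size = 3) +
    ggplot2::facet_wrap(~covariate) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100)) +
    ggplot2::labs(x = "probe view (deg)", y = "gallery view (deg)",
                  fill = "rank-1 (%)") +
    ggplot2::theme_minimal()
}

#' Plot a training log
#'
#' Loss and accuracy per epoch for the training and validation splits.
#'
#' @param object A trained `gait_cnn`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gait_cnn <- function(object, ...) {
  log <- object$log
  df <- rbind(
    data.frame(epoch = log$epoch, split = "train", metric = "loss",
               value = log$train_loss),
    data.frame(epoch = log$epoch, split = "train", metric = "accuracy",
               value = log$train_acc),
    data.frame(epoch = log$epoch, split = "validation", metric = "loss",
               value = log$val_loss),
    data.frame(epoch = log$epoch, split = "validation", metric = "accuracy",
               value = log$val_acc))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   color = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
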