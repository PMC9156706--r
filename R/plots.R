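.raster_df <- function(m, value = "intensity") {
  df <- expand.grid(z = seq_len(nrow(m)), x = seq_len(ncol(m)))
  df[[value]] <- as.vector(m)
  df
}

#' Plot an OCT frame
#'
#' Depth increases downwards, matching the physical B-scan orientation.
#'
#' @param object An [oct_frame()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot oct_frame
#' @export
autoplot.oct_frame <- function(object, ...) {
  df <- .raster_df(object$pixels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "X (px)", y = "depth Z (px)",
                  title = as.character(object$label)) +
    ggplot2::theme_minimal()
}

#' Plot a Grad-CAM heatmap over its source frame
#'
#' @param object An `oct_heatmap` from [gradcam()].
#' @param alpha Maximum overlay opacity.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot oct_heatmap
#' @export
autoplot.oct_heatmap <- function(object, alpha = 0.6, ...) {
  df <- .raster_df(object$pixels)
  df$saliency <- as.vector(object$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255), guide = "none") +
    ggplot2::geom_raster(ggplot2::aes(alpha = .data$saliency),
                         fill = "red") +
    ggplot2::scale_alpha(range = c(0, alpha), limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "X (px)", y = "depth Z (px)",
                  title = paste0("Grad-CAM: ", object$target_class),
                  alpha = "saliency") +
    ggplot2::theme_minimal()
}

#' Plot the traffic-light timeline of a cascade run
#'
#' The displayed class-1 fraction over the stream, coloured by zone, with
#' stage switches marked; no fraction is shown once stage 4 is active.
#'
#' @param object A `cascade_run` from [run_stream()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cascade_run
#' @export
autoplot.cascade_run <- function(object, ...) {
  ann <- object$annotations
  p <- ggplot2::ggplot(ann[!is.na(ann$fraction), ],
                       ggplot2::aes(x = .data$t, y = .data$fraction)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$zone), size = 0.6) +
    ggplot2::scale_colour_manual(values = c(GREEN = "forestgreen",
                                            YELLOW = "goldenrod2",
                                            RED = "firebrick")) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "frame", y = "class-1 fraction of last 50") +
    ggplot2::theme_minimal()
  if (nrow(object$switches) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = object$switches$frame,
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot per-fold test metrics of a nested evaluation
#'
#' @param object A `nested_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot nested_result
#' @export
autoplot.nested_result <- function(object, ...) {
  ggplot2::ggplot(object$test,
                  ggplot2::aes(x = factor(.data$test_subject),
                               y = .data$metric)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$summary$mean,
                        linetype = "dashed") +
    ggplot2::labs(x = "testing fold (held-out subject)",
                  y = object$metric_name) +
    ggplot2::theme_minimal()
}
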