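# 1-D bilinear interpolation weights mapping n_in samples onto n_out,
# pixel centres aligned
.bilinear_weights <- function(n_out, n_in) {
  W <- matrix(0, n_out, n_in)
  for (t in seq_len(n_out)) {
    s <- (t - 0.5) * n_in / n_out + 0.5
    if (s <= 1) {
      W[t, 1] <- 1
    } else if (s >= n_in) {
      W[t, n_in] <- 1
    } else {
      i0 <- floor(s)
      fr <- s - i0
      W[t, i0] <- 1 - fr
      W[t, i0 + 1] <- fr
    }
  }
  W
}

#' Grad-CAM class-activation heatmap
#'
#' Gradient-weighted class activation mapping for a trained classifier:
#' the gradient of the target-class score (pre-softmax) with respect to the
#' deepest convolutional feature maps is spatially averaged into channel
#' weights; the weighted sum of the feature maps is rectified at zero,
#' bilinearly upsampled to the frame's pixel grid and normalised by its
#' maximum to \[0, 1\]. A class with identically zero gradient yields an
#' all-zero heatmap (documented fallback).
#'
#' @param model A classification `oct_cnn`.
#' @param frame An [oct_frame()] (or pixel matrix) matching the model's
#'   geometry.
#' @param target_class Class name or index; defaults to the predicted
#'   class.
#' @return An `oct_heatmap`: list with `values` (matrix in \[0, 1\], same
#'   dimensions as the frame), `target_class`, `layer`, and the source
#'   `pixels` for overlay plotting.
#' @export
gradcam <- function(model, frame, target_class = NULL) {
  if (!inherits(model, "oct_cnn")) abort("model must be an oct_cnn")
  if (model$type != "class") {
    abort("Grad-CAM requires a classification model, not a regressor")
  }
  conv_idx <- which(vapply(model$net$layers, function(l) l$type, "") == "conv")
  if (length(conv_idx) == 0) abort("model has no convolutional feature layer")
  i_conv <- max(conv_idx)
  ly <- model$net$layers[[i_conv]]

  X <- .model_tensor(model, .as_frame_list(frame))
  if (ncol(X) != 1) abort("gradcam explains a single frame at a time")
  fw <- .net_forward(model$net, X, keep = TRUE)

  if (is.null(target_class)) {
    target_class <- which.max(fw$out[, 1])
  } else if (is.character(target_class)) {
    target_class <- match(target_class, model$classes)
    if (is.na(target_class)) abort("unknown target class")
  }
  dZ <- matrix(0, nrow(fw$out), 1)
  dZ[target_class, 1] <- 1

  bw <- .net_backward(model$net, fw$caches, dZ, stop_at = i_conv + 1L)
  G <- bw$G_stop                        # gradient at the ReLU'd feature maps
  A <- fw$caches[[i_conv + 1L]]$A       # the feature maps themselves
  w <- rowMeans(G)
  m <- as.vector(colSums(A * w))
  m[m < 0] <- 0
  M <- matrix(m, ly$hout, ly$wout)

  pix <- .frame_pixels(.as_frame_list(frame)[[1]])
  up <- .bilinear_weights(nrow(pix), ly$hout) %*% M %*%
        t(.bilinear_weights(ncol(pix), ly$wout))
  mx <- max(up)
  if (mx > 0) up <- up / mx
  structure(
    list(values = up,
         target_class = model$classes[target_class],
         layer = paste0("conv", match(i_conv, conv_idx)),
         pixels = pix),
    class = "oct_heatmap"
  )
}

#' @export
print.oct_heatmap <- function(x, ...) {
  cat(sprintf("<oct_heatmap> %d x %d, class '%s' at layer %s, max %.3f\n",
              nrow(x$values), ncol(x$values), x$target_class, x$layer,
              max(x$values)))
  invisible(x)
}
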