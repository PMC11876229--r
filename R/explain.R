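# Grad-CAM attention maps for the fine-tuned classifier: which image
# regions drive the positive-class (cancer) logit.

#' Grad-CAM attention map
#'
#' Channel weights are the spatially averaged gradients of the
#' positive-class logit with respect to the chosen convolutional layer's
#' (post-activation) feature maps; the map is the rectified weighted sum
#' of those maps, bilinearly upsampled to the input size and min-max
#' normalized to \[0, 1\] (an all-zero map stays all-zero).
#'
#' @param model A `classifier_model`.
#' @param image Numeric matrix.
#' @param layer 1-based index of the convolutional block to explain;
#'   default is the last (deepest) spatial block, standard Grad-CAM
#'   practice.
#' @return An object of class `cam_map`: list with `heatmap` (matrix in
#'   \[0, 1\], same size as `image`), `target_layer`, `predicted_class`
#'   (1 if score >= 0.5) and `score`.
#' @export
grad_cam <- function(model, image, layer = NULL) {
  stopifnot(inherits(model, "classifier_model"))
  L <- n_enc_layers(model$params)
  if (is.null(layer)) layer <- L
  if (layer < 1L || layer > L)
    stop("layer must be in 1..", L, " (spatial conv blocks)", call. = FALSE)
  fw <- classifier_forward(model, image, keep = TRUE)
  gfeat <- drop(model$params$head.W)  # d logit / d pooled features
  bw <- encoder_backward(model$params, model$spec, fw$cache, gfeat,
                         keep_act_grads = TRUE)
  acts <- pmax(fw$cache$preacts[[layer]], 0)
  g <- bw$act_grads[[layer]]
  w <- apply(g, 3, mean)
  cam <- matrix(0, dim(acts)[1], dim(acts)[2])
  for (k in seq_len(dim(acts)[3])) cam <- cam + w[k] * acts[, , k]
  cam <- pmax(cam, 0)
  up <- as.matrix(EBImage::resize(EBImage::Image(cam),
                                  w = nrow(image), h = ncol(image)))
  up <- array(as.numeric(up), dim = dim(up))  # drop EBImage attributes
  mx <- max(up)
  if (mx > 0) up <- (up - min(up)) / (mx - min(up))
  structure(list(heatmap = up, target_layer = layer,
                 predicted_class = as.integer(fw$score >= 0.5),
                 score = unname(fw$score)),
            class = "cam_map")
}

#' Render a Grad-CAM overlay as an 8-bit PNG
#'
#' Red marks strongly emphasized regions, blue weakly emphasized ones,
#' alpha-blended over the grayscale image. Raw heatmap values can be
#' written alongside as CSV.
#'
#' @param cam A `cam_map`.
#' @param image The explained grayscale matrix.
#' @param path Output PNG path.
#' @param raw_csv Optional CSV path for the raw heatmap values.
#' @param alpha Blend weight of the color layer.
#' @export
cam_overlay <- function(cam, image, path, raw_csv = NULL, alpha = 0.4) {
  stopifnot(inherits(cam, "cam_map"))
  h <- cam$heatmap
  rgb <- array(0, c(nrow(image), ncol(image), 3))
  rgb[, , 1] <- (1 - alpha) * image + alpha * h
  rgb[, , 2] <- (1 - alpha) * image + alpha * 0.2 * h * (1 - h) * 4
  rgb[, , 3] <- (1 - alpha) * image + alpha * (1 - h)
  rgb <- pmin(pmax(rgb, 0), 1)
  png::writePNG(rgb, path)
  if (!is.null(raw_csv))
    utils::write.table(h, raw_csv, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  invisible(path)
}
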