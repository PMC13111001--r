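# Class-activation-map explainers hooked on the final attention-refined
# stage (x4', 2048 channels at 7x7 for the full-size network). Grad-CAM and
# Grad-CAM++ differentiate the pre-softmax class score with respect to that
# layer; Score-CAM is gradient-free. All heatmaps are bilinearly resized to
# the input resolution and min-max normalized; a constant pre-normalization
# map yields an all-zero heatmap (the normalization is undefined there).

as_single_image <- function(image, model) {
  if (length(dim(image)) == 3) dim(image) <- c(1L, dim(image))
  check_input_batch(model, image)
  if (dim(image)[1] != 1)
    hmc_stop("explainers take a single image", "hmcnet_input_error")
  image
}

check_class_index <- function(model, class_index) {
  K <- model$config$num_classes
  if (class_index < 0 || class_index >= K)
    hmc_stop(sprintf("class_index %d out of range [0, %d)", class_index, K),
             "hmcnet_input_error")
}

# forward to the target layer + gradient of y_c at that layer.
# The head after x4' is global-average-pool + fully-connected, so the
# gradient is obtained by back-propagating through those two maps only.
target_forward_grad <- function(model, image, class_index, wrt = "logit") {
  logits <- model_fwd_internal(model, bchw_to_bhwc(image), training = FALSE)
  A <- model$stage_out$x4p                      # (1, h, w, C)
  dA_list <- list()
  dlog <- matrix(0, 1, model$config$num_classes)
  if (wrt == "logit") {
    dlog[1, class_index + 1] <- 1
  } else {
    p <- softmax_rows(logits)[1, ]
    dlog[1, ] <- -p[class_index + 1] * p
    dlog[1, class_index + 1] <- dlog[1, class_index + 1] + p[class_index + 1]
  }
  fc <- model$mods$fc
  dpooled <- dlog %*% t(fc$W)
  G <- gap_bwd(dpooled, dim(A)[2:3], 1L, dim(A)[4])
  list(A = A, G = G, logits = logits)
}

finalize_heatmap <- function(cam, out_size, method, class_index) {
  hm <- normalize_resize(cam, c(out_size, out_size))
  attr(hm, "method") <- method
  attr(hm, "class_index") <- class_index
  hm
}

#' Resize and min-max normalize a raw activation map
#'
#' Bilinear resize to `out_size`, then `(x - min) / (max - min)`. A constant
#' input (max = min) maps to an all-zero heatmap.
#'
#' @param cam finite numeric matrix.
#' @param out_size integer vector `(H, W)`.
#' @return matrix in `[0, 1]`.
#' @export
normalize_resize <- function(cam, out_size) {
  check_finite(cam, "activation map")
  hm <- resize_bilinear_2d(cam, out_size[1], out_size[2])
  rng <- range(hm)
  if (degenerate_range(rng)) return(matrix(0, out_size[1], out_size[2]))
  (hm - rng[1]) / (rng[2] - rng[1])
}

# a map is treated as constant when its spread is at rounding level
# relative to its magnitude (the min-max normalization is undefined there)
degenerate_range <- function(rng) {
  rng[2] - rng[1] <= 1e-9 * max(abs(rng), 1e-12)
}

#' Grad-CAM heatmap
#'
#' Channel weights are the spatial means of the gradients of the class
#' score at the target layer; the map is `ReLU(sum_k alpha_k A_k)`,
#' bilinearly resized to the input resolution and min-max normalized.
#'
#' @param model a `hmc_model`.
#' @param image preprocessed input `(3, H, W)` (or `(1, 3, H, W)`).
#' @param class_index 0-based target class.
#' @param wrt `"logit"` (default; pre-softmax score) or `"prob"`.
#' @return heatmap matrix in `[0, 1]` at input resolution, with attributes
#'   `method` and `class_index`.
#' @export
grad_cam <- function(model, image, class_index, wrt = c("logit", "prob")) {
  wrt <- match.arg(wrt)
  check_class_index(model, class_index)
  image <- as_single_image(image, model)
  tg <- target_forward_grad(model, image, class_index, wrt)
  d <- dim(tg$A)
  alpha <- colMeans(matrix(tg$G, d[2] * d[3], d[4]))       # spatial mean per channel
  cam <- matrix(matrix(tg$A, d[2] * d[3], d[4]) %*% alpha, d[2], d[3])
  cam <- pmax(cam, 0)
  finalize_heatmap(cam, model$config$input_size, "gradcam", class_index)
}

#' Grad-CAM++ heatmap
#'
#' Pixel weights use the closed form in powers of first derivatives,
#' `alpha_ij = G_ij^2 / (2 G_ij^2 + sum(A) G_ij^3)` (zero where the
#' denominator vanishes). By default the channel weight is
#' `sum_ij alpha_ij * ReLU(G_ij)`; `literal_eq24 = TRUE` drops the ReLU(G)
#' factor and sums the pixel weights alone.
#'
#' @inheritParams grad_cam
#' @param literal_eq24 use the plain sum of pixel weights as the channel
#'   weight instead of the ReLU-of-gradient weighting.
#' @return heatmap matrix in `[0, 1]`, attributes as in [grad_cam()].
#' @export
grad_cam_pp <- function(model, image, class_index, literal_eq24 = FALSE,
                        wrt = c("logit", "prob")) {
  wrt <- match.arg(wrt)
  check_class_index(model, class_index)
  image <- as_single_image(image, model)
  tg <- target_forward_grad(model, image, class_index, wrt)
  d <- dim(tg$A)
  Am <- matrix(tg$A, d[2] * d[3], d[4])
  Gm <- matrix(tg$G, d[2] * d[3], d[4])
  sumA <- colSums(Am)
  num <- Gm^2
  den <- 2 * Gm^2 + sweep(Gm^3, 2, sumA, `*`)
  alpha_ij <- ifelse(den == 0, 0, num / den)
  w <- if (literal_eq24) colSums(alpha_ij) else colSums(alpha_ij * pmax(Gm, 0))
  cam <- pmax(matrix(Am %*% w, d[2], d[3]), 0)
  finalize_heatmap(cam, model$config$input_size, "gradcampp", class_index)
}

#' Score-CAM heatmap (gradient-free)
#'
#' Each target-layer channel is min-max normalized and upsampled to the
#' input size (constant channels give a zero mask), multiplied into the
#' input image, and the masked image's softmax probability for the target
#' class becomes the channel weight. The heatmap is
#' `ReLU(sum_k s_k A_k)`, resized and normalized. Channel passes are
#' batched in chunks; the result does not depend on the chunk size.
#'
#' @inheritParams grad_cam
#' @param chunk number of masked images per forward batch.
#' @param wrt `"prob"` (default; softmax confidence) or `"logit"`.
#' @return heatmap matrix in `[0, 1]`, attributes as in [grad_cam()].
#' @export
score_cam <- function(model, image, class_index, chunk = 32L,
                      wrt = c("prob", "logit")) {
  wrt <- match.arg(wrt)
  check_class_index(model, class_index)
  image <- as_single_image(image, model)
  size <- model$config$input_size
  model_fwd_internal(model, bchw_to_bhwc(image), training = FALSE)
  A <- model$stage_out$x4p
  d <- dim(A)
  C <- d[4]
  img_hwc <- bchw_to_bhwc(image)[1, , , ]      # (H, W, 3)
  scores <- numeric(C)
  for (start in seq(1, C, by = chunk)) {
    ks <- start:min(start + chunk - 1L, C)
    xb <- array(0, c(length(ks), size, size, 3L))
    for (j in seq_along(ks)) {
      Ak <- matrix(A[1, , , ks[j]], d[2], d[3])
      rng <- range(Ak)
      Mk <- if (degenerate_range(rng)) matrix(0, size, size) else
        resize_bilinear_2d((Ak - rng[1]) / (rng[2] - rng[1]), size, size)
      # clip: bilinear overshoot cannot occur (convex weights) but keep [0,1]
      xb[j, , , ] <- img_hwc * array(Mk, c(size, size, 3L))
    }
    logits <- model_fwd_internal(model, xb, training = FALSE)
    scores[ks] <- if (wrt == "prob")
      softmax_rows(logits)[, class_index + 1] else logits[, class_index + 1]
  }
  cam <- pmax(matrix(matrix(A, d[2] * d[3], C) %*% scores, d[2], d[3]), 0)
  finalize_heatmap(cam, size, "scorecam", class_index)
}

#' Intersection-over-union between a binarized heatmap and a lesion mask
#'
#' The mask is resampled to the heatmap resolution by nearest neighbour,
#' the heatmap is binarized at `>= threshold`, and
#' `IoU = |intersection| / |union|`; an empty union returns 0.
#'
#' @param heatmap `[0,1]` matrix.
#' @param roi_mask binary (0/1) ground-truth mask.
#' @param threshold binarization threshold in `(0, 1)`; 0.5 by default.
#' @return IoU in `[0, 1]`.
#' @export
localization_iou <- function(heatmap, roi_mask, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    hmc_stop("threshold must be in (0, 1)", "hmcnet_input_error")
  if (!all(roi_mask %in% c(0, 1)))
    hmc_stop("roi_mask must be binary", "hmcnet_input_error")
  h <- nrow(heatmap); w <- ncol(heatmap)
  if (!identical(dim(roi_mask), dim(heatmap))) {
    ri <- nn_index(h, nrow(roi_mask)); ci <- nn_index(w, ncol(roi_mask))
    roi_mask <- roi_mask[ri, ci, drop = FALSE]
  }
  bin <- heatmap >= threshold
  msk <- roi_mask > 0
  uni <- sum(bin | msk)
  if (uni == 0) return(0)
  sum(bin & msk) / uni
}

#' Write a heatmap as grayscale PNG plus an RGB overlay
#'
#' The overlay blends a jet-style colormap of the heatmap over the image at
#' fixed alpha.
#'
#' @param heatmap `[0,1]` matrix.
#' @param path output PNG path (grayscale); the overlay is written next to
#'   it as `<path>_overlay.png` when `image` is given.
#' @param image optional `[0,1]` grayscale matrix to blend under the map.
#' @param alpha overlay opacity.
#' @return invisibly, the path(s) written.
#' @export
save_heatmap <- function(heatmap, path, image = NULL, alpha = 0.4) {
  png::writePNG(pmin(pmax(heatmap, 0), 1), path)
  written <- path
  if (!is.null(image)) {
    h <- nrow(heatmap); w <- ncol(heatmap)
    img <- resize_bilinear_2d(image, h, w)
    v <- pmin(pmax(heatmap, 0), 1)
    r <- pmin(pmax(1.5 - abs(4 * v - 3), 0), 1)
    g <- pmin(pmax(1.5 - abs(4 * v - 2), 0), 1)
    b <- pmin(pmax(1.5 - abs(4 * v - 1), 0), 1)
    rgb <- array(0, c(h, w, 3))
    rgb[, , 1] <- (1 - alpha) * img + alpha * r
    rgb[, , 2] <- (1 - alpha) * img + alpha * g
    rgb[, , 3] <- (1 - alpha) * img + alpha * b
    over <- sub("\\.png$", "_overlay.png", path)
    png::writePNG(pmin(pmax(rgb, 0), 1), over)
    written <- c(written, over)
  }
  invisible(written)
}
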