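# Gradient-weighted class-activation mapping for the scalar score
# regressor, and a quantitative focus-correctness score against known
# calcification masks.

#' Gradient-weighted activation heatmap for a score prediction
#'
#' Computes, at a chosen backbone block, per-channel weights as the
#' spatial mean of the gradients of the scalar output with respect to the
#' block's activations, forms the rectified weighted activation sum,
#' bilinearly upsamples it to the patch size and max-normalises to
#' `[0, 1]` (an all-zero map stays all-zero).
#'
#' @param model A trained `aac_net`.
#' @param patch An [aac_patch()] or matrix of the model's input size.
#' @param target_layer Backbone block index, or `"last"` (default) for
#'   the final convolutional block.
#' @return Object of class `aac_heatmap`: list with `values` (matrix in
#'   `[0,1]`, patch-sized), `target_layer`, `prediction`.
#' @export
grad_cam <- function(model, patch, target_layer = "last") {
  px <- patch_pixels(patch)
  blocks <- build_backbone_cached(model)$mods
  n_blocks <- length(blocks)
  if (identical(target_layer, "last")) target_layer <- n_blocks
  if (!(target_layer %in% seq_len(n_blocks))) {
    stop(sprintf("unknown target layer %s; available blocks: 1..%d",
                 target_layer, n_blocks), call. = FALSE)
  }
  x <- as_map(px)
  # forward with caches (train = TRUE so convolutions retain the
  # backward-pass buffers), remembering the target block's activation
  caches <- vector("list", n_blocks)
  act <- NULL
  h <- x
  for (i in seq_len(n_blocks)) {
    r <- blocks[[i]]$fw(model$params$blocks[[i]], h, TRUE)
    h <- r$y
    caches[[i]] <- r$cache
    if (i == target_layer) act <- r$y
  }
  d <- dim(h)
  feat <- colMeans(matrix(h, d[1] * d[2], d[3]))
  hf <- head_fw(model$params$head, matrix(feat, 1), model$bn_state, FALSE,
                0, NULL)
  hb <- head_bw(model$params$head, hf$cache, matrix(feat, 1),
                matrix(1, 1, 1), FALSE, 0, NULL)
  # backprop to the target block's output
  n <- d[1] * d[2]
  dy <- array(rep(hb$dfeat[1, ] / n, each = n), d)
  if (target_layer < n_blocks) {
    for (i in rev((target_layer + 1L):n_blocks)) {
      dy <- blocks[[i]]$bw(model$params$blocks[[i]], caches[[i]], dy)$dx
    }
  }
  wts <- apply(dy, 3, mean)
  cam <- matrix(0, dim(act)[1], dim(act)[2])
  for (c in seq_along(wts)) cam <- cam + wts[c] * act[, , c]
  cam <- pmax(cam, 0)
  up <- EBImage::imageData(
    EBImage::resize(EBImage::Image(cam), w = nrow(px), h = ncol(px),
                    filter = "bilinear"))
  up <- pmax(matrix(up, nrow(px), ncol(px)), 0)
  if (max(up) > 0) up <- up / max(up)
  structure(list(values = up, target_layer = target_layer,
                 prediction = as.numeric(hf$out)),
            class = "aac_heatmap")
}

#' @export
print.aac_heatmap <- function(x, ...) {
  cat(sprintf(
    "aac_heatmap %d x %d from block %d; prediction %.2f; mass > 0.5: %.1f%%\n",
    nrow(x$values), ncol(x$values), x$target_layer, x$prediction,
    100 * mean(x$values > 0.5)))
  invisible(x)
}

#' Fraction of top heatmap activation inside the calcification mask
#'
#' Takes the top `top_q` quantile of heatmap pixels and returns the
#' fraction of them lying inside the (optionally dilated) calcification
#' mask mapped into patch space. A quantitative proxy for "correct focus".
#'
#' @param h An `aac_heatmap` (or matrix).
#' @param calc_mask Binary mask aligned with the heatmap (use
#'   [warp_mask_to_patch()] semantics to map an image-space mask through
#'   the same crop/resize as the patch).
#' @param top_q Top quantile of heatmap values considered (default 0.1).
#' @param dilate_radius Optional disc dilation radius (pixels) applied to
#'   the mask before scoring.
#' @return Numeric in `[0, 1]`; `NA` with a warning for an empty mask.
#' @export
focus_fraction <- function(h, calc_mask, top_q = 0.1, dilate_radius = 0) {
  v <- if (inherits(h, "aac_heatmap")) h$values else h
  if (!identical(dim(v), dim(calc_mask))) {
    stop("heatmap and mask differ in shape", call. = FALSE)
  }
  m <- calc_mask != 0
  if (!any(m)) {
    warning("empty calcification mask; focus fraction undefined")
    return(NA_real_)
  }
  if (dilate_radius > 0) {
    kern <- EBImage::makeBrush(2 * dilate_radius + 1, shape = "disc")
    m <- EBImage::imageData(EBImage::dilate(EBImage::Image(m * 1),
                                            kern)) > 0
  }
  thr <- stats::quantile(v, 1 - top_q, names = FALSE)
  top <- v >= thr
  mean(m[top])
}

#' Write a heatmap overlay image
#'
#' Renders the patch in grayscale with the heatmap blended on top in a
#' warm colormap at fixed alpha, as an RGB PNG.
#'
#' @param patch The patch the heatmap was computed on.
#' @param h The `aac_heatmap`.
#' @param path Output PNG path.
#' @param alpha Blend weight of the heatmap.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(patch, h, path, alpha = 0.4) {
  px <- patch_pixels(patch)
  g <- (px - min(px)) / max(diff(range(px)), 1e-12)
  v <- h$values
  rgb <- array(0, c(dim(g), 3))
  rgb[, , 1] <- (1 - alpha) * g + alpha * v
  rgb[, , 2] <- (1 - alpha) * g + alpha * v * 0.4
  rgb[, , 3] <- (1 - alpha) * g
  png::writePNG(pmin(pmax(rgb, 0), 1), path)
  invisible(path)
}
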