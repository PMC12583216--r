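# Vertebra segmentation: an encoder-decoder ("U") convolutional network
# labelling L1-L5 on a lateral radiograph, trained with a combined soft
# dice + cross-entropy loss, plus mask quality control.

#' Vertebra label mask
#'
#' @param labels Integer matrix; 0 = background, 1..5 = L1..L5.
#' @param pixel_spacing Optional mm/pixel.
#' @param anterior_side `"left"` or `"right"`.
#' @return Object of class `vertebra_mask`.
#' @export
vertebra_mask <- function(labels, pixel_spacing = NULL,
                          anterior_side = "left") {
  if (!is.matrix(labels)) stop("labels must be a matrix", call. = FALSE)
  u <- unique(as.vector(labels))
  if (!all(u %in% 0:5)) {
    stop("labels must be integers in 0..5; found ",
         paste(setdiff(u, 0:5), collapse = ", "), call. = FALSE)
  }
  structure(list(labels = matrix(as.integer(labels), nrow(labels)),
                 pixel_spacing = pixel_spacing,
                 anterior_side = match.arg(anterior_side,
                                           c("left", "right"))),
            class = "vertebra_mask")
}

#' @export
print.vertebra_mask <- function(x, ...) {
  cat(sprintf("vertebra_mask %d x %d, labels present: %s, anterior side %s\n",
              nrow(x$labels), ncol(x$labels),
              paste(sort(setdiff(unique(as.vector(x$labels)), 0L)),
                    collapse = ","),
              x$anterior_side))
  invisible(x)
}

#' Segmentation network configuration
#'
#' Desk-scale defaults (depth 4, channel ladder 16-128, 128 x 256 patches)
#' keep a full training run on one CPU within minutes; `preset = "full"`
#' selects a radiograph-scale configuration (deep ladder topping out at
#' 512 channels, 1536 x 1024 patches, batch 2).
#'
#' @param depth Encoder levels (>= 3).
#' @param base_channels Channel ladder, one entry per level.
#' @param patch_size Training patch `(rows, cols)`; each dimension must be
#'   divisible by `2^(depth-1)`.
#' @param batch_size Gradient-accumulation batch.
#' @param loss_weights Weights `(dice, ce)` of the combined loss.
#' @param folds Cross-validation folds; 1 means a plain train/val split.
#' @param epochs,learning_rate Optimisation settings (Adam).
#' @param val_fraction Held-out fraction when `folds = 1`.
#' @param seed Integer seed for initialisation and shuffling.
#' @param preset `"desk"` or `"full"` (overrides the size arguments).
#' @return Object of class `seg_config`.
#' @export
seg_config <- function(depth = 4L,
                       base_channels = c(16L, 32L, 64L, 128L),
                       patch_size = c(128L, 256L),
                       batch_size = 4L,
                       loss_weights = c(dice = 0.5, ce = 0.5),
                       folds = 1L,
                       epochs = 4L,
                       learning_rate = 3e-3,
                       val_fraction = 0.15,
                       seed = 1L,
                       preset = c("desk", "full")) {
  preset <- match.arg(preset)
  if (preset == "full") {
    depth <- 9L
    base_channels <- c(32L, 64L, 128L, 256L, 512L, 512L, 512L, 512L, 512L)
    patch_size <- c(1536L, 1024L)
    batch_size <- 2L
    folds <- 5L
  }
  if (depth < 3L) stop("depth must be >= 3", call. = FALSE)
  if (length(base_channels) != depth) {
    stop("base_channels must have one entry per level", call. = FALSE)
  }
  div <- 2^(depth - 1)
  if (any(patch_size %% div != 0)) {
    stop(sprintf("patch dimensions must be divisible by %d", div),
         call. = FALSE)
  }
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 patch_size = as.integer(patch_size),
                 batch_size = as.integer(batch_size),
                 loss_weights = loss_weights, folds = as.integer(folds),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 val_fraction = val_fraction, seed = as.integer(seed),
                 preset = preset),
            class = "seg_config")
}

# U-shaped encoder-decoder over the nn_* primitives. Input has two
# channels: the Z-scored intensities and a normalised row coordinate (the
# coordinate channel gives the otherwise translation-equivariant network
# the craniocaudal position cue needed to tell L1 from L5).
nn_unet <- function(depth, channels, in_ch = 2L, n_classes = 6L) {
  enc <- vector("list", depth)
  for (l in seq_len(depth)) {
    cin <- if (l == 1L) in_ch else channels[l - 1L]
    enc[[l]] <- nn_seq(list(nn_conv(3L, cin, channels[l]),
                            nn_inorm(channels[l]), nn_relu(),
                            nn_conv(3L, channels[l], channels[l]),
                            nn_inorm(channels[l]), nn_relu()))
  }
  pools <- lapply(seq_len(depth - 1L), function(l) nn_maxpool())
  ups <- vector("list", depth - 1L)
  dec <- vector("list", depth - 1L)
  for (l in seq_len(depth - 1L)) {
    # lean decoder: 1x1 channel projection after upsampling, then a single
    # 3x3 fusion conv on the concatenated skip features
    ups[[l]] <- nn_seq(list(nn_conv(1L, channels[l + 1L], channels[l]),
                            nn_inorm(channels[l]), nn_relu()))
    dec[[l]] <- nn_seq(list(nn_conv(3L, 2L * channels[l], channels[l]),
                            nn_inorm(channels[l]), nn_relu()))
  }
  final <- nn_conv(1L, channels[1L], n_classes)
  upsample <- nn_upsample()
  params <- list(enc = lapply(enc, `[[`, "params"),
                 ups = lapply(ups, `[[`, "params"),
                 dec = lapply(dec, `[[`, "params"),
                 final = final$params)
  fw <- function(p, x, train = FALSE) {
    feats <- vector("list", depth)
    ec <- vector("list", depth)
    pc <- vector("list", depth - 1L)
    h <- x
    for (l in seq_len(depth)) {
      r <- enc[[l]]$fw(p$enc[[l]], h, train)
      feats[[l]] <- r$y
      ec[[l]] <- r$cache
      if (l < depth) {
        pr <- pools[[l]]$fw(list(), r$y, train)
        h <- pr$y
        pc[[l]] <- pr$cache
      }
    }
    h <- feats[[depth]]
    uc <- vector("list", depth - 1L)
    dc <- vector("list", depth - 1L)
    for (l in rev(seq_len(depth - 1L))) {
      h <- upsample$fw(list(), h, train)$y
      ru <- ups[[l]]$fw(p$ups[[l]], h, train)
      uc[[l]] <- ru$cache
      cat_in <- array(c(ru$y, feats[[l]]),
                      c(dim(ru$y)[1:2], 2L * dim(ru$y)[3]))
      rd <- dec[[l]]$fw(p$dec[[l]], cat_in, train)
      dc[[l]] <- rd$cache
      h <- rd$y
    }
    rf <- final$fw(p$final, h, train)
    list(y = rf$y, cache = list(ec = ec, pc = pc, uc = uc, dc = dc,
                                fc = rf$cache,
                                fdims = lapply(feats, dim)))
  }
  bw <- function(p, cache, dy) {
    g <- list(enc = vector("list", depth),
              ups = vector("list", depth - 1L),
              dec = vector("list", depth - 1L), final = NULL)
    dfeat <- vector("list", depth)   # accumulated grads wrt encoder outputs
    rf <- final$bw(p$final, cache$fc, dy)
    g$final <- rf$grads
    dh <- rf$dx
    for (l in seq_len(depth - 1L)) {
      rd <- dec[[l]]$bw(p$dec[[l]], cache$dc[[l]], dh)
      g$dec[[l]] <- rd$grads
      ch <- dim(rd$dx)[3] %/% 2L
      d_up <- rd$dx[, , seq_len(ch), drop = FALSE]
      d_skip <- rd$dx[, , ch + seq_len(ch), drop = FALSE]
      dfeat[[l]] <- d_skip
      ru <- ups[[l]]$bw(p$ups[[l]], cache$uc[[l]], d_up)
      g$ups[[l]] <- ru$grads
      dh <- upsample$bw(list(), NULL, ru$dx)$dx
    }
    dfeat[[depth]] <- dh
    dx <- NULL
    for (l in rev(seq_len(depth))) {
      d <- dfeat[[l]]
      if (l < depth) {
        # gradient arriving through the pooling path from level l+1
        d <- d + pools[[l]]$bw(list(), cache$pc[[l]], d_pool_in)$dx
      }
      re <- enc[[l]]$bw(p$enc[[l]], cache$ec[[l]], d)
      g$enc[[l]] <- re$grads
      if (l > 1L) d_pool_in <- re$dx else dx <- re$dx
    }
    list(dx = dx, grads = g)
  }
  list(params = params, fw = fw, bw = bw)
}

# softmax over the class dimension of an H x W x K logit array
# (pixelwise vectors recycle column-major over the slices)
softmax3 <- function(z) {
  d <- dim(z)
  zm <- z[, , 1]
  for (k in seq_len(d[3])[-1]) zm <- pmax(zm, z[, , k])
  e <- exp(z - as.vector(zm))
  s <- rowSums(matrix(e, d[1] * d[2], d[3]))
  array(e / s, d)
}

# Combined soft-dice + cross-entropy loss; returns loss value and the
# gradient with respect to the logits.
seg_loss <- function(logits, labels, weights = c(dice = 0.5, ce = 0.5),
                     smooth = 1e-6) {
  d <- dim(logits)
  K <- d[3]
  P <- softmax3(logits)
  n <- d[1] * d[2]
  G <- array(0, d)
  for (k in seq_len(K)) G[, , k] <- (labels == (k - 1L)) * 1
  eps <- 1e-12
  ce <- -sum(G * log(P + eps)) / n
  A <- colSums(matrix(P * G, n, K))
  Bp <- colSums(matrix(P, n, K))
  Bg <- colSums(matrix(G, n, K))
  dice_c <- (2 * A + smooth) / (Bp + Bg + smooth)
  loss <- weights["ce"] * ce + weights["dice"] * (1 - mean(dice_c))
  # gradient wrt P (dice part), then through softmax; CE folds to P - G
  dP <- array(0, d)
  for (k in seq_len(K)) {
    dP[, , k] <- -(2 * G[, , k] * (Bp[k] + Bg[k] + smooth) -
                     (2 * A[k] + smooth)) /
      (K * (Bp[k] + Bg[k] + smooth)^2)
  }
  dP <- weights["dice"] * dP
  inner <- rowSums(matrix(dP * P, n, K))
  dlogits <- P * (dP - as.vector(inner)) + weights["ce"] * (P - G) / n
  list(loss = as.numeric(loss), dlogits = dlogits,
       ce = ce, dice = mean(dice_c))
}

# Z-score the image and stack the normalised row-coordinate channel.
seg_input <- function(image) {
  s <- stats::sd(image)
  z <- if (s > 0) (image - mean(image)) / s else image * 0
  coord <- matrix(seq(0, 1, length.out = nrow(image)), nrow(image),
                  ncol(image))
  array(c(z, coord), c(dim(image), 2L))
}

#' Train the vertebra segmentation network
#'
#' Optimises a U-shaped encoder-decoder with a combined soft-dice and
#' cross-entropy loss (equal weights by default) using Adam. Images are
#' Z-score normalised; with `folds > 1` a per-fold model is trained and
#' prediction averages the fold scores before the argmax.
#'
#' @param train List of `phantom_sample` objects, or a list with elements
#'   `images` (list of matrices) and `masks` (list of `vertebra_mask`).
#' @param config A [seg_config()].
#' @param verbose Print per-epoch loss.
#' @return Object of class `seg_model` with elements `folds` (list of
#'   parameter trees), `config`, `history` (data.frame of per-epoch
#'   train/val loss), `val_index`.
#' @export
train_segmenter <- function(train, config = seg_config(), verbose = FALSE) {
  data <- as_seg_data(train)
  n <- length(data$images)
  min_n <- max(2L, 2L * config$folds)
  if (n < min_n) {
    stop(sprintf("need at least %d training samples, got %d", min_n, n),
         call. = FALSE)
  }
  set.seed(config$seed)
  perm <- sample.int(n)
  fold_of <- if (config$folds > 1L) {
    rep_len(seq_len(config$folds), n)[order(perm)]
  } else {
    n_val <- max(1L, round(config$val_fraction * n))
    ifelse(seq_len(n) %in% perm[seq_len(n_val)], 1L, 0L)
  }
  folds <- if (config$folds > 1L) seq_len(config$folds) else 1L
  models <- vector("list", length(folds))
  histories <- list()
  for (f in folds) {
    tr_idx <- if (config$folds > 1L) which(fold_of != f) else
      which(fold_of == 0L)
    va_idx <- setdiff(seq_len(n), tr_idx)
    set.seed(config$seed + f)
    net <- nn_unet(config$depth, config$base_channels)
    params <- net$params
    opt <- adam_init(params)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(tr_idx)
      ep_loss <- 0
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      for (bt in batches) {
        gacc <- NULL
        bl <- 0
        for (i in bt) {
          x <- seg_input(data$images[[i]])
          r <- net$fw(params, x, train = TRUE)
          ls <- seg_loss(r$y, data$labels[[i]], config$loss_weights)
          bl <- bl + ls$loss
          bwr <- net$bw(params, r$cache, ls$dlogits)
          gacc <- if (is.null(gacc)) bwr$grads else
            ptree_map2(`+`, gacc, bwr$grads)
        }
        gacc <- ptree_map(function(g) g / length(bt), gacc)
        st <- adam_step(params, gacc, opt, lr = config$learning_rate)
        params <- st$params
        opt <- st$state
        ep_loss <- ep_loss + bl
      }
      val_loss <- mean(vapply(va_idx, function(i) {
        r <- net$fw(params, seg_input(data$images[[i]]), FALSE)
        seg_loss(r$y, data$labels[[i]], config$loss_weights)$loss
      }, numeric(1)))
      histories[[length(histories) + 1L]] <-
        data.frame(fold = f, epoch = epoch,
                   train_loss = ep_loss / length(tr_idx),
                   val_loss = val_loss)
      if (verbose) {
        message(sprintf("fold %d epoch %d: train %.4f val %.4f",
                        f, epoch, ep_loss / length(tr_idx), val_loss))
      }
    }
    models[[f]] <- params
  }
  structure(list(folds = models, config = config,
                 net_depth = config$depth,
                 net_channels = config$base_channels,
                 history = do.call(rbind, histories),
                 val_index = if (config$folds > 1L) integer(0) else
                   which(fold_of == 1L)),
            class = "seg_model")
}

as_seg_data <- function(train) {
  if (!length(train)) {
    list(images = list(), labels = list())
  } else if (inherits(train[[1]], "phantom_sample")) {
    list(images = lapply(train, `[[`, "image"),
         labels = lapply(train, function(s) s$vertebra_mask$labels))
  } else if (!is.null(train$images)) {
    labs <- lapply(train$masks, function(m) mask_labels(m))
    list(images = train$images, labels = labs)
  } else {
    stop("train must be phantom samples or list(images=, masks=)",
         call. = FALSE)
  }
}

#' @export
print.seg_model <- function(x, ...) {
  cat(sprintf(
    "seg_model: depth %d, channels %s, %d fold(s), %d epochs trained\n",
    x$net_depth, paste(x$net_channels, collapse = "-"),
    length(x$folds), max(x$history$epoch)))
  invisible(x)
}

#' Segment vertebrae on an image
#'
#' Runs the trained network (averaging per-fold class scores when the
#' model was trained with cross-validation), takes the per-pixel argmax,
#' and keeps, for each label, only its largest connected component.
#'
#' @param model A `seg_model`.
#' @param image Numeric matrix.
#' @param anterior_side Laterality annotation copied onto the result.
#' @return A [vertebra_mask()].
#' @export
segment_vertebrae <- function(model, image, anterior_side = "left") {
  if (!is.matrix(image) || !all(is.finite(image))) {
    stop("image must be a finite numeric matrix", call. = FALSE)
  }
  net <- nn_unet(model$net_depth, model$net_channels)
  x <- seg_input(image)
  probs <- NULL
  for (params in model$folds) {
    p <- softmax3(net$fw(params, x, FALSE)$y)
    probs <- if (is.null(probs)) p else probs + p
  }
  lab <- matrix(0L, nrow(image), ncol(image))
  best <- probs[, , 1]
  for (k in seq_len(dim(probs)[3])[-1]) {
    sel <- probs[, , k] > best
    lab[sel] <- k - 1L
    best[sel] <- probs[, , k][sel]
  }
  vertebra_mask(postprocess_labels(lab), anterior_side = anterior_side)
}

#' @export
predict.seg_model <- function(object, newdata, ...) {
  segment_vertebrae(object, newdata, ...)
}

# keep only the largest 4-connected component of each label
postprocess_labels <- function(lab) {
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (v in sort(setdiff(unique(as.vector(lab)), 0L))) {
    cc <- EBImage::bwlabel(EBImage::Image((lab == v) * 1))
    cc <- EBImage::imageData(cc)
    if (max(cc) == 0) next
    sizes <- tabulate(cc[cc > 0])
    out[cc == which.max(sizes)] <- v
  }
  out
}

#' Dice overlap coefficient
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b Logical/0-1 matrices of equal shape.
#' @return Numeric in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop("masks differ in shape", call. = FALSE)
  }
  a <- a != 0
  b <- b != 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1.0)
  2 * sum(a & b) / denom
}

# mean Dice over the five vertebra labels
mean_label_dice <- function(pred_labels, true_labels) {
  mean(vapply(1:5, function(v) dice(pred_labels == v, true_labels == v),
              numeric(1)))
}

#' Quality control of a predicted vertebra mask
#'
#' Checks the criteria a mask must meet before ROI extraction: all five
#' labels present, a single connected component each, correct
#' superior-to-inferior ordering (by centroid row), and each vertebra's
#' height within a plausibility band around the median height.
#'
#' @param mask A [vertebra_mask()] or label matrix.
#' @param height_band Allowed height range as multiples of the median
#'   vertebral height.
#' @return Object of class `coverage_report`: list with logical `pass`
#'   and character `reasons`.
#' @export
check_roi_coverage <- function(mask, height_band = c(0.3, 3)) {
  labels <- mask_labels(mask)
  reasons <- character(0)
  heights <- rep(NA_real_, 5)
  centroids <- rep(NA_real_, 5)
  for (v in 1:5) {
    sel <- labels == v
    if (!any(sel)) {
      reasons <- c(reasons, sprintf("missing L%d", v))
      next
    }
    ncomp <- label_components(sel)
    if (ncomp > 1L) {
      reasons <- c(reasons, sprintf("L%d fragmented into %d components",
                                    v, ncomp))
    }
    rows <- which(apply(sel, 1, any))
    heights[v] <- max(rows) - min(rows) + 1
    centroids[v] <- mean(which(sel, arr.ind = TRUE)[, 1])
  }
  if (!anyNA(centroids) && any(diff(centroids) <= 0)) {
    reasons <- c(reasons, "superior-to-inferior ordering violated")
  }
  if (!anyNA(heights)) {
    med <- stats::median(heights)
    bad <- which(heights < height_band[1] * med |
                   heights > height_band[2] * med)
    if (length(bad)) {
      reasons <- c(reasons,
                   sprintf("implausible height for L%d", bad))
    }
  }
  structure(list(pass = length(reasons) == 0L, reasons = reasons),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  if (x$pass) cat("coverage check: PASS\n") else {
    cat("coverage check: FAIL\n -", paste(x$reasons, collapse = "\n - "),
        "\n")
  }
  invisible(x)
}
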