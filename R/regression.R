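# Continuous AAC-score regression: a residual convolutional network with
# spatial and channel squeeze-and-excitation (SCse) attention after each
# residual block, a batch-norm/dropout/linear head producing one scalar,
# SGD with momentum under a linear-warmup + cosine-decay learning-rate
# schedule, and the photometric/geometric training augmentation suite.

#' Regressor architecture configuration
#'
#' The desk-scale default is a reduced residual backbone (stem + three
#' stages of two residual blocks) on 250 x 125 inputs; `preset = "full"`
#' selects the 34-layer residual layout on 1000 x 500 inputs.
#'
#' @param stem_channels Channels after the stem convolution.
#' @param stage_blocks Residual blocks per stage.
#' @param stage_channels Channels per stage (first block of each stage
#'   after the first downsamples by stride 2).
#' @param attention Insert an SCse module after each residual block.
#' @param dropout Head dropout probability.
#' @param input_size Input shape `(rows, cols)`.
#' @param seed Seed for parameter initialisation.
#' @param init_params Optional parameter tree from a compatible model
#'   (e.g. a previously trained `aac_net`'s `$params`) used to initialise
#'   the network instead of random weights.
#' @param preset `"desk"` or `"full"`.
#' @return Object of class `regressor_config`.
#' @export
regressor_config <- function(stem_channels = 8L,
                             stage_blocks = c(2L, 2L, 2L),
                             stage_channels = c(8L, 16L, 32L),
                             attention = TRUE,
                             dropout = 0.5,
                             input_size = c(250L, 125L),
                             seed = 1L,
                             init_params = NULL,
                             preset = c("desk", "full")) {
  preset <- match.arg(preset)
  if (preset == "full") {
    stem_channels <- 64L
    stage_blocks <- c(3L, 4L, 6L, 3L)
    stage_channels <- c(64L, 128L, 256L, 512L)
    input_size <- c(1000L, 500L)
  }
  if (dropout < 0 || dropout > 1) stop("dropout must be in [0,1]",
                                       call. = FALSE)
  if (length(stage_blocks) != length(stage_channels)) {
    stop("stage_blocks and stage_channels must align", call. = FALSE)
  }
  structure(list(stem_channels = as.integer(stem_channels),
                 stage_blocks = as.integer(stage_blocks),
                 stage_channels = as.integer(stage_channels),
                 attention = isTRUE(attention), dropout = dropout,
                 input_size = as.integer(input_size),
                 seed = as.integer(seed), init_params = init_params,
                 preset = preset),
            class = "regressor_config")
}

#' Optimisation configuration for the score regressor
#'
#' Defaults follow the training recipe: SGD with momentum 0.9 and weight
#' decay 5e-4; base learning rate 0.01 reached by a 200-iteration linear
#' warmup from 0.01/3, then cosine decay to 1e-4; mean-squared-error loss;
#' validation monitored every 10 epochs with early stopping.
#'
#' @param base_lr,min_lr,warmup_iters,warmup_start_lr Schedule parameters
#'   (see [lr_at()]).
#' @param momentum,weight_decay SGD parameters.
#' @param batch_size,max_epochs Loop sizes.
#' @param val_check_every Epochs between validation evaluations.
#' @param patience Validation checks without improvement before stopping.
#' @param augment An [augment_config()] applied to the training set before
#'   each epoch, or `NULL` for none.
#' @param seed Seed for shuffling, dropout and augmentation.
#' @return Object of class `train_config`.
#' @export
train_config <- function(base_lr = 0.01,
                         min_lr = 1e-4,
                         warmup_iters = 200L,
                         warmup_start_lr = base_lr / 3,
                         momentum = 0.9,
                         weight_decay = 5e-4,
                         batch_size = 32L,
                         max_epochs = 500L,
                         val_check_every = 10L,
                         patience = 5L,
                         augment = NULL,
                         seed = 1L) {
  if (!(min_lr > 0 && min_lr < base_lr)) {
    stop("need 0 < min_lr < base_lr", call. = FALSE)
  }
  if (warmup_iters < 0) stop("warmup_iters must be >= 0", call. = FALSE)
  structure(list(base_lr = base_lr, min_lr = min_lr,
                 warmup_iters = as.integer(warmup_iters),
                 warmup_start_lr = warmup_start_lr, momentum = momentum,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 val_check_every = as.integer(val_check_every),
                 patience = as.integer(patience), augment = augment,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Training augmentation configuration
#'
#' The augmentation suite applied to training patches, in fixed order:
#' random brightness adjustment (plus/minus 10%), random contrast
#' adjustment (plus/minus 10%), additive Gaussian noise with sigma drawn
#' uniformly from `[0, 10]` intensity units on a 0-255 scale (rescaled to
#' the patch's own intensity range), random shift (plus/minus 5% of image
#' size), random scaling (plus/minus 5%) and random rotation (plus/minus
#' 30 degrees). Any magnitude may be set to zero to disable that
#' transform; the associated score label is never altered.
#'
#' @param brightness,contrast Relative adjustment half-ranges.
#' @param noise_sigma_max Upper bound of the noise sigma (0-255 scale).
#' @param shift Shift half-range as a fraction of image size.
#' @param scale Scaling half-range.
#' @param rotate Rotation half-range in degrees.
#' @return Object of class `augment_config`.
#' @export
augment_config <- function(brightness = 0.10, contrast = 0.10,
                           noise_sigma_max = 10, shift = 0.05,
                           scale = 0.05, rotate = 30) {
  vals <- c(brightness = brightness, contrast = contrast,
            noise_sigma_max = noise_sigma_max, shift = shift,
            scale = scale, rotate = rotate)
  if (any(vals < 0)) stop("augmentation magnitudes must be non-negative",
                          call. = FALSE)
  structure(as.list(vals), class = "augment_config")
}

#' Randomly augment a patch
#'
#' Applies the transforms of [augment_config()] in fixed order with
#' independently drawn magnitudes. Output dimensions equal input
#' dimensions; geometric transforms fill exposed regions with zero.
#'
#' @param patch An [aac_patch()] or numeric matrix.
#' @param config An [augment_config()].
#' @param seed Integer seed (the draw is fully reproducible).
#' @return Same type as `patch`.
#' @export
augment_patch <- function(patch, config = augment_config(), seed = 1L) {
  px <- if (inherits(patch, "aac_patch")) patch$pixels else patch
  rng <- local_rng(seed)
  rng_u <- function(half) if (half == 0) 0 else (rng$unif(1) * 2 - 1) * half
  span <- diff(range(px))
  # brightness: additive offset relative to the intensity span
  db <- rng_u(config$brightness)
  if (db != 0) px <- px + db * max(span, 1e-12)
  # contrast: scale around the mean
  dg <- rng_u(config$contrast)
  if (dg != 0) px <- mean(px) + (px - mean(px)) * (1 + dg)
  # additive gaussian noise, sigma uniform in [0, noise_sigma_max] on a
  # 0-255 intensity scale, mapped to the patch's own span
  if (config$noise_sigma_max > 0) {
    sigma <- rng$unif(1) * config$noise_sigma_max * max(span, 1e-12) / 255
    px <- px + rng$norm(length(px), sd = sigma)
  }
  dms <- dim(px)
  img <- EBImage::Image(px)
  dr <- round(rng_u(config$shift) * dms[1])
  dc <- round(rng_u(config$shift) * dms[2])
  if (dr != 0 || dc != 0) {
    img <- EBImage::translate(img, c(dr, dc), bg.col = 0)
  }
  sc <- 1 + rng_u(config$scale)
  if (sc != 1) {
    w2 <- max(2L, round(dms[1] * sc)); h2 <- max(2L, round(dms[2] * sc))
    img <- EBImage::resize(img, w = w2, h = h2, filter = "bilinear")
    img <- center_fit(img, dms)
  }
  ang <- rng_u(config$rotate)
  if (ang != 0) {
    img <- EBImage::rotate(img, ang, bg.col = 0,
                           output.dim = dms, output.origin = c(0, 0))
  }
  out <- matrix(EBImage::imageData(img), dms[1], dms[2])
  if (inherits(patch, "aac_patch")) {
    patch$pixels <- out
    patch
  } else {
    out
  }
}

# centre-crop or zero-pad an EBImage to the target (rows, cols)
center_fit <- function(img, dms) {
  m <- EBImage::imageData(img)
  out <- matrix(0, dms[1], dms[2])
  r_off <- floor((nrow(m) - dms[1]) / 2)
  c_off <- floor((ncol(m) - dms[2]) / 2)
  rr_src <- max(1, 1 + r_off):min(nrow(m), dms[1] + r_off)
  cc_src <- max(1, 1 + c_off):min(ncol(m), dms[2] + c_off)
  out[rr_src - r_off, cc_src - c_off] <- m[rr_src, cc_src]
  EBImage::Image(out)
}

#' Learning rate at a given iteration
#'
#' Linear warmup from `base_lr / 3` to `base_lr` over the first
#' `warmup_iters` iterations, then cosine decay
#' `min_lr + 0.5 (base_lr - min_lr)(1 + cos(pi t))` where `t` is the
#' fraction of post-warmup training elapsed. Continuous at the warmup
#' boundary and non-increasing afterwards.
#'
#' @param iteration 0-based global iteration.
#' @param total_iterations Total iterations of the run (defines the point
#'   where the floor `min_lr` is reached).
#' @param config A [train_config()].
#' @return Learning rate (numeric scalar).
#' @export
lr_at <- function(iteration, total_iterations, config = train_config()) {
  if (any(iteration < 0)) stop("iteration must be >= 0", call. = FALSE)
  w <- config$warmup_iters
  warm <- config$warmup_start_lr +
    (config$base_lr - config$warmup_start_lr) * pmin(iteration, w) / max(w, 1)
  t <- pmin(1, pmax(0, (iteration - w) / max(total_iterations - 1 - w, 1)))
  cosine <- config$min_lr +
    0.5 * (config$base_lr - config$min_lr) * (1 + cos(pi * t))
  ifelse(iteration < w, warm, cosine)
}

# ---- model ---------------------------------------------------------------

build_backbone <- function(config) {
  # classic residual stem: stride-2 convolution followed by 2x2 max
  # pooling (4x downsampling before the residual stages)
  blocks <- list(nn_seq(list(
    nn_conv(3L, 1L, config$stem_channels, stride = 2L),
    nn_inorm(config$stem_channels), nn_relu(), nn_maxpool())))
  cin <- config$stem_channels
  for (s in seq_along(config$stage_blocks)) {
    for (b in seq_len(config$stage_blocks[s])) {
      stride <- if (b == 1L && s > 1L) 2L else 1L
      blocks[[length(blocks) + 1L]] <-
        nn_resblock(cin, config$stage_channels[s], stride,
                    attention = config$attention)
      cin <- config$stage_channels[s]
    }
  }
  blocks
}

#' Build an untrained score-regression network
#'
#' Residual backbone (with optional SCse attention after each residual
#' block), global average pooling, and a batch-norm / dropout / linear
#' head emitting a single continuous score. Initialisation is seeded.
#'
#' @param config A [regressor_config()].
#' @return Object of class `aac_net`.
#' @export
build_regressor <- function(config = regressor_config()) {
  n_down <- 2L + length(config$stage_blocks) - 1L  # stem conv+pool, stages
  min_dim <- 2^n_down
  if (any(config$input_size < min_dim)) {
    stop(sprintf("input_size too small for %d downsamplings", n_down),
         call. = FALSE)
  }
  set.seed(config$seed)
  blocks <- build_backbone(config)
  C <- utils::tail(config$stage_channels, 1)
  head <- list(gamma = rep(1, C), beta = numeric(C),
               W = matrix(stats::rnorm(C, sd = sqrt(1 / C)), C, 1),
               b = 0)
  params <- list(blocks = lapply(blocks, `[[`, "params"), head = head)
  if (!is.null(config$init_params)) {
    same_shape <- tryCatch({
      ok <- TRUE
      invisible(ptree_map2(function(a, b) {
        if (!identical(dim(a), dim(b)) || length(a) != length(b)) {
          ok <<- FALSE
        }
        a
      }, params, config$init_params))
      ok
    }, error = function(e) FALSE)
    if (!same_shape) {
      stop("init_params does not match this architecture", call. = FALSE)
    }
    params <- config$init_params
  }
  structure(list(
    params = params,
    bn_state = list(mean = numeric(C), var = rep(1, C), n_updates = 0),
    config = config, history = NULL),
    class = "aac_net")
}

#' @export
print.aac_net <- function(x, ...) {
  np <- ptree_count(x$params)
  cat(sprintf(
    "aac_net: %s preset, stages (%s) x (%s), attention %s, %d parameters%s\n",
    x$config$preset,
    paste(x$config$stage_blocks, collapse = ","),
    paste(x$config$stage_channels, collapse = ","),
    if (x$config$attention) "on" else "off", np,
    if (is.null(x$history)) " (untrained)" else ""))
  invisible(x)
}

# forward through backbone + GAP for one sample; returns feature vector
backbone_fw <- function(blocks, bparams, x, train = FALSE) {
  caches <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    r <- blocks[[i]]$fw(bparams[[i]], x, train)
    x <- r$y
    caches[[i]] <- r$cache
  }
  d <- dim(x)
  feat <- colMeans(matrix(x, d[1] * d[2], d[3]))
  list(feat = feat, caches = caches, top_dim = d, top = x)
}

backbone_bw <- function(blocks, bparams, caches, top_dim, dfeat,
                        stop_at = 0L) {
  # gradient of GAP: spread evenly over spatial positions
  n <- top_dim[1] * top_dim[2]
  dy <- array(rep(dfeat / n, each = n), top_dim)
  grads <- vector("list", length(blocks))
  for (i in rev(seq_along(blocks))) {
    if (i <= stop_at) break
    r <- blocks[[i]]$bw(bparams[[i]], caches[[i]], dy)
    dy <- r$dx
    grads[[i]] <- r$grads
  }
  list(dinput = dy, grads = grads)
}

# head forward over a batch of feature vectors (rows = samples)
head_fw <- function(head, feats, bn_state, train, dropout, drop_mask) {
  if (train) {
    mu <- colMeans(feats)
    v <- colMeans(feats^2) - mu^2
  } else {
    mu <- bn_state$mean
    v <- bn_state$var
  }
  istd <- 1 / sqrt(v + 1e-5)
  xhat <- sweep(sweep(feats, 2, mu, "-"), 2, istd, "*")
  z <- sweep(sweep(xhat, 2, head$gamma, "*"), 2, head$beta, "+")
  if (train && dropout > 0) {
    z <- z * drop_mask / (1 - dropout)
  }
  out <- as.numeric(z %*% head$W) + head$b
  list(out = out, cache = list(xhat = xhat, istd = istd, z = z,
                               mu = mu, v = v))
}

head_bw <- function(head, cache, feats, dout, train, dropout, drop_mask) {
  dz <- dout %*% t(head$W)
  dW <- t(cache$z) %*% dout
  db <- sum(dout)
  if (train && dropout > 0) {
    dz <- dz * drop_mask / (1 - dropout)
  }
  dgamma <- colSums(dz * cache$xhat)
  dbeta <- colSums(dz)
  dxhat <- sweep(dz, 2, head$gamma, "*")
  B <- nrow(feats)
  if (train) {
    dfeat <- sweep(
      dxhat - matrix(colMeans(dxhat), B, ncol(feats), byrow = TRUE) -
        cache$xhat * matrix(colMeans(dxhat * cache$xhat), B, ncol(feats),
                            byrow = TRUE),
      2, cache$istd, "*")
  } else {
    dfeat <- sweep(dxhat, 2, cache$istd, "*")
  }
  list(dfeat = dfeat,
       grads = list(gamma = dgamma, beta = dbeta,
                    W = matrix(dW, ncol = 1), b = db))
}

#' Train the AAC score regressor
#'
#' Minimises mean squared error between the network output and the
#' continuous score with SGD (momentum, weight decay) under the
#' warmup + cosine schedule of [lr_at()]. Augmentation, when configured,
#' is applied to the training patches before each epoch; validation loss
#' is evaluated every `val_check_every` epochs and training stops early
#' once it has failed to improve for `patience` consecutive checks (the
#' best-validation parameters are kept).
#'
#' @param train,val Lists with elements `patches` (list of matrices or
#'   `aac_patch`es) and `scores` (numeric in `[0, 24]`).
#' @param rc A [regressor_config()].
#' @param tc A [train_config()].
#' @param verbose Print progress.
#' @return A trained `aac_net`; `$history` holds per-iteration learning
#'   rates and per-epoch losses.
#' @export
train_regressor <- function(train, val, rc = regressor_config(),
                            tc = train_config(), verbose = FALSE) {
  tr_x <- lapply(train$patches, patch_pixels)
  va_x <- lapply(val$patches, patch_pixels)
  tr_y <- as.numeric(train$scores)
  va_y <- as.numeric(val$scores)
  if (!length(tr_x) || !length(va_x)) {
    stop("train and val sets must be non-empty", call. = FALSE)
  }
  if (any(tr_y < 0 | tr_y > 24) || any(va_y < 0 | va_y > 24)) {
    stop("scores must lie in [0, 24]", call. = FALSE)
  }
  model <- build_regressor(rc)
  blocks <- build_backbone_cached(model)
  params <- model$params
  # start the head at the training-score mean so early iterations refine
  # structure rather than the output offset
  params$head$b <- mean(tr_y)
  vel <- ptree_zeros(params)
  bn_state <- model$bn_state
  n <- length(tr_x)
  iters_per_epoch <- ceiling(n / tc$batch_size)
  total_iters <- iters_per_epoch * tc$max_epochs
  iter <- 0L
  best <- list(val = Inf, params = params, bn = bn_state)
  bad_checks <- 0L
  hist <- list()
  set.seed(tc$seed)
  for (epoch in seq_len(tc$max_epochs)) {
    ex <- tr_x
    if (!is.null(tc$augment)) {
      aug_seeds <- sample.int(2^30, n)
      ex <- lapply(seq_len(n), function(i) {
        augment_patch(tr_x[[i]], tc$augment, seed = aug_seeds[i])
      })
    }
    ord <- sample.int(n)
    ep_loss <- 0
    for (bt in split(ord, ceiling(seq_along(ord) / tc$batch_size))) {
      B <- length(bt)
      fw <- lapply(bt, function(i) {
        backbone_fw(blocks$mods, params$blocks, as_map(ex[[i]]), TRUE)
      })
      feats <- do.call(rbind, lapply(fw, `[[`, "feat"))
      drop_mask <- matrix(stats::runif(length(feats)) >= rc$dropout,
                          nrow(feats))
      hf <- head_fw(params$head, feats, bn_state, TRUE, rc$dropout,
                    drop_mask)
      err <- hf$out - tr_y[bt]
      loss <- mean(err^2)
      ep_loss <- ep_loss + loss * B
      dout <- matrix(2 * err / B, ncol = 1)
      hb <- head_bw(params$head, hf$cache, feats, dout, TRUE, rc$dropout,
                    drop_mask)
      gacc <- NULL
      for (j in seq_len(B)) {
        bb <- backbone_bw(blocks$mods, params$blocks, fw[[j]]$caches,
                          fw[[j]]$top_dim, hb$dfeat[j, ])
        gacc <- if (is.null(gacc)) bb$grads else
          ptree_map2(`+`, gacc, bb$grads)
      }
      grads <- list(blocks = gacc, head = hb$grads)
      lr <- lr_at(iter, total_iters, tc)
      st <- sgd_step(params, grads, vel, lr, tc$momentum, tc$weight_decay)
      params <- st$p
      vel <- st$v
      # running batch-norm statistics for inference
      mom <- 0.9
      bn_state$mean <- mom * bn_state$mean + (1 - mom) * hf$cache$mu
      bn_state$var <- mom * bn_state$var + (1 - mom) * hf$cache$v
      bn_state$n_updates <- bn_state$n_updates + 1
      hist[[length(hist) + 1L]] <-
        data.frame(epoch = epoch, iter = iter, lr = lr,
                   train_mse = loss, val_mse = NA_real_)
      iter <- iter + 1L
    }
    if (epoch %% tc$val_check_every == 0L || epoch == tc$max_epochs) {
      preds <- predict_batch(blocks$mods, params, bn_state, va_x)
      val_mse <- mean((preds - va_y)^2)
      hist[[length(hist)]]$val_mse <- val_mse
      if (verbose) {
        message(sprintf("epoch %d iter %d: train %.3f val %.3f lr %.5f",
                        epoch, iter, ep_loss / n, val_mse,
                        lr_at(iter - 1, total_iters, tc)))
      }
      if (!is.na(val_mse) && val_mse < best$val - 1e-8) {
        best <- list(val = val_mse, params = params, bn = bn_state)
        bad_checks <- 0L
      } else {
        bad_checks <- bad_checks + 1L
        if (bad_checks >= tc$patience) break
      }
    }
  }
  model$params <- best$params
  model$bn_state <- best$bn
  model$history <- do.call(rbind, hist)
  model$train_config <- tc
  model$best_val_mse <- best$val
  model
}

patch_pixels <- function(p) if (inherits(p, "aac_patch")) p$pixels else p

# rebuild the module closures for a model (parameters live in the model)
build_backbone_cached <- function(model) {
  set.seed(model$config$seed)
  list(mods = build_backbone(model$config))
}

predict_batch <- function(mods, params, bn_state, xs) {
  feats <- do.call(rbind, lapply(xs, function(x) {
    backbone_fw(mods, params$blocks, as_map(x), FALSE)$feat
  }))
  hf <- head_fw(params$head, feats, bn_state, FALSE, 0, NULL)
  hf$out
}

#' Predict an AAC score for a patch
#'
#' @param model A trained `aac_net`.
#' @param patch An [aac_patch()] or matrix matching the model input size.
#' @param type `"raw"` (continuous network output), `"clamped"` (clamped
#'   to `[0, 24]`), or `"category"` (clamped, rounded half-to-even, then
#'   classified with [classify_severity()]).
#' @return Numeric scalar, or severity factor for `type = "category"`.
#' @export
predict_score <- function(model, patch, type = c("raw", "clamped",
                                                 "category")) {
  type <- match.arg(type)
  px <- patch_pixels(patch)
  if (!identical(dim(px), as.integer(model$config$input_size))) {
    stop(sprintf("patch is %s but model expects %s",
                 paste(dim(px), collapse = "x"),
                 paste(model$config$input_size, collapse = "x")),
         call. = FALSE)
  }
  blocks <- build_backbone_cached(model)
  raw <- predict_batch(blocks$mods, model$params, model$bn_state, list(px))
  switch(type,
         raw = raw,
         clamped = min(24, max(0, raw)),
         category = classify_severity(round(min(24, max(0, raw)))))
}

#' @export
predict.aac_net <- function(object, newdata, type = "raw", ...) {
  if (is.list(newdata) && !inherits(newdata, "aac_patch")) {
    vapply(newdata, function(p) as.numeric(
      predict_score(object, p, if (type == "category") "clamped" else type)),
      numeric(1)) -> out
    if (type == "category") classify_severity(round(out)) else out
  } else {
    predict_score(object, newdata, type)
  }
}

#' @export
plot.aac_net <- function(x, ...) {
  h <- x$history
  if (is.null(h)) stop("model has no training history", call. = FALSE)
  graphics::par(mfrow = c(1, 2))
  graphics::plot(h$iter, h$lr, type = "l", xlab = "iteration",
                 ylab = "learning rate", main = "schedule")
  ep <- stats::aggregate(train_mse ~ epoch, h, mean)
  graphics::plot(ep$epoch, ep$train_mse, type = "l", xlab = "epoch",
                 ylab = "MSE", main = "training loss", log = "y")
  vm <- h[!is.na(h$val_mse), ]
  graphics::points(vm$epoch, vm$val_mse, col = 2, pch = 19)
  invisible(x)
}
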