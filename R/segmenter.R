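#' Segmenter configuration
#'
#' Describes the three-class encoder-decoder segmenter: a residual encoder
#' whose deepest stage runs at 1/16 resolution with dilated (atrous)
#' convolutions instead of a stride, an atrous spatial pyramid pooling
#' (ASPP) head with exactly five parallel branches (a 1x1 convolution,
#' three 3x3 dilated convolutions, and a global-pooling branch) fused by a
#' 1x1 convolution, and a decoder that projects an early 1/4-resolution
#' feature map to `low_level_channels` with a 1x1 convolution, upsamples
#' the ASPP output 4-fold, concatenates, applies a 3x3 convolution, and
#' upsamples 4-fold again to input resolution before a per-pixel softmax
#' over the three classes.
#'
#' Two presets: `"desk"` (stage widths 16/32/64/128, head 64, 96 px input)
#' sized to train on one CPU core, and `"full"` (widths 64/128/256/512,
#' head 256, 320 px input) matching the capacity class of a 50-layer
#' residual encoder for GPU-scale work.
#'
#' @param preset "desk" or "full"; sets defaults for the other arguments.
#' @param backbone_widths channel counts of the four residual stages.
#' @param aspp_rates dilation rates of the four convolutional ASPP branches.
#' @param aspp_global_pool include the global-pooling branch (must be TRUE:
#'   the architecture has exactly five branches).
#' @param low_level_channels decoder projection width (default 48).
#' @param head_channels ASPP/decoder working width.
#' @param num_classes number of classes (must be 3).
#' @param input_size nominal input side in pixels; must be divisible by 16.
#' @param seed weight initialization seed.
#' @return object of class `segmenter_config`.
#' @export
segmenter_config <- function(preset = c("desk", "full"),
                             backbone_widths = NULL,
                             aspp_rates = c(1, 6, 12, 18),
                             aspp_global_pool = TRUE,
                             low_level_channels = 48,
                             head_channels = NULL,
                             num_classes = 3,
                             input_size = NULL, seed = 1) {
  preset <- match.arg(preset)
  if (is.null(backbone_widths)) {
    backbone_widths <- if (preset == "desk") c(16, 32, 64, 128)
                       else c(64, 128, 256, 512)
  }
  if (is.null(head_channels)) {
    head_channels <- if (preset == "desk") 64 else 256
  }
  if (is.null(input_size)) input_size <- if (preset == "desk") 96 else 320
  if (num_classes != 3) stop("the segmenter is a three-class model")
  if (length(aspp_rates) != 4 || !isTRUE(aspp_global_pool)) {
    stop("ASPP must have exactly 5 branches: 4 convolutional + 1 pooled")
  }
  if (length(backbone_widths) != 4) stop("need 4 backbone stage widths")
  if (input_size %% 16 != 0) {
    stop("input_size must be divisible by 16 (two 4-fold decoder upsamplings)")
  }
  structure(list(preset = preset, backbone_widths = backbone_widths,
                 aspp_rates = aspp_rates, aspp_global_pool = TRUE,
                 low_level_channels = low_level_channels,
                 head_channels = head_channels, num_classes = 3L,
                 input_size = as.integer(input_size),
                 seed = as.integer(seed)), class = "segmenter_config")
}

# residual block: conv-bn-relu, conv-bn, (+ projected skip), relu
add_res_block <- function(net, inp, cin, cout, stride, dilation, name) {
  r1 <- add_cbr(net, inp, cin, cout, 3, stride, dilation, paste0(name, ".c1"))
  c2 <- add_conv(net, r1, cout, cout, 3, 1, dilation, paste0(name, ".c2"))
  b2 <- add_bn(net, c2, cout, paste0(name, ".c2.bn"))
  skip <- if (stride != 1 || cin != cout) {
    sc <- add_conv(net, inp, cin, cout, 1, stride, 1, paste0(name, ".sk"))
    add_bn(net, sc, cout, paste0(name, ".sk.bn"))
  } else inp
  add_relu(net, add_add(net, b2, skip))
}

#' Build the encoder-decoder ASPP segmenter
#'
#' @param config a `segmenter_config`.
#' @return object of class `segmenter`: the network environment plus the
#'   config. The network is fully convolutional; it accepts any input whose
#'   sides are divisible by 16.
#' @export
build_segmenter <- function(config = segmenter_config()) {
  stopifnot(inherits(config, "segmenter_config"))
  w <- config$backbone_widths
  hc <- config$head_channels
  net <- nn_new(config$seed)
  set.seed(config$seed)

  x <- add_op(net, "input")
  s1 <- add_cbr(net, x, 3, w[1], 3, 2, 1, "stem1")          # 1/2
  low <- add_cbr(net, s1, w[1], w[1], 3, 2, 1, "stem2")     # 1/4 (low-level)
  e2 <- add_res_block(net, low, w[1], w[2], 2, 1, "stage2") # 1/8
  e3 <- add_res_block(net, e2, w[2], w[3], 2, 1, "stage3")  # 1/16
  e4 <- add_res_block(net, e3, w[3], w[4], 1, 2, "stage4")  # 1/16, dilated

  rates <- config$aspp_rates
  a1 <- add_cbr(net, e4, w[4], hc, 1, 1, 1, "aspp1")
  a2 <- add_cbr(net, e4, w[4], hc, 3, 1, rates[2], "aspp2")
  a3 <- add_cbr(net, e4, w[4], hc, 3, 1, rates[3], "aspp3")
  a4 <- add_cbr(net, e4, w[4], hc, 3, 1, rates[4], "aspp4")
  gp <- add_gpool(net, e4)
  gc <- add_conv(net, gp, w[4], hc, 1, 1, 1, "aspp5")
  gr <- add_relu(net, gc)
  a5 <- add_broadcast(net, gr, e4)
  cat5 <- add_concat(net, c(a1, a2, a3, a4, a5))
  fuse <- add_cbr(net, cat5, 5 * hc, hc, 1, 1, 1, "asppf")

  lowp <- add_cbr(net, low, w[1], config$low_level_channels, 1, 1, 1, "lowp")
  up1 <- add_upsample(net, fuse, 4, "up1")
  dcat <- add_concat(net, c(lowp, up1))
  dconv <- add_cbr(net, dcat, config$low_level_channels + hc, hc, 3, 1, 1,
                   "dec")
  cls <- add_conv(net, dconv, hc, config$num_classes, 1, 1, 1, "cls")
  out <- add_upsample(net, cls, 4, "up2")

  structure(list(net = net, config = config, output_id = out),
            class = "segmenter")
}

#' Number of trainable parameters of a segmenter
#' @param segmenter a `segmenter` (or `trained_segmenter`).
#' @return integer parameter count.
#' @export
n_parameters <- function(segmenter) {
  if (inherits(segmenter, "trained_segmenter")) segmenter <- segmenter$model
  sum(vapply(segmenter$net$params, length, integer(1)))
}

# rgb (HxWx3, 0-255) -> C x (H*W) input matrix in roughly [-0.5, 0.5]
rgb_to_input <- function(rgb) {
  H <- dim(rgb)[1]; W <- dim(rgb)[2]
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3) {
    stop("image must have 3 channels")
  }
  t(matrix(as.numeric(rgb), H * W, 3)) / 255 - 0.5
}

# stack a list of equally sized rgb tiles into one input value
tiles_to_value <- function(rgbs) {
  H <- dim(rgbs[[1]])[1]; W <- dim(rgbs[[1]])[2]
  list(x = do.call(cbind, lapply(rgbs, rgb_to_input)),
       H = H, W = W, B = length(rgbs))
}

# forward pass returning class probabilities (3 x H*W*B)
segmenter_probs <- function(segmenter, value, train = FALSE) {
  fw <- nn_forward(segmenter$net, value, train = train)
  logits <- fw$vals[[segmenter$output_id]]
  list(probs = softmax_probs(logits$x), logits = logits, fw = fw)
}

#' Training configuration
#'
#' @param epochs number of passes over the training tiles (>= 1).
#' @param batch_size tiles per optimization step.
#' @param learning_rate Adam learning rate.
#' @param seed shuffling/initialization seed, recorded in the history.
#' @param augment_flip random horizontal flips during training.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 20, batch_size = 8, learning_rate = 1e-3,
                         seed = 1, augment_flip = FALSE) {
  if (epochs < 1) stop("epochs must be >= 1")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 augment_flip = isTRUE(augment_flip)),
            class = "train_config")
}

#' Train the segmenter by per-pixel cross-entropy
#'
#' Minimizes mean per-pixel cross-entropy with Adam, records per-epoch
#' training loss and validation MIoU, and returns the checkpoint with the
#' best validation MIoU. Fully reproducible for a fixed seed on a fixed
#' thread configuration.
#'
#' @param segmenter a `segmenter` from [build_segmenter()].
#' @param train_tiles,val_tiles `tile_set`s whose tiles carry `rgb` and
#'   `mask` (labels 0/1/2).
#' @param tconfig a `train_config`.
#' @param verbose print per-epoch progress.
#' @return object of class `trained_segmenter`: list(model, history,
#'   train_config, best_epoch).
#' @export
train_segmenter <- function(segmenter, train_tiles, val_tiles,
                            tconfig = train_config(), verbose = FALSE) {
  stopifnot(inherits(segmenter, "segmenter"))
  tiles <- train_tiles$tiles
  if (length(tiles) == 0) stop("empty training tile set")
  for (tl in c(tiles, val_tiles$tiles)) {
    labs <- unique(as.integer(tl$mask))
    if (any(!labs %in% 0:2)) {
      stop("mask labels outside {0, 1, 2}")
    }
  }
  net <- segmenter$net
  opt <- adam_new(net$params, lr = tconfig$learning_rate)
  set.seed(tconfig$seed)
  n <- length(tiles)
  # precompute per-tile input matrices and label vectors once
  xin <- lapply(tiles, function(tl) rgb_to_input(tl$rgb))
  lab <- lapply(tiles, function(tl) as.integer(tl$mask))
  th <- dim(tiles[[1]]$rgb)[1]; tw <- dim(tiles[[1]]$rgb)[2]
  flip_idx <- rep((rev(seq_len(tw)) - 1L) * th, each = th) + seq_len(th)
  vxin <- lapply(val_tiles$tiles, function(tl) rgb_to_input(tl$rgb))
  vlab <- lapply(val_tiles$tiles, function(tl) as.integer(tl$mask))
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_miou = numeric(0))
  best <- list(miou = -Inf, params = NULL, state = NULL, epoch = 0L)
  for (ep in seq_len(tconfig$epochs)) {
    perm <- sample.int(n)
    losses <- numeric(0)
    i <- 1L
    while (i <= n) {
      idx <- perm[i:min(i + tconfig$batch_size - 1L, n)]
      bx <- xin[idx]
      bl <- lab[idx]
      if (tconfig$augment_flip) {
        flip <- stats::runif(length(idx)) < 0.5
        for (k in which(flip)) {
          bx[[k]] <- bx[[k]][, flip_idx, drop = FALSE]
          bl[[k]] <- bl[[k]][flip_idx]
        }
      }
      value <- list(x = do.call(cbind, bx), H = th, W = tw, B = length(idx))
      labels <- unlist(bl)
      fw <- nn_forward(net, value, train = TRUE)
      logits <- fw$vals[[segmenter$output_id]]
      ce <- softmax_ce(logits$x, labels)
      losses <- c(losses, ce$loss)
      grads <- nn_backward(net, fw, list(x = ce$dlogits, H = logits$H,
                                         W = logits$W, B = logits$B))
      st <- adam_step(opt, net$params, grads)
      opt <- st$opt
      net$params <- st$params
      i <- i + tconfig$batch_size
    }
    vm <- miou_precomputed(segmenter, vxin, vlab, th, tw,
                           tconfig$batch_size)
    history <- rbind(history, data.frame(epoch = ep,
                                         train_loss = mean(losses),
                                         val_miou = vm))
    if (!is.na(vm) && vm > best$miou) {
      best <- list(miou = vm, params = net$params, state = net$state,
                   epoch = ep)
    }
    if (verbose) {
      message(sprintf("epoch %d | loss %.4f | val MIoU %.4f",
                      ep, mean(losses), vm))
    }
  }
  if (!is.null(best$params)) {
    net$params <- best$params
    net$state <- best$state
  }
  structure(list(model = segmenter, history = history,
                 train_config = tconfig, best_epoch = best$epoch),
            class = "trained_segmenter")
}

# pooled MIoU of predictions over a tile set
validation_miou <- function(segmenter, tileset, batch_size = 8) {
  tiles <- tileset$tiles
  if (length(tiles) == 0) return(NA_real_)
  xin <- lapply(tiles, function(tl) rgb_to_input(tl$rgb))
  lab <- lapply(tiles, function(tl) as.integer(tl$mask))
  miou_precomputed(segmenter, xin, lab, dim(tiles[[1]]$rgb)[1],
                   dim(tiles[[1]]$rgb)[2], batch_size)
}

miou_precomputed <- function(segmenter, xin, lab, th, tw, batch_size = 8) {
  if (length(xin) == 0) return(NA_real_)
  tensor <- matrix(0, 3, 3)
  i <- 1L
  while (i <= length(xin)) {
    idx <- i:min(i + batch_size - 1L, length(xin))
    value <- list(x = do.call(cbind, xin[idx]), H = th, W = tw,
                  B = length(idx))
    pr <- segmenter_probs(segmenter, value, train = FALSE)
    pred <- max.col(t(pr$probs), ties.method = "first") - 1L
    truth <- unlist(lab[idx])
    tensor <- tensor + unclass(confusion_counts(pred, truth, k = 3))
    i <- i + batch_size
  }
  class(tensor) <- c("confusion_tensor", class(tensor))
  iou_and_miou(tensor)$miou
}

#' Predict a label mask for an image
#'
#' Per-pixel argmax of the class probabilities; exact probability ties are
#' broken toward the lowest class index (soil < wheat < weed). Images whose
#' sides are divisible by 16 are processed whole; larger or ragged images
#' are processed in `input_size` chunks on an overlap-free grid (border
#' chunks are aligned to the image edge) and reassembled by provenance.
#'
#' @param trained a `trained_segmenter` (or an untrained `segmenter`).
#' @param image HxWx3 array, values 0-255.
#' @return HxW integer matrix of labels 0/1/2.
#' @export
infer_mask <- function(trained, image) {
  segmenter <- if (inherits(trained, "trained_segmenter")) trained$model
               else trained
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3) stop("image must have 3 channels")
  H <- d[1]; W <- d[2]
  s <- segmenter$config$input_size
  predict_block <- function(rgb) {
    value <- tiles_to_value(list(rgb))
    pr <- segmenter_probs(segmenter, value, train = FALSE)
    matrix(max.col(t(pr$probs), ties.method = "first") - 1L,
           dim(rgb)[1], dim(rgb)[2])
  }
  if (H %% 16 == 0 && W %% 16 == 0 && H <= 2 * s && W <= 2 * s) {
    return(predict_block(image))
  }
  if (H < s || W < s) {
    stop(sprintf("image sides must be at least %d px (or divisible by 16)", s))
  }
  starts <- function(total) {
    st <- seq(0L, total - s, by = s)
    if (max(st) + s < total) st <- c(st, total - s)
    st
  }
  out <- matrix(NA_integer_, H, W)
  for (r0 in starts(H)) {
    for (c0 in starts(W)) {
      blk <- image[r0 + seq_len(s), c0 + seq_len(s), , drop = FALSE]
      out[r0 + seq_len(s), c0 + seq_len(s)] <- predict_block(blk)
    }
  }
  out
}

#' Save and load segmenter checkpoints
#'
#' The checkpoint embeds the architecture configuration (including its
#' initialization seed), the trained parameters, the batch-norm running
#' statistics, and the training history, so a reloaded model reproduces
#' predictions exactly.
#'
#' @param trained a `trained_segmenter` (or bare `segmenter`).
#' @param path checkpoint file path (RDS).
#' @export
save_segmenter <- function(trained, path) {
  segmenter <- if (inherits(trained, "trained_segmenter")) trained$model
               else trained
  obj <- list(config = segmenter$config,
              params = segmenter$net$params,
              state = segmenter$net$state,
              history = if (inherits(trained, "trained_segmenter"))
                trained$history else NULL,
              train_config = if (inherits(trained, "trained_segmenter"))
                trained$train_config else NULL)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_segmenter
#' @export
load_segmenter <- function(path) {
  obj <- readRDS(path)
  segmenter <- build_segmenter(obj$config)
  segmenter$net$params <- obj$params
  segmenter$net$state <- obj$state
  if (is.null(obj$history)) return(segmenter)
  structure(list(model = segmenter, history = obj$history,
                 train_config = obj$train_config,
                 best_epoch = obj$history$epoch[
                   which.max(obj$history$val_miou)]),
            class = "trained_segmenter")
}
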