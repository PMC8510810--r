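#' @title Wavelet U-shaped segmentation network
#' @name segnet
#' @description
#' A U-shaped fully convolutional network whose down- and up-sampling
#' operators are the discrete wavelet transform and its inverse: the encoder
#' applies a 4-layer conv/BN/ReLU block then a DWT at each level (the four
#' subbands stacked channel-wise), the decoder mirrors it with the IWT, with
#' channel-wise skip concatenation between same-level stages, ending in a
#' K-channel 1x1 projection. Trained with pixelwise softmax cross entropy.
NULL

#' Segmentation network configuration
#'
#' @param levels number of DWT stages (default 3).
#' @param channels integer vector of per-level feature widths, length
#'   `levels` (default `c(32, 64, 128)` truncated/recycled to `levels`).
#' @param block_depth conv layers per CNN block; the architecture fixes 4 —
#'   other values are accepted with a warning.
#' @param kernel spatial kernel size (3).
#' @param classes number of output classes K (default 2: background,
#'   mitosis).
#' @param wavelet_name wavelet filter identifier (default "haar").
#' @param in_channels input image channels (3 for RGB).
#' @param seed integer RNG seed for weight initialization.
#' @return a `segnet_config` list.
#' @export
segnet_config <- function(levels = 3L, channels = NULL, block_depth = 4L,
                          kernel = 3L, classes = 2L, wavelet_name = "haar",
                          in_channels = 3L, seed = 1L) {
  levels <- as.integer(levels)
  if (levels < 1L) stop("`levels` must be >= 1")
  if (is.null(channels)) channels <- c(32L, 64L, 128L)[seq_len(min(levels, 3L))]
  if (length(channels) < levels) {
    channels <- c(channels, rep(channels[length(channels)],
                                levels - length(channels)))
  }
  if (length(channels) != levels) {
    stop("`channels` must have one entry per level (", levels,
         "), got ", length(channels))
  }
  if (block_depth != 4L) {
    warning("block_depth = ", block_depth,
            " deviates from the 4-layer FCN block of the architecture")
  }
  if (classes < 2L) stop("`classes` must be >= 2")
  wavelet_lowpass(wavelet_name)  # validate name early
  structure(list(levels = levels, channels = as.integer(channels),
                 block_depth = as.integer(block_depth),
                 kernel = as.integer(kernel), classes = as.integer(classes),
                 wavelet_name = wavelet_name,
                 in_channels = as.integer(in_channels),
                 seed = as.integer(seed)),
            class = "segnet_config")
}

#' Build the segmentation network
#'
#' Instantiates all layers with seeded He initialization. The same config and
#' seed always produce bit-identical initial parameters.
#'
#' @param config a [segnet_config()].
#' @return an object of class `mito_segnet` (untrained).
#' @export
build_segnet <- function(config) {
  if (!inherits(config, "segnet_config")) config <- do.call(segnet_config, config)
  set.seed(config$seed)
  L <- config$levels
  ch <- config$channels
  k <- config$kernel
  d <- config$block_depth
  enc <- vector("list", L)
  enc[[1]] <- nn_block(config$in_channels, ch[1], d, k)
  if (L > 1) for (l in 2:L) enc[[l]] <- nn_block(4L * ch[l - 1L], ch[l], d, k)
  bottom <- nn_block(4L * ch[L], 4L * ch[L], d, k)
  dec <- vector("list", L)
  for (l in L:1) {
    cout <- if (l > 1) 4L * ch[l - 1L] else ch[1]
    dec[[l]] <- nn_block(2L * ch[l], cout, d, k)
  }
  head <- nn_layer_conv(1L, ch[1], config$classes, bias = TRUE)
  structure(list(config = config,
                 blocks = list(enc = enc, bottom = bottom, dec = dec,
                               head = list(head))),
            class = "mito_segnet")
}

#' @export
print.mito_segnet <- function(x, ...) {
  cfg <- x$config
  cat("<mito_segnet> levels:", cfg$levels,
      " channels:", paste(cfg$channels, collapse = "/"),
      " K:", cfg$classes,
      " wavelet:", cfg$wavelet_name,
      " params:", segnet_n_params(x), "\n")
  if (!is.null(x$history)) {
    cat("  trained", nrow(x$history), "epochs; final mean loss",
        signif(x$history$loss[nrow(x$history)], 4), "\n")
  }
  invisible(x)
}

#' Number of learnable parameters of a segmentation network
#' @param model a `mito_segnet`.
#' @return integer parameter count.
#' @export
segnet_n_params <- function(model) nn_count_params(model$blocks)

# forward pass on an (H, W, N, C) tensor; H, W must be multiples of 2^levels.
segnet_forward <- function(model, x, train = FALSE) {
  cfg <- model$config
  L <- cfg$levels
  wv <- cfg$wavelet_name
  b <- model$blocks
  skips <- vector("list", L)
  caches <- list(enc = vector("list", L), dec = vector("list", L))
  for (l in seq_len(L)) {
    r <- nn_seq_forward(b$enc[[l]], x, train)
    b$enc[[l]] <- r$layers
    caches$enc[[l]] <- r$caches
    skips[[l]] <- r$y
    x <- dwt2_stack(r$y, wv)
  }
  r <- nn_seq_forward(b$bottom, x, train)
  b$bottom <- r$layers
  caches$bottom <- r$caches
  x <- r$y
  for (l in L:1) {
    up <- iwt2_stack(x, wv)
    d <- dim(up)
    cat_in <- array(0, c(d[1], d[2], d[3], d[4] + dim(skips[[l]])[4]))
    cat_in[, , , seq_len(d[4])] <- up
    cat_in[, , , (d[4] + 1):(d[4] + dim(skips[[l]])[4])] <- skips[[l]]
    r <- nn_seq_forward(b$dec[[l]], cat_in, train)
    b$dec[[l]] <- r$layers
    caches$dec[[l]] <- r$caches
    caches$split[[l]] <- d[4]
    x <- r$y
  }
  r <- nn_seq_forward(b$head, x, train)
  b$head <- r$layers
  caches$head <- r$caches
  model$blocks <- b
  list(logits = r$y, caches = caches, model = model)
}

segnet_backward <- function(model, caches, dlogits) {
  cfg <- model$config
  L <- cfg$levels
  wv <- cfg$wavelet_name
  b <- model$blocks
  grads <- list(enc = vector("list", L), dec = vector("list", L))
  r <- nn_seq_backward(b$head, caches$head, dlogits)
  grads$head <- r$grads
  dy <- r$dx
  dskips <- vector("list", L)
  for (l in seq_len(L)) {
    r <- nn_seq_backward(b$dec[[l]], caches$dec[[l]], dy)
    grads$dec[[l]] <- r$grads
    nup <- caches$split[[l]]
    d <- dim(r$dx)
    dup <- r$dx[, , , seq_len(nup), drop = FALSE]
    dskips[[l]] <- r$dx[, , , (nup + 1):d[4], drop = FALSE]
    # adjoint of the orthonormal IWT is the DWT
    dy <- dwt2_stack(dup, wv)
  }
  r <- nn_seq_backward(b$bottom, caches$bottom, dy)
  grads$bottom <- r$grads
  dy <- r$dx
  for (l in L:1) {
    denc_out <- iwt2_stack(dy, wv) + dskips[[l]]
    r <- nn_seq_backward(b$enc[[l]], caches$enc[[l]], denc_out)
    grads$enc[[l]] <- r$grads
    dy <- r$dx
  }
  grads
}

#' Pixelwise softmax
#'
#' Converts a per-pixel activation array a_k(x) into class probabilities
#' p_k(x) = exp(a_k(x)) / sum_k' exp(a_k'(x)), numerically stabilized by
#' subtracting the per-pixel maximum (the softmax is shift-invariant).
#'
#' @param activations numeric `(H, W, K)` array of pre-softmax activations.
#' @return a `probability_map`: list with `probs` (`(H, W, K)`, rows sum to 1
#'   per pixel) and `activations`.
#' @examples
#' pm <- softmax_pixelwise(array(0, c(2, 2, 2)))
#' pm$probs[1, 1, ]  # 0.5 0.5
#' @export
softmax_pixelwise <- function(activations) {
  if (any(is.na(activations))) stop("activations contain NaN/NA")
  d <- dim(activations)
  if (length(d) != 3L) stop("`activations` must be an (H, W, K) array")
  a <- matrix(activations, d[1] * d[2], d[3])
  mx <- apply(a, 1, max)
  ex <- exp(a - mx)
  p <- ex / rowSums(ex)
  probability_map(array(p, d), activations)
}

probability_map <- function(probs, activations = NULL) {
  structure(list(probs = probs, activations = activations),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  d <- dim(x$probs)
  cat("<probability_map>", d[1], "x", d[2], "pixels,", d[3], "classes\n")
  invisible(x)
}

#' Pixelwise cross-entropy loss
#'
#' E = -sum_x log p_l(x)(x), the negative log-probability of the true class
#' summed over pixels. Non-negative; zero iff every true-class probability
#' is 1.
#'
#' @param probmap a [probability_map][softmax_pixelwise()] or an `(H, W, K)`
#'   probability array.
#' @param labels integer `(H, W)` matrix of true class indices in `[0, K)`
#'   (0 = background, 1 = mitosis).
#' @return scalar loss.
#' @examples
#' p <- array(0.5, c(4, 4, 2))
#' pixelwise_cross_entropy(p, matrix(0L, 4, 4))  # 16 * log(2)
#' @export
pixelwise_cross_entropy <- function(probmap, labels) {
  probs <- if (inherits(probmap, "probability_map")) probmap$probs else probmap
  d <- dim(probs)
  if (!all(dim(labels) == d[1:2])) {
    stop("label map shape ", paste(dim(labels), collapse = "x"),
         " does not match probability map ", paste(d[1:2], collapse = "x"))
  }
  K <- d[3]
  if (any(labels < 0L | labels >= K)) {
    stop("labels must lie in [0, ", K, ")")
  }
  pm <- matrix(probs, d[1] * d[2], K)
  idx <- cbind(seq_len(d[1] * d[2]), as.integer(labels) + 1L)
  -sum(log(pmax(pm[idx], 1e-300)))
}

#' Training configuration
#'
#' Defaults follow the published schedule: Adam, batch size 8, 100 epochs,
#' learning rate decayed log-linearly from 1e-3 (first epoch) to 1e-6 (last).
#'
#' @param epochs number of passes over the training tiles.
#' @param batch_size tiles per minibatch.
#' @param lr_start,lr_end learning-rate endpoints of the log-linear decay.
#' @param seed RNG seed for shuffling.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 100L, batch_size = 8L,
                         lr_start = 1e-3, lr_end = 1e-6, seed = 1L) {
  if (epochs < 1L) stop("`epochs` must be >= 1")
  if (!(lr_start >= lr_end && lr_end > 0)) {
    stop("need lr_start >= lr_end > 0")
  }
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 optimizer = "adam", lr_start = lr_start, lr_end = lr_end,
                 seed = as.integer(seed)),
            class = "train_config")
}

# stack a list of (H,W,C) tiles into an (H,W,N,C) tensor
stack_tiles <- function(tiles) {
  d <- dim(tiles[[1]])
  if (length(d) == 2L) d <- c(d, 1L)
  x <- array(0, c(d[1], d[2], length(tiles), d[3]))
  for (i in seq_along(tiles)) x[, , i, ] <- tiles[[i]]
  x
}

#' Train the segmentation network
#'
#' Minimizes mean pixelwise cross entropy with Adam under the log-linear
#' learning-rate schedule. Fully reproducible under fixed seeds.
#'
#' @param tiles list of `(H, W, 3)` arrays with values in `[0, 1]`.
#' @param masks list of `(H, W)` 0/1 integer matrices (1 = mitosis).
#' @param cfg a [train_config()].
#' @param net_cfg a [segnet_config()]; `levels` must divide the tile size
#'   (tiles are used as-is during training).
#' @return a trained `mito_segnet` with a `history` tibble
#'   (epoch, loss, lr); `loss` is the mean per-pixel cross entropy.
#' @export
train_segmentation <- function(tiles, masks, cfg = train_config(),
                               net_cfg = segnet_config()) {
  if (length(tiles) == 0L) stop("empty training set: no tiles supplied")
  if (length(tiles) != length(masks)) {
    stop("got ", length(tiles), " tiles but ", length(masks), " masks")
  }
  for (i in seq_along(tiles)) {
    if (!all(dim(tiles[[i]])[1:2] == dim(masks[[i]])[1:2])) {
      stop("tile/mask shape mismatch at index ", i)
    }
  }
  model <- build_segnet(net_cfg)
  K <- model$config$classes
  opt <- nn_adam_init(model$blocks)
  set.seed(cfg$seed)
  n <- length(tiles)
  history <- data.frame(epoch = integer(0), loss = numeric(0), lr = numeric(0))
  t_step <- 0L
  for (ep in seq_len(cfg$epochs)) {
    lr <- nn_lr_schedule(ep, cfg$epochs, cfg$lr_start, cfg$lr_end)
    ord <- sample.int(n)
    ep_loss <- 0
    ep_pix <- 0
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      x <- stack_tiles(tiles[idx])
      fw <- segnet_forward(model, x, train = TRUE)
      model <- fw$model
      d <- dim(fw$logits)
      logits <- fw$logits; dim(logits) <- c(d[1] * d[2] * d[3], d[4])
      # logits rows run (H, W, N) column-major = pixel-major, tile slowest;
      # concatenated column-major masks give the same order
      lab <- unlist(lapply(masks[idx], function(m) as.integer(m))) + 1L
      ce <- nn_softmax_ce(logits, lab)
      npix <- nrow(logits)
      dlogits <- ce$dlogits / npix
      dim(dlogits) <- d
      grads <- segnet_backward(model, fw$caches, dlogits)
      t_step <- t_step + 1L
      upd <- nn_adam_step(model$blocks, grads, opt, lr, t_step)
      model$blocks <- upd$layers
      opt <- upd$state
      ep_loss <- ep_loss + ce$loss
      ep_pix <- ep_pix + npix
    }
    history <- rbind(history,
                     data.frame(epoch = ep, loss = ep_loss / ep_pix, lr = lr))
  }
  model$history <- tibble::as_tibble(history)
  model$train_cfg <- cfg
  model
}

# reflect-pad an (H, W, C) tile on the bottom/right to multiples of 2^levels
pad_to_multiple <- function(tile, mult) {
  d <- dim(tile)
  ph <- (mult - d[1] %% mult) %% mult
  pw <- (mult - d[2] %% mult) %% mult
  if (ph == 0L && pw == 0L) return(list(tile = tile, ph = 0L, pw = 0L))
  ridx <- c(seq_len(d[1]), pmax(1L, d[1] - seq_len(ph)))
  cidx <- c(seq_len(d[2]), pmax(1L, d[2] - seq_len(pw)))
  list(tile = tile[ridx, cidx, , drop = FALSE], ph = ph, pw = pw)
}

#' Predict a per-pixel probability map
#'
#' Runs the network in inference mode (batch-norm running statistics). Inputs
#' whose spatial size is not a multiple of `2^levels` are reflect-padded
#' internally and the output cropped back, so the map's spatial shape always
#' equals the input's.
#'
#' @param model a trained (or freshly built) `mito_segnet`.
#' @param tile `(H, W, 3)` array in `[0, 1]`.
#' @return a [probability_map][softmax_pixelwise()] of shape `(H, W, K)`.
#' @export
predict_probmap <- function(model, tile) {
  cfg <- model$config
  if (length(dim(tile)) == 2L) dim(tile) <- c(dim(tile), 1L)
  if (dim(tile)[3] != cfg$in_channels) {
    stop("tile has ", dim(tile)[3], " channels; model expects ",
         cfg$in_channels)
  }
  d0 <- dim(tile)
  p <- pad_to_multiple(tile, 2L^cfg$levels)
  x <- p$tile
  dim(x) <- c(dim(x)[1], dim(x)[2], 1L, dim(x)[3])
  fw <- segnet_forward(model, x, train = FALSE)
  logits <- fw$logits[seq_len(d0[1]), seq_len(d0[2]), 1L, , drop = TRUE]
  dim(logits) <- c(d0[1], d0[2], cfg$classes)
  softmax_pixelwise(logits)
}

#' Dice coefficient of two binary masks
#' @param pred,truth 0/1 matrices of equal shape.
#' @return 2|A∩B| / (|A|+|B|); 1 when both masks are empty.
#' @export
dice_coefficient <- function(pred, truth) {
  a <- sum(pred > 0); b <- sum(truth > 0)
  if (a + b == 0) return(1)
  2 * sum(pred > 0 & truth > 0) / (a + b)
}
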