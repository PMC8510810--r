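# Minimal CNN engine: conv / batch-norm / ReLU / pooling layers with manual
# backpropagation and an Adam optimizer, on base-R matrix algebra.
#
# Tensor layout throughout: (H, W, N, C) — spatial dims first so a shifted
# window slice reshapes to an (H*W*N) x C matrix with no permutation.

nn_layer_conv <- function(k, cin, cout, bias = FALSE) {
  # He initialization; draws consumed from the current RNG stream so a model
  # built under set.seed() is reproducible.
  sd <- sqrt(2 / (k * k * cin))
  W <- array(stats::rnorm(k * k * cin * cout, sd = sd), c(k, k, cin, cout))
  l <- list(type = "conv", k = k, cin = cin, cout = cout, W = W)
  if (bias) l$b <- numeric(cout)
  l
}

nn_layer_bn <- function(C, momentum = 0.1, eps = 1e-5) {
  list(type = "bn", C = C, gamma = rep(1, C), beta = rep(0, C),
       running_mean = rep(0, C), running_var = rep(1, C),
       momentum = momentum, eps = eps)
}

nn_layer_relu <- function() list(type = "relu")
nn_layer_pool2 <- function() list(type = "pool2")

nn_pad_zero <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3], d[4]))
  xp[(p + 1):(p + d[1]), (p + 1):(p + d[2]), , ] <- x
  xp
}

nn_forward_conv <- function(layer, x) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  k <- layer$k
  p <- (k - 1L) %/% 2L
  xp <- nn_pad_zero(x, p)
  y <- matrix(0, H * W * N, layer$cout)
  for (di in seq_len(k)) {
    for (dj in seq_len(k)) {
      Xs <- xp[di:(di + H - 1L), dj:(dj + W - 1L), , , drop = FALSE]
      dim(Xs) <- c(H * W * N, C)
      Wm <- matrix(layer$W[di, dj, , ], C, layer$cout)
      y <- y + Xs %*% Wm
    }
  }
  if (!is.null(layer$b)) y <- sweep(y, 2, layer$b, "+")
  dim(y) <- c(H, W, N, layer$cout)
  list(y = y, cache = list(xp = xp, H = H, W = W, N = N, C = C))
}

nn_backward_conv <- function(layer, cache, dy) {
  H <- cache$H; W <- cache$W; N <- cache$N; C <- cache$C
  k <- layer$k
  p <- (k - 1L) %/% 2L
  xp <- cache$xp
  dym <- dy; dim(dym) <- c(H * W * N, layer$cout)
  dW <- array(0, dim(layer$W))
  dxp <- array(0, dim(xp))
  for (di in seq_len(k)) {
    for (dj in seq_len(k)) {
      Xs <- xp[di:(di + H - 1L), dj:(dj + W - 1L), , , drop = FALSE]
      dim(Xs) <- c(H * W * N, C)
      dW[di, dj, , ] <- crossprod(Xs, dym)
      Wm <- matrix(layer$W[di, dj, , ], C, layer$cout)
      dxs <- dym %*% t(Wm)
      dim(dxs) <- c(H, W, N, C)
      dxp[di:(di + H - 1L), dj:(dj + W - 1L), , ] <-
        dxp[di:(di + H - 1L), dj:(dj + W - 1L), , , drop = FALSE] + dxs
    }
  }
  dx <- dxp[(p + 1):(p + H), (p + 1):(p + W), , , drop = FALSE]
  g <- list(W = dW)
  if (!is.null(layer$b)) g$b <- colSums(dym)
  list(dx = dx, grads = g)
}

nn_forward_bn <- function(layer, x, train) {
  d <- dim(x)
  m <- d[1] * d[2] * d[3]
  xm <- x; dim(xm) <- c(m, d[4])
  if (train) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2, mu)
    v <- colMeans(xc^2)
    invstd <- 1 / sqrt(v + layer$eps)
    xhat <- sweep(xc, 2, invstd, "*")
    layer$running_mean <- (1 - layer$momentum) * layer$running_mean + layer$momentum * mu
    layer$running_var <- (1 - layer$momentum) * layer$running_var + layer$momentum * v
    cache <- list(xhat = xhat, invstd = invstd, m = m, d = d)
  } else {
    invstd <- 1 / sqrt(layer$running_var + layer$eps)
    xhat <- sweep(sweep(xm, 2, layer$running_mean), 2, invstd, "*")
    cache <- NULL
  }
  y <- sweep(sweep(xhat, 2, layer$gamma, "*"), 2, layer$beta, "+")
  dim(y) <- d
  list(y = y, cache = cache, layer = layer)
}

nn_backward_bn <- function(layer, cache, dy) {
  d <- cache$d
  m <- cache$m
  dym <- dy; dim(dym) <- c(m, d[4])
  xhat <- cache$xhat
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, layer$gamma, "*")
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dx <- m * dxhat -
    matrix(s1, m, d[4], byrow = TRUE) -
    xhat * matrix(s2, m, d[4], byrow = TRUE)
  dx <- sweep(dx, 2, cache$invstd / m, "*")
  dim(dx) <- d
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

nn_forward_pool2 <- function(x) {
  d <- dim(x)
  ri <- seq(1L, d[1], 2L); ci <- seq(1L, d[2], 2L)
  y <- (x[ri, ci, , , drop = FALSE] + x[ri + 1L, ci, , , drop = FALSE] +
        x[ri, ci + 1L, , , drop = FALSE] + x[ri + 1L, ci + 1L, , , drop = FALSE]) / 4
  list(y = y, cache = d)
}

nn_backward_pool2 <- function(cache, dy) {
  d <- cache
  dx <- array(0, d)
  ri <- seq(1L, d[1], 2L); ci <- seq(1L, d[2], 2L)
  g <- dy / 4
  dx[ri, ci, , ] <- g
  dx[ri + 1L, ci, , ] <- g
  dx[ri, ci + 1L, , ] <- g
  dx[ri + 1L, ci + 1L, , ] <- g
  dx
}

# sequential container -------------------------------------------------------

nn_block <- function(cin, cout, depth, k = 3L) {
  layers <- list()
  cprev <- cin
  for (i in seq_len(depth)) {
    layers[[length(layers) + 1L]] <- nn_layer_conv(k, cprev, cout)
    layers[[length(layers) + 1L]] <- nn_layer_bn(cout)
    layers[[length(layers) + 1L]] <- nn_layer_relu()
    cprev <- cout
  }
  layers
}

nn_seq_forward <- function(layers, x, train) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "conv") {
      r <- nn_forward_conv(l, x)
      x <- r$y; caches[[i]] <- r$cache
    } else if (l$type == "bn") {
      r <- nn_forward_bn(l, x, train)
      x <- r$y; caches[[i]] <- r$cache
      layers[[i]] <- r$layer  # running stats updated in train mode
    } else if (l$type == "relu") {
      caches[[i]] <- x > 0
      x <- x * caches[[i]]
    } else if (l$type == "pool2") {
      r <- nn_forward_pool2(x)
      x <- r$y; caches[[i]] <- r$cache
    } else stop("unknown layer type: ", l$type)
  }
  list(y = x, caches = caches, layers = layers)
}

nn_seq_backward <- function(layers, caches, dy) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    if (l$type == "conv") {
      r <- nn_backward_conv(l, caches[[i]], dy)
      dy <- r$dx; grads[[i]] <- r$grads
    } else if (l$type == "bn") {
      r <- nn_backward_bn(l, caches[[i]], dy)
      dy <- r$dx; grads[[i]] <- r$grads
    } else if (l$type == "relu") {
      dy <- dy * caches[[i]]
      grads[[i]] <- list()
    } else if (l$type == "pool2") {
      dy <- nn_backward_pool2(caches[[i]], dy)
      grads[[i]] <- list()
    }
  }
  list(dx = dy, grads = grads)
}

# Adam over an arbitrarily nested list of layers -----------------------------

.nn_param_names <- c("W", "b", "gamma", "beta")

nn_is_layer <- function(x) is.list(x) && !is.null(x$type)

nn_adam_init <- function(layers) {
  if (nn_is_layer(layers)) {
    st <- list()
    for (p in .nn_param_names) {
      if (!is.null(layers[[p]])) {
        st[[p]] <- list(m = array(0, dim(layers[[p]]) %||% length(layers[[p]])),
                        v = array(0, dim(layers[[p]]) %||% length(layers[[p]])))
      }
    }
    return(st)
  }
  lapply(layers, nn_adam_init)
}

nn_adam_step <- function(layers, grads, state, lr, t,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (nn_is_layer(layers)) {
    for (p in names(state)) {
      g <- grads[[p]]
      m <- beta1 * state[[p]]$m + (1 - beta1) * g
      v <- beta2 * state[[p]]$v + (1 - beta2) * g^2
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      layers[[p]] <- layers[[p]] - lr * mhat / (sqrt(vhat) + eps)
      state[[p]]$m <- m
      state[[p]]$v <- v
    }
    return(list(layers = layers, state = state))
  }
  nm <- names(layers)
  for (i in seq_along(layers)) {
    g <- if (!is.null(nm) && nzchar(nm[i])) grads[[nm[i]]] else grads[[i]]
    r <- nn_adam_step(layers[[i]], g, state[[i]], lr, t,
                      beta1, beta2, eps)
    layers[[i]] <- r$layers
    state[[i]] <- r$state
  }
  list(layers = layers, state = state)
}

nn_count_params <- function(layers) {
  if (nn_is_layer(layers)) {
    return(sum(vapply(.nn_param_names,
                      function(p) length(layers[[p]]), numeric(1))))
  }
  sum(vapply(layers, nn_count_params, numeric(1)))
}

# softmax cross entropy on a logits matrix (M x K), labels in 1..K.
# Returns summed loss and d(loss)/d(logits) for the SUM (caller rescales).
nn_softmax_ce <- function(logits, labels) {
  M <- nrow(logits); K <- ncol(logits)
  mx <- apply(logits, 1, max)
  ex <- exp(logits - mx)
  Z <- rowSums(ex)
  p <- ex / Z
  idx <- cbind(seq_len(M), labels)
  loss <- -sum(log(pmax(p[idx], 1e-300)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, p = p, dlogits = dlogits)
}

# log-linear learning-rate schedule from lr_start (epoch 1) to lr_end (epoch E)
nn_lr_schedule <- function(epoch, epochs, lr_start, lr_end) {
  if (epochs == 1L) return(lr_start)
  lr_start * (lr_end / lr_start)^((epoch - 1) / (epochs - 1))
}
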