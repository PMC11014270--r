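# One-dimensional neural-network layer engine.
#
# Activations are 3-D arrays of dim (batch n, length L, channels C); dense
# layers operate on (n, d) matrices. Layers are environments so forward
# caches and optimizer state mutate in place; all math is double precision
# on BLAS-backed matrix products (convolution via im2col). Each leaf layer
# exposes a named list `params` and, after a backward pass, matching
# `grads`; composite layers (residual block, inception module) delegate to
# their `children`.

new_layer <- function(cls, ...) {
  e <- new.env(parent = emptyenv())
  for (nm in names(list(...))) assign(nm, list(...)[[nm]], envir = e)
  e$params <- if (is.null(e$params)) list() else e$params
  class(e) <- c(cls, "nn_layer")
  e
}

layer_forward <- function(layer, x, training = FALSE) {
  UseMethod("layer_forward")
}
layer_backward <- function(layer, dy) UseMethod("layer_backward")

# Uniform fan-in initialization: U(-sqrt(6/fan_in), sqrt(6/fan_in)),
# drawn from the active RNG stream.
init_uniform <- function(nrow, ncol, fan_in) {
  lim <- sqrt(6 / fan_in)
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

pad3 <- function(x, pad, value = 0) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(value, c(d[1], d[2] + 2L * pad, d[3]))
  out[, pad + seq_len(d[2]), ] <- x
  out
}

conv_out_len <- function(L, k, stride, pad) {
  (L + 2L * pad - k) %/% stride + 1L
}

## ---- convolution ----------------------------------------------------------

layer_conv1d <- function(in_ch, out_ch, k, stride = 1L, pad = 0L) {
  l <- new_layer("nn_conv1d", in_ch = in_ch, out_ch = out_ch,
                 k = as.integer(k), stride = as.integer(stride),
                 pad = as.integer(pad))
  l$params <- list(W = init_uniform(k * in_ch, out_ch, k * in_ch),
                   b = numeric(out_ch))
  l
}

#' @export
layer_forward.nn_conv1d <- function(layer, x, training = FALSE) {
  d <- dim(x)
  n <- d[1]; L <- d[2]; C <- d[3]
  xp <- pad3(x, layer$pad)
  Lp <- L + 2L * layer$pad
  k <- layer$k
  Lout <- conv_out_len(L, k, layer$stride, layer$pad)
  if (Lout < 1L) {
    stop(sprintf("input length %d too short for kernel %d (stride %d)",
                 L, k, layer$stride), call. = FALSE)
  }
  starts <- seq.int(1L, by = layer$stride, length.out = Lout)
  M <- array(0, c(n, Lout, k * C))
  for (j in seq_len(k)) {
    M[, , ((j - 1L) * C + 1L):(j * C)] <- xp[, starts + (j - 1L), ,
                                             drop = FALSE]
  }
  dim(M) <- c(n * Lout, k * C)
  y <- M %*% layer$params$W
  y <- y + rep(layer$params$b, each = nrow(y))
  dim(y) <- c(n, Lout, layer$out_ch)
  if (training) {
    layer$cache <- list(M = M, n = n, L = L, C = C, Lp = Lp, Lout = Lout,
                        starts = starts)
  }
  y
}

#' @export
layer_backward.nn_conv1d <- function(layer, dy) {
  cc <- layer$cache
  k <- layer$k
  dym <- dy
  dim(dym) <- c(cc$n * cc$Lout, layer$out_ch)
  layer$grads <- list(W = crossprod(cc$M, dym), b = colSums(dym))
  dM <- dym %*% t(layer$params$W)
  dim(dM) <- c(cc$n, cc$Lout, k * cc$C)
  dxp <- array(0, c(cc$n, cc$Lp, cc$C))
  for (j in seq_len(k)) {
    idx <- cc$starts + (j - 1L)
    dxp[, idx, ] <- dxp[, idx, , drop = FALSE] +
      dM[, , ((j - 1L) * cc$C + 1L):(j * cc$C), drop = FALSE]
  }
  if (layer$pad > 0L) {
    dxp <- dxp[, layer$pad + seq_len(cc$L), , drop = FALSE]
  }
  dxp
}

## ---- ReLU -----------------------------------------------------------------

layer_relu <- function() new_layer("nn_relu")

#' @export
layer_forward.nn_relu <- function(layer, x, training = FALSE) {
  mask <- x > 0
  if (training) layer$cache <- mask
  x * mask
}

#' @export
layer_backward.nn_relu <- function(layer, dy) dy * layer$cache

## ---- max pooling ----------------------------------------------------------

layer_maxpool1d <- function(k = 2L, stride = k, pad = 0L) {
  new_layer("nn_maxpool1d", k = as.integer(k), stride = as.integer(stride),
            pad = as.integer(pad))
}

#' @export
layer_forward.nn_maxpool1d <- function(layer, x, training = FALSE) {
  d <- dim(x)
  n <- d[1]; L <- d[2]; C <- d[3]
  xp <- pad3(x, layer$pad, value = -Inf)
  Lout <- conv_out_len(L, layer$k, layer$stride, layer$pad)
  if (Lout < 1L) {
    stop(sprintf("input length %d too short for pool of size %d", L,
                 layer$k), call. = FALSE)
  }
  starts <- seq.int(1L, by = layer$stride, length.out = Lout)
  maxv <- xp[, starts, , drop = FALSE]
  argj <- array(1L, dim(maxv))
  for (j in 2:layer$k) {
    cand <- xp[, starts + (j - 1L), , drop = FALSE]
    upd <- cand > maxv
    maxv[upd] <- cand[upd]
    argj[upd] <- j
  }
  if (training) {
    layer$cache <- list(argj = argj, n = n, L = L, C = C,
                        Lp = L + 2L * layer$pad, starts = starts)
  }
  maxv
}

#' @export
layer_backward.nn_maxpool1d <- function(layer, dy) {
  cc <- layer$cache
  dxp <- array(0, c(cc$n, cc$Lp, cc$C))
  for (j in seq_len(layer$k)) {
    idx <- cc$starts + (j - 1L)
    dxp[, idx, ] <- dxp[, idx, , drop = FALSE] + dy * (cc$argj == j)
  }
  if (layer$pad > 0L) dxp <- dxp[, layer$pad + seq_len(cc$L), , drop = FALSE]
  dxp
}

## ---- batch normalization (per channel over batch x position) --------------

layer_batchnorm <- function(channels, momentum = 0.9, eps = 1e-5) {
  l <- new_layer("nn_batchnorm", channels = channels, momentum = momentum,
                 eps = eps,
                 running_mean = numeric(channels),
                 running_var = rep(1, channels))
  l$params <- list(gamma = rep(1, channels), beta = numeric(channels))
  l
}

#' @export
layer_forward.nn_batchnorm <- function(layer, x, training = FALSE) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1] * d[2], d[3])
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    layer$running_mean <- layer$momentum * layer$running_mean +
      (1 - layer$momentum) * mu
    layer$running_var <- layer$momentum * layer$running_var +
      (1 - layer$momentum) * v
  } else {
    mu <- layer$running_mean
    v <- layer$running_var
  }
  istd <- 1 / sqrt(v + layer$eps)
  xhat <- sweep(sweep(xm, 2, mu, "-"), 2, istd, "*")
  y <- sweep(sweep(xhat, 2, layer$params$gamma, "*"), 2,
             layer$params$beta, "+")
  if (training) layer$cache <- list(xhat = xhat, istd = istd, d = d)
  dim(y) <- d
  y
}

#' @export
layer_backward.nn_batchnorm <- function(layer, dy) {
  cc <- layer$cache
  d <- cc$d
  dym <- dy
  dim(dym) <- c(d[1] * d[2], d[3])
  m <- nrow(dym)
  layer$grads <- list(gamma = colSums(dym * cc$xhat), beta = colSums(dym))
  dxhat <- sweep(dym, 2, layer$params$gamma, "*")
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cc$xhat)
  dx <- sweep(dxhat, 2, s1 / m, "-") -
    sweep(cc$xhat, 2, s2 / m, "*")
  dx <- sweep(dx, 2, cc$istd, "*")
  dim(dx) <- d
  dx
}

## ---- global average pool, flatten, dense ----------------------------------

layer_gap <- function() new_layer("nn_gap")

#' @export
layer_forward.nn_gap <- function(layer, x, training = FALSE) {
  d <- dim(x)
  y <- matrix(0, d[1], d[3])
  for (c in seq_len(d[3])) y[, c] <- rowMeans(x[, , c, drop = FALSE])
  if (training) layer$cache <- d
  y
}

#' @export
layer_backward.nn_gap <- function(layer, dy) {
  d <- layer$cache
  dx <- array(0, d)
  for (c in seq_len(d[3])) dx[, , c] <- dy[, c] / d[2]
  dx
}

layer_flatten <- function() new_layer("nn_flatten")

#' @export
layer_forward.nn_flatten <- function(layer, x, training = FALSE) {
  d <- dim(x)
  if (training) layer$cache <- d
  dim(x) <- c(d[1], prod(d[-1]))
  x
}

#' @export
layer_backward.nn_flatten <- function(layer, dy) {
  dim(dy) <- layer$cache
  dy
}

layer_dense <- function(in_dim, out_dim) {
  l <- new_layer("nn_dense", in_dim = in_dim, out_dim = out_dim)
  l$params <- list(W = init_uniform(in_dim, out_dim, in_dim),
                   b = numeric(out_dim))
  l
}

#' @export
layer_forward.nn_dense <- function(layer, x, training = FALSE) {
  y <- x %*% layer$params$W
  y <- y + rep(layer$params$b, each = nrow(y))
  if (training) layer$cache <- x
  y
}

#' @export
layer_backward.nn_dense <- function(layer, dy) {
  layer$grads <- list(W = crossprod(layer$cache, dy), b = colSums(dy))
  dy %*% t(layer$params$W)
}

## ---- residual block -------------------------------------------------------

# Two k3 convolutions with batch norm on the main path, identity shortcut
# (1x1 projection convolution when the stride or channel count changes),
# ReLU on the sum.
layer_residual_block <- function(in_ch, out_ch, stride = 1L) {
  l <- new_layer("nn_residual", in_ch = in_ch, out_ch = out_ch,
                 stride = as.integer(stride))
  l$children <- list(
    conv1 = layer_conv1d(in_ch, out_ch, 3L, stride = stride, pad = 1L),
    bn1 = layer_batchnorm(out_ch),
    conv2 = layer_conv1d(out_ch, out_ch, 3L, stride = 1L, pad = 1L),
    bn2 = layer_batchnorm(out_ch))
  if (stride != 1L || in_ch != out_ch) {
    l$children$proj <- layer_conv1d(in_ch, out_ch, 1L, stride = stride)
  }
  l
}

#' @export
layer_forward.nn_residual <- function(layer, x, training = FALSE) {
  ch <- layer$children
  h <- layer_forward(ch$conv1, x, training)
  h <- layer_forward(ch$bn1, h, training)
  mask1 <- h > 0
  h <- h * mask1
  h <- layer_forward(ch$conv2, h, training)
  h <- layer_forward(ch$bn2, h, training)
  s <- if (is.null(ch$proj)) x else layer_forward(ch$proj, x, training)
  y <- h + s
  mask_out <- y > 0
  if (training) layer$cache <- list(mask1 = mask1, mask_out = mask_out)
  y * mask_out
}

#' @export
layer_backward.nn_residual <- function(layer, dy) {
  ch <- layer$children
  cc <- layer$cache
  dsum <- dy * cc$mask_out
  dh <- layer_backward(ch$bn2, dsum)
  dh <- layer_backward(ch$conv2, dh)
  dh <- dh * cc$mask1
  dh <- layer_backward(ch$bn1, dh)
  dx_main <- layer_backward(ch$conv1, dh)
  dx_short <- if (is.null(ch$proj)) dsum else layer_backward(ch$proj, dsum)
  dx_main + dx_short
}

## ---- inception module -----------------------------------------------------

# Parallel branches at multiple receptive-field scales, all length-
# preserving, concatenated along the channel axis: 1x1 conv, 3-wide conv,
# 5-wide conv, and max-pool followed by a 1x1 conv. ReLU after each conv.
layer_inception <- function(in_ch, ch_k1, ch_k3, ch_k5, ch_pool) {
  l <- new_layer("nn_inception", in_ch = in_ch,
                 branch_channels = c(ch_k1, ch_k3, ch_k5, ch_pool),
                 out_ch = ch_k1 + ch_k3 + ch_k5 + ch_pool)
  l$children <- list(
    b1 = layer_conv1d(in_ch, ch_k1, 1L),
    b2 = layer_conv1d(in_ch, ch_k3, 3L, pad = 1L),
    b3 = layer_conv1d(in_ch, ch_k5, 5L, pad = 2L),
    pool = layer_maxpool1d(3L, stride = 1L, pad = 1L),
    b4 = layer_conv1d(in_ch, ch_pool, 1L))
  l
}

#' @export
layer_forward.nn_inception <- function(layer, x, training = FALSE) {
  ch <- layer$children
  y1 <- layer_forward(ch$b1, x, training)
  y2 <- layer_forward(ch$b2, x, training)
  y3 <- layer_forward(ch$b3, x, training)
  p <- layer_forward(ch$pool, x, training)
  y4 <- layer_forward(ch$b4, p, training)
  masks <- list(y1 > 0, y2 > 0, y3 > 0, y4 > 0)
  if (training) layer$cache <- masks
  d <- dim(y1)
  out <- array(0, c(d[1], d[2], layer$out_ch))
  bc <- layer$branch_channels
  off <- cumsum(c(0L, bc))
  ys <- list(y1 * masks[[1]], y2 * masks[[2]], y3 * masks[[3]],
             y4 * masks[[4]])
  for (i in 1:4) out[, , (off[i] + 1L):off[i + 1L]] <- ys[[i]]
  out
}

#' @export
layer_backward.nn_inception <- function(layer, dy) {
  ch <- layer$children
  masks <- layer$cache
  bc <- layer$branch_channels
  off <- cumsum(c(0L, bc))
  dparts <- lapply(1:4, function(i) {
    dy[, , (off[i] + 1L):off[i + 1L], drop = FALSE] * masks[[i]]
  })
  dx <- layer_backward(ch$b1, dparts[[1]])
  dx <- dx + layer_backward(ch$b2, dparts[[2]])
  dx <- dx + layer_backward(ch$b3, dparts[[3]])
  dp <- layer_backward(ch$b4, dparts[[4]])
  dx + layer_backward(ch$pool, dp)
}

## ---- parameter walking, Adam, snapshots -----------------------------------

# Depth-first list of leaf layers that own parameters or running stats.
collect_leaves <- function(layers) {
  out <- list()
  for (l in layers) {
    if (!is.null(l$children)) {
      out <- c(out, collect_leaves(l$children))
    } else {
      out <- c(out, list(l))
    }
  }
  out
}

count_parameters <- function(layers) {
  sum(vapply(collect_leaves(layers), function(l) {
    sum(vapply(l$params, length, integer(1)))
  }, numeric(1)))
}

adam_step <- function(leaves, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (l in leaves) {
    if (length(l$params) == 0L || is.null(l$grads)) next
    if (is.null(l$opt_m)) {
      l$opt_m <- lapply(l$params, function(p) p * 0)
      l$opt_v <- lapply(l$params, function(p) p * 0)
    }
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      l$opt_m[[nm]] <- beta1 * l$opt_m[[nm]] + (1 - beta1) * g
      l$opt_v[[nm]] <- beta2 * l$opt_v[[nm]] + (1 - beta2) * g^2
      mhat <- l$opt_m[[nm]] / bc1
      vhat <- l$opt_v[[nm]] / bc2
      l$params[[nm]] <- l$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  invisible(NULL)
}

snapshot_weights <- function(leaves) {
  lapply(leaves, function(l) {
    list(params = l$params,
         running_mean = l$running_mean,
         running_var = l$running_var)
  })
}

restore_weights <- function(leaves, snap) {
  for (i in seq_along(leaves)) {
    leaves[[i]]$params <- snap[[i]]$params
    if (!is.null(snap[[i]]$running_mean)) {
      leaves[[i]]$running_mean <- snap[[i]]$running_mean
      leaves[[i]]$running_var <- snap[[i]]$running_var
    }
  }
  invisible(NULL)
}

network_forward <- function(net, x, training = FALSE) {
  h <- x
  for (l in net$layers) h <- layer_forward(l, h, training)
  h
}

network_backward <- function(net, dy) {
  g <- dy
  for (l in rev(net$layers)) g <- layer_backward(l, g)
  g
}
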