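# Primitive trainable layers.  Each constructor returns an environment-backed
# layer (see nn-core.R); forward caches whatever backward needs.

#' 2-D convolution layer
#'
#' Grouped, strided, dilated cross-correlation on `(H, W, C, N)` arrays,
#' backed by compiled im2col/GEMM kernels. `groups = in_ch` gives a depthwise
#' convolution.
#'
#' @param in_ch,out_ch channel counts.
#' @param kernel kernel size (scalar or `c(kh, kw)`).
#' @param stride,pad,dilation integer scalars or length-2 vectors.
#' @param groups number of channel groups.
#' @param bias include an additive bias (convolutions feeding a batch norm
#'   conventionally do not).
#' @return an `nn_layer`.
#' @export
nn_conv2d <- function(in_ch, out_ch, kernel, stride = 1, pad = 0,
                      dilation = 1, groups = 1, bias = FALSE) {
  kernel <- rep(as.integer(kernel), length.out = 2)
  stride <- rep(as.integer(stride), length.out = 2)
  pad <- rep(as.integer(pad), length.out = 2)
  dilation <- rep(as.integer(dilation), length.out = 2)
  if (in_ch %% groups != 0 || out_ch %% groups != 0) {
    stop("channel counts must be divisible by groups")
  }
  l <- new_layer("conv2d", in_ch = in_ch, out_ch = out_ch, kernel = kernel,
                 stride = stride, pad = pad, dilation = dilation,
                 groups = groups, has_bias = bias)
  fan_in <- prod(kernel) * in_ch / groups
  add_param(l, "W", init_kaiming(c(kernel, in_ch / groups, out_ch), fan_in))
  if (bias) add_param(l, "b", numeric(out_ch))
  l
}

#' @export
nn_forward.nn_conv2d <- function(layer, x, training = FALSE) {
  layer$cache <- if (training) x else NULL
  .cpp_conv2d_fwd(x, layer$params$W,
                  if (layer$has_bias) layer$params$b else numeric(0),
                  layer$stride, layer$pad, layer$dilation, layer$groups)
}

#' @export
nn_backward.nn_conv2d <- function(layer, gy) {
  g <- .cpp_conv2d_bwd(layer$cache, layer$params$W, gy, layer$stride,
                       layer$pad, layer$dilation, layer$groups,
                       layer$has_bias)
  layer$grads$W <- layer$grads$W + g$gw
  if (layer$has_bias) layer$grads$b <- layer$grads$b + g$gb
  g$gx
}

#' Batch normalisation over (H, W, N) per channel
#'
#' @param ch channel count.
#' @param momentum running-moment update rate.
#' @param eps variance floor.
#' @export
nn_bn2d <- function(ch, momentum = 0.1, eps = 1e-5) {
  l <- new_layer("bn2d", ch = ch, momentum = momentum, eps = eps)
  add_param(l, "gamma", rep(1, ch))
  add_param(l, "beta", numeric(ch))
  l$buffers$running_mean <- numeric(ch)
  l$buffers$running_var <- rep(1, ch)
  l
}

#' @export
nn_forward.nn_bn2d <- function(layer, x, training = FALSE) {
  d <- dim(x)
  C <- d[3]
  m <- d[1] * d[2] * d[4]
  xm <- matrix(x, ncol = C * d[4])                       # HW x (C*N)
  if (training) {
    csum <- rowSums(matrix(colSums(xm), nrow = C))
    mu <- csum / m
    csq <- rowSums(matrix(colSums(xm^2), nrow = C))
    v <- csq / m - mu^2
    v <- pmax(v, 0)
    layer$buffers$running_mean <-
      (1 - layer$momentum) * layer$buffers$running_mean + layer$momentum * mu
    vu <- if (m > 1) v * m / (m - 1) else v
    layer$buffers$running_var <-
      (1 - layer$momentum) * layer$buffers$running_var + layer$momentum * vu
  } else {
    mu <- layer$buffers$running_mean
    v <- layer$buffers$running_var
  }
  invstd <- 1 / sqrt(v + layer$eps)
  mu_col <- rep(mu, times = d[4])
  is_col <- rep(invstd, times = d[4])
  xhat <- sweep(sweep(xm, 2, mu_col, "-"), 2, is_col, "*")
  y <- sweep(xhat, 2, rep(layer$params$gamma, times = d[4]), "*")
  y <- sweep(y, 2, rep(layer$params$beta, times = d[4]), "+")
  if (training) layer$cache <- list(xhat = xhat, invstd = invstd, d = d, m = m)
  array(y, d)
}

#' @export
nn_backward.nn_bn2d <- function(layer, gy) {
  cc <- layer$cache
  d <- cc$d
  C <- d[3]
  gym <- matrix(gy, ncol = C * d[4])
  gxhat <- sweep(gym, 2, rep(layer$params$gamma, times = d[4]), "*")
  s1 <- rowSums(matrix(colSums(gxhat), nrow = C))                 # per channel
  s2 <- rowSums(matrix(colSums(gxhat * cc$xhat), nrow = C))
  layer$grads$beta <- layer$grads$beta + s1
  layer$grads$gamma <- layer$grads$gamma +
    rowSums(matrix(colSums(gym * cc$xhat), nrow = C))
  t1 <- sweep(gxhat, 2, rep(s1 / cc$m, times = d[4]), "-")
  t2 <- sweep(cc$xhat, 2, rep(s2 / cc$m, times = d[4]), "*")
  gx <- sweep(t1 - t2, 2, rep(cc$invstd, times = d[4]), "*")
  array(gx, d)
}

#' Batch normalisation over samples for channel vectors (C x N matrices)
#' @inheritParams nn_bn2d
#' @export
nn_bn1d <- function(ch, momentum = 0.1, eps = 1e-5) {
  l <- new_layer("bn1d", ch = ch, momentum = momentum, eps = eps)
  add_param(l, "gamma", rep(1, ch))
  add_param(l, "beta", numeric(ch))
  l$buffers$running_mean <- numeric(ch)
  l$buffers$running_var <- rep(1, ch)
  l
}

#' @export
nn_forward.nn_bn1d <- function(layer, x, training = FALSE) {
  N <- ncol(x)
  if (training) {
    mu <- rowMeans(x)
    v <- rowMeans(x^2) - mu^2
    v <- pmax(v, 0)
    layer$buffers$running_mean <-
      (1 - layer$momentum) * layer$buffers$running_mean + layer$momentum * mu
    vu <- if (N > 1) v * N / (N - 1) else v
    layer$buffers$running_var <-
      (1 - layer$momentum) * layer$buffers$running_var + layer$momentum * vu
  } else {
    mu <- layer$buffers$running_mean
    v <- layer$buffers$running_var
  }
  invstd <- 1 / sqrt(v + layer$eps)
  xhat <- (x - mu) * invstd
  if (training) layer$cache <- list(xhat = xhat, invstd = invstd, N = N)
  xhat * layer$params$gamma + layer$params$beta
}

#' @export
nn_backward.nn_bn1d <- function(layer, gy) {
  cc <- layer$cache
  gxhat <- gy * layer$params$gamma
  s1 <- rowSums(gxhat)
  s2 <- rowSums(gxhat * cc$xhat)
  layer$grads$beta <- layer$grads$beta + s1
  layer$grads$gamma <- layer$grads$gamma + rowSums(gy * cc$xhat)
  (gxhat - s1 / cc$N - cc$xhat * (s2 / cc$N)) * cc$invstd
}

#' Elementwise activation layer
#' @param type one of `"swish"` (x * sigmoid(x)), `"relu"`, `"sigmoid"`.
#' @export
nn_act <- function(type = c("swish", "relu", "sigmoid")) {
  new_layer("act", type = match.arg(type))
}

#' @export
nn_forward.nn_act <- function(layer, x, training = FALSE) {
  y <- switch(layer$type,
              swish = x * sigmoid(x),
              relu = pmax(x, 0),
              sigmoid = sigmoid(x))
  if (is.array(x)) dim(y) <- dim(x)
  if (training) layer$cache <- x
  y
}

#' @export
nn_backward.nn_act <- function(layer, gy) {
  x <- layer$cache
  g <- switch(layer$type,
              swish = { s <- sigmoid(x); s + x * s * (1 - s) },
              relu = (x > 0) + 0,
              sigmoid = { s <- sigmoid(x); s * (1 - s) })
  out <- gy * g
  if (is.array(gy)) dim(out) <- dim(gy)
  out
}

#' Fully connected layer on N x in matrices
#' @param in_ch,out_ch feature widths.
#' @param bias include bias (default `TRUE`).
#' @export
nn_linear <- function(in_ch, out_ch, bias = TRUE) {
  l <- new_layer("linear", in_ch = in_ch, out_ch = out_ch, has_bias = bias)
  add_param(l, "W", init_kaiming(c(in_ch, out_ch), in_ch))
  if (bias) add_param(l, "b", numeric(out_ch))
  l
}

#' @export
nn_forward.nn_linear <- function(layer, x, training = FALSE) {
  if (training) layer$cache <- x
  y <- x %*% layer$params$W
  if (layer$has_bias) y <- sweep(y, 2, layer$params$b, "+")
  y
}

#' @export
nn_backward.nn_linear <- function(layer, gy) {
  layer$grads$W <- layer$grads$W + crossprod(layer$cache, gy)
  if (layer$has_bias) layer$grads$b <- layer$grads$b + colSums(gy)
  gy %*% t(layer$params$W)
}

#' Inverted dropout layer
#' @param p drop probability in `[0, 1)`.
#' @export
nn_dropout <- function(p = 0.2) {
  if (p < 0 || p >= 1) stop("dropout probability must be in [0, 1)")
  new_layer("dropout", p = p)
}

#' @export
nn_forward.nn_dropout <- function(layer, x, training = FALSE) {
  if (!training || layer$p == 0) return(x)
  mask <- array(stats::rbinom(length(x), 1, 1 - layer$p) / (1 - layer$p),
                dim = dim(x) %||% length(x))
  layer$cache <- mask
  x * mask
}

#' @export
nn_backward.nn_dropout <- function(layer, gy) {
  if (is.null(layer$cache)) gy else gy * layer$cache
}

#' Global average pooling to C x N channel vectors
#' @export
nn_gap <- function() new_layer("gap")

#' @export
nn_forward.nn_gap <- function(layer, x, training = FALSE) {
  d <- dim(x)
  if (training) layer$cache <- d
  reduce_hw(x) / (d[1] * d[2])
}

#' @export
nn_backward.nn_gap <- function(layer, gy) {
  d <- layer$cache
  bcast_cn(gy / (d[1] * d[2]), d)
}

#' 1-D convolution across the channel sequence (one input/output channel)
#'
#' Operates on C x N matrices of pooled channel descriptors with symmetric
#' zero padding `(k - 1) / 2`, so the sequence length stays C.
#'
#' @param k odd kernel size.
#' @export
nn_conv1d_channel <- function(k) {
  if (k < 1 || k %% 2 == 0) stop("1-D channel kernel size must be odd and >= 1")
  l <- new_layer("conv1d_channel", k = as.integer(k))
  add_param(l, "W", numeric(k) + stats::rnorm(k, sd = sqrt(2 / k)))
  add_param(l, "b", 0)
  l
}

#' @export
nn_forward.nn_conv1d_channel <- function(layer, x, training = FALSE) {
  k <- layer$k
  p <- (k - 1L) %/% 2L
  C <- nrow(x)
  xp <- rbind(matrix(0, p, ncol(x)), x, matrix(0, p, ncol(x)))
  y <- matrix(layer$params$b, C, ncol(x))
  for (j in seq_len(k)) {
    y <- y + layer$params$W[j] * xp[j:(j + C - 1L), , drop = FALSE]
  }
  if (training) layer$cache <- list(xp = xp, C = C)
  y
}

#' @export
nn_backward.nn_conv1d_channel <- function(layer, gy) {
  k <- layer$k
  p <- (k - 1L) %/% 2L
  cc <- layer$cache
  C <- cc$C
  gxp <- matrix(0, nrow(cc$xp), ncol(gy))
  for (j in seq_len(k)) {
    idx <- j:(j + C - 1L)
    layer$grads$W[j] <- layer$grads$W[j] +
      sum(gy * cc$xp[idx, , drop = FALSE])
    gxp[idx, ] <- gxp[idx, ] + layer$params$W[j] * gy
  }
  layer$grads$b <- layer$grads$b + sum(gy)
  gxp[(p + 1L):(p + C), , drop = FALSE]
}

#' Sequential container
#' @param ... child layers, applied in order.
#' @export
nn_sequential <- function(...) {
  l <- new_layer("sequential")
  l$children <- list(...)
  l
}

#' @export
nn_forward.nn_sequential <- function(layer, x, training = FALSE) {
  for (ch in layer$children) x <- nn_forward(ch, x, training)
  x
}

#' @export
nn_backward.nn_sequential <- function(layer, gy) {
  for (ch in rev(layer$children)) gy <- nn_backward(ch, gy)
  gy
}
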