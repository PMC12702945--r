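# The architecture's bespoke blocks: multi-scale efficient channel attention
# with a light spatial-attention stage, the channel context module (CCM),
# light atrous spatial pyramid pooling, learnable mixed pooling, learnable
# stochastic depth, and the squeeze-and-excitation block used by the
# baseline.  Every block implements both nn_forward and nn_backward; the
# attention blocks apply the product rule through their own gating factors.

#' Block hyper-parameter bundle
#'
#' Collects the tunable settings of the attention / pooling blocks.
#'
#' @param eca_kernel_sizes odd 1-D kernel sizes for the multi-scale channel
#'   attention branches.
#' @param ccm_reduction channel reduction ratio r of the channel context
#'   module; hidden width is `max(floor(C / r), 1)`.
#' @param aspp_rates strictly increasing dilation rates of the pyramid
#'   branches.
#' @param aspp_branch_channels output width of each dilated branch.
#' @param aspp_gap_channels width the global-pooling branch is compressed to.
#' @param mixed_pool_lambda_init initial max/average mixing weight in
#'   `[0, 1]`.
#' @param droppath_p_max upper bound (< 1) of the learnable per-block drop
#'   probability.
#' @param eca_learnable_fusion if `TRUE`, fuse the channel-attention branches
#'   with learnable softmax weights instead of a plain mean.
#' @return a list of class `"block_config"`.
#' @export
block_config <- function(eca_kernel_sizes = c(3, 5, 7),
                         ccm_reduction = 16,
                         aspp_rates = c(3, 6, 9),
                         aspp_branch_channels = 128,
                         aspp_gap_channels = 128,
                         mixed_pool_lambda_init = 0.5,
                         droppath_p_max = 0.2,
                         eca_learnable_fusion = FALSE) {
  if (any(eca_kernel_sizes < 1) || any(eca_kernel_sizes %% 2 == 0)) {
    stop("eca_kernel_sizes must be odd integers >= 1")
  }
  if (ccm_reduction < 1) stop("ccm_reduction must be a positive integer")
  if (any(aspp_rates <= 0)) stop("aspp_rates must be positive")
  if (any(diff(aspp_rates) <= 0)) stop("aspp_rates must be strictly increasing")
  if (mixed_pool_lambda_init < 0 || mixed_pool_lambda_init > 1) {
    stop("mixed_pool_lambda_init must lie in [0, 1]")
  }
  if (droppath_p_max < 0 || droppath_p_max >= 1) {
    stop("droppath_p_max must lie in [0, 1)")
  }
  structure(list(eca_kernel_sizes = as.integer(eca_kernel_sizes),
                 ccm_reduction = as.integer(ccm_reduction),
                 aspp_rates = as.integer(aspp_rates),
                 aspp_branch_channels = as.integer(aspp_branch_channels),
                 aspp_gap_channels = as.integer(aspp_gap_channels),
                 mixed_pool_lambda_init = mixed_pool_lambda_init,
                 droppath_p_max = droppath_p_max,
                 eca_learnable_fusion = eca_learnable_fusion),
            class = "block_config")
}

# internal: 1x1 convolution on C x N channel vectors (a linear map applied
# column-wise), used by SE, CCM and the pyramid's global branch.
nn_cvec_linear <- function(in_ch, out_ch, bias = TRUE) {
  l <- new_layer("cvec_linear", in_ch = in_ch, out_ch = out_ch,
                 has_bias = bias)
  add_param(l, "W", init_kaiming(c(out_ch, in_ch), in_ch))
  if (bias) add_param(l, "b", numeric(out_ch))
  l
}

#' @export
nn_forward.nn_cvec_linear <- function(layer, x, training = FALSE) {
  if (training) layer$cache <- x
  y <- layer$params$W %*% x
  if (layer$has_bias) y <- y + layer$params$b
  y
}

#' @export
nn_backward.nn_cvec_linear <- function(layer, gy) {
  layer$grads$W <- layer$grads$W + tcrossprod(gy, layer$cache)
  if (layer$has_bias) layer$grads$b <- layer$grads$b + rowSums(gy)
  crossprod(layer$params$W, gy)
}

# ---------------------------------------------------------------------------
# Multi-scale efficient channel attention + light spatial attention
# ---------------------------------------------------------------------------

#' Multi-scale efficient channel attention block
#'
#' Channel stage: global average pooling gives one descriptor per channel;
#' parallel 1-D convolutions (default kernel sizes 3, 5, 7) run along the
#' channel sequence; their outputs are fused by an arithmetic mean (or by
#' learnable softmax weights) and squashed by a sigmoid into channel weights.
#' Spatial stage: channel-wise average and max maps are concatenated and a
#' 7x7 convolution followed by a sigmoid yields a single spatial weight map.
#' The block output is `x * w_channel * w_spatial`, so no activation can grow
#' in magnitude.
#'
#' @param channels number of input channels.
#' @param kernel_sizes odd 1-D kernel sizes.
#' @param learnable_fusion fuse branches with learnable softmax weights
#'   instead of a plain mean.
#' @return an `nn_layer`.
#' @export
nn_multiscale_eca <- function(channels, kernel_sizes = c(3, 5, 7),
                              learnable_fusion = FALSE) {
  if (channels < 1) stop("channel count must be >= 1")
  if (any(kernel_sizes < 1) || any(kernel_sizes %% 2 == 0)) {
    stop("1-D kernel sizes must be odd integers >= 1")
  }
  l <- new_layer("mseca", channels = channels,
                 kernel_sizes = as.integer(kernel_sizes),
                 learnable_fusion = learnable_fusion)
  branches <- lapply(kernel_sizes, nn_conv1d_channel)
  spatial <- nn_conv2d(2, 1, 7, pad = 3, bias = TRUE)
  l$children <- c(branches, list(spatial))
  l$n_branch <- length(branches)
  if (learnable_fusion) add_param(l, "fuse_logits", numeric(length(branches)))
  l
}

mseca_channel_stage <- function(layer, x, training) {
  d <- dim(x)
  s <- reduce_hw(x) / (d[1] * d[2])                    # C x N descriptors
  fb <- lapply(seq_len(layer$n_branch),
               function(i) nn_forward(layer$children[[i]], s, training))
  if (layer$learnable_fusion) {
    a <- exp(layer$params$fuse_logits)
    a <- a / sum(a)
    f <- Reduce(`+`, Map(function(w, m) w * m, a, fb))
  } else {
    a <- NULL
    f <- Reduce(`+`, fb) / layer$n_branch
  }
  list(s = s, fb = fb, a = a, f = f, wc = sigmoid(f))
}

#' @export
nn_forward.nn_mseca <- function(layer, x, training = FALSE) {
  stopifnot_fmap(x)
  d <- dim(x)
  ch <- mseca_channel_stage(layer, x, training)
  x1 <- x * bcast_cn(ch$wc, d)
  # spatial stage on the recalibrated map
  A <- reduce_c(x1) / d[3]
  m3 <- array(x1, c(d[1] * d[2], d[3], d[4]))
  am <- matrix(0L, d[1] * d[2], d[4])
  M <- matrix(0, d[1] * d[2], d[4])
  for (n in seq_len(d[4])) {
    mn <- m3[, , n, drop = TRUE]
    if (is.null(dim(mn))) mn <- matrix(mn, ncol = d[3])
    am[, n] <- max.col(mn, ties.method = "first")
    M[, n] <- mn[cbind(seq_len(nrow(mn)), am[, n])]
  }
  Fsp <- array(0, c(d[1], d[2], 2, d[4]))
  Fsp[, , 1, ] <- A
  Fsp[, , 2, ] <- array(M, c(d[1], d[2], d[4]))
  spatial <- layer$children[[layer$n_branch + 1L]]
  z <- nn_forward(spatial, Fsp, training)
  ws <- sigmoid(z)
  y <- x1 * bcast_hwn(ws, d)
  if (training) {
    layer$cache <- list(x = x, d = d, s = ch$s, fb = ch$fb, a = ch$a,
                        f = ch$f, wc = ch$wc, x1 = x1, am = am, ws = ws)
  }
  y
}

#' @export
nn_backward.nn_mseca <- function(layer, gy) {
  cc <- layer$cache
  d <- cc$d
  HW <- d[1] * d[2]
  spatial <- layer$children[[layer$n_branch + 1L]]

  gx1 <- gy * bcast_hwn(cc$ws, d)
  gws <- reduce_c(gy * cc$x1)
  gz <- gws * cc$ws * (1 - cc$ws)
  gFsp <- nn_backward(spatial, gz)
  gA <- gFsp[, , 1, , drop = FALSE]
  gM <- gFsp[, , 2, , drop = FALSE]
  gx1 <- gx1 + bcast_hwn(gA, d) / d[3]
  # route max-map gradient to the argmax channel
  hw_idx <- rep(seq_len(HW), d[4])
  n_idx <- rep(seq_len(d[4]), each = HW)
  flat <- hw_idx + HW * ((as.vector(cc$am) - 1L) + d[3] * (n_idx - 1L))
  gx1[flat] <- gx1[flat] + as.vector(gM)

  gwc <- reduce_hw(gx1 * cc$x)
  gx <- gx1 * bcast_cn(cc$wc, d)
  gf <- gwc * cc$wc * (1 - cc$wc)
  gs <- 0
  if (layer$learnable_fusion) {
    ga <- vapply(cc$fb, function(m) sum(gf * m), numeric(1))
    a <- cc$a
    layer$grads$fuse_logits <- layer$grads$fuse_logits +
      a * (ga - sum(a * ga))
    for (i in seq_len(layer$n_branch)) {
      gs <- gs + nn_backward(layer$children[[i]], a[i] * gf)
    }
  } else {
    for (i in seq_len(layer$n_branch)) {
      gs <- gs + nn_backward(layer$children[[i]], gf / layer$n_branch)
    }
  }
  gx + bcast_cn(gs / HW, d)
}

#' Multi-scale channel attention weights
#'
#' Runs only the channel stage of [nn_multiscale_eca()]: global average
#' pooling, parallel 1-D channel convolutions, mean fusion and sigmoid.
#'
#' @param x feature map, `dim = c(H, W, C, N)`.
#' @param block an [nn_multiscale_eca()] block for `C` channels; built fresh
#'   (random weights) when omitted.
#' @param kernel_sizes used when `block` is omitted.
#' @return C x N matrix of channel weights in (0, 1), one per channel and
#'   sample.
#' @export
multiscale_channel_weights <- function(x, block = NULL,
                                       kernel_sizes = c(3, 5, 7)) {
  stopifnot_fmap(x)
  if (is.null(block)) block <- nn_multiscale_eca(dim(x)[3], kernel_sizes)
  mseca_channel_stage(block, x, FALSE)$wc
}

#' Light spatial attention map
#'
#' Concatenates channel-wise average and max maps and applies the block's
#' 7x7 convolution plus sigmoid.
#'
#' @inheritParams multiscale_channel_weights
#' @return array `dim = c(H, W, 1, N)` with entries in (0, 1).
#' @export
spatial_attention <- function(x, block = NULL) {
  stopifnot_fmap(x)
  d <- dim(x)
  if (is.null(block)) block <- nn_multiscale_eca(d[3])
  A <- reduce_c(x) / d[3]
  m3 <- array(x, c(d[1] * d[2], d[3], d[4]))
  M <- matrix(0, d[1] * d[2], d[4])
  for (n in seq_len(d[4])) {
    mn <- matrix(m3[, , n], ncol = d[3])
    M[, n] <- mn[cbind(seq_len(nrow(mn)), max.col(mn, ties.method = "first"))]
  }
  Fsp <- array(0, c(d[1], d[2], 2, d[4]))
  Fsp[, , 1, ] <- A
  Fsp[, , 2, ] <- array(M, c(d[1], d[2], d[4]))
  spatial <- block$children[[block$n_branch + 1L]]
  sigmoid(nn_forward(spatial, Fsp, FALSE))
}

#' Full multi-scale ECA forward pass
#'
#' @inheritParams multiscale_channel_weights
#' @return recalibrated feature map of the same shape as `x`.
#' @export
multiscale_eca_forward <- function(x, block = NULL,
                                   kernel_sizes = c(3, 5, 7)) {
  stopifnot_fmap(x)
  if (is.null(block)) block <- nn_multiscale_eca(dim(x)[3], kernel_sizes)
  nn_forward(block, x, FALSE)
}

# ---------------------------------------------------------------------------
# Channel context module
# ---------------------------------------------------------------------------

#' Channel context module (CCM)
#'
#' Global average pooling, 1x1 compression to `max(floor(C/r), 1)` channels
#' (batch norm + ReLU), 1x1 restoration (batch norm), sigmoid gating,
#' channel-wise rescaling of the input.
#'
#' @param channels input channel count.
#' @param r reduction ratio.
#' @return an `nn_layer`.
#' @export
nn_ccm <- function(channels, r = 16) {
  if (r < 1) stop("reduction ratio r must be >= 1")
  if (channels < 1) stop("channel count must be >= 1")
  hidden <- max(channels %/% r, 1L)
  l <- new_layer("ccm", channels = channels, r = r, hidden = hidden)
  l$children <- list(nn_sequential(
    nn_cvec_linear(channels, hidden, bias = TRUE),
    nn_bn1d(hidden),
    nn_act("relu"),
    nn_cvec_linear(hidden, channels, bias = TRUE),
    nn_bn1d(channels)))
  l
}

#' @export
nn_forward.nn_ccm <- function(layer, x, training = FALSE) {
  stopifnot_fmap(x)
  d <- dim(x)
  s <- reduce_hw(x) / (d[1] * d[2])
  z2 <- nn_forward(layer$children[[1]], s, training)
  wc <- sigmoid(z2)
  if (training) layer$cache <- list(x = x, d = d, wc = wc)
  x * bcast_cn(wc, d)
}

#' @export
nn_backward.nn_ccm <- function(layer, gy) {
  cc <- layer$cache
  d <- cc$d
  gwc <- reduce_hw(gy * cc$x)
  gx <- gy * bcast_cn(cc$wc, d)
  gz2 <- gwc * cc$wc * (1 - cc$wc)
  gs <- nn_backward(layer$children[[1]], gz2)
  gx + bcast_cn(gs / (d[1] * d[2]), d)
}

#' Functional CCM forward
#'
#' @param x feature map.
#' @param r reduction ratio, used when `block` is omitted.
#' @param block an existing [nn_ccm()] block.
#' @return gated feature map, same shape as `x`.
#' @export
ccm_forward <- function(x, r = 16, block = NULL) {
  stopifnot_fmap(x)
  if (is.null(block)) block <- nn_ccm(dim(x)[3], r)
  nn_forward(block, x, FALSE)
}

# ---------------------------------------------------------------------------
# Light atrous spatial pyramid pooling
# ---------------------------------------------------------------------------

#' Light atrous spatial pyramid pooling block
#'
#' Three parallel 3x3 dilated convolutions (padding equal to the rate keeps
#' H x W), each with batch norm + ReLU, plus a global-average-pooling branch
#' compressed to `gap_channels` by a 1x1 convolution (batch norm + ReLU) and
#' bilinearly upsampled back to H x W (interpolation of a 1x1 map, i.e. a
#' spatial constant).  Branch outputs are concatenated without a fusing 1x1
#' convolution, so the output width is
#' `3 * branch_channels + gap_channels`.
#'
#' @param in_ch input channels.
#' @param rates dilation rates.
#' @param branch_channels width of each dilated branch.
#' @param gap_channels width of the global branch.
#' @return an `nn_layer`.
#' @export
nn_light_aspp <- function(in_ch, rates = c(3, 6, 9), branch_channels = 128,
                          gap_channels = 128) {
  if (any(rates <= 0)) stop("dilation rates must be positive")
  l <- new_layer("light_aspp", in_ch = in_ch, rates = as.integer(rates),
                 branch_channels = as.integer(branch_channels),
                 gap_channels = as.integer(gap_channels))
  dil <- lapply(rates, function(r) nn_sequential(
    nn_conv2d(in_ch, branch_channels, 3, pad = r, dilation = r),
    nn_bn2d(branch_channels),
    nn_act("relu")))
  gapb <- nn_sequential(nn_cvec_linear(in_ch, gap_channels, bias = FALSE),
                        nn_bn1d(gap_channels),
                        nn_act("relu"))
  l$children <- c(dil, list(gapb))
  l$out_ch <- length(rates) * branch_channels + gap_channels
  l
}

#' @export
nn_forward.nn_light_aspp <- function(layer, x, training = FALSE) {
  stopifnot_fmap(x)
  d <- dim(x)
  nr <- length(layer$rates)
  bc <- layer$branch_channels
  y <- array(0, c(d[1], d[2], layer$out_ch, d[4]))
  for (i in seq_len(nr)) {
    y[, , ((i - 1) * bc + 1):(i * bc), ] <-
      nn_forward(layer$children[[i]], x, training)
  }
  s <- reduce_hw(x) / (d[1] * d[2])
  g <- nn_forward(layer$children[[nr + 1L]], s, training)   # gap_ch x N
  y[, , (nr * bc + 1):layer$out_ch, ] <-
    bcast_cn(g, c(d[1], d[2], layer$gap_channels, d[4]))
  if (training) layer$cache <- list(d = d)
  y
}

#' @export
nn_backward.nn_light_aspp <- function(layer, gy) {
  d <- layer$cache$d
  nr <- length(layer$rates)
  bc <- layer$branch_channels
  gx <- array(0, d)
  for (i in seq_len(nr)) {
    gx <- gx + nn_backward(layer$children[[i]],
                           gy[, , ((i - 1) * bc + 1):(i * bc), , drop = FALSE])
  }
  gg <- reduce_hw(gy[, , (nr * bc + 1):layer$out_ch, , drop = FALSE])
  gs <- nn_backward(layer$children[[nr + 1L]], gg)
  gx + bcast_cn(gs / (d[1] * d[2]), d)
}

#' Functional light-ASPP forward
#'
#' @param x feature map.
#' @param cfg a [block_config()]; its `aspp_*` entries set the geometry when
#'   `block` is omitted.
#' @param block an existing [nn_light_aspp()] block.
#' @return feature map with `3 * branch + gap` channels and unchanged H x W.
#' @export
light_aspp_forward <- function(x, cfg = block_config(), block = NULL) {
  stopifnot_fmap(x)
  if (is.null(block)) {
    block <- nn_light_aspp(dim(x)[3], cfg$aspp_rates,
                           cfg$aspp_branch_channels, cfg$aspp_gap_channels)
  }
  nn_forward(block, x, FALSE)
}

# ---------------------------------------------------------------------------
# Mixed pooling
# ---------------------------------------------------------------------------

#' Mixed max/average pooling (functional form)
#'
#' `y = lambda * maxpool(x) + (1 - lambda) * avgpool(x)`, computed per
#' window, or over all of H x W in global mode.
#'
#' @param x feature map.
#' @param lam mixing weight in `[0, 1]`.
#' @param mode `"global"` or `"window"`.
#' @param window,stride pooling geometry in window mode.
#' @return pooled feature map (`1 x 1 x C x N` in global mode).
#' @export
mixed_pool <- function(x, lam, mode = c("global", "window"), window = 2,
                       stride = window) {
  stopifnot_fmap(x)
  if (lam < 0 || lam > 1) stop("lambda must lie in [0, 1]")
  mode <- match.arg(mode)
  d <- dim(x)
  if (mode == "global") {
    xm <- matrix(x, nrow = d[1] * d[2])
    mx <- apply(xm, 2, max)
    av <- colMeans(xm)
    array(lam * mx + (1 - lam) * av, c(1, 1, d[3], d[4]))
  } else {
    window <- rep(as.integer(window), length.out = 2)
    stride <- rep(as.integer(stride), length.out = 2)
    if (window[1] > d[1] || window[2] > d[2]) {
      stop("pooling window larger than input")
    }
    mx <- .cpp_pool2d_fwd(x, window, stride, 0L)$y
    av <- .cpp_pool2d_fwd(x, window, stride, 1L)$y
    lam * mx + (1 - lam) * av
  }
}

#' Global mixed pooling layer with trainable mixing weight
#'
#' The mixing weight is stored as a logit `rho` and squashed by a sigmoid,
#' which keeps `lambda = sigmoid(rho)` inside `[0, 1]` while leaving it
#' freely trainable. Output is an `N x C` matrix ready for a classifier.
#'
#' @param lambda_init initial mixing weight.
#' @export
nn_mixed_pool_global <- function(lambda_init = 0.5) {
  if (lambda_init < 0 || lambda_init > 1) stop("lambda_init must be in [0, 1]")
  l <- new_layer("mixed_pool_global")
  rho <- stats::qlogis(min(max(lambda_init, 1e-6), 1 - 1e-6))
  add_param(l, "rho", rho)
  l
}

#' @export
nn_forward.nn_mixed_pool_global <- function(layer, x, training = FALSE) {
  d <- dim(x)
  lam <- sigmoid(layer$params$rho)
  xm <- matrix(x, nrow = d[1] * d[2])                 # HW x (C*N)
  am <- max.col(t(xm), ties.method = "first")
  mx <- xm[cbind(am, seq_along(am))]
  av <- colMeans(xm)
  y <- lam * mx + (1 - lam) * av
  if (training) layer$cache <- list(d = d, am = am, mx = mx, av = av, lam = lam)
  t(matrix(y, nrow = d[3]))                            # N x C
}

#' @export
nn_backward.nn_mixed_pool_global <- function(layer, gy) {
  cc <- layer$cache
  d <- cc$d
  HW <- d[1] * d[2]
  g <- as.vector(t(gy))                                # per (c, n) column
  layer$grads$rho <- layer$grads$rho +
    sum(g * (cc$mx - cc$av)) * cc$lam * (1 - cc$lam)
  gxm <- matrix(rep(g * (1 - cc$lam) / HW, each = HW), nrow = HW)
  idx <- cbind(cc$am, seq_along(cc$am))
  gxm[idx] <- gxm[idx] + g * cc$lam
  array(gxm, d)
}

#' Current mixing weight of a mixed-pooling layer
#' @param layer an [nn_mixed_pool_global()] layer.
#' @return lambda in `[0, 1]`.
#' @export
mixed_pool_lambda <- function(layer) sigmoid(layer$params$rho)

# ---------------------------------------------------------------------------
# Learnable stochastic depth
# ---------------------------------------------------------------------------

#' Learnable stochastic-depth gate
#'
#' Drop probability `p = sigmoid(theta) * p_max` with trainable `theta`.
#' In training, each sample's residual branch is kept with probability
#' `1 - p` and rescaled by `1 / (1 - p)` so the expectation matches the
#' identity; gradient reaches `theta` through the rescaling factor. In
#' evaluation the layer is the identity.
#'
#' @param p_init initial drop probability in `[0, 1)`.
#' @param p_max upper bound of the drop probability, `< 1`.
#' @export
nn_droppath <- function(p_init = 0.0, p_max = 0.2) {
  if (p_max >= 1) stop("p_max must be < 1")
  if (p_init < 0 || p_init >= 1) stop("p_init must lie in [0, 1)")
  frac <- min(max(p_init / p_max, 1e-6), 1 - 1e-6)
  l <- new_layer("droppath", p_max = p_max)
  add_param(l, "theta", stats::qlogis(frac))
  l
}

#' @export
nn_forward.nn_droppath <- function(layer, x, training = FALSE) {
  if (!training) {
    layer$cache <- NULL
    return(x)
  }
  d <- dim(x)
  p <- sigmoid(layer$params$theta) * layer$p_max
  g <- stats::rbinom(d[4], 1, 1 - p)
  scale <- g / (1 - p)
  fac <- array(rep(scale, each = prod(d[1:3])), d)
  layer$cache <- list(x = x, g = g, p = p, d = d)
  x * fac
}

#' @export
nn_backward.nn_droppath <- function(layer, gy) {
  cc <- layer$cache
  if (is.null(cc)) return(gy)
  d <- cc$d
  scale <- cc$g / (1 - cc$p)
  per_sample <- colSums(matrix(gy * cc$x, ncol = d[4]))
  th <- layer$params$theta
  dp_dtheta <- layer$p_max * sigmoid(th) * (1 - sigmoid(th))
  layer$grads$theta <- layer$grads$theta +
    sum(per_sample * cc$g / (1 - cc$p)^2) * dp_dtheta
  gy * array(rep(scale, each = prod(d[1:3])), d)
}

#' Drop probability of a stochastic-depth layer
#' @param layer an [nn_droppath()] layer.
#' @return current drop probability.
#' @export
droppath_p <- function(layer) sigmoid(layer$params$theta) * layer$p_max

#' Functional learnable stochastic depth
#'
#' @param x_residual residual-branch feature map.
#' @param theta drop-probability logit; `p = sigmoid(theta) * p_max`.
#' @param training apply the stochastic gate (`TRUE`) or the identity.
#' @param seed RNG seed for the per-sample gates.
#' @param p_max upper bound of the drop probability (< 1).
#' @return gated feature map with expectation equal to `x_residual`.
#' @export
learnable_droppath <- function(x_residual, theta, training = TRUE,
                               seed = NULL, p_max = 0.2) {
  stopifnot_fmap(x_residual)
  if (p_max >= 1) stop("p_max must be < 1")
  if (!training) return(x_residual)
  d <- dim(x_residual)
  p <- sigmoid(theta) * p_max
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  }
  g <- stats::rbinom(d[4], 1, 1 - p)
  x_residual * array(rep(g / (1 - p), each = prod(d[1:3])), d)
}

# ---------------------------------------------------------------------------
# Squeeze-and-excitation (baseline MBConv)
# ---------------------------------------------------------------------------

# Standard SE block: squeeze width max(1, floor(block_in / 4)) measured on
# the block's input channels (pre-expansion), two biased 1x1 convolutions
# with swish in between, sigmoid gate.
nn_se <- function(expanded_ch, block_in_ch) {
  sq <- max(1L, block_in_ch %/% 4L)
  l <- new_layer("se", channels = expanded_ch, squeeze = sq)
  l$children <- list(nn_sequential(
    nn_cvec_linear(expanded_ch, sq, bias = TRUE),
    nn_act("swish"),
    nn_cvec_linear(sq, expanded_ch, bias = TRUE)))
  l
}

#' @export
nn_forward.nn_se <- function(layer, x, training = FALSE) {
  d <- dim(x)
  s <- reduce_hw(x) / (d[1] * d[2])
  wc <- sigmoid(nn_forward(layer$children[[1]], s, training))
  if (training) layer$cache <- list(x = x, d = d, wc = wc)
  x * bcast_cn(wc, d)
}

#' @export
nn_backward.nn_se <- function(layer, gy) {
  cc <- layer$cache
  d <- cc$d
  gwc <- reduce_hw(gy * cc$x)
  gx <- gy * bcast_cn(cc$wc, d)
  gz <- gwc * cc$wc * (1 - cc$wc)
  gs <- nn_backward(layer$children[[1]], gz)
  gx + bcast_cn(gs / (d[1] * d[2]), d)
}
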