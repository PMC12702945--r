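# Unit tests for the attention / pooling / stochastic-depth blocks, checked
# against the nested-loop oracles in helper-oracles.R.

test_that("compiled convolution matches the nested-loop oracle", {
  set.seed(10)
  cases <- list(
    list(h = 7, w = 6, cin = 3, cout = 4, k = 3, stride = 1, pad = 1,
         dil = 1, groups = 1),
    list(h = 8, w = 8, cin = 4, cout = 4, k = 3, stride = 2, pad = 1,
         dil = 1, groups = 4),                      # depthwise
    list(h = 9, w = 9, cin = 2, cout = 3, k = 3, stride = 1, pad = 3,
         dil = 3, groups = 1),                      # dilated
    list(h = 5, w = 5, cin = 4, cout = 6, k = 1, stride = 1, pad = 0,
         dil = 1, groups = 2))                      # grouped 1x1
  for (cs in cases) {
    x <- rand_fmap(cs$h, cs$w, cs$cin, 2)
    l <- nn_conv2d(cs$cin, cs$cout, cs$k, stride = cs$stride, pad = cs$pad,
                   dilation = cs$dil, groups = cs$groups, bias = TRUE)
    y <- nn_forward(l, x)
    yo <- oracle_conv2d(x, l$params$W, l$params$b,
                        stride = rep(cs$stride, 2), pad = rep(cs$pad, 2),
                        dilation = rep(cs$dil, 2), groups = cs$groups)
    expect_equal(y, yo, tolerance = 1e-10)
  }
})

test_that("multi-scale channel attention follows its defining equations", {
  set.seed(21)
  x <- rand_fmap(5, 5, 4, 2)
  blk <- nn_multiscale_eca(4, c(3, 5, 7))
  # zero 1-D weights: sigmoid(0) = 0.5 everywhere
  set_all_params(blk)
  expect_true(all(multiscale_channel_weights(x, blk) == 0.5))

  # identical branches with k = 3: mean fusion equals a single branch
  blk3 <- nn_multiscale_eca(4, c(3, 3, 3))
  w3 <- c(0.2, -0.4, 0.7)
  for (i in 1:3) {
    blk3$children[[i]]$params$W <- w3
    blk3$children[[i]]$params$b <- 0.1
  }
  single <- nn_multiscale_eca(4, 3)
  single$children[[1]]$params$W <- w3
  single$children[[1]]$params$b <- 0.1
  expect_equal(multiscale_channel_weights(x, blk3),
               multiscale_channel_weights(x, single), tolerance = 1e-12)

  # centre-tap kernel picks out each channel's own pooled mean
  xc <- array(0, c(3, 3, 4, 1))
  for (c in 1:4) xc[, , c, 1] <- c
  blk1 <- nn_multiscale_eca(4, 3)
  blk1$children[[1]]$params$W <- c(0, 1, 0)
  blk1$children[[1]]$params$b <- 0
  expect_equal(as.vector(multiscale_channel_weights(xc, blk1)),
               1 / (1 + exp(-(1:4))), tolerance = 1e-12)

  # random weights agree with the first-principles oracle
  blkr <- nn_multiscale_eca(6, c(3, 5, 7))
  xr <- rand_fmap(4, 6, 6, 3)
  wo <- oracle_channel_weights(
    xr, lapply(blkr$children[1:3], function(b) b$params$W),
    lapply(blkr$children[1:3], function(b) b$params$b))
  expect_equal(multiscale_channel_weights(xr, blkr), wo, tolerance = 1e-10)
  expect_true(all(wo > 0 & wo < 1))
})

test_that("spatial attention matches channel-pool + 7x7 conv oracle", {
  set.seed(22)
  x <- rand_fmap(5, 5, 3, 1)
  blk <- nn_multiscale_eca(3)
  ws <- spatial_attention(x, blk)
  expect_equal(dim(ws), c(5, 5, 1, 1))
  # oracle: explicit channel mean/max then 7x7 correlation
  Fsp <- array(0, c(5, 5, 2, 1))
  for (i in 1:5) for (j in 1:5) {
    Fsp[i, j, 1, 1] <- mean(x[i, j, , 1])
    Fsp[i, j, 2, 1] <- max(x[i, j, , 1])
  }
  sc <- blk$children[[4]]
  z <- oracle_conv2d(Fsp, sc$params$W, sc$params$b, pad = c(3, 3))
  expect_equal(ws, 1 / (1 + exp(-z)), tolerance = 1e-10)

  # input constant across channels: avg and max maps coincide
  xc <- array(rep(rand_fmap(4, 4, 1, 1), 3), c(4, 4, 3, 1))
  for (i in 1:4) for (j in 1:4) {
    expect_equal(mean(xc[i, j, , 1]), max(xc[i, j, , 1]))
  }

  # zero conv weights: weight map is 0.5 everywhere
  set_all_params(blk)
  expect_true(all(spatial_attention(x, blk) == 0.5))
})

test_that("full multi-scale ECA contracts and hits its analytic limits", {
  set.seed(23)
  x <- rand_fmap(7, 7, 5, 2)
  blk <- nn_multiscale_eca(5)
  y <- nn_forward(blk, x)
  expect_equal(dim(y), dim(x))
  expect_true(all(abs(y) <= abs(x) + 1e-12))

  # zero weights everywhere: 0.5 channel x 0.5 spatial = 0.25 x
  set_all_params(blk)
  expect_equal(nn_forward(blk, x), 0.25 * x, tolerance = 1e-12)

  # huge spatial bias pushes both gates to ~1: output approaches x
  blk$children[[4]]$params$b <- 50
  for (i in 1:3) blk$children[[i]]$params$b <- 50
  expect_equal(nn_forward(blk, x), x, tolerance = 1e-6)

  # shape preservation across degenerate spatial sizes
  for (hw in c(1, 7, 8)) {
    xs <- rand_fmap(hw, hw, 3, 1)
    expect_equal(dim(nn_forward(nn_multiscale_eca(3), xs)), dim(xs))
  }
})

test_that("channel context module gates per channel and contracts", {
  set.seed(24)
  x <- rand_fmap(6, 5, 8, 2)
  blk <- nn_ccm(8, r = 4)
  y <- nn_forward(blk, x)
  expect_equal(dim(y), dim(x))
  expect_true(all(abs(y) <= abs(x) + 1e-12))
  # the gate is one scalar per channel: constant ratio across H, W
  ratio <- y / x
  for (c in 1:8) for (n in 1:2) {
    expect_equal(max(ratio[, , c, n]) - min(ratio[, , c, n]), 0,
                 tolerance = 1e-9)
  }

  # forcing the second 1x1 conv to zero gives exactly 0.5 x (fresh batch
  # norms are identity in eval mode up to the variance floor)
  inner <- blk$children[[1]]$children
  inner[[4]]$params$W[] <- 0
  inner[[4]]$params$b[] <- 0
  expect_equal(nn_forward(blk, x), 0.5 * x, tolerance = 1e-5)

  # hidden width rule: floor(C / r) with a minimum of 1
  expect_equal(nn_ccm(32, 16)$hidden, 2L)
  expect_equal(nn_ccm(8, 16)$hidden, 1L)
  expect_error(nn_ccm(8, 0), "reduction")
})

test_that("light ASPP geometry, constant-input and dilation oracle checks", {
  set.seed(25)
  x <- rand_fmap(9, 9, 2, 1)
  blk <- nn_light_aspp(2, rates = c(3, 6, 9), branch_channels = 4,
                       gap_channels = 3)
  y <- nn_forward(blk, x)
  expect_equal(dim(y), c(9, 9, 3 * 4 + 3, 1))

  # output channel count for the published widths
  expect_equal(nn_light_aspp(320, branch_channels = 128,
                             gap_channels = 128)$out_ch, 512L)

  # global branch of a constant input is spatially constant
  xc <- array(2.5, c(6, 6, 2, 1))
  yc <- nn_forward(blk, xc)
  gap_slice <- yc[, , 13:15, 1, drop = FALSE]
  for (c in 1:3) {
    expect_equal(max(gap_slice[, , c, 1]) - min(gap_slice[, , c, 1]), 0,
                 tolerance = 1e-12)
  }

  # rate-3 branch against the nested-loop dilated convolution oracle
  br <- blk$children[[1]]$children[[1]]
  z <- nn_forward(br, x)
  zo <- oracle_conv2d(x, br$params$W, NULL, pad = c(3, 3),
                      dilation = c(3, 3))
  expect_equal(z, zo, tolerance = 1e-10)
  # with an identity-like centre-tap kernel the branch is channel mixing
  br$params$W[] <- 0
  br$params$W[2, 2, 1, 1] <- 1
  z1 <- nn_forward(br, x)
  expect_equal(z1[, , 1, 1], x[, , 1, 1], tolerance = 1e-12)

  expect_error(nn_light_aspp(2, rates = c(0, 3, 6)), "positive")
})

test_that("mixed pooling interpolates between max and average pooling", {
  set.seed(26)
  x <- rand_fmap(8, 8, 3, 1)
  expect_equal(mixed_pool(x, 1, "window", 2, 2),
               oracle_pool2d(x, 2, 2, max), tolerance = 1e-12)
  expect_equal(mixed_pool(x, 0, "window", 2, 2),
               oracle_pool2d(x, 2, 2, mean), tolerance = 1e-12)

  # the printed single-window example: values {1,2,3,4}, lambda = 0.5
  xw <- array(c(1, 2, 3, 4), c(2, 2, 1, 1))
  expect_equal(as.vector(mixed_pool(xw, 0.5, "window", 2, 2)), 3.25)

  # arbitrary lambda against the per-window oracle
  y <- mixed_pool(x, 0.3, "window", 2, 2)
  yo <- 0.3 * oracle_pool2d(x, 2, 2, max) + 0.7 * oracle_pool2d(x, 2, 2, mean)
  expect_equal(y, yo, tolerance = 1e-12)

  # global mode bounds and monotonicity in lambda
  lams <- seq(0, 1, by = 0.25)
  ys <- vapply(lams, function(l) as.vector(mixed_pool(x, l))[1], numeric(1))
  expect_true(all(diff(ys) >= -1e-12))
  g <- mixed_pool(x, 0.6)
  expect_true(all(g >= min(x) - 1e-12 & g <= max(x) + 1e-12))

  expect_error(mixed_pool(x, 0.5, "window", 16, 16), "window")
  expect_error(mixed_pool(x, 1.5), "lambda")
})

test_that("learnable stochastic depth is identity in eval and unbiased in training", {
  set.seed(27)
  x <- rand_fmap(3, 3, 2, 4)
  expect_identical(learnable_droppath(x, theta = 1.3, training = FALSE), x)
  # p -> 0 limit: training output equals the input
  expect_equal(learnable_droppath(x, theta = -30, training = TRUE, seed = 1),
               x, tolerance = 1e-10)
  # Monte-Carlo expectation at p = 0.5: mean gate scale within 3 SE of 1
  p_max <- 0.6
  theta <- stats::qlogis(0.5 / p_max)   # p = 0.5
  B <- 10000
  xb <- array(1, c(1, 1, 1, B))
  y <- learnable_droppath(xb, theta, training = TRUE, seed = 99,
                          p_max = p_max)
  se <- stats::sd(y) / sqrt(B)
  expect_lt(abs(mean(y) - 1), 3 * se)
  expect_error(learnable_droppath(x, 0, p_max = 1), "p_max")
})

test_that("attention weights stay in [0,1] and blocks preserve shape on random inputs", {
  set.seed(28)
  for (trial in 1:5) {
    h <- sample(c(1, 4, 7, 8), 1); w <- sample(c(1, 5, 8), 1)
    c <- sample(c(1, 3, 8), 1); n <- sample(1:3, 1)
    x <- rand_fmap(h, w, c, n)
    wc <- multiscale_channel_weights(x, nn_multiscale_eca(c))
    expect_true(all(wc >= 0 & wc <= 1))
    ws <- spatial_attention(x, nn_multiscale_eca(c))
    expect_true(all(ws >= 0 & ws <= 1))
    y1 <- nn_forward(nn_multiscale_eca(c), x)
    y2 <- nn_forward(nn_ccm(c, 4), x)
    expect_equal(dim(y1), dim(x))
    expect_equal(dim(y2), dim(x))
    expect_true(all(abs(y1) <= abs(x) + 1e-12))
    expect_true(all(abs(y2) <= abs(x) + 1e-12))
  }
  expect_error(nn_multiscale_eca(4, kernel_sizes = c(2, 4)), "odd")
})

test_that("composite blocks backpropagate correctly (finite differences)", {
  set.seed(31)
  x0 <- rand_fmap(6, 6, 4, 3)
  tgt <- rand_fmap(6, 6, 4, 3)
  for (maker in list(function() nn_multiscale_eca(4),
                     function() nn_ccm(4, 2),
                     function() nn_mbconv(4, 4, 6, 3, 1, "mseca",
                                          use_ccm = TRUE,
                                          droppath_p_init = 0.1))) {
    blk <- maker()
    loss_fn <- function() {
      set.seed(5)
      y <- nn_forward(blk, x0, training = TRUE)
      0.5 * sum((y - tgt)^2)
    }
    loss_fn()
    set.seed(5)
    y <- nn_forward(blk, x0, training = TRUE)
    nn_zero_grad(blk)
    nn_backward(blk, y - tgt)
    ps <- nn_parameters(blk)
    set.seed(77)
    for (i in sample(seq_along(ps), min(10, length(ps)))) {
      p <- ps[[i]]
      arr <- p$layer$params[[p$name]]
      j <- sample(length(arr), 1)
      eps <- 1e-5
      p$layer$params[[p$name]][j] <- arr[j] + eps; lp <- loss_fn()
      p$layer$params[[p$name]][j] <- arr[j] - eps; lm <- loss_fn()
      p$layer$params[[p$name]][j] <- arr[j]
      num <- (lp - lm) / (2 * eps)
      ana <- p$layer$grads[[p$name]][j]
      rel <- abs(num - ana) / max(1e-4, abs(num) + abs(ana))
      expect_lt(rel, 1e-3,
                label = sprintf("%s$%s[%d] gradient error", p$layer$kind,
                                p$name, j))
    }
  }
})
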