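# Network assembly and complexity accounting.

std_stages <- function() {
  list(stage_spec(1, 3, 1, 16, 1), stage_spec(6, 3, 2, 24, 2),
       stage_spec(6, 5, 2, 40, 2), stage_spec(6, 3, 2, 80, 3),
       stage_spec(6, 5, 1, 112, 3), stage_spec(6, 5, 2, 192, 4),
       stage_spec(6, 3, 1, 320, 1))
}

test_that("baseline build matches the standard profile", {
  set.seed(1)
  b0 <- build_baseline_b0(8)
  expect_equal(count_parameters(b0, millions = FALSE), 4017796)
  expect_equal(count_mbconv_blocks(b0), 16L)  # 1+2+2+3+3+4+1
  expect_error(build_baseline_b0(1), "num_classes")
})

test_that("modified build has 13 blocks and the calibrated complexity", {
  set.seed(1)
  en <- build_enet_caem()
  expect_equal(count_mbconv_blocks(en), 13L)
  expect_equal(count_parameters(en), 6.55)
  # invalid repeat total under the 13-block profile is a configuration error
  bad <- enet_caem_config()$stages
  bad[[7]]$repeats <- 2L
  expect_error(architecture_config(bad, total_mbconv_blocks = 13), "repeats")
  # CCM outside Stages 4-6 is rejected on the 7-stage profile
  st <- std_stages()
  st[[1]]$use_ccm <- TRUE
  expect_error(architecture_config(st), "Stages 4-6")
})

test_that("MBConv blocks honour stride, expansion and residual contracts", {
  set.seed(2)
  # residual identity: zero projection + eval mode returns the input
  blk <- nn_mbconv(6, 6, 6, 3, 1, "mseca")
  proj <- blk$children$proj$children[[1]]
  proj$params$W[] <- 0
  x <- rand_fmap(8, 8, 6, 2)
  expect_equal(improved_mbconv_forward(x, blk, training = FALSE), x,
               tolerance = 1e-12)
  # stride-2 halves the spatial dims
  blk2 <- nn_mbconv(16, 24, 6, 3, 2, "mseca")
  y <- improved_mbconv_forward(rand_fmap(32, 32, 16, 1), blk2)
  expect_equal(dim(y), c(16, 16, 24, 1))
  # expansion width
  expect_equal(nn_mbconv(16, 16, 6, 3, 1)$expanded, 96)
  expect_error(improved_mbconv_forward(rand_fmap(8, 8, 5, 1), blk),
               "channels")
})

test_that("parameter counting agrees with closed forms and a brute-force walk", {
  set.seed(3)
  expect_equal(count_parameters(nn_conv2d(2, 4, 3), millions = FALSE), 72)
  expect_equal(count_parameters(nn_linear(512, 8), millions = FALSE), 4104)
  net <- build_enet_caem(enet_caem_mini_config())
  # independent recursive walk over every parameter array
  walk <- function(l) {
    sum(vapply(l$params, length, numeric(1))) +
      sum(vapply(l$children, walk, numeric(1)))
  }
  expect_equal(count_parameters(net, millions = FALSE), walk(net))
})

test_that("MAC counting matches closed-form recomputation on a toy net", {
  set.seed(4)
  l1 <- nn_conv2d(2, 4, 3, pad = 1)
  expect_equal(macs_of(l1, c(8, 8))$macs, 3 * 3 * 2 * 4 * 8 * 8)  # 4608
  ldw <- nn_conv2d(4, 4, 3, pad = 1, groups = 4)
  expect_equal(macs_of(ldw, c(8, 8))$macs, 3 * 3 * 4 * 8 * 8)     # 2304
  toy <- nn_sequential(l1, ldw, nn_gap(), nn_linear(4, 3))
  expect_equal(macs_of(toy, c(8, 8))$macs, 4608 + 2304 + 4 * 3)
  # a strided layer halves the spatial size seen downstream
  ls <- nn_conv2d(2, 2, 3, stride = 2, pad = 1)
  two <- nn_sequential(ls, nn_conv2d(2, 4, 3, pad = 1))
  expect_equal(macs_of(two, c(8, 8))$macs,
               3 * 3 * 2 * 2 * 4 * 4 + 3 * 3 * 2 * 4 * 4 * 4)
})

test_that("builds are deterministic and forward passes are reproducible", {
  set.seed(7)
  n1 <- build_enet_caem(enet_caem_mini_config())
  set.seed(7)
  n2 <- build_enet_caem(enet_caem_mini_config())
  expect_equal(count_parameters(n1, millions = FALSE),
               count_parameters(n2, millions = FALSE))
  x <- rand_fmap(48, 48, 3, 2, seed = 8)
  expect_identical(nn_forward(n1, x), nn_forward(n2, x))
})

test_that("full-size forward passes produce finite logits of the right shape", {
  set.seed(9)
  en <- build_enet_caem()
  y <- nn_forward(en, rand_fmap(224, 224, 3, 2, seed = 10))
  expect_equal(dim(y), c(2, 8))
  expect_true(all(is.finite(y)))
  b0 <- build_baseline_b0(8)
  y0 <- nn_forward(b0, rand_fmap(224, 224, 3, 1, seed = 11))
  expect_equal(dim(y0), c(1, 8))
  expect_true(all(is.finite(y0)))
})

test_that("every trainable tensor receives a finite gradient after one step", {
  set.seed(12)
  net <- build_enet_caem(enet_caem_mini_config(num_classes = 4,
                                               input_size = 16))
  x <- rand_fmap(16, 16, 3, 4, seed = 13)
  nn_zero_grad(net)
  logits <- nn_forward(net, x, training = TRUE)
  g <- matrix(stats::rnorm(length(logits)), nrow(logits))
  nn_backward(net, g)
  kinds <- character(0)
  for (p in nn_parameters(net)) {
    gr <- p$layer$grads[[p$name]]
    expect_true(all(is.finite(gr)),
                label = sprintf("finite grad for %s$%s", p$layer$kind,
                                p$name))
    if (sum(abs(gr)) > 0) kinds <- c(kinds, p$layer$kind)
  }
  # the bespoke trainables all sit on the gradient path
  for (k in c("mixed_pool_global", "droppath", "conv1d_channel",
              "cvec_linear", "conv2d", "bn2d", "linear")) {
    expect_true(k %in% kinds, label = sprintf("%s receives gradient", k))
  }
})

test_that("structural ablations move the parameter count the right way", {
  set.seed(14)
  with_ccm <- nn_mbconv(16, 16, 6, 5, 1, "mseca", use_ccm = TRUE,
                        learnable_droppath = FALSE)
  without_ccm <- nn_mbconv(16, 16, 6, 5, 1, "mseca", use_ccm = FALSE,
                           learnable_droppath = FALSE)
  with_se <- nn_mbconv(16, 16, 6, 5, 1, "se", learnable_droppath = FALSE)
  p <- function(b) count_parameters(b, millions = FALSE)
  expect_gt(p(with_ccm), p(without_ccm))     # CCM adds parameters
  expect_lt(p(without_ccm), p(with_se))      # 1-D attention is lighter than SE
})
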