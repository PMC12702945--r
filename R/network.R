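# Backbone assembly: baseline EfficientNetB0 and the modified variant with a
# reduced 13-block backbone, CCM in the 40/80/112-channel stages, multi-scale
# channel attention in every block, and a light-ASPP + mixed-pooling head.
# Also the closed-form parameter / multiply-accumulate accounting.

#' Stage specification
#'
#' One backbone stage: a run of `repeats` inverted-bottleneck (MBConv)
#' blocks. Stride applies to the first block of the stage only.
#'
#' @param expansion channel expansion factor (1 or 6 in the standard
#'   profiles).
#' @param kernel odd depthwise kernel size.
#' @param stride 1 or 2.
#' @param out_channels output width of the stage.
#' @param repeats number of blocks.
#' @param use_ccm embed a channel context module after the depthwise
#'   convolution of each block in this stage.
#' @return a list of class `"stage_spec"`.
#' @export
stage_spec <- function(expansion, kernel, stride, out_channels, repeats,
                       use_ccm = FALSE) {
  if (!stride %in% c(1, 2)) stop("stride must be 1 or 2")
  if (kernel %% 2 == 0) stop("depthwise kernel size must be odd")
  if (out_channels < 1 || repeats < 1) stop("channels and repeats must be >= 1")
  structure(list(expansion = expansion, kernel = as.integer(kernel),
                 stride = as.integer(stride),
                 out_channels = as.integer(out_channels),
                 repeats = as.integer(repeats), use_ccm = isTRUE(use_ccm)),
            class = "stage_spec")
}

#' Architecture configuration
#'
#' Declarative description of a backbone build; the single source of truth
#' for [build_enet_caem()] and the complexity accounting.
#'
#' @param stages list of [stage_spec()]s (backbone Stages 2...8; the stem is
#'   Stage 1 and the head Stage 9).
#' @param num_classes classifier width (>= 2).
#' @param input_size `c(H, W)` the model is accounted at.
#' @param stem_channels stem convolution width.
#' @param block a [block_config()] with the attention/pooling settings.
#' @param head list with `retain_1x1_expand` (keep the 1x1 expansion to 1280
#'   channels in front of the pyramid head) and `dropout_rate`.
#' @param total_mbconv_blocks expected sum of repeats; a mismatch is a
#'   configuration error.
#' @return a list of class `"architecture_config"`.
#' @export
architecture_config <- function(stages, num_classes = 8,
                                input_size = c(224, 224),
                                stem_channels = 32,
                                block = block_config(),
                                head = list(retain_1x1_expand = TRUE,
                                            dropout_rate = 0.2),
                                total_mbconv_blocks = NULL) {
  if (num_classes < 2) stop("num_classes must be >= 2")
  reps <- vapply(stages, function(s) s$repeats, integer(1))
  if (is.null(total_mbconv_blocks)) total_mbconv_blocks <- sum(reps)
  if (sum(reps) != total_mbconv_blocks) {
    stop(sprintf("stage repeats sum to %d but total_mbconv_blocks is %d",
                 sum(reps), total_mbconv_blocks))
  }
  if (length(stages) == 7) {
    ccm_pos <- which(vapply(stages, function(s) s$use_ccm, logical(1)))
    if (length(ccm_pos) && any(!ccm_pos %in% 3:5)) {
      stop("use_ccm is only supported in Stages 4-6 (the 40/80/112 stages)")
    }
  }
  if (is.null(head$dropout_rate)) head$dropout_rate <- 0.2
  if (is.null(head$retain_1x1_expand)) head$retain_1x1_expand <- TRUE
  structure(list(stages = stages, num_classes = as.integer(num_classes),
                 input_size = as.integer(input_size),
                 stem_channels = as.integer(stem_channels), block = block,
                 head = head, total_mbconv_blocks = total_mbconv_blocks),
            class = "architecture_config")
}

#' Default calibrated configuration of the modified network
#'
#' The 13-block profile: one block is removed from the 80-channel stage and
#' two from the 112-channel stage relative to EfficientNetB0, CCM is enabled
#' in the 40/80/112-channel stages, the 1x1 expansion to 1280 channels is
#' retained in front of the pyramid head, and each dilated pyramid branch is
#' 97 channels wide. Branch width, repeat profile and head variant were fixed
#' by a grid calibration against the published 6.55 M parameter / 0.461 G
#' multiply-accumulate complexity of the full model (see the methods
#' vignette).
#'
#' @param num_classes classifier width.
#' @param input_size nominal input size.
#' @return an [architecture_config()].
#' @export
enet_caem_config <- function(num_classes = 8, input_size = c(224, 224)) {
  architecture_config(
    stages = list(
      stage_spec(1, 3, 1, 16, 1),
      stage_spec(6, 3, 2, 24, 2),
      stage_spec(6, 5, 2, 40, 2, use_ccm = TRUE),
      stage_spec(6, 3, 2, 80, 2, use_ccm = TRUE),
      stage_spec(6, 5, 1, 112, 1, use_ccm = TRUE),
      stage_spec(6, 5, 2, 192, 4),
      stage_spec(6, 3, 1, 320, 1)),
    num_classes = num_classes,
    input_size = input_size,
    block = block_config(aspp_branch_channels = 97, aspp_gap_channels = 128),
    head = list(retain_1x1_expand = TRUE, dropout_rate = 0.2),
    total_mbconv_blocks = 13)
}

#' Desk-scale configuration of the modified network
#'
#' A three-stage miniature with the same block inventory as the full model
#' (MBConv with multi-scale ECA, CCM in the middle stage, learnable
#' stochastic depth, light-ASPP + mixed-pooling head), sized so that
#' training runs in minutes on one CPU. Used by the examples and the
#' learnability checks.
#'
#' @param num_classes classifier width.
#' @param input_size square input side in pixels.
#' @return an [architecture_config()].
#' @export
enet_caem_mini_config <- function(num_classes = 8, input_size = 48) {
  architecture_config(
    stages = list(stage_spec(1, 3, 1, 8, 1),
                  stage_spec(6, 3, 2, 16, 2, use_ccm = TRUE),
                  stage_spec(6, 5, 2, 24, 2)),
    num_classes = num_classes,
    input_size = c(input_size, input_size),
    stem_channels = 8,
    block = block_config(aspp_branch_channels = 16, aspp_gap_channels = 16),
    head = list(retain_1x1_expand = FALSE, dropout_rate = 0.1))
}

b0_stages <- function() {
  list(stage_spec(1, 3, 1, 16, 1),
       stage_spec(6, 3, 2, 24, 2),
       stage_spec(6, 5, 2, 40, 2),
       stage_spec(6, 3, 2, 80, 3),
       stage_spec(6, 5, 1, 112, 3),
       stage_spec(6, 5, 2, 192, 4),
       stage_spec(6, 3, 1, 320, 1))
}

# internal transpose layer (C x N channel vectors -> N x C classifier input)
nn_tpose <- function() new_layer("tpose")
#' @export
nn_forward.nn_tpose <- function(layer, x, training = FALSE) t(x)
#' @export
nn_backward.nn_tpose <- function(layer, gy) t(gy)

# ---------------------------------------------------------------------------
# MBConv block
# ---------------------------------------------------------------------------

#' Inverted-bottleneck (MBConv) block
#'
#' 1x1 expansion (omitted when `expansion == 1`), depthwise convolution,
#' optional channel context module, channel attention (squeeze-and-excitation
#' for the baseline or multi-scale ECA for the modified variant), 1x1
#' projection. When stride is 1 and widths match, the block output is
#' `x + droppath(f(x))`.
#'
#' @param in_ch,out_ch input/output widths.
#' @param expansion expansion factor.
#' @param kernel depthwise kernel size.
#' @param stride 1 or 2.
#' @param attention `"se"` or `"mseca"`.
#' @param use_ccm insert an [nn_ccm()] after the depthwise stage.
#' @param blockcfg a [block_config()].
#' @param droppath_p_init initial drop probability of the residual gate.
#' @param learnable_droppath gate the residual with [nn_droppath()]; the
#'   baseline build uses plain residuals instead.
#' @return an `nn_layer`.
#' @export
nn_mbconv <- function(in_ch, out_ch, expansion, kernel, stride,
                      attention = c("mseca", "se"), use_ccm = FALSE,
                      blockcfg = block_config(), droppath_p_init = 0,
                      learnable_droppath = TRUE) {
  attention <- match.arg(attention)
  ec <- in_ch * expansion
  residual <- stride == 1 && in_ch == out_ch
  l <- new_layer("mbconv", in_ch = in_ch, out_ch = out_ch,
                 expansion = expansion, kernel = as.integer(kernel),
                 stride = as.integer(stride), expanded = ec,
                 residual = residual, attention = attention,
                 use_ccm = isTRUE(use_ccm))
  ch <- list()
  if (expansion != 1) {
    ch$expand <- nn_sequential(nn_conv2d(in_ch, ec, 1), nn_bn2d(ec),
                               nn_act("swish"))
  }
  ch$dw <- nn_sequential(
    nn_conv2d(ec, ec, kernel, stride = stride, pad = (kernel - 1) %/% 2,
              groups = ec),
    nn_bn2d(ec), nn_act("swish"))
  if (use_ccm) ch$ccm <- nn_ccm(ec, blockcfg$ccm_reduction)
  ch$attn <- if (attention == "se") nn_se(ec, in_ch) else
    nn_multiscale_eca(ec, blockcfg$eca_kernel_sizes,
                      blockcfg$eca_learnable_fusion)
  ch$proj <- nn_sequential(nn_conv2d(ec, out_ch, 1), nn_bn2d(out_ch))
  if (residual && learnable_droppath) {
    ch$droppath <- nn_droppath(droppath_p_init, blockcfg$droppath_p_max)
  }
  l$children <- ch
  l
}

#' @export
nn_forward.nn_mbconv <- function(layer, x, training = FALSE) {
  if (dim(x)[3] != layer$in_ch) {
    stop(sprintf("block expects %d input channels, got %d", layer$in_ch,
                 dim(x)[3]))
  }
  h <- x
  for (nm in setdiff(names(layer$children), "droppath")) {
    h <- nn_forward(layer$children[[nm]], h, training)
  }
  if (layer$residual) {
    if (!is.null(layer$children$droppath)) {
      h <- nn_forward(layer$children$droppath, h, training)
    }
    h <- h + x
  }
  h
}

#' @export
nn_backward.nn_mbconv <- function(layer, gy) {
  g <- gy
  if (layer$residual && !is.null(layer$children$droppath)) {
    g <- nn_backward(layer$children$droppath, g)
  }
  for (nm in rev(setdiff(names(layer$children), "droppath"))) {
    g <- nn_backward(layer$children[[nm]], g)
  }
  if (layer$residual) g <- g + gy
  g
}

#' Forward pass through an MBConv block
#'
#' @param x feature map with the block's input width.
#' @param block an [nn_mbconv()] block.
#' @param training training-mode flag (batch statistics, stochastic depth).
#' @return feature map with spatial dims divided by the block stride.
#' @export
improved_mbconv_forward <- function(x, block, training = FALSE) {
  nn_forward(block, x, training)
}

# ---------------------------------------------------------------------------
# Network builders
# ---------------------------------------------------------------------------

build_backbone <- function(cfg, attention) {
  stem <- nn_sequential(
    nn_conv2d(3, cfg$stem_channels, 3, stride = 2, pad = 1),
    nn_bn2d(cfg$stem_channels), nn_act("swish"))
  blocks <- list()
  inc <- cfg$stem_channels
  total <- sum(vapply(cfg$stages, function(s) s$repeats, integer(1)))
  bi <- 0L
  for (s in cfg$stages) {
    for (r in seq_len(s$repeats)) {
      bi <- bi + 1L
      # drop-prob init ramps linearly from 0 to 0.1 with depth
      p0 <- if (total > 1) 0.1 * (bi - 1) / (total - 1) else 0
      blocks[[bi]] <- nn_mbconv(
        in_ch = inc, out_ch = s$out_channels, expansion = s$expansion,
        kernel = s$kernel, stride = if (r == 1) s$stride else 1L,
        attention = attention, use_ccm = s$use_ccm, blockcfg = cfg$block,
        droppath_p_init = if (attention == "mseca") p0 else 0,
        learnable_droppath = attention == "mseca")
      inc <- s$out_channels
    }
  }
  list(stem = stem, blocks = blocks, top_channels = inc)
}

new_network <- function(cfg, stem, blocks, head, variant) {
  net <- new_layer("network")
  net$children <- list(stem = stem, blocks = nn_sequential2(blocks),
                       head = head)
  net$arch <- cfg
  net$variant <- variant
  class(net) <- c("caem_network", class(net))
  net
}

nn_sequential2 <- function(children) {
  l <- new_layer("sequential")
  l$children <- children
  l
}

#' @export
nn_forward.nn_network <- function(layer, x, training = FALSE) {
  for (ch in layer$children) x <- nn_forward(ch, x, training)
  x
}

#' @export
nn_backward.nn_network <- function(layer, gy) {
  for (ch in rev(layer$children)) gy <- nn_backward(ch, gy)
  gy
}

#' Build the baseline EfficientNetB0 classifier
#'
#' Standard B0: 3x3 stride-2 stem (32 channels, batch norm, swish), seven
#' MBConv stages with squeeze-and-excitation (repeats 1,2,2,3,3,4,1; widths
#' 16,24,40,80,112,192,320), then a 1x1 convolution to 1280 channels, global
#' average pooling, dropout and a fully connected classifier.
#'
#' @param num_classes classifier width (>= 2).
#' @param input_size nominal input size for accounting.
#' @return a `caem_network`.
#' @export
build_baseline_b0 <- function(num_classes = 8, input_size = c(224, 224)) {
  if (num_classes < 2) stop("num_classes must be >= 2")
  cfg <- architecture_config(b0_stages(), num_classes = num_classes,
                             input_size = input_size,
                             total_mbconv_blocks = 16)
  bb <- build_backbone(cfg, attention = "se")
  head <- nn_sequential(
    nn_conv2d(bb$top_channels, 1280, 1), nn_bn2d(1280), nn_act("swish"),
    nn_gap(), nn_tpose(), nn_dropout(0.2),
    nn_linear(1280, num_classes))
  new_network(cfg, bb$stem, bb$blocks, head, "baseline_b0")
}

#' Build the modified network
#'
#' Assembles the reduced backbone described by `cfg`: 13 MBConv blocks with
#' multi-scale channel attention, CCM in the 40/80/112-channel stages,
#' learnable stochastic depth on residual connections, and a head of
#' (optionally) the retained 1x1 expansion, light atrous spatial pyramid
#' pooling, global mixed pooling, dropout and the classifier.
#'
#' @param cfg an [architecture_config()]; defaults to the calibrated
#'   [enet_caem_config()].
#' @return a `caem_network`.
#' @export
build_enet_caem <- function(cfg = enet_caem_config()) {
  if (!inherits(cfg, "architecture_config")) stop("cfg must be an architecture_config")
  bb <- build_backbone(cfg, attention = "mseca")
  bcfg <- cfg$block
  aspp_in <- bb$top_channels
  pre <- list()
  if (isTRUE(cfg$head$retain_1x1_expand)) {
    pre <- list(nn_conv2d(bb$top_channels, 1280, 1), nn_bn2d(1280),
                nn_act("swish"))
    aspp_in <- 1280L
  }
  aspp <- nn_light_aspp(aspp_in, bcfg$aspp_rates, bcfg$aspp_branch_channels,
                        bcfg$aspp_gap_channels)
  head <- nn_sequential2(c(pre, list(
    aspp,
    nn_mixed_pool_global(bcfg$mixed_pool_lambda_init),
    nn_dropout(cfg$head$dropout_rate),
    nn_linear(aspp$out_ch, cfg$num_classes))))
  new_network(cfg, bb$stem, bb$blocks, head, "enet_caem")
}

#' Number of MBConv blocks in a built network
#' @param net a `caem_network`.
#' @return integer count.
#' @export
count_mbconv_blocks <- function(net) {
  length(net$children$blocks$children)
}

#' @export
print.caem_network <- function(x, ...) {
  cat(sprintf("<caem_network: %s>\n", x$variant))
  cat(sprintf("  MBConv blocks : %d\n", count_mbconv_blocks(x)))
  cat(sprintf("  classes       : %d\n", x$arch$num_classes))
  cat(sprintf("  parameters    : %.2f M\n", count_parameters(x)))
  cat(sprintf("  MACs @%dx%d : %.3f G\n", x$arch$input_size[1],
              x$arch$input_size[2], count_flops(x)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Multiply-accumulate accounting
# ---------------------------------------------------------------------------

# macs_of returns list(macs, hw): closed-form MAC count of the layer applied
# at spatial size hw, and the output spatial size.  Only convolution,
# depthwise and linear layers contribute; normalisation, activations and
# pooling are excluded from the count.
macs_of <- function(layer, hw) UseMethod("macs_of")

#' @export
macs_of.default <- function(layer, hw) list(macs = 0, hw = hw)

#' @export
macs_of.nn_conv2d <- function(layer, hw) {
  eff <- (layer$kernel - 1L) * layer$dilation + 1L
  ho <- (hw[1] + 2L * layer$pad[1] - eff[1]) %/% layer$stride[1] + 1L
  wo <- (hw[2] + 2L * layer$pad[2] - eff[2]) %/% layer$stride[2] + 1L
  m <- prod(layer$kernel) * (layer$in_ch / layer$groups) * layer$out_ch *
    ho * wo
  list(macs = m, hw = c(ho, wo))
}

#' @export
macs_of.nn_linear <- function(layer, hw) {
  list(macs = layer$in_ch * layer$out_ch, hw = hw)
}

#' @export
macs_of.nn_cvec_linear <- function(layer, hw) {
  list(macs = layer$in_ch * layer$out_ch, hw = hw)
}

#' @export
macs_of.nn_sequential <- function(layer, hw) {
  total <- 0
  for (ch in layer$children) {
    r <- macs_of(ch, hw)
    total <- total + r$macs
    hw <- r$hw
  }
  list(macs = total, hw = hw)
}

#' @export
macs_of.nn_network <- macs_of.nn_sequential

#' @export
macs_of.nn_gap <- function(layer, hw) list(macs = 0, hw = c(1L, 1L))

#' @export
macs_of.nn_mixed_pool_global <- function(layer, hw) {
  list(macs = 0, hw = c(1L, 1L))
}

#' @export
macs_of.nn_se <- function(layer, hw) {
  list(macs = layer$channels * layer$squeeze * 2, hw = hw)
}

#' @export
macs_of.nn_ccm <- function(layer, hw) {
  list(macs = layer$channels * layer$hidden * 2, hw = hw)
}

#' @export
macs_of.nn_mseca <- function(layer, hw) {
  m <- sum(layer$kernel_sizes) * layer$channels +       # 1-D channel convs
    7 * 7 * 2 * 1 * hw[1] * hw[2]                       # 7x7 spatial conv
  list(macs = m, hw = hw)
}

#' @export
macs_of.nn_light_aspp <- function(layer, hw) {
  m <- length(layer$rates) * 9 * layer$in_ch * layer$branch_channels *
    hw[1] * hw[2] + layer$in_ch * layer$gap_channels
  list(macs = m, hw = hw)
}

#' @export
macs_of.nn_mbconv <- function(layer, hw) {
  total <- 0
  for (nm in setdiff(names(layer$children), "droppath")) {
    r <- macs_of(layer$children[[nm]], hw)
    total <- total + r$macs
    hw <- r$hw
  }
  list(macs = total, hw = hw)
}

#' Multiply-accumulate count of a network
#'
#' Closed-form count over convolution, depthwise-convolution and linear
#' layers for one forward pass at batch 1; batch norm, activations and
#' pooling are excluded. Reported in units of 1e9 MACs.
#'
#' @param net a `caem_network` (or any `nn_layer`).
#' @param input_size `c(H, W)`; defaults to the network's configured size.
#' @return GMACs rounded to 3 decimals.
#' @export
count_flops <- function(net, input_size = NULL) {
  if (is.null(input_size)) {
    input_size <- if (!is.null(net$arch)) net$arch$input_size else c(224, 224)
  }
  round(macs_of(net, as.integer(input_size))$macs / 1e9, 3)
}

#' Complexity report of a built network
#'
#' @param net a `caem_network`.
#' @param input_size `c(H, W)` for the MAC count.
#' @return list with `params_millions` and `flops_g`.
#' @export
complexity_report <- function(net, input_size = NULL) {
  list(params_millions = count_parameters(net),
       flops_g = count_flops(net, input_size))
}
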