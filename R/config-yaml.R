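# YAML run configuration: a single file describing the architecture, block
# hyper-parameters and training recipe.  Schema (all keys optional, defaults
# from the calibrated build):
#
#   model:
#     variant: enet_caem | baseline_b0
#     num_classes: 8
#     input_size: 224
#     stages:            # optional override, list of
#       - {expansion: 6, kernel: 5, stride: 2, out_channels: 40,
#          repeats: 2, use_ccm: true}
#     head: {retain_1x1_expand: true, dropout_rate: 0.2, lambda_init: 0.5}
#   eca: {kernel_sizes: [3, 5, 7], learnable_fusion: false}
#   ccm: {reduction: 16}
#   aspp: {rates: [3, 6, 9], branch_channels: 97, gap_channels: 128}
#   droppath: {p_max: 0.2}
#   train: {epochs: 200, batch_size: 32, lr_max: 0.001, lr_min: 0,
#           label_smoothing: 0.1, seed: 1}

#' Read a YAML run configuration
#'
#' @param path YAML file.
#' @return list with `arch` (an [architecture_config()]), `train` (a
#'   [train_config()]) and `variant`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  y <- yaml::read_yaml(path)
  model <- y$model %||% list()
  variant <- model$variant %||% "enet_caem"
  blk <- block_config(
    eca_kernel_sizes = y$eca$kernel_sizes %||% c(3, 5, 7),
    ccm_reduction = y$ccm$reduction %||% 16,
    aspp_rates = y$aspp$rates %||% c(3, 6, 9),
    aspp_branch_channels = y$aspp$branch_channels %||% 97,
    aspp_gap_channels = y$aspp$gap_channels %||% 128,
    mixed_pool_lambda_init = model$head$lambda_init %||% 0.5,
    droppath_p_max = y$droppath$p_max %||% 0.2,
    eca_learnable_fusion = isTRUE(y$eca$learnable_fusion))
  isz <- model$input_size %||% 224
  isz <- rep(as.integer(isz), length.out = 2)
  stages <- if (!is.null(model$stages)) {
    lapply(model$stages, function(s) {
      stage_spec(s$expansion, s$kernel, s$stride, s$out_channels, s$repeats,
                 isTRUE(s$use_ccm))
    })
  } else if (variant == "baseline_b0") b0_stages() else
    enet_caem_config()$stages
  arch <- architecture_config(
    stages = stages,
    num_classes = model$num_classes %||% 8,
    input_size = isz,
    stem_channels = model$stem_channels %||% 32,
    block = blk,
    head = list(retain_1x1_expand = model$head$retain_1x1_expand %||% TRUE,
                dropout_rate = model$head$dropout_rate %||% 0.2))
  tr <- y$train %||% list()
  train <- train_config(
    epochs = tr$epochs %||% 200, batch_size = tr$batch_size %||% 32,
    lr_max = tr$lr_max %||% 1e-3, lr_min = tr$lr_min %||% 0,
    label_smoothing = tr$label_smoothing %||% 0.1, seed = tr$seed %||% 1,
    weight_decay = tr$weight_decay %||% 0)
  list(arch = arch, train = train, variant = variant)
}

#' Write a YAML run configuration
#'
#' Serialises an architecture + training configuration in the schema read by
#' [read_run_config()].
#'
#' @param arch an [architecture_config()].
#' @param train a [train_config()].
#' @param path output file.
#' @param variant `"enet_caem"` or `"baseline_b0"`.
#' @return invisibly, the written list.
#' @export
write_run_config <- function(arch, train, path, variant = "enet_caem") {
  blk <- arch$block
  y <- list(
    model = list(
      variant = variant,
      num_classes = arch$num_classes,
      input_size = arch$input_size[1],
      stem_channels = arch$stem_channels,
      stages = lapply(arch$stages, function(s) {
        list(expansion = s$expansion, kernel = s$kernel, stride = s$stride,
             out_channels = s$out_channels, repeats = s$repeats,
             use_ccm = s$use_ccm)
      }),
      head = list(retain_1x1_expand = arch$head$retain_1x1_expand,
                  dropout_rate = arch$head$dropout_rate,
                  lambda_init = blk$mixed_pool_lambda_init)),
    eca = list(kernel_sizes = blk$eca_kernel_sizes,
               learnable_fusion = blk$eca_learnable_fusion),
    ccm = list(reduction = blk$ccm_reduction),
    aspp = list(rates = blk$aspp_rates,
                branch_channels = blk$aspp_branch_channels,
                gap_channels = blk$aspp_gap_channels),
    droppath = list(p_max = blk$droppath_p_max),
    train = list(epochs = train$epochs, batch_size = train$batch_size,
                 lr_max = train$lr_max, lr_min = train$lr_min,
                 label_smoothing = train$label_smoothing, seed = train$seed))
  yaml::write_yaml(y, path)
  invisible(y)
}

#' Build a network from a run configuration
#'
#' @param cfg result of [read_run_config()].
#' @return a `caem_network`.
#' @export
build_from_config <- function(cfg) {
  if (cfg$variant == "baseline_b0") {
    build_baseline_b0(cfg$arch$num_classes, cfg$arch$input_size)
  } else {
    build_enet_caem(cfg$arch)
  }
}
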