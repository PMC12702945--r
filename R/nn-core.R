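#' @useDynLib enetcaem, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rbinom predict
NULL

# ---------------------------------------------------------------------------
# Minimal mutable layer framework.
#
# A layer is an environment carrying `params` (named list of numeric arrays),
# `grads` (same shapes, accumulated by nn_backward), `buffers` (non-trained
# state such as batch-norm running moments), `children` (sub-layers) and a
# forward cache.  Feature maps are column-major arrays dim = c(H, W, C, N).
# Parameter initialisation draws from the session RNG, so builds are
# deterministic under set.seed().
# ---------------------------------------------------------------------------

new_layer <- function(.kind, ...) {
  e <- new.env(parent = emptyenv())
  e$kind <- .kind
  e$params <- list()
  e$grads <- list()
  e$buffers <- list()
  e$children <- list()
  e$cache <- NULL
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- c(paste0("nn_", .kind), "nn_layer")
  e
}

add_param <- function(layer, name, value) {
  layer$params[[name]] <- value
  layer$grads[[name]] <- array(0, dim = dim(value) %||% length(value))
  invisible(layer)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Forward pass through a layer or network
#'
#' @param layer a layer built by one of the `nn_*` constructors or a network
#'   from [build_baseline_b0()] / [build_enet_caem()].
#' @param x input array, `dim = c(H, W, C, N)` for convolutional layers.
#' @param training logical; enables batch statistics, dropout and stochastic
#'   depth. Intermediate values needed by [nn_backward()] are cached on the
#'   layer.
#' @return the layer output.
#' @export
nn_forward <- function(layer, x, training = FALSE) UseMethod("nn_forward")

#' Backward pass through a layer or network
#'
#' Accumulates parameter gradients into each layer's `grads` list and returns
#' the gradient with respect to the layer input. Must follow a
#' `nn_forward(..., training = TRUE)` call on the same layer.
#'
#' @param layer a layer previously run forward.
#' @param gy gradient of the loss with respect to the layer output.
#' @return gradient with respect to the layer input.
#' @export
nn_backward <- function(layer, gy) UseMethod("nn_backward")

#' Collect trainable parameters
#'
#' @param layer a layer or network.
#' @return list of references, each `list(layer =, name =)`, in a fixed
#'   traversal order (depth-first, parameters before children).
#' @export
nn_parameters <- function(layer) {
  out <- list()
  for (nm in names(layer$params)) {
    out[[length(out) + 1L]] <- list(layer = layer, name = nm)
  }
  for (ch in layer$children) out <- c(out, nn_parameters(ch))
  out
}

#' Count trainable parameters of a network
#'
#' Sums the element counts of every trainable tensor reachable from `layer`.
#'
#' @param layer a layer or built network.
#' @param millions if `TRUE` (default) report millions rounded to 2 decimals,
#'   else the raw integer count.
#' @return numeric scalar.
#' @export
count_parameters <- function(layer, millions = TRUE) {
  n <- sum(vapply(nn_parameters(layer),
                  function(p) length(p$layer$params[[p$name]]), numeric(1)))
  if (millions) round(n / 1e6, 2) else n
}

#' @export
nn_zero_grad <- function(layer) {
  for (nm in names(layer$grads)) layer$grads[[nm]][] <- 0
  for (ch in layer$children) nn_zero_grad(ch)
  invisible(layer)
}

#' Extract or restore the full numeric state of a network
#'
#' @param layer a layer or network.
#' @return nested list of parameter and buffer arrays.
#' @export
nn_state_dict <- function(layer) {
  list(params = layer$params, buffers = layer$buffers,
       children = lapply(layer$children, nn_state_dict))
}

#' @param state a state produced by [nn_state_dict()].
#' @rdname nn_state_dict
#' @export
nn_load_state <- function(layer, state) {
  layer$params <- state$params
  layer$buffers <- state$buffers
  for (i in seq_along(layer$children)) {
    nn_load_state(layer$children[[i]], state$children[[i]])
  }
  invisible(layer)
}

# He-normal initialisation for convolution / linear weights.
init_kaiming <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- broadcast helpers (H, W, C, N layout) --------------------------------

# multiply feature map by per-(channel, sample) factors wc: C x N
bcast_cn <- function(wc, d) {
  array(rep(as.vector(wc), each = d[1] * d[2]), dim = d)
}

# multiply feature map by per-(h, w, sample) map ws: H x W x 1 x N
bcast_hwn <- function(ws, d) {
  m <- matrix(ws, nrow = d[1] * d[2])           # HW x N
  array(m[, rep(seq_len(d[4]), each = d[3]), drop = FALSE], dim = d)
}

# sum over H, W -> C x N matrix
reduce_hw <- function(x) {
  d <- dim(x)
  matrix(colSums(matrix(x, nrow = d[1] * d[2])), nrow = d[3])
}

# sum over C -> H x W x 1 x N array
reduce_c <- function(x) {
  d <- dim(x)
  x3 <- array(x, c(d[1] * d[2], d[3], d[4]))
  out <- vapply(seq_len(d[4]), function(n) rowSums(x3[, , n, drop = FALSE]),
                numeric(d[1] * d[2]))
  array(out, c(d[1], d[2], 1, d[4]))
}

stopifnot_fmap <- function(x) {
  if (!(is.array(x) && length(dim(x)) == 4)) {
    stop("feature map must be a rank-4 array (H, W, C, N)", call. = FALSE)
  }
  if (any(dim(x) < 1)) stop("feature map dimensions must be >= 1", call. = FALSE)
  if (!all(is.finite(x))) stop("feature map contains non-finite values", call. = FALSE)
  invisible(x)
}
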