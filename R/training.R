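# Training recipe: Adam with a cosine-annealed learning rate, label-smoothed
# cross-entropy, per-epoch validation, best-checkpoint retention and full
# seeding.  train_network() is the package's fitting function; it returns a
# classed fit with print / summary / predict / plot methods.

#' Cosine-annealed learning rate
#'
#' `lr(t) = lr_min + (lr_max - lr_min) * (1 + cos(pi t / T)) / 2`, monotone
#' non-increasing from `lr_max` at `t = 0` to `lr_min` at `t = T`.
#'
#' @param t epoch index in `[0, T]`.
#' @param T total number of epochs (>= 1).
#' @param lr_max,lr_min schedule endpoints, `lr_min <= lr_max`.
#' @return learning rate at epoch `t` (vectorised over `t`).
#' @export
cosine_lr <- function(t, T, lr_max, lr_min = 0) {
  if (T < 1) stop("total epochs T must be >= 1")
  if (lr_min > lr_max) stop("lr_min must not exceed lr_max")
  if (any(t < 0 | t > T)) stop("epoch index t must lie in [0, T]")
  lr_min + 0.5 * (lr_max - lr_min) * (1 + cos(pi * t / T))
}

#' Label-smoothed cross-entropy
#'
#' Soft targets `q = (1 - eps) * onehot + eps / K` (uniform-mixture
#' convention; the alternative places `eps / (K - 1)` off the true class).
#' With `eps = 0` this is the standard cross-entropy. The loss is bounded
#' below by the entropy of `q`, so it cannot reach zero when `eps > 0`.
#'
#' @param logits N x K matrix of unnormalised scores.
#' @param labels integer vector of 0-based class indices, length N.
#' @param eps smoothing weight in `[0, 1)`.
#' @return mean loss over the batch.
#' @export
label_smoothing_ce <- function(logits, labels, eps = 0.1) {
  g <- ls_ce_grad(logits, labels, eps)
  g$loss
}

# loss + gradient wrt logits (gradient already divided by batch size)
ls_ce_grad <- function(logits, labels, eps) {
  if (eps < 0 || eps >= 1) stop("label smoothing eps must lie in [0, 1)")
  K <- ncol(logits)
  N <- nrow(logits)
  if (K < 2) stop("need at least 2 classes")
  labels <- as.integer(labels)
  if (length(labels) != N) stop("labels must match the batch size")
  if (any(labels < 0 | labels >= K)) stop("label outside [0, K)")
  m <- apply(logits, 1, max)
  z <- logits - m
  lse <- log(rowSums(exp(z)))
  logp <- z - lse
  q <- matrix(eps / K, N, K)
  q[cbind(seq_len(N), labels + 1L)] <- 1 - eps + eps / K
  loss <- -sum(q * logp) / N
  p <- exp(logp)
  list(loss = loss, grad = (p - q) / N)
}

#' Training configuration
#'
#' @param epochs number of epochs (the published recipe uses 200; tests use
#'   far fewer).
#' @param batch_size minibatch size.
#' @param lr_max,lr_min cosine schedule endpoints.
#' @param label_smoothing smoothing weight `eps` in `[0, 1)`.
#' @param seed integer seed controlling data order, dropout, stochastic
#'   depth and initial shuffling.
#' @param weight_decay decoupled L2 coefficient (default 0).
#' @return list of class `"train_config"`. The optimiser is Adam with
#'   `beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-8`.
#' @export
train_config <- function(epochs = 200, batch_size = 32, lr_max = 1e-3,
                         lr_min = 0, label_smoothing = 0.1, seed = 1,
                         weight_decay = 0) {
  if (epochs < 1) stop("epochs must be >= 1")
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (lr_min > lr_max) stop("lr_min must not exceed lr_max")
  if (label_smoothing < 0 || label_smoothing >= 1) {
    stop("label_smoothing must lie in [0, 1)")
  }
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr_max = lr_max,
                 lr_min = lr_min, label_smoothing = label_smoothing,
                 seed = as.integer(seed), weight_decay = weight_decay,
                 beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8),
            class = "train_config")
}

# ---- input normalisation ---------------------------------------------------

# stack a labeled_dataset (or list of images) into (H, W, 3, N) in [-1, 1]
dataset_to_tensor <- function(x) {
  imgs <- if (inherits(x, "labeled_dataset")) x$images else x
  d <- dim(imgs[[1]])
  out <- array(0, c(d[1], d[2], 3, length(imgs)))
  for (i in seq_along(imgs)) out[, , , i] <- as_rgb255(imgs[[i]])
  out / 127.5 - 1
}

adam_init <- function(params) {
  lapply(params, function(p) {
    v <- p$layer$params[[p$name]]
    list(m = array(0, dim(v) %||% length(v)),
         v = array(0, dim(v) %||% length(v)))
  })
}

adam_step <- function(params, state, lr, cfg, t) {
  b1 <- cfg$beta1; b2 <- cfg$beta2
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$layer$grads[[p$name]]
    if (cfg$weight_decay > 0) {
      g <- g + cfg$weight_decay * p$layer$params[[p$name]]
    }
    st <- state[[i]]
    st$m <- b1 * st$m + (1 - b1) * g
    st$v <- b2 * st$v + (1 - b2) * g^2
    state[[i]] <- st
    mhat <- st$m / (1 - b1^t)
    vhat <- st$v / (1 - b2^t)
    old <- p$layer$params[[p$name]]
    new <- old - lr * mhat / (sqrt(vhat) + cfg$adam_eps)
    dim(new) <- dim(old)   # keep plain vectors/scalars plain
    p$layer$params[[p$name]] <- new
  }
  state
}

eval_on <- function(net, x, labels, eps, batch_size) {
  N <- dim(x)[4]
  loss <- 0; correct <- 0
  for (s in seq(1, N, by = batch_size)) {
    idx <- s:min(s + batch_size - 1, N)
    logits <- nn_forward(net, x[, , , idx, drop = FALSE], training = FALSE)
    loss <- loss + ls_ce_grad(logits, labels[idx], eps)$loss * length(idx)
    pred <- max.col(logits, ties.method = "first") - 1L
    correct <- correct + sum(pred == labels[idx])
  }
  list(loss = loss / N, acc = correct / N)
}

# current mixing weight / drop probabilities, if the network has them
net_lambda <- function(net) {
  for (ch in net$children$head$children) {
    if (inherits(ch, "nn_mixed_pool_global")) return(mixed_pool_lambda(ch))
  }
  NA_real_
}

#' Per-block drop probabilities of a built network
#' @param net a `caem_network`.
#' @return numeric vector, one entry per residual-gated block.
#' @export
droppath_probs <- function(net) {
  out <- numeric(0)
  for (b in net$children$blocks$children) {
    if (!is.null(b$children$droppath)) {
      out <- c(out, droppath_p(b$children$droppath))
    }
  }
  out
}

#' Train a network
#'
#' Runs the full recipe: shuffled minibatches, Adam, cosine-annealed
#' learning rate, label-smoothed cross-entropy, per-epoch validation and
#' retention of the best-validation-accuracy checkpoint (ties resolved
#' toward the earlier epoch). Fully reproducible given `cfg$seed`.
#'
#' @param net a `caem_network` whose classifier width matches the number of
#'   classes in `train`.
#' @param train,val [labeled_dataset()]s.
#' @param cfg a [train_config()].
#' @param verbose print one line per epoch.
#' @return an object of class `"caem_fit"`: the network (restored to the
#'   best checkpoint), a per-epoch `history` data frame (losses, validation
#'   accuracy, learning rate, pooling weight, mean drop probability; the
#'   full per-block drop-probability trace is in
#'   `attr(history, "droppath_p")`), the configuration and the class
#'   names.
#' @export
train_network <- function(net, train, val, cfg = train_config(),
                          verbose = FALSE) {
  if (!length(train$images) || !length(val$images)) {
    stop("training and validation sets must be non-empty")
  }
  K <- length(train$class_names)
  probe <- nn_forward(net, dataset_to_tensor(list(train$images[[1]])),
                      training = FALSE)
  if (ncol(probe) != K) {
    stop(sprintf("network has %d outputs but the data has %d classes",
                 ncol(probe), K))
  }
  xtr <- dataset_to_tensor(train)
  xva <- dataset_to_tensor(val)
  ytr <- train$labels
  set.seed(cfg$seed)
  params <- nn_parameters(net)
  state <- adam_init(params)
  N <- dim(xtr)[4]
  hist <- vector("list", cfg$epochs)
  dp_trace <- vector("list", cfg$epochs)
  best <- list(acc = -Inf, epoch = 0L, state = NULL)
  step <- 0L
  for (ep in seq_len(cfg$epochs)) {
    lr <- cosine_lr(ep - 1, cfg$epochs, cfg$lr_max, cfg$lr_min)
    ord <- sample.int(N)
    ep_loss <- 0
    for (s in seq(1, N, by = cfg$batch_size)) {
      idx <- ord[s:min(s + cfg$batch_size - 1, N)]
      xb <- xtr[, , , idx, drop = FALSE]
      nn_zero_grad(net)
      logits <- nn_forward(net, xb, training = TRUE)
      lg <- ls_ce_grad(logits, ytr[idx], cfg$label_smoothing)
      if (!is.finite(lg$loss)) {
        stop(sprintf("non-finite loss at epoch %d, batch starting %d", ep, s))
      }
      nn_backward(net, lg$grad)
      step <- step + 1L
      state <- adam_step(params, state, lr, cfg, step)
      ep_loss <- ep_loss + lg$loss * length(idx)
    }
    ev <- eval_on(net, xva, val$labels, cfg$label_smoothing, cfg$batch_size)
    dp <- droppath_probs(net)
    dp_trace[[ep]] <- dp
    hist[[ep]] <- data.frame(
      epoch = ep, lr = lr, train_loss = ep_loss / N, val_loss = ev$loss,
      val_acc = ev$acc, lambda = net_lambda(net),
      mean_droppath_p = if (length(dp)) mean(dp) else NA_real_)
    if (ev$acc > best$acc) {
      best <- list(acc = ev$acc, epoch = ep, state = nn_state_dict(net))
    }
    if (verbose) {
      message(sprintf("epoch %3d  lr %.2e  train %.4f  val %.4f  acc %.3f",
                      ep, lr, ep_loss / N, ev$loss, ev$acc))
    }
  }
  if (!is.null(best$state)) nn_load_state(net, best$state)
  history <- do.call(rbind, hist)
  attr(history, "droppath_p") <- do.call(rbind, dp_trace)
  structure(list(network = net, history = history,
                 config = cfg, class_names = train$class_names,
                 best_epoch = best$epoch, best_val_acc = best$acc),
            class = "caem_fit")
}

#' @export
print.caem_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<caem_fit: %s, %d epochs>\n", x$network$variant, nrow(h)))
  cat(sprintf("  best val accuracy %.3f at epoch %d\n", x$best_val_acc,
              x$best_epoch))
  cat(sprintf("  final train loss  %.4f\n", h$train_loss[nrow(h)]))
  invisible(x)
}

#' @export
summary.caem_fit <- function(object, ...) {
  h <- object$history
  dp <- droppath_probs(object$network)
  out <- list(
    variant = object$network$variant,
    epochs = nrow(h),
    best_epoch = object$best_epoch,
    best_val_acc = object$best_val_acc,
    final_train_loss = h$train_loss[nrow(h)],
    lambda = net_lambda(object$network),
    droppath_p = dp,
    params_millions = count_parameters(object$network))
  class(out) <- "summary.caem_fit"
  out
}

#' @export
print.summary.caem_fit <- function(x, ...) {
  cat(sprintf("Fitted %s (%.2f M parameters), %d epochs\n", x$variant,
              x$params_millions, x$epochs))
  cat(sprintf("  best validation accuracy: %.3f (epoch %d)\n",
              x$best_val_acc, x$best_epoch))
  cat(sprintf("  final training loss:      %.4f\n", x$final_train_loss))
  if (!is.na(x$lambda)) {
    cat(sprintf("  mixed-pooling lambda:     %.3f\n", x$lambda))
  }
  if (length(x$droppath_p)) {
    cat(sprintf("  drop probabilities:       %s\n",
                paste(sprintf("%.3f", x$droppath_p), collapse = " ")))
  }
  invisible(x)
}

#' Predict from a fitted network
#'
#' @param object a `caem_fit`.
#' @param newdata a [labeled_dataset()], a list of images, or an
#'   `(H, W, 3, N)` array already scaled to `[-1, 1]`.
#' @param type `"class"` (0-based indices), `"label"` (class names),
#'   `"prob"` (softmax matrix) or `"logit"`.
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @return predictions as described under `type`.
#' @export
predict.caem_fit <- function(object, newdata,
                             type = c("class", "label", "prob", "logit"),
                             batch_size = 32, ...) {
  type <- match.arg(type)
  x <- if (is.array(newdata) && length(dim(newdata)) == 4) newdata else
    dataset_to_tensor(newdata)
  N <- dim(x)[4]
  out <- NULL
  for (s in seq(1, N, by = batch_size)) {
    idx <- s:min(s + batch_size - 1, N)
    lo <- nn_forward(object$network, x[, , , idx, drop = FALSE],
                     training = FALSE)
    out <- rbind(out, lo)
  }
  switch(type,
         logit = out,
         prob = {
           e <- exp(out - apply(out, 1, max))
           e / rowSums(e)
         },
         class = max.col(out, ties.method = "first") - 1L,
         label = object$class_names[max.col(out, ties.method = "first")])
}

#' Plot training history
#'
#' Two panels: losses and validation accuracy across epochs.
#'
#' @param x a `caem_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.caem_fit <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "loss", main = "loss", ...)
  graphics::lines(h$epoch, h$val_loss, lty = 2)
  graphics::legend("topright", c("train", "val"), lty = 1:2, bty = "n")
  graphics::plot(h$epoch, h$val_acc, type = "l", xlab = "epoch",
                 ylab = "accuracy", main = "validation accuracy",
                 ylim = c(0, 1), ...)
  invisible(x)
}
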