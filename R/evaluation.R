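# Evaluation: confusion matrices, accuracy / per-class precision / recall /
# F1 with macro (default) or micro aggregation, and stratified k-fold
# cross-validation with mean +/- sd summaries.

#' Confusion matrix
#'
#' `counts[i, j]` is the number of samples whose true class is `i - 1` and
#' predicted class is `j - 1` (rows = truth, columns = prediction).
#'
#' @param preds,labels integer vectors of 0-based class indices.
#' @param K number of classes.
#' @param class_names optional dimnames.
#' @return K x K integer matrix of class `"confusion_matrix"`.
#' @export
confusion_matrix <- function(preds, labels, K, class_names = NULL) {
  if (length(preds) != length(labels)) {
    stop("preds and labels must have the same length")
  }
  preds <- as.integer(preds); labels <- as.integer(labels)
  if (length(preds) && (min(preds, labels) < 0 || max(preds, labels) >= K)) {
    stop("class indices must lie in [0, K)")
  }
  cm <- matrix(0L, K, K)
  for (i in seq_along(preds)) {
    cm[labels[i] + 1L, preds[i] + 1L] <- cm[labels[i] + 1L, preds[i] + 1L] + 1L
  }
  if (!is.null(class_names)) dimnames(cm) <- list(true = class_names,
                                                  pred = class_names)
  structure(cm, class = c("confusion_matrix", "matrix", "array"))
}

#' Classification metrics from a confusion matrix
#'
#' Per-class one-vs-rest precision `TP / (TP + FP)`, recall
#' `TP / (TP + FN)` and their harmonic mean F1; accuracy is the trace over
#' the total. Ratios with a zero denominator are reported as 0 and flagged.
#' Aggregate metrics are unweighted class means (macro) by default; micro
#' aggregation pools the per-sample counts.
#'
#' @param cm a [confusion_matrix()].
#' @param average `"macro"` or `"micro"`.
#' @return list of class `"metrics_report"`: `accuracy`, vectors
#'   `precision`, `recall`, `f1`, aggregate `macro_*` (or `micro_*`), and
#'   `undefined` flags.
#' @export
compute_metrics <- function(cm, average = c("macro", "micro")) {
  average <- match.arg(average)
  cm <- unclass(cm)
  K <- nrow(cm)
  total <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  undefined <- (tp + fp) == 0 | (tp + fn) == 0
  out <- list(accuracy = if (total > 0) sum(tp) / total else 0,
              precision = precision, recall = recall, f1 = f1,
              undefined = undefined, average = average)
  if (average == "macro") {
    out$macro_precision <- mean(precision)
    out$macro_recall <- mean(recall)
    out$macro_f1 <- mean(f1)
  } else {
    mp <- safe_div(sum(tp), sum(tp + fp))
    mr <- safe_div(sum(tp), sum(tp + fn))
    out$micro_precision <- mp
    out$micro_recall <- mr
    out$micro_f1 <- safe_div(2 * mp * mr, mp + mr)
  }
  class(out) <- "metrics_report"
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy: %.4f\n", x$accuracy))
  df <- data.frame(precision = round(x$precision, 4),
                   recall = round(x$recall, 4), f1 = round(x$f1, 4))
  print(df)
  if (x$average == "macro") {
    cat(sprintf("macro: P %.4f  R %.4f  F1 %.4f\n", x$macro_precision,
                x$macro_recall, x$macro_f1))
  } else {
    cat(sprintf("micro: P %.4f  R %.4f  F1 %.4f\n", x$micro_precision,
                x$micro_recall, x$micro_f1))
  }
  invisible(x)
}

#' Evaluate a fitted network on a dataset
#'
#' @param fit a `caem_fit`.
#' @param ds a [labeled_dataset()].
#' @param average aggregation passed to [compute_metrics()].
#' @return list with `metrics` and `confusion`.
#' @export
evaluate_model <- function(fit, ds, average = "macro") {
  preds <- predict(fit, ds, type = "class")
  cm <- confusion_matrix(preds, ds$labels, length(ds$class_names),
                         ds$class_names)
  list(metrics = compute_metrics(cm, average), confusion = cm)
}

stratified_folds <- function(labels, k, seed) {
  K <- max(labels) + 1L
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cls in seq_len(K) - 1L) {
      pool <- which(labels == cls)
      if (length(pool) < k) {
        stop(sprintf("class %d has %d items; need at least k = %d", cls,
                     length(pool), k))
      }
      pool <- sample(pool)
      fold[pool] <- rep_len(seq_len(k), length(pool))
    }
  })
  fold
}

#' Stratified k-fold cross-validation
#'
#' Partitions the data into k stratified folds; each fold is held out once
#' while a model is trained from scratch on the remainder and evaluated on
#' the holdout. The summary reports each metric's mean and sample (n - 1)
#' standard deviation across folds.
#'
#' @param ds a [labeled_dataset()].
#' @param k number of folds (>= 2; every class needs >= k items).
#' @param trainer function `(train_ds, fold_seed)` returning a function
#'   `ds -> integer predictions`. The default trains [build_enet_caem()]
#'   under `archcfg` / `traincfg`.
#' @param archcfg an [architecture_config()] for the default trainer.
#' @param traincfg a [train_config()] for the default trainer.
#' @param seed integer seed controlling fold assignment and fold seeds.
#' @param average aggregation passed to [compute_metrics()].
#' @return list of class `"cv_result"`: per-fold `reports`, `folds`
#'   assignment vector and a `summary` data frame (mean, sd per metric).
#' @export
kfold_cv <- function(ds, k = 5, trainer = NULL,
                     archcfg = enet_caem_config(), traincfg = train_config(),
                     seed = 1, average = "macro") {
  if (k < 2) stop("k must be >= 2")
  if (is.null(trainer)) {
    trainer <- function(train_ds, fold_seed) {
      set.seed(fold_seed)
      cfg <- archcfg
      cfg$num_classes <- length(train_ds$class_names)
      net <- build_enet_caem(cfg)
      tc <- traincfg
      tc$seed <- fold_seed
      sp <- stratified_split(train_ds, c(0.9, 0.05, 0.05), seed = fold_seed)
      fit <- train_network(net, sp$train, sp$val, tc)
      function(eval_ds) predict(fit, eval_ds, type = "class")
    }
  }
  fold <- stratified_folds(ds$labels, k, seed)
  K <- length(ds$class_names)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- ds_subset(ds, which(fold != f))
    ho <- ds_subset(ds, which(fold == f))
    predict_fn <- trainer(tr, seed + f)
    preds <- predict_fn(ho)
    cm <- confusion_matrix(preds, ho$labels, K, ds$class_names)
    reports[[f]] <- compute_metrics(cm, average)
  }
  pick <- function(r) {
    agg <- if (average == "macro") {
      c(r$macro_precision, r$macro_recall, r$macro_f1)
    } else c(r$micro_precision, r$micro_recall, r$micro_f1)
    c(accuracy = r$accuracy, precision = agg[1], recall = agg[2], f1 = agg[3])
  }
  m <- t(vapply(reports, pick, numeric(4)))
  summary <- data.frame(metric = colnames(m), mean = colMeans(m),
                        sd = apply(m, 2, stats::sd), row.names = NULL)
  structure(list(reports = reports, folds = fold, summary = summary, k = k),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation\n", x$k))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-9s %.4f +/- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}
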