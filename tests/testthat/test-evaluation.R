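# Confusion matrices, metrics and cross-validation.

test_that("confusion matrix counts truth rows against prediction columns", {
  # perfect predictions: diagonal with row sums equal to supports
  cm <- confusion_matrix(c(0, 0, 1, 2, 2, 2), c(0, 0, 1, 2, 2, 2), 3)
  expect_equal(diag(unclass(cm)), c(2L, 1L, 3L))
  expect_equal(sum(cm) - sum(diag(unclass(cm))), 0L)
  # the printed small example
  cm2 <- confusion_matrix(preds = c(0, 1, 1), labels = c(0, 0, 1), K = 2)
  expect_equal(unclass(cm2), matrix(c(1L, 0L, 1L, 1L), 2, 2))
  # empty input: all-zero K x K
  cm0 <- confusion_matrix(integer(0), integer(0), 4)
  expect_equal(sum(cm0), 0L)
  expect_equal(dim(cm0), c(4L, 4L))
  expect_error(confusion_matrix(c(0, 1), c(0), 2), "length")
})

test_that("metrics follow their defining ratios on hand-checked cases", {
  # class 0: TP = 3, FP = 1, FN = 1
  cm <- matrix(c(3L, 1L, 1L, 5L), 2, 2, byrow = TRUE)
  class(cm) <- c("confusion_matrix", "matrix", "array")
  m <- compute_metrics(cm)
  expect_equal(m$precision[1], 0.75)
  expect_equal(m$recall[1], 0.75)
  expect_equal(m$f1[1], 0.75)
  # perfect matrix: everything is 1
  mp <- compute_metrics(confusion_matrix(c(0, 1, 2), c(0, 1, 2), 3))
  expect_equal(mp$accuracy, 1)
  expect_equal(mp$macro_f1, 1)
  expect_true(all(mp$precision == 1 & mp$recall == 1))
  # the worked 2x2 example
  m2 <- compute_metrics(confusion_matrix(c(0, 1, 1), c(0, 0, 1), 2))
  expect_equal(m2$accuracy, 2 / 3)
  expect_equal(m2$precision, c(1, 0.5))
  expect_equal(m2$recall, c(0.5, 1))
  expect_equal(m2$f1, c(2 / 3, 2 / 3))
  # zero-denominator convention: flagged zero, never NaN
  cmz <- confusion_matrix(c(0, 0), c(0, 1), 3)
  mz <- compute_metrics(cmz)
  expect_equal(mz$precision[3], 0)
  expect_true(mz$undefined[3])
  expect_false(anyNA(unlist(mz[c("precision", "recall", "f1")])))
})

test_that("metrics agree with a per-sample reference on random predictions", {
  set.seed(71)
  for (K in c(2L, 8L)) {
    for (trial in 1:500) {
      n <- sample(3:40, 1)
      labels <- sample(0:(K - 1), n, replace = TRUE)
      preds <- sample(0:(K - 1), n, replace = TRUE)
      m <- compute_metrics(confusion_matrix(preds, labels, K))
      o <- oracle_metrics(preds, labels, K)
      expect_equal(m$accuracy, o$accuracy)
      expect_equal(m$precision, o$precision)
      expect_equal(m$recall, o$recall)
      expect_equal(m$f1, o$f1)
      # macro F1 lies between the per-class extremes
      expect_gte(m$macro_f1, min(m$f1) - 1e-12)
      expect_lte(m$macro_f1, max(m$f1) + 1e-12)
    }
  }
})

test_that("stratified k-fold partitions, reproduces and scores a known dummy", {
  ds <- labeled_dataset(
    lapply(1:100, function(i) array(i, c(2, 2, 3))),
    rep(0:1, each = 50), c("a", "b"))
  # a constant classifier on balanced two-class data: accuracy 1/2, sd 0
  const_trainer <- function(train_ds, fold_seed) {
    function(eval_ds) rep(0L, length(eval_ds$images))
  }
  cv <- kfold_cv(ds, k = 5, trainer = const_trainer, seed = 4)
  accs <- vapply(cv$reports, function(r) r$accuracy, numeric(1))
  expect_equal(accs, rep(0.5, 5))
  expect_equal(cv$summary$sd[cv$summary$metric == "accuracy"], 0)
  # folds partition the data, 10 per class per fold
  expect_equal(sort(unique(cv$folds)), 1:5)
  for (f in 1:5) {
    expect_equal(sum(cv$folds == f & ds$labels == 0), 10)
    expect_equal(sum(cv$folds == f & ds$labels == 1), 10)
  }
  # identical seed: identical assignment and reports
  cv2 <- kfold_cv(ds, k = 5, trainer = const_trainer, seed = 4)
  expect_identical(cv$folds, cv2$folds)
  expect_identical(cv$summary, cv2$summary)
  expect_error(kfold_cv(ds, k = 60, trainer = const_trainer), "at least")
})

test_that("cross-validation with a real (tiny) model trains per fold", {
  ds <- generate_dataset(synth_spec(n_per_class = 10, image_size = 24,
                                    noise_sigma = 5, seed = 72))
  quick_trainer <- function(train_ds, fold_seed) {
    set.seed(fold_seed)
    net <- build_enet_caem(enet_caem_mini_config(input_size = 24))
    sp <- stratified_split(train_ds, c(0.6, 0.2, 0.2), seed = fold_seed)
    fit <- train_network(net, sp$train, sp$val,
                         train_config(epochs = 1, batch_size = 16,
                                      seed = fold_seed))
    function(eval_ds) predict(fit, eval_ds, type = "class")
  }
  cv <- kfold_cv(ds, k = 2, trainer = quick_trainer, seed = 5)
  expect_length(cv$reports, 2)
  expect_true(all(is.finite(cv$summary$mean)))
  expect_equal(nrow(cv$summary), 4)
})
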