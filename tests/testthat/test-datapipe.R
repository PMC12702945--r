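# Augmentation, balancing, splitting and folder I/O.

tiny_ds <- function(sizes, px = 8) {
  # images tagged with unique pixel values so multisets can be compared
  images <- list(); labels <- integer(0); id <- 0
  for (k in seq_along(sizes)) {
    for (i in seq_len(sizes[k])) {
      id <- id + 1
      images[[id]] <- array(id %% 256, c(px, px, 3))
      labels <- c(labels, k - 1L)
    }
  }
  labeled_dataset(images, labels, paste0("class", seq_along(sizes)))
}

img_ids <- function(ds) sort(vapply(ds$images, function(im) im[1, 1, 1],
                                    numeric(1)))

test_that("augmentation yields the contracted number of seeded 224x224 versions", {
  set.seed(41)
  img <- array(runif(240 * 240 * 3, 0, 255), c(240, 240, 3))
  out <- augment_image(img, augmentation_policy(), seed = 5)
  expect_length(out, 2)
  for (o in out) {
    expect_equal(dim(o), c(224, 224, 3))
    expect_true(all(o >= 0 & o <= 255))
  }
  # bit-identical under the same seed, different under another
  out2 <- augment_image(img, augmentation_policy(), seed = 5)
  expect_identical(out, out2)
  out3 <- augment_image(img, augmentation_policy(), seed = 6)
  expect_false(identical(out, out3))
})

test_that("additive noise has the advertised standard deviation", {
  set.seed(42)
  img <- array(128, c(100, 100, 3))
  noisy <- apply_transform(img, "noise", augmentation_policy())
  s <- stats::sd(noisy - img)
  expect_lt(abs(s - 10) / 10, 0.05)
})

test_that("class balancing hits its targets by over/undersampling", {
  ds <- tiny_ds(c(5, 20))
  bal <- balance_classes(ds, c(class1 = 10, class2 = 10), seed = 3)
  expect_equal(as.vector(table(bal$labels)), c(10, 10))
  # the oversampled class draws (with replacement) only from its 5 items
  src <- vapply(ds$images[ds$labels == 0], function(im) im[1, 1, 1],
                numeric(1))
  got <- vapply(bal$images[bal$labels == 0], function(im) im[1, 1, 1],
                numeric(1))
  expect_true(all(got %in% src))
  # targets equal to current sizes: identity in multiset terms
  noop <- balance_classes(ds, c(class1 = 5, class2 = 20), seed = 9)
  expect_identical(img_ids(noop), img_ids(ds))
  # different seeds keep sizes but generally change the multiset
  b1 <- balance_classes(ds, 10, seed = 1)
  b2 <- balance_classes(ds, 10, seed = 2)
  expect_equal(table(b1$labels), table(b2$labels))
  expect_error(balance_classes(labeled_dataset(list(), integer(0),
                                               c("a", "b")), 5), "empty")
})

test_that("stratified splitting is an exact seeded partition", {
  ds <- tiny_ds(rep(10, 4))
  sp <- stratified_split(ds, c(0.8, 0.1, 0.1), seed = 7)
  for (k in 0:3) {
    expect_equal(sum(sp$train$labels == k), 8)
    expect_equal(sum(sp$val$labels == k), 1)
    expect_equal(sum(sp$test$labels == k), 1)
  }
  # union of splits equals the original multiset; intersections empty
  all_ids <- c(img_ids(sp$train), img_ids(sp$val), img_ids(sp$test))
  expect_identical(sort(all_ids), img_ids(ds))
  expect_identical(sp, stratified_split(ds, c(0.8, 0.1, 0.1), seed = 7))
  expect_error(stratified_split(tiny_ds(c(2, 10))), "at least 3")
})

test_that("class-wise 8:1:1 proportions hold within one item on uneven sizes", {
  sizes <- c(288, 299, 296, 269, 266, 293, 284, 266)  # sums to 2261
  ds <- tiny_ds(sizes, px = 1)
  sp <- stratified_split(ds, seed = 11)
  total <- length(sp$train) + length(sp$val) + length(sp$test)
  expect_equal(total, 2261)
  for (k in seq_along(sizes) - 1L) {
    n <- sizes[k + 1]
    expect_lte(abs(sum(sp$train$labels == k) - 0.8 * n), 1)
    expect_lte(abs(sum(sp$val$labels == k) - 0.1 * n), 1)
    expect_lte(abs(sum(sp$test$labels == k) - 0.1 * n), 1)
  }
})

test_that("balancing then splitting preserves per-class proportions", {
  ds <- tiny_ds(c(7, 23, 15))
  bal <- balance_classes(ds, 20, seed = 2)
  sp <- stratified_split(bal, seed = 2)
  for (k in 0:2) {
    expect_equal(sum(sp$train$labels == k), 16)
    expect_equal(sum(sp$val$labels == k), 2)
    expect_equal(sum(sp$test$labels == k), 2)
  }
})

test_that("folder round trip preserves images, labels and class order", {
  set.seed(43)
  root <- withr::local_tempdir()
  ds <- generate_dataset(synth_spec(n_per_class = 3, image_size = 16,
                                    noise_sigma = 0, seed = 2))
  save_image_folder(ds, root)
  expect_true(file.exists(file.path(root, "manifest.csv")))
  back <- load_image_folder(root)
  expect_length(back$images, 24)
  expect_equal(back$class_names, ds$class_names)
  expect_equal(back$labels, ds$labels)
  # PNG storage rounds to 8 bits
  expect_equal(back$images[[1]], round(ds$images[[1]]), tolerance = 0.51)
  # non-image files are skipped with a warning, count unaffected
  writeLines("not an image", file.path(root, ds$class_names[1], "notes.txt"))
  expect_warning(again <- load_image_folder(root), "non-image")
  expect_length(again$images, 24)
  expect_error(load_image_folder(file.path(root, "missing_dir")),
               "missing_dir")
})
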