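# Image pipeline: directory-per-class I/O, the seeded augmentation policy,
# resample-based class balancing and stratified train/val/test splitting.
#
# Images are numeric arrays dim = c(H, W, 3) with values in [0, 255]
# (8-bit RGB intensities held as doubles).

#' Labelled image dataset
#'
#' @param images list of H x W x 3 arrays with values in `[0, 255]`.
#' @param labels integer vector of 0-based class indices, one per image.
#' @param class_names ordered character vector; `labels` index into it.
#' @return a list of class `"labeled_dataset"`.
#' @export
labeled_dataset <- function(images, labels, class_names) {
  labels <- as.integer(labels)
  if (length(images) != length(labels)) {
    stop("images and labels must have the same length")
  }
  K <- length(class_names)
  if (length(labels) && (min(labels) < 0 || max(labels) >= K)) {
    stop("labels must lie in [0, K)")
  }
  structure(list(images = images, labels = labels,
                 class_names = as.character(class_names)),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset: %d images, %d classes>\n", length(x$images),
              length(x$class_names)))
  tab <- table(factor(x$labels, levels = seq_along(x$class_names) - 1L,
                      labels = x$class_names))
  print(tab)
  invisible(x)
}

#' @export
length.labeled_dataset <- function(x) length(x$images)

ds_subset <- function(ds, idx) {
  labeled_dataset(ds$images[idx], ds$labels[idx], ds$class_names)
}

# ---- conversions between plain arrays and EBImage objects -----------------

to_eb <- function(img) {
  EBImage::Image(aperm(img, c(2, 1, 3)) / 255, colormode = "Color")
}

from_eb <- function(eb) {
  a <- as.array(eb)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  pmin(pmax(aperm(a, c(2, 1, 3)) * 255, 0), 255)
}

as_rgb255 <- function(img) {
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 1) img <- array(rep(img, 3), c(dim(img)[1:2], 3))
  img
}

resize_rgb <- function(img, h, w) {
  if (dim(img)[1] == h && dim(img)[2] == w) return(img)
  from_eb(EBImage::resize(to_eb(img), w = w, h = h))
}

#' Read an image file as an H x W x 3 array in [0, 255]
#' @param path PNG, JPEG or TIFF file.
#' @export
read_rgb <- function(path) {
  if (!file.exists(path)) stop(sprintf("image file not found: %s", path))
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    a <- png::readPNG(path)
    if (length(dim(a)) == 2) array(rep(a, 3), c(dim(a), 3)) else a
  } else {
    aperm(as.array(EBImage::readImage(path)), c(2, 1, 3))
  }
  as_rgb255(img * 255)
}

#' Load a directory-per-class image tree
#'
#' Subdirectories of `root`, in lexicographic order, become classes 0..K-1.
#' Non-image files are skipped with a warning.
#'
#' @param root directory containing one subdirectory per class.
#' @param resize_to if non-`NULL`, a side length images are resized to.
#' @return a [labeled_dataset()].
#' @export
load_image_folder <- function(root, resize_to = NULL) {
  if (!dir.exists(root)) stop(sprintf("dataset root not found: %s", root))
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (!length(classes)) stop(sprintf("no class directories under %s", root))
  images <- list(); labels <- integer(0)
  for (k in seq_along(classes)) {
    files <- sort(list.files(file.path(root, classes[k]), full.names = TRUE))
    ok <- grepl("\\.(png|jpe?g|tiff?)$", files, ignore.case = TRUE)
    if (any(!ok)) {
      warning(sprintf("skipping %d non-image file(s) in %s", sum(!ok),
                      classes[k]))
    }
    files <- files[ok]
    if (!length(files)) stop(sprintf("class directory '%s' holds no images",
                                     classes[k]))
    for (f in files) {
      img <- read_rgb(f)
      if (!is.null(resize_to)) img <- resize_rgb(img, resize_to, resize_to)
      images[[length(images) + 1L]] <- img
      labels <- c(labels, k - 1L)
    }
  }
  labeled_dataset(images, labels, classes)
}

#' Write a dataset as a directory-per-class PNG tree with a manifest
#'
#' @param ds a [labeled_dataset()].
#' @param root output directory (created).
#' @param manifest name of the manifest CSV written under `root`.
#' @return invisibly, the manifest data frame (filepath, label, class).
#' @export
save_image_folder <- function(ds, root, manifest = "manifest.csv") {
  rows <- list()
  for (k in seq_along(ds$class_names)) {
    dir.create(file.path(root, ds$class_names[k]), recursive = TRUE,
               showWarnings = FALSE)
  }
  counter <- integer(length(ds$class_names))
  for (i in seq_along(ds$images)) {
    k <- ds$labels[i] + 1L
    counter[k] <- counter[k] + 1L
    rel <- file.path(ds$class_names[k],
                     sprintf("%s_%04d.png", ds$class_names[k], counter[k]))
    png::writePNG(ds$images[[i]] / 255, file.path(root, rel))
    rows[[i]] <- data.frame(filepath = rel, label = ds$labels[i],
                            class = ds$class_names[k])
  }
  mf <- do.call(rbind, rows)
  utils::write.csv(mf, file.path(root, manifest), row.names = FALSE)
  invisible(mf)
}

# ---------------------------------------------------------------------------
# Augmentation
# ---------------------------------------------------------------------------

#' Augmentation policy
#'
#' Parameter ranges of the eight image transforms: random rotation, horizontal
#' flip, random 200x200 crop with resize back to 224x224, Gaussian blur,
#' additive Gaussian noise, and brightness / contrast / saturation scaling.
#' Each augmentation cycle samples 2-3 distinct transforms and produces
#' `versions_per_image` outputs.
#'
#' @param rotation_deg rotation range in degrees.
#' @param hflip_prob probability a selected flip is applied.
#' @param crop_size side length of the random crop (then resized back).
#' @param blur_radius Gaussian blur sigma range (pixels).
#' @param noise_sigma additive noise standard deviation (8-bit units).
#' @param brightness,contrast,saturation multiplicative factor ranges.
#' @param transforms_per_image range of how many transforms are combined.
#' @param versions_per_image augmented versions per source image.
#' @param out_size output side length.
#' @return list of class `"augmentation_policy"`.
#' @export
augmentation_policy <- function(rotation_deg = c(-45, 45), hflip_prob = 0.5,
                                crop_size = 200, blur_radius = c(0.5, 1.5),
                                noise_sigma = 10,
                                brightness = c(0.7, 1.3),
                                contrast = c(0.8, 1.2),
                                saturation = c(0.6, 1.4),
                                transforms_per_image = c(2, 3),
                                versions_per_image = 2, out_size = 224) {
  structure(list(rotation_deg = rotation_deg, hflip_prob = hflip_prob,
                 crop_size = crop_size, blur_radius = blur_radius,
                 noise_sigma = noise_sigma, brightness = brightness,
                 contrast = contrast, saturation = saturation,
                 transforms_per_image = transforms_per_image,
                 versions_per_image = versions_per_image,
                 out_size = out_size),
            class = "augmentation_policy")
}

aug_transform_names <- function() {
  c("rotate", "hflip", "crop", "blur", "noise", "brightness", "contrast",
    "saturation")
}

#' Apply one named augmentation transform
#'
#' Exposed mainly so single transforms can be exercised in isolation (for
#' example the noise moment check); [augment_image()] is the user-facing
#' entry point. Draws its random parameters from the current RNG state.
#'
#' @param img H x W x 3 array in `[0, 255]`.
#' @param name one of `"rotate"`, `"hflip"`, `"crop"`, `"blur"`, `"noise"`,
#'   `"brightness"`, `"contrast"`, `"saturation"`.
#' @param policy an [augmentation_policy()].
#' @return transformed image, same size as input.
#' @export
apply_transform <- function(img, name, policy = augmentation_policy()) {
  d <- dim(img)
  out <- switch(
    name,
    rotate = {
      ang <- stats::runif(1, policy$rotation_deg[1], policy$rotation_deg[2])
      from_eb(EBImage::rotate(to_eb(img), ang, output.dim = c(d[2], d[1]),
                              bg.col = "black"))
    },
    hflip = {
      if (stats::rbinom(1, 1, policy$hflip_prob) == 1) {
        img[, d[2]:1, , drop = FALSE]
      } else img
    },
    crop = {
      cs <- policy$crop_size
      if (d[1] < cs || d[2] < cs) {
        stop(sprintf("image %dx%d smaller than crop size %d", d[1], d[2], cs))
      }
      i0 <- sample.int(d[1] - cs + 1L, 1)
      j0 <- sample.int(d[2] - cs + 1L, 1)
      resize_rgb(img[i0:(i0 + cs - 1L), j0:(j0 + cs - 1L), , drop = FALSE],
                 d[1], d[2])
    },
    blur = {
      s <- stats::runif(1, policy$blur_radius[1], policy$blur_radius[2])
      from_eb(EBImage::gblur(to_eb(img), sigma = s))
    },
    noise = img + stats::rnorm(length(img), sd = policy$noise_sigma),
    brightness = img * stats::runif(1, policy$brightness[1],
                                    policy$brightness[2]),
    contrast = (img - 128) * stats::runif(1, policy$contrast[1],
                                          policy$contrast[2]) + 128,
    saturation = {
      f <- stats::runif(1, policy$saturation[1], policy$saturation[2])
      g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
      gr <- array(rep(g, 3), dim(img))
      gr + f * (img - gr)
    },
    stop(sprintf("unknown transform '%s'", name)))
  pmin(pmax(out, 0), 255)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", .GlobalEnv)
  }
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv) else
    rm(".Random.seed", envir = .GlobalEnv))
  force(code)
}

#' Augment one image
#'
#' Resizes the input to the policy output size, then produces
#' `policy$versions_per_image` augmented versions, each from an independently
#' sampled combination of 2-3 distinct transforms. Deterministic given
#' `seed`.
#'
#' @param img H x W x 3 array in `[0, 255]` (any size >= the crop size after
#'   resizing).
#' @param policy an [augmentation_policy()].
#' @param seed integer seed.
#' @return list of augmented `out_size` x `out_size` x 3 arrays.
#' @export
augment_image <- function(img, policy = augmentation_policy(), seed = 1) {
  if (is.null(dim(img)) || length(dim(img)) < 2) {
    stop("img must be an image array")
  }
  img <- as_rgb255(img)
  with_seed(seed, {
    img <- resize_rgb(img, policy$out_size, policy$out_size)
    lapply(seq_len(policy$versions_per_image), function(v) {
      n_tr <- sample(seq(policy$transforms_per_image[1],
                         policy$transforms_per_image[2]), 1)
      chosen <- sample(aug_transform_names(), n_tr)
      out <- img
      for (tr in chosen) out <- apply_transform(out, tr, policy)
      out
    })
  })
}

#' Augment a whole dataset
#'
#' Keeps each original image and appends its augmented versions with the same
#' label.
#'
#' @param ds a [labeled_dataset()].
#' @param policy an [augmentation_policy()].
#' @param seed integer seed.
#' @param keep_original include the (resized) source images.
#' @return a larger [labeled_dataset()].
#' @export
augment_dataset <- function(ds, policy = augmentation_policy(), seed = 1,
                            keep_original = TRUE) {
  images <- list(); labels <- integer(0)
  for (i in seq_along(ds$images)) {
    aug <- augment_image(ds$images[[i]], policy, seed = seed + i - 1L)
    if (keep_original) {
      aug <- c(list(resize_rgb(as_rgb255(ds$images[[i]]), policy$out_size,
                               policy$out_size)), aug)
    }
    images <- c(images, aug)
    labels <- c(labels, rep(ds$labels[i], length(aug)))
  }
  labeled_dataset(images, labels, ds$class_names)
}

# ---------------------------------------------------------------------------
# Balancing and splitting
# ---------------------------------------------------------------------------

#' Balance class sizes by resampling
#'
#' Classes below their target are oversampled with replacement; classes above
#' it are downsampled without replacement. Deterministic given `seed`.
#'
#' @param ds a [labeled_dataset()].
#' @param target_counts named integer vector (class name -> target), a single
#'   integer applied to all classes, or `NULL` for the median class size.
#' @param seed integer seed.
#' @return a [labeled_dataset()] whose class sizes equal the targets.
#' @export
balance_classes <- function(ds, target_counts = NULL, seed = 1) {
  K <- length(ds$class_names)
  sizes <- vapply(seq_len(K) - 1L, function(k) sum(ds$labels == k), integer(1))
  if (is.null(target_counts)) {
    target_counts <- rep(as.integer(round(stats::median(sizes))), K)
  } else if (length(target_counts) == 1L && is.null(names(target_counts))) {
    target_counts <- rep(as.integer(target_counts), K)
  } else {
    tc <- rep(NA_integer_, K)
    names(tc) <- ds$class_names
    tc[names(target_counts)] <- as.integer(target_counts)
    if (any(is.na(tc))) stop("target_counts must cover every class")
    target_counts <- tc
  }
  if (any(target_counts < 1)) stop("target counts must be positive")
  with_seed(seed, {
    idx <- integer(0)
    for (k in seq_len(K)) {
      pool <- which(ds$labels == k - 1L)
      tgt <- target_counts[k]
      if (!length(pool)) {
        stop(sprintf("class '%s' is empty but has target %d",
                     ds$class_names[k], tgt))
      }
      sel <- if (length(pool) < tgt) {
        sample(pool, tgt, replace = TRUE)
      } else if (length(pool) > tgt) {
        sample(pool, tgt, replace = FALSE)
      } else pool
      idx <- c(idx, sel)
    }
    ds_subset(ds, idx)
  })
}

largest_remainder <- function(n, ratios) {
  q <- n * ratios
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    # ties broken toward the earlier split
    ord <- order(q - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Stratified train/validation/test split
#'
#' Splits every class independently in the given ratios using
#' largest-remainder rounding, so each split's class proportions match the
#' ratios to within one item per class. Deterministic given `seed`.
#'
#' @param ds a [labeled_dataset()].
#' @param ratios length-3 positive vector summing to 1.
#' @param seed integer seed.
#' @return named list of [labeled_dataset()]s: `train`, `val`, `test`.
#' @export
stratified_split <- function(ds, ratios = c(0.8, 0.1, 0.1), seed = 1) {
  if (length(ratios) != 3 || any(ratios < 0) ||
      abs(sum(ratios) - 1) > 1e-8) {
    stop("ratios must be three non-negative numbers summing to 1")
  }
  K <- length(ds$class_names)
  parts <- list(integer(0), integer(0), integer(0))
  with_seed(seed, {
    for (k in seq_len(K)) {
      pool <- which(ds$labels == k - 1L)
      if (length(pool) < 3) {
        stop(sprintf("class '%s' has %d items; need at least 3 to split",
                     ds$class_names[k], length(pool)))
      }
      pool <- sample(pool)
      sizes <- largest_remainder(length(pool), ratios)
      ends <- cumsum(sizes)
      starts <- c(1L, head(ends, -1) + 1L)
      for (s in 1:3) {
        if (sizes[s] > 0) {
          parts[[s]] <- c(parts[[s]], pool[starts[s]:ends[s]])
        }
      }
    }
  })
  list(train = ds_subset(ds, parts[[1]]), val = ds_subset(ds, parts[[2]]),
       test = ds_subset(ds, parts[[3]]))
}
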