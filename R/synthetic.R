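# Seeded synthetic lesion-image generator.  Eight classes mirror the field's
# usual strawberry roster (four leaf states, four fruit states); each class
# is defined by a background shade, a lesion shape family (circular spot,
# angular patch, diffuse powder, or none), a lesion scale/count range and a
# lesion colour.  The classes are constructed to be separable by colour
# statistics alone at zero noise, so a failure of the full network on this
# data indicates an implementation bug rather than data ambiguity.  This is
# a stand-in for field imagery, not a simulation of real pathology.

synth_class_table <- function() {
  list(
    angular_leafspot = list(bg = c(62, 138, 66), shape = "angular",
                            col = c(96, 64, 24), count = c(3, 6),
                            radius = c(10, 20)),
    anthracnose_fruit_rot = list(bg = c(176, 48, 52), shape = "circle",
                                 col = c(52, 30, 24), count = c(2, 5),
                                 radius = c(12, 26)),
    gray_mold = list(bg = c(156, 62, 60), shape = "circle",
                     col = c(138, 134, 128), count = c(2, 4),
                     radius = c(18, 34)),
    healthy_leaf = list(bg = c(58, 150, 74), shape = "none",
                        col = c(0, 0, 0), count = c(0, 0), radius = c(0, 0)),
    healthy_ripe_fruit = list(bg = c(196, 44, 46), shape = "none",
                              col = c(0, 0, 0), count = c(0, 0),
                              radius = c(0, 0)),
    leaf_spot = list(bg = c(74, 126, 58), shape = "circle",
                     col = c(70, 44, 78), count = c(5, 10),
                     radius = c(5, 10)),
    powdery_mildew_fruit = list(bg = c(186, 66, 70), shape = "powder",
                                col = c(236, 236, 230), count = c(40, 80),
                                radius = c(2, 4)),
    powdery_mildew_leaf = list(bg = c(70, 142, 88), shape = "powder",
                               col = c(240, 240, 235), count = c(40, 80),
                               radius = c(2, 4)))
}

#' Synthetic dataset specification
#'
#' @param n_per_class images per class.
#' @param image_size square image side in pixels.
#' @param noise_sigma additive Gaussian pixel noise (8-bit units).
#' @param lesion_scale multiplier on every class's lesion radius range.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return list of class `"synth_spec"`.
#' @export
synth_spec <- function(n_per_class = 50, image_size = 224, noise_sigma = 5,
                       lesion_scale = 1, seed = 1) {
  if (image_size < 16) stop("image_size must be >= 16")
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(n_per_class = as.integer(n_per_class),
                 image_size = as.integer(image_size),
                 noise_sigma = noise_sigma, lesion_scale = lesion_scale,
                 seed = as.integer(seed), classes = synth_class_table()),
            class = "synth_spec")
}

draw_lesion_mask <- function(size, shape, cx, cy, r, ang) {
  gx <- matrix(rep(seq_len(size), size), size)       # row coordinate
  gy <- t(gx)
  dx <- gx - cx
  dy <- gy - cy
  switch(shape,
         circle = dx^2 + dy^2 <= r^2,
         angular = {
           # rotated diamond: an angular patch with four corners
           u <- cos(ang) * dx + sin(ang) * dy
           v <- -sin(ang) * dx + cos(ang) * dy
           abs(u) + abs(v) <= r * 1.2
         },
         powder = dx^2 + dy^2 <= r^2,
         matrix(FALSE, size, size))
}

synth_one_image <- function(cls, size, noise_sigma, lesion_scale) {
  img <- array(0, c(size, size, 3))
  # mottled background: base shade + low-frequency sinusoidal texture
  ph <- stats::runif(2, 0, 2 * pi)
  fr <- stats::runif(2, 1, 3)
  gx <- matrix(rep(seq_len(size), size), size) / size
  gy <- t(gx)
  tex <- 10 * sin(2 * pi * fr[1] * gx + ph[1]) * cos(2 * pi * fr[2] * gy + ph[2])
  shift <- stats::runif(1, -3, 3)
  for (c in 1:3) img[, , c] <- cls$bg[c] + tex + shift
  if (cls$shape != "none") {
    n_les <- if (cls$count[1] == cls$count[2]) cls$count[1] else
      sample(cls$count[1]:cls$count[2], 1)
    for (i in seq_len(n_les)) {
      cx <- stats::runif(1, 1, size)
      cy <- stats::runif(1, 1, size)
      r <- stats::runif(1, cls$radius[1], cls$radius[2]) * lesion_scale *
        size / 224
      ang <- stats::runif(1, 0, pi)
      mask <- draw_lesion_mask(size, cls$shape, cx, cy, max(r, 1), ang)
      alpha <- if (cls$shape == "powder") 0.85 else 1
      for (c in 1:3) {
        plane <- img[, , c]
        plane[mask] <- (1 - alpha) * plane[mask] + alpha * cls$col[c]
        img[, , c] <- plane
      }
    }
  }
  if (noise_sigma > 0) {
    img <- img + stats::rnorm(length(img), sd = noise_sigma)
  }
  pmin(pmax(img, 0), 255)
}

#' Generate a synthetic lesion-image dataset
#'
#' Produces `8 * n_per_class` images in the directory-per-class sense:
#' class names are ordered lexicographically and labels index into them.
#' Bit-identical output for identical specs.
#'
#' @param spec a [synth_spec()].
#' @return a [labeled_dataset()].
#' @export
generate_dataset <- function(spec = synth_spec()) {
  cls_names <- names(spec$classes)   # already lexicographic
  images <- list()
  labels <- integer(0)
  with_seed(spec$seed, {
    for (k in seq_along(cls_names)) {
      for (i in seq_len(spec$n_per_class)) {
        images[[length(images) + 1L]] <-
          synth_one_image(spec$classes[[k]], spec$image_size,
                          spec$noise_sigma, spec$lesion_scale)
        labels <- c(labels, k - 1L)
      }
    }
  })
  labeled_dataset(images, labels, cls_names)
}

#' Generate datasets over a sweep of lesion scales
#'
#' Each dataset is generated from the same seed and differs only in the
#' lesion radius multiplier, so lesion positions and counts coincide across
#' scales. Oversized lesions are clipped to the frame.
#'
#' @param base a [synth_spec()].
#' @param scales positive lesion-radius multipliers.
#' @return list of [labeled_dataset()]s, one per scale.
#' @export
generate_scale_series <- function(base = synth_spec(),
                                  scales = c(0.5, 1, 2)) {
  if (any(scales <= 0)) stop("scales must be positive")
  lapply(scales, function(s) {
    sp <- base
    sp$lesion_scale <- base$lesion_scale * s
    generate_dataset(sp)
  })
}

#' Count lesion-coloured pixels in an image
#'
#' Helper for generator checks: pixels within `tol` (max channel distance)
#' of the class's lesion colour.
#'
#' @param img H x W x 3 array.
#' @param lesion_col length-3 RGB colour.
#' @param tol per-channel tolerance.
#' @export
count_lesion_pixels <- function(img, lesion_col, tol = 12) {
  d <- abs(sweep(img, 3, lesion_col, "-"))
  sum(apply(d, c(1, 2), max) <= tol)
}
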