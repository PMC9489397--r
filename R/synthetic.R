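# Synthetic colposcopy-like image generator.  Five classes are rendered
# from class-specific generative parameters — base hue, bright blob count
# and sinusoidal texture frequency — plus i.i.d. Gaussian pixel noise.  At
# noise_sd = 0 the classes are separable from mean color alone; raising
# noise_sd makes them progressively confusable.

#' Synthetic dataset configuration
#'
#' The default per-class counts mirror the clinical class-imbalance profile
#' (2352:780:2532:408:924) scaled down by `scale` with a floor, e.g.
#' `scale = 12` gives 196/65/211/34/77.
#'
#' @param per_class_counts Named (or ordered) non-negative counts for labels
#'   0..K-1; default the scaled clinical profile.
#' @param image_size Square image side in pixels (default 256).
#' @param class_signal data.frame with one row per class and columns `hue`
#'   (base hue in `[0, 1)`), `blobs` (bright ellipse count) and `freq`
#'   (texture cycles per image).
#' @param noise_sd Gaussian pixel-noise standard deviation (>= 0).
#' @param seed Integer seed; the dataset is a pure function of the config.
#' @param scale Divisor applied to the clinical counts when
#'   `per_class_counts` is not given.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(per_class_counts = NULL, image_size = 256L,
                             class_signal = default_class_signal(),
                             noise_sd = 0.05, seed = 1L, scale = 12) {
  if (is.null(per_class_counts))
    per_class_counts <- as.integer(floor(clinical_class_counts() / scale))
  per_class_counts <- as.integer(per_class_counts)
  if (any(per_class_counts < 0L)) stop("synthetic_config: counts must be >= 0")
  if (noise_sd < 0) stop("synthetic_config: noise_sd must be >= 0")
  if (nrow(class_signal) != length(per_class_counts))
    stop("synthetic_config: class_signal rows must match class count")
  structure(list(per_class_counts = per_class_counts,
                 image_size = as.integer(image_size),
                 class_signal = class_signal,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Default class-signal table
#'
#' Base hues are spread over the color circle so mean image hue is monotone
#' in the class index; blob counts and texture frequencies also increase
#' with the class.
#'
#' @return data.frame with columns `hue`, `blobs`, `freq`.
#' @export
default_class_signal <- function() {
  data.frame(hue = c(0.02, 0.22, 0.45, 0.65, 0.85),
             blobs = c(1L, 2L, 3L, 4L, 5L),
             freq = c(2, 4, 6, 8, 10))
}

render_synthetic_image <- function(size, hue, blobs, freq, noise_sd) {
  base <- col2rgb(hsv(hue, 0.55, 0.70)) / 255
  img <- array(rep(base, each = size * size), c(size, size, 3L))
  yy <- matrix(seq_len(size), size, size)
  xx <- matrix(seq_len(size), size, size, byrow = TRUE)
  # bright elliptical blobs (lesion-like highlights)
  if (blobs > 0L) {
    for (b in seq_len(blobs)) {
      cy <- runif(1, 0.2, 0.8) * size
      cx <- runif(1, 0.2, 0.8) * size
      ry <- runif(1, 0.06, 0.15) * size
      rx <- runif(1, 0.06, 0.15) * size
      mask <- ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1
      for (c in 1:3) {
        ch <- img[, , c]
        ch[mask] <- ch[mask] + 0.18
        img[, , c] <- ch
      }
    }
  }
  # sinusoidal texture along the diagonal
  tex <- 0.06 * sin(2 * pi * freq * (yy + xx) / (2 * size))
  for (c in 1:3) img[, , c] <- img[, , c] + tex
  if (noise_sd > 0)
    img <- img + array(rnorm(size * size * 3L, sd = noise_sd),
                       c(size, size, 3L))
  pmin(pmax(img, 0), 1)
}

#' Generate a synthetic labeled image dataset
#'
#' Renders every image from its class recipe (see [synthetic_config()]),
#' fully reproducibly from the seed.  Optionally writes the dataset to disk
#' in the image-folder layout `dir/<label>/img_<label>_<i>.png` together
#' with a `manifest.csv`.
#'
#' @param config A [synthetic_config()].
#' @param dir Optional output directory for PNG files.
#' @return An [image_dataset()] with in-memory images (and paths when `dir`
#'   is given).
#' @export
generate_synthetic_dataset <- function(config = synthetic_config(),
                                       dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  images <- list(); labels <- integer(); paths <- character(0)
  sig <- config$class_signal
  for (k in seq_along(config$per_class_counts)) {
    lab <- k - 1L
    for (i in seq_len(config$per_class_counts[k])) {
      img <- render_synthetic_image(config$image_size, sig$hue[k],
                                    sig$blobs[k], sig$freq[k],
                                    config$noise_sd)
      images[[length(images) + 1L]] <- img
      labels <- c(labels, lab)
    }
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(length(labels))
    cnt <- integer(max(length(config$per_class_counts), 1L))
    for (j in seq_along(labels)) {
      lab <- labels[j]
      sub <- file.path(dir, lab)
      dir.create(sub, showWarnings = FALSE)
      cnt[lab + 1L] <- cnt[lab + 1L] + 1L
      paths[j] <- file.path(sub, sprintf("img_%d_%04d.png", lab, cnt[lab + 1L]))
      png::writePNG(images[[j]], paths[j])
    }
    # empty classes still get their directory
    for (k in seq_along(config$per_class_counts))
      dir.create(file.path(dir, k - 1L), showWarnings = FALSE)
    manifest <- data.frame(path = paths, label = labels,
                           stringsAsFactors = FALSE)
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    return(image_dataset(labels, images = images, paths = paths))
  }
  image_dataset(labels, images = images)
}

#' Mean-color feature of an image
#'
#' @param img `H x W x 3` array.
#' @return Length-3 RGB mean vector.
#' @export
mean_color <- function(img) colMeans(matrix(img, ncol = 3L))
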