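# Dataset handling: image-folder I/O, inventory, stratified 90/10 split and
# the augmentation pipeline.  The working container is an `image_dataset`:
# integer labels (0-based) plus either in-memory images (H x W x 3 arrays in
# [0, 1]) or file paths, or both.

#' Construct an image dataset
#'
#' @param labels Integer class labels, 0-based.
#' @param images Optional list of `H x W x 3` arrays in `[0, 1]`.
#' @param paths Optional character vector of image files.
#' @param group_id Optional per-record grouping identifier (e.g. patient).
#' @return An object of class `image_dataset`.
#' @export
image_dataset <- function(labels, images = NULL, paths = NULL,
                          group_id = NULL) {
  labels <- as.integer(labels)
  n <- length(labels)
  if (!is.null(images) && length(images) != n)
    stop("image_dataset: images/labels length mismatch")
  if (!is.null(paths) && length(paths) != n)
    stop("image_dataset: paths/labels length mismatch")
  if (is.null(images) && is.null(paths))
    stop("image_dataset: need images or paths")
  structure(list(labels = labels, images = images, paths = paths,
                 group_id = group_id),
            class = "image_dataset")
}

#' @export
length.image_dataset <- function(x) length(x$labels)

#' @export
print.image_dataset <- function(x, ...) {
  inv <- inventory(x)
  cat(sprintf("image_dataset: %d records, %d classes (%s)\n",
              inv$total, length(inv$per_class_counts),
              if (is.null(x$images)) "on disk" else "in memory"))
  print(inv$per_class_counts)
  invisible(x)
}

subset_dataset <- function(ds, idx) {
  image_dataset(ds$labels[idx],
                images = if (!is.null(ds$images)) ds$images[idx],
                paths = if (!is.null(ds$paths)) ds$paths[idx],
                group_id = if (!is.null(ds$group_id)) ds$group_id[idx])
}

#' Read one image file as an `H x W x 3` array in `[0, 1]`
#'
#' Grayscale images are replicated to 3 channels; alpha is dropped.
#'
#' @param path A PNG or JPEG file.
#' @return Numeric array `H x W x 3`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                jpg = , jpeg = jpeg::readJPEG(path),
                stop(sprintf("read_image: unsupported extension '%s'", ext)))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Get the i-th image of a dataset
#'
#' @param ds An [image_dataset()].
#' @param i Record index.
#' @return `H x W x 3` array.
#' @export
get_image <- function(ds, i) {
  if (!is.null(ds$images)) ds$images[[i]] else read_image(ds$paths[i])
}

#' Load an image-folder dataset
#'
#' Expects `root/<label-int>/*.png|jpg|jpeg` with consecutive integer labels
#' starting at 0.  Files are ordered lexicographically (byte order) so
#' repeated loads are identical; unreadable files are skipped with a
#' warning and counted in `attr(, "skipped")`.
#'
#' @param root Dataset root directory.
#' @param scheme A [label_scheme()]; only labels present in the scheme are
#'   loaded.
#' @param validate Attempt to read every file and drop unreadable ones
#'   (default `TRUE`).
#' @return An [image_dataset()] with paths.
#' @export
load_image_folder <- function(root, scheme = label_scheme(), validate = TRUE) {
  if (!dir.exists(root)) stop(sprintf("dataset root '%s' does not exist", root))
  subdirs <- list.dirs(root, recursive = FALSE, full.names = TRUE)
  subdirs <- subdirs[basename(subdirs) %in% names(scheme)]
  paths <- character(); labels <- integer()
  for (d in subdirs) {
    fs <- list.files(d, pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE,
                     full.names = TRUE)
    fs <- fs[order(fs, method = "radix")]
    paths <- c(paths, fs)
    labels <- c(labels, rep(as.integer(basename(d)), length(fs)))
  }
  skipped <- 0L
  if (validate && length(paths)) {
    ok <- vapply(paths, function(p) {
      !inherits(try(read_image(p), silent = TRUE), "try-error")
    }, logical(1))
    skipped <- sum(!ok)
    if (skipped > 0L)
      warning(sprintf("skipped %d unreadable image file(s)", skipped))
    paths <- paths[ok]; labels <- labels[ok]
  }
  if (length(paths) == 0L)
    stop(sprintf("empty dataset: no readable images under '%s'", root))
  o <- order(paths, method = "radix")
  ds <- image_dataset(labels[o], paths = paths[o])
  attr(ds, "skipped") <- skipped
  ds
}

#' Per-class inventory
#'
#' @param x An [image_dataset()] or an integer label vector.
#' @return List of class `dataset_inventory` with `per_class_counts` (named
#'   by label) and `total`.
#' @export
inventory <- function(x) {
  labels <- if (inherits(x, "image_dataset")) x$labels else as.integer(x)
  counts <- table(factor(labels, levels = sort(unique(labels))))
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(list(per_class_counts = counts, total = sum(counts)),
            class = "dataset_inventory")
}

#' @export
print.dataset_inventory <- function(x, ...) {
  cat("per-class counts:\n")
  print(x$per_class_counts)
  cat("total:", x$total, "\n")
  invisible(x)
}

#' The clinical dataset's per-class image counts
#'
#' Reference per-class counts of the clinical colposcopy dataset this
#' architecture family targets (labels 0-4): 2352, 780, 2532, 408, 924 —
#' 6,996 images in total.  Used as the class-imbalance profile for the
#' synthetic generator.
#'
#' @return Named integer vector over labels "0".."4".
#' @export
clinical_class_counts <- function() {
  stats::setNames(c(2352L, 780L, 2532L, 408L, 924L), as.character(0:4))
}

#' Stratified train/validation split
#'
#' Splits per class at `train_fraction` (default the 90/10 protocol).
#' Per-class train counts are rounded half-up and then balanced so the
#' global train count is within one record of `round(total * fraction)`;
#' every class keeps at least one record on each side.  With
#' `grouped = TRUE`, records sharing `group_id` stay in one subset
#' (split by groups, approximate stratification).
#'
#' @param ds An [image_dataset()]; every class needs >= 2 records.
#' @param train_fraction Fraction of records for training.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @param grouped Keep `group_id` groups intact.
#' @return List with `train` and `val` datasets.
#' @export
stratified_split <- function(ds, train_fraction = 0.9, seed = 1L,
                             grouped = FALSE) {
  stopifnot(inherits(ds, "image_dataset"))
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("stratified_split: train_fraction must be in (0, 1)")
  inv <- inventory(ds)
  if (any(inv$per_class_counts < 2L))
    stop("stratified_split: every class needs at least 2 records")
  set.seed(seed)
  if (grouped && !is.null(ds$group_id)) {
    groups <- unique(ds$group_id)
    groups <- sample(groups)
    target <- round(length(ds) * train_fraction)
    take <- logical(length(groups)); cum <- 0L
    for (i in seq_along(groups)) {
      sz <- sum(ds$group_id == groups[i])
      if (cum < target) { take[i] <- TRUE; cum <- cum + sz }
    }
    tr_idx <- which(ds$group_id %in% groups[take])
    va_idx <- setdiff(seq_along(ds$labels), tr_idx)
    return(list(train = subset_dataset(ds, tr_idx),
                val = subset_dataset(ds, va_idx)))
  }
  labs <- sort(unique(ds$labels))
  n_train <- integer(length(labs))
  idx_by_class <- lapply(labs, function(l) {
    i <- which(ds$labels == l)
    i[sample.int(length(i))]
  })
  nk <- vapply(idx_by_class, length, integer(1))
  n_train <- pmin(pmax(floor(nk * train_fraction + 0.5), 1L), nk - 1L)
  target <- round(length(ds) * train_fraction)
  # balance the global count to within one record
  while (sum(n_train) > target + 1L) {
    cand <- which(n_train > 1L)
    j <- cand[which.max(n_train[cand])]
    n_train[j] <- n_train[j] - 1L
  }
  while (sum(n_train) < target - 1L) {
    cand <- which(n_train < nk - 1L)
    j <- cand[which.max(nk[cand] - n_train[cand])]
    n_train[j] <- n_train[j] + 1L
  }
  tr_idx <- unlist(mapply(function(i, n) i[seq_len(n)], idx_by_class,
                          n_train, SIMPLIFY = FALSE))
  va_idx <- setdiff(seq_along(ds$labels), tr_idx)
  list(train = subset_dataset(ds, sort(tr_idx)),
       val = subset_dataset(ds, sort(va_idx)))
}

#' Write a split manifest as CSV
#'
#' Columns `path,label,subset,group_id` — the plain-text record of a split.
#'
#' @param split List with `train`/`val` as from [stratified_split()].
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(split, path) {
  row <- function(ds, subset) {
    data.frame(path = if (is.null(ds$paths)) NA_character_ else ds$paths,
               label = ds$labels, subset = subset,
               group_id = if (is.null(ds$group_id)) NA else ds$group_id,
               stringsAsFactors = FALSE)
  }
  write.csv(rbind(row(split$train, "train"), row(split$val, "val")),
            path, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# augmentation

#' Bilinear image resize
#'
#' @param img `H x W x C` array.
#' @param new_h,new_w Target dims.
#' @return Resized array.
#' @export
resize_image <- function(img, new_h, new_w) {
  d <- dim(img)
  if (d[1L] == new_h && d[2L] == new_w) return(img)
  ys <- (seq_len(new_h) - 0.5) * d[1L] / new_h - 0.5
  xs <- (seq_len(new_w) - 0.5) * d[2L] / new_w - 0.5
  y0 <- pmin(pmax(floor(ys), 0), d[1L] - 1L); y1 <- pmin(y0 + 1, d[1L] - 1L)
  x0 <- pmin(pmax(floor(xs), 0), d[2L] - 1L); x1 <- pmin(x0 + 1, d[2L] - 1L)
  wy <- pmin(pmax(ys - y0, 0), 1); wx <- pmin(pmax(xs - x0, 0), 1)
  out <- array(0, c(new_h, new_w, d[3L]))
  for (c in seq_len(d[3L])) {
    ch <- img[, , c]
    a <- ch[y0 + 1L, x0 + 1L, drop = FALSE] * outer(1 - wy, 1 - wx) +
         ch[y1 + 1L, x0 + 1L, drop = FALSE] * outer(wy, 1 - wx) +
         ch[y0 + 1L, x1 + 1L, drop = FALSE] * outer(1 - wy, wx) +
         ch[y1 + 1L, x1 + 1L, drop = FALSE] * outer(wy, wx)
    out[, , c] <- a
  }
  out
}

resize_shorter_side <- function(img, target) {
  d <- dim(img)
  if (min(d[1:2]) == target) return(img)
  if (d[1L] <= d[2L]) {
    resize_image(img, target, max(round(d[2L] * target / d[1L]), target))
  } else {
    resize_image(img, max(round(d[1L] * target / d[2L]), target), target)
  }
}

#' Per-channel normalization statistics of a dataset
#'
#' Mean and standard deviation per RGB channel over all pixels of the given
#' records — computed from the training split, so standardized training
#' tensors have mean approximately 0 and sd approximately 1 per channel.
#'
#' @param ds An [image_dataset()].
#' @param max_images Cap on images scanned (uniformly spaced), default all.
#' @return List with `mean` and `sd`, each length 3.
#' @export
compute_norm_stats <- function(ds, max_images = Inf) {
  n <- length(ds)
  idx <- if (n > max_images)
    unique(round(seq(1, n, length.out = max_images))) else seq_len(n)
  s <- numeric(3); s2 <- numeric(3); cnt <- 0
  for (i in idx) {
    img <- get_image(ds, i)
    m <- matrix(img, ncol = 3L)
    s <- s + colSums(m); s2 <- s2 + colSums(m * m)
    cnt <- cnt + nrow(m)
  }
  mu <- s / cnt
  sdv <- sqrt(pmax(s2 / cnt - mu^2, 1e-12))
  list(mean = mu, sd = sdv)
}

#' Default normalization constants
#'
#' A generic fallback (mean 0.5, sd 0.25 per channel) for use when the
#' training-split statistics are not available.
#'
#' @return List with `mean` and `sd`.
#' @export
norm_stats_default <- function() {
  list(mean = rep(0.5, 3), sd = rep(0.25, 3))
}

standardize_image <- function(img, stats) {
  d <- dim(img)
  sweep(sweep(img, 3L, stats$mean), 3L, stats$sd, "/")
}

#' Training-time augmentation
#'
#' Applies, in order: resize policy (shorter side to `resize_to`, skipped
#' when `resize_to` is `NULL` and the image already covers the crop), a
#' random `crop_size` crop, random horizontal and vertical flips (p = 0.5
#' each), and per-channel standardization.  Randomness comes from the
#' current RNG state.
#'
#' @param img `H x W x 3` array in `[0, 1]`.
#' @param crop_size Output spatial size (default 224).
#' @param resize_to Shorter-side resize target before cropping (default 256;
#'   `NULL` to skip).
#' @param stats Normalization statistics ([compute_norm_stats()]); default
#'   the generic constants.
#' @param hflip,vflip Enable the random flips.
#' @return Standardized `crop_size x crop_size x 3` array.
#' @export
augment_train <- function(img, crop_size = 224L, resize_to = 256L,
                          stats = norm_stats_default(),
                          hflip = TRUE, vflip = TRUE) {
  if (!is.null(resize_to)) img <- resize_shorter_side(img, resize_to)
  d <- dim(img)
  if (d[1L] < crop_size || d[2L] < crop_size)
    stop(sprintf("augment_train: image %dx%d smaller than crop %d",
                 d[1L], d[2L], crop_size))
  oy <- if (d[1L] > crop_size) sample.int(d[1L] - crop_size + 1L, 1L) else 1L
  ox <- if (d[2L] > crop_size) sample.int(d[2L] - crop_size + 1L, 1L) else 1L
  img <- img[oy:(oy + crop_size - 1L), ox:(ox + crop_size - 1L), , drop = FALSE]
  if (hflip && runif(1) < 0.5) img <- img[, crop_size:1L, , drop = FALSE]
  if (vflip && runif(1) < 0.5) img <- img[crop_size:1L, , , drop = FALSE]
  standardize_image(img, stats)
}

#' Evaluation-time transform
#'
#' Deterministic counterpart of [augment_train()]: resize policy, center
#' crop, standardization.  A 256 x 256 input center-cropped to 224 spans
#' rows and columns 16..239 (0-based).
#'
#' @inheritParams augment_train
#' @return Standardized `crop_size x crop_size x 3` array.
#' @export
augment_eval <- function(img, crop_size = 224L, resize_to = 256L,
                         stats = norm_stats_default()) {
  if (!is.null(resize_to)) img <- resize_shorter_side(img, resize_to)
  d <- dim(img)
  if (d[1L] < crop_size || d[2L] < crop_size)
    stop(sprintf("augment_eval: image %dx%d smaller than crop %d",
                 d[1L], d[2L], crop_size))
  oy <- (d[1L] - crop_size) %/% 2L + 1L
  ox <- (d[2L] - crop_size) %/% 2L + 1L
  img <- img[oy:(oy + crop_size - 1L), ox:(ox + crop_size - 1L), , drop = FALSE]
  standardize_image(img, stats)
}
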