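# Data pipeline: folder I/O, inventory, stratified split, augmentation,
# synthetic generator.

test_that("image folders load deterministically with correct labels", {
  root <- tempfile("imgds")
  dir.create(file.path(root, "0"), recursive = TRUE)
  dir.create(file.path(root, "3"), recursive = TRUE)
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  png::writePNG(img, file.path(root, "0", "a.png"))
  png::writePNG(img, file.path(root, "0", "b.png"))
  png::writePNG(img, file.path(root, "3", "c.png"))
  ds <- load_image_folder(root)
  expect_equal(length(ds), 3)
  expect_equal(ds$labels, c(0L, 0L, 3L))
  expect_equal(inventory(ds)$total, 3)
  ds2 <- load_image_folder(root)
  expect_identical(ds$paths, ds2$paths)
  # unreadable file is skipped with a warning
  writeLines("not a png", file.path(root, "0", "broken.png"))
  expect_warning(ds3 <- load_image_folder(root), "unreadable")
  expect_equal(length(ds3), 3)
  expect_equal(attr(ds3, "skipped"), 1L)
  # empty dataset errors
  empty <- tempfile("empty"); dir.create(file.path(empty, "0"), recursive = TRUE)
  expect_error(load_image_folder(empty), "empty dataset")
  unlink(root, recursive = TRUE); unlink(empty, recursive = TRUE)
})

test_that("inventory counts the clinical reference profile to 6,996", {
  counts <- clinical_class_counts()
  labels <- rep(0:4, times = counts)
  inv <- inventory(labels)
  expect_equal(unname(inv$per_class_counts),
               c(2352L, 780L, 2532L, 408L, 924L))
  expect_equal(inv$total, 6996L)
  # permutation invariance and empty case
  expect_equal(inventory(sample(labels))$total, 6996L)
  expect_equal(inventory(integer(0))$total, 0L)
})

test_that("stratified split is a seeded partition at the 90/10 ratio", {
  ds <- image_dataset(rep(0:4, each = 10),
                      paths = sprintf("img%02d.png", 1:50))
  sp <- stratified_split(ds, 0.9, seed = 7)
  expect_equal(length(sp$train), 45)
  expect_equal(length(sp$val), 5)
  expect_equal(unname(inventory(sp$train)$per_class_counts), rep(9L, 5))
  # partition: union is everything, intersection empty
  expect_setequal(c(sp$train$paths, sp$val$paths), ds$paths)
  expect_length(intersect(sp$train$paths, sp$val$paths), 0)
  # determinism and seed sensitivity
  sp2 <- stratified_split(ds, 0.9, seed = 7)
  expect_identical(sp$train$paths, sp2$train$paths)
  sp3 <- stratified_split(ds, 0.9, seed = 8)
  expect_false(identical(sp$train$paths, sp3$train$paths))
  expect_equal(unname(inventory(sp3$train)$per_class_counts), rep(9L, 5))
  # class with < 2 records errors
  tiny <- image_dataset(c(0L, 1L, 1L), paths = c("a", "b", "c"))
  expect_error(stratified_split(tiny), "at least 2")
})

test_that("grouped split keeps groups intact", {
  ds <- image_dataset(rep(0:1, each = 20), paths = sprintf("p%02d", 1:40),
                      group_id = rep(1:8, each = 5))
  sp <- stratified_split(ds, 0.75, seed = 1, grouped = TRUE)
  tg <- unique(ds$group_id[ds$paths %in% sp$train$paths])
  vg <- unique(ds$group_id[ds$paths %in% sp$val$paths])
  expect_length(intersect(tg, vg), 0)
})

test_that("training augmentation yields standardized crops of the right size", {
  set.seed(40)
  img <- array(runif(256 * 300 * 3), c(256, 300, 3))
  out <- augment_train(img, crop_size = 224, resize_to = 256)
  expect_equal(dim(out), c(224, 224, 3))
  # degenerate configuration is deterministic
  o1 <- augment_eval(img, crop_size = 224, resize_to = 256)
  o2 <- augment_eval(img, crop_size = 224, resize_to = 256)
  expect_identical(o1, o2)
  # center crop of a 256x256 image spans rows/cols 16..239 (0-based)
  img2 <- array(0, c(256, 256, 3))
  img2[17, 17, 1] <- 1  # 0-based row 16
  ce <- augment_eval(img2, crop_size = 224, resize_to = NULL,
                     stats = list(mean = rep(0, 3), sd = rep(1, 3)))
  expect_equal(ce[1, 1, 1], 1)
  expect_error(augment_train(array(0, c(32, 32, 3)), crop_size = 224,
                             resize_to = NULL), "smaller than crop")
})

test_that("standardization with split statistics centers the training set", {
  ds <- tiny_synth(n_per_class = 6L, size = 48L, noise = 0.05, seed = 3L)
  stats <- compute_norm_stats(ds)
  px <- do.call(rbind, lapply(seq_len(length(ds)), function(i) {
    t <- augment_eval(get_image(ds, i), crop_size = 48, resize_to = NULL,
                      stats = stats)
    matrix(t, ncol = 3)
  }))
  expect_true(all(abs(colMeans(px)) < 0.05))
  expect_true(all(abs(apply(px, 2, sd) - 1) < 0.05))
})

test_that("synthetic generator is seeded, scaled and separable at zero noise", {
  cfg <- synthetic_config(scale = 12)
  expect_equal(cfg$per_class_counts, c(196L, 65L, 211L, 34L, 77L))
  # identical seeds give pixel-identical datasets
  a <- generate_synthetic_dataset(synthetic_config(
    per_class_counts = rep(3L, 5), image_size = 32L, seed = 5L))
  b <- generate_synthetic_dataset(synthetic_config(
    per_class_counts = rep(3L, 5), image_size = 32L, seed = 5L))
  expect_identical(a$images, b$images)
  # 1-NN on mean color is perfect at noise_sd = 0
  ds <- tiny_synth(n_per_class = 8L, size = 32L, noise = 0)
  feats <- t(vapply(ds$images, mean_color, numeric(3)))
  pred <- vapply(seq_len(nrow(feats)), function(i) {
    d <- colSums((t(feats[-i, ]) - feats[i, ])^2)
    ds$labels[-i][which.min(d)]
  }, integer(1))
  expect_equal(pred, ds$labels)
})

test_that("class mean hue is monotone in the configured base hue", {
  ds <- tiny_synth(n_per_class = 4L, size = 32L, noise = 0)
  sig <- default_class_signal()
  hues <- vapply(0:4, function(k) {
    cols <- vapply(ds$images[ds$labels == k], mean_color, numeric(3))
    mean(apply(cols, 2, function(cc) grDevices::rgb2hsv(cc[1], cc[2], cc[3],
                                                        maxColorValue = 1)[1]))
  }, numeric(1))
  expect_equal(order(hues), order(sig$hue))
})

test_that("synthetic datasets write a valid image-folder layout", {
  out <- tempfile("synthout")
  ds <- generate_synthetic_dataset(
    synthetic_config(per_class_counts = c(2L, 1L, 0L, 1L, 2L),
                     image_size = 24L, seed = 2L), dir = out)
  expect_true(dir.exists(file.path(out, "2")))   # zero-count class dir exists
  expect_equal(length(list.files(file.path(out, "0"))), 2)
  re <- load_image_folder(out)
  expect_equal(unname(inventory(re)$per_class_counts), c(2L, 1L, 1L, 2L))
  # written pixels survive the PNG round trip to 8-bit precision
  img <- read_image(re$paths[1])
  expect_equal(img, ds$images[[1]], tolerance = 1 / 255)
  unlink(out, recursive = TRUE)
})
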