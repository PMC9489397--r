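# Network assembly, prediction contract, determinism, checkpoints.

test_that("build_model produces 5 logits and accepts /32 input sizes", {
  set.seed(30)
  m <- build_model(model_config_small())
  x <- array(rnorm(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  r <- shufflecerv:::model_forward(m, x)
  expect_equal(dim(r$logits), c(5, 2))
  x96 <- array(rnorm(96 * 96 * 3), c(96, 96, 3, 1))
  expect_equal(dim(shufflecerv:::model_forward(m, x96)$logits), c(5, 1))
})

test_that("attention builds differ from the baseline only by attention layers", {
  set.seed(31)
  s0 <- model_structure(build_model(model_config_small()))
  sse <- model_structure(build_model(model_config_small(attention_config("se"))))
  extra <- setdiff(sse$path, s0$path)
  expect_true(length(extra) > 0)
  expect_true(all(grepl("attn", extra)))
  expect_setequal(setdiff(s0$path, sse$path), character(0))
})

test_that("forward pass is deterministic in eval mode", {
  set.seed(32)
  m <- build_model(model_config_small())
  x <- array(rnorm(64 * 64 * 3), c(64, 64, 3, 1))
  r1 <- shufflecerv:::model_forward(m, x)$logits
  r2 <- shufflecerv:::model_forward(m, x)$logits
  expect_identical(r1, r2)
  # identical seed, identical build
  set.seed(99); m1 <- build_model(model_config_small())
  set.seed(99); m2 <- build_model(model_config_small())
  expect_equal(shufflecerv:::model_forward(m1, x)$logits,
               shufflecerv:::model_forward(m2, x)$logits)
})

test_that("predict_batch yields normalized probabilities and argmax classes", {
  set.seed(33)
  m <- build_model(model_config_small())
  x <- array(rnorm(64 * 64 * 3 * 4), c(64, 64, 3, 4))
  p <- predict_batch(m, x)
  expect_equal(rowSums(p$prob), rep(1, 4), tolerance = 1e-5)
  # argmax agrees with a brute-force scan of the logits
  for (i in 1:4) {
    best <- 0; bi <- 1
    for (j in seq_len(ncol(p$logits)))
      if (p$logits[i, j] > p$logits[i, bi]) bi <- j
    expect_equal(p$class[i], bi - 1L)
  }
  # uniform logits: probabilities 1/K, tie broken to class 0
  P <- shufflecerv:::softmax_rows(matrix(0, 5, 3))
  expect_equal(P, matrix(0.2, 5, 3))
  expect_equal(apply(matrix(0, 5, 3), 2, which.max) - 1L, rep(0L, 3))
})

test_that("parameter ordering: attention variants exceed the baseline", {
  set.seed(34)
  p0 <- model_params(build_model(model_config_small()))
  pse <- model_params(build_model(model_config_small(attention_config("se"))))
  psk <- model_params(build_model(model_config_small(attention_config("sk"))))
  expect_gt(pse, p0)
  expect_gt(psk, p0)
})

test_that("checkpoints round-trip with embedded config metadata", {
  set.seed(35)
  m <- build_model(model_config_small())
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  x <- array(rnorm(64 * 64 * 3), c(64, 64, 3, 1))
  expect_equal(shufflecerv:::model_forward(m, x)$logits,
               shufflecerv:::model_forward(m2, x)$logits)
  raw <- readRDS(path)
  cfg <- jsonlite::fromJSON(raw$config_json)
  expect_equal(cfg$num_classes, 5)
  unlink(path)
})

test_that("invalid configurations are rejected", {
  expect_error(model_config(num_classes = 1), "num_classes")
  expect_error(model_config(stage_repeats = c(2, 2),
                            stage_channels = c(48, 96, 192)), "equal length")
  expect_error(block_spec(8, 16, stride = 1), "channels_out")
})
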