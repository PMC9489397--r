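# Building blocks: channel split/shuffle, depthwise separable convolution,
# SE and SK attention, inverted residual units.

test_that("channel split follows the floor rule and round-trips exactly", {
  set.seed(1)
  x4 <- array(rnorm(3 * 3 * 4 * 2), c(3, 3, 4, 2))
  sp <- channel_split(x4)
  expect_equal(dim(sp$x1)[3], 2)
  expect_equal(sp$x1, x4[, , 1:2, , drop = FALSE])
  expect_identical(channel_concat(sp$x1, sp$x2), x4)

  # odd channel count: floor puts 2 in the first part, 3 in the second
  x5 <- array(rnorm(2 * 2 * 5), c(2, 2, 5))
  sp5 <- channel_split(x5)
  expect_equal(dim(sp5$x1)[3], 2)
  expect_equal(dim(sp5$x2)[3], 3)
  expect_identical(channel_concat(sp5$x1, sp5$x2), x5)

  expect_error(channel_split(array(0, c(2, 2, 1))), "channel count")
})

test_that("channel shuffle matches the reshape-transpose index map", {
  # brute-force oracle: reshape 0:(C-1) to (G, n) row-major, transpose,
  # flatten row-major — equivalently read the (G, n) fill by columns
  shuffle_oracle <- function(C, G)
    as.vector(matrix(0:(C - 1), nrow = G, byrow = TRUE))

  x <- array(0, c(1, 1, 4, 1)); x[1, 1, , 1] <- 0:3
  expect_equal(as.vector(channel_shuffle(x, 2)), c(0, 2, 1, 3))
  expect_equal(as.vector(channel_shuffle(x, 2)), shuffle_oracle(4, 2))

  for (C in c(6, 8, 12, 30)) {
    for (G in which(C %% seq_len(C) == 0)) {
      xi <- array(0:(C - 1), c(1, 1, C, 1))
      expect_equal(as.vector(channel_shuffle(xi, G)), shuffle_oracle(C, G))
    }
  }
  # G = 1 identity; inverse shuffle restores random tensors
  set.seed(2)
  y <- array(rnorm(4 * 5 * 12 * 2), c(4, 5, 12, 2))
  expect_identical(channel_shuffle(y, 1), y)
  for (G in c(2, 3, 4, 6))
    expect_identical(channel_shuffle(channel_shuffle(y, G), 12 / G), y)
  expect_error(channel_shuffle(y, 5), "divisible")
})

test_that("depthwise separable convolution matches hand convolution", {
  # identity kernels reproduce the input
  x <- array(2.5, c(1, 1, 1))
  expect_equal(dws_conv(x, array(1, c(1, 1, 1)), matrix(1, 1, 1)), x)

  # all-ones 3x3 depthwise kernel on a constant map: center value 9c
  xc <- array(3, c(3, 3, 1))
  y <- depthwise_conv(xc, array(1, c(3, 3, 1)))
  expect_equal(y[2, 2, 1], 9 * 3)
  expect_equal(y[1, 1, 1], 4 * 3)   # corner sees 4 taps under zero padding

  # random case against the naive loop oracle, both stages
  set.seed(3)
  x <- array(rnorm(5 * 4 * 3), c(5, 4, 3))
  wd <- array(rnorm(3 * 3 * 3), c(3, 3, 3))
  wp <- matrix(rnorm(3 * 2), 3, 2)
  mid <- array(0, c(5, 4, 3))
  for (c in 1:3)
    mid[, , c] <- naive_conv(x[, , c, drop = FALSE],
                             array(wd[, , c], c(3, 3, 1, 1)))
  ref <- array(0, c(5, 4, 2))
  for (co in 1:2) ref[, , co] <- mid[, , 1] * wp[1, co] +
    mid[, , 2] * wp[2, co] + mid[, , 3] * wp[3, co]
  expect_equal(dws_conv(x, wd, wp), ref, tolerance = 1e-12)

  expect_error(dws_conv(x, array(0, c(3, 3, 4)), wp), "channel mismatch")
})

test_that("standard convolution agrees with the naive loop oracle", {
  set.seed(4)
  x <- array(rnorm(6 * 5 * 2), c(6, 5, 2))
  w <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  for (s in 1:2)
    expect_equal(conv2d(x, w, stride = s), naive_conv(x, w, stride = s),
                 tolerance = 1e-12)
  for (dl in 1:2)
    expect_equal(conv2d(x, w, dilation = dl),
                 naive_conv(x, w, dilation = dl), tolerance = 1e-12)
})

test_that("se_squeeze is the global average pool", {
  # constant map
  expect_equal(se_squeeze(array(7, c(3, 4, 2))), c(7, 7))
  # hand mean
  x <- array(c(1, 2, 3, 4), c(2, 2, 1))
  expect_equal(se_squeeze(x), 2.5)
  # double-loop oracle on random 5x7 maps
  set.seed(5)
  U <- array(rnorm(5 * 7 * 6), c(5, 7, 6))
  z <- numeric(6)
  for (c in 1:6) {
    s <- 0
    for (i in 1:5) for (j in 1:7) s <- s + U[i, j, c]
    z[c] <- s / (5 * 7)
  }
  expect_equal(se_squeeze(U), z, tolerance = 1e-6)
  # batch form
  Ub <- array(rnorm(3 * 3 * 2 * 4), c(3, 3, 2, 4))
  zb <- se_squeeze(Ub)
  expect_equal(dim(zb), c(2, 4))
  expect_equal(zb[1, 2], mean(Ub[, , 1, 2]))
})

test_that("se_excite produces gates strictly inside (0, 1)", {
  # zero weights: sigmoid(0) = 0.5 for every channel
  expect_equal(se_excite(c(1, -2, 3)), rep(0.5, 3))
  # generic weights: open interval
  set.seed(6)
  w <- se_weights(8, 4)
  s <- se_excite(rnorm(8), weights = w)
  expect_true(all(s > 0 & s < 1))
  # nonzero sensitivity to the input (finite difference)
  z <- rnorm(8)
  eps <- 1e-6
  d <- (se_excite(z + eps * (seq_len(8) == 1), weights = w) -
        se_excite(z - eps * (seq_len(8) == 1), weights = w)) / (2 * eps)
  expect_gt(max(abs(d)), 0)
})

test_that("se_apply gates channels and contracts magnitudes", {
  set.seed(7)
  U <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  expect_equal(se_apply(U, gates = rep(1, 3)), U)
  expect_equal(se_apply(U, gates = rep(0, 3)), U * 0)
  w <- se_weights(3, 2)
  Y <- se_apply(U, weights = w)
  expect_equal(dim(Y), dim(U))
  expect_true(all(abs(Y) <= abs(U) + 1e-12))
})

test_that("sk_apply selects and mixes dilation branches", {
  set.seed(8)
  U <- array(rnorm(6 * 6 * 4 * 2), c(6, 6, 4, 2))
  w <- sk_weights(4, 2)
  # degenerate selection: weight (1, 0) returns branch 1 exactly
  b1 <- pointwise_conv(depthwise_conv(U, w$dw1, 1, 1), w$pw1)
  y1 <- sk_apply(U, weights = w,
                 branch_weights = list(rep(1, 4), rep(0, 4)))
  expect_equal(y1, b1, tolerance = 1e-12)
  # shape contract
  y <- sk_apply(U, weights = w)
  expect_equal(dim(y), dim(U))
  # softmax normalization: recompute the weights and verify they sum to 1
  att <- attention_config("sk", 2)
  fused <- b1 + pointwise_conv(depthwise_conv(U, w$dw2, 1, 2), w$pw2)
  z <- se_squeeze(fused)
  a <- pmax(w$Wz %*% z + w$bz, 0)
  w1 <- plogis((w$Wa %*% a + w$ba) - (w$Wb %*% a + w$bb))
  expect_true(all(w1 > 0 & w1 < 1))
  expect_equal(w1 + (1 - w1), matrix(1, 4, 2))
})

test_that("stride-1 units preserve shape and keep an exact identity branch", {
  set.seed(9)
  for (kind in c("none", "se", "sk")) {
    spec <- block_spec(8, 8, stride = 1,
                       attention = attention_config(kind, 4))
    u <- shuffle_unit(spec)
    x <- array(rnorm(6 * 6 * 8 * 2), c(6, 6, 8, 2))
    y <- unit_forward(u, x)
    expect_equal(dim(y), dim(x))
    # undo the shuffle: the first half of the concat is the untouched x1
    p <- shufflecerv:::shuffle_perm(8, 2)
    y0 <- y[, , order(p), , drop = FALSE]
    expect_identical(y0[, , 1:4, , drop = FALSE],
                     x[, , 1:4, , drop = FALSE])
  }
  expect_error(inverted_residual_unit(array(0, c(4, 4, 8)),
                                      block_spec(8, 16, stride = 2)),
               "stride")
})

test_that("downsampling units halve spatial dims and set channels_out", {
  set.seed(10)
  spec <- block_spec(8, 24, stride = 2)
  x <- array(rnorm(7 * 9 * 8), c(7, 9, 8))
  y <- downsample_unit(x, spec)
  expect_equal(dim(y), c(4, 5, 24))       # ceil(7/2), ceil(9/2)
  x2 <- array(rnorm(224 * 224 * 8), c(224, 224, 8))
  expect_equal(dim(downsample_unit(x2, spec))[1:2], c(112, 112))
})

test_that("attention-fused units add exactly the attention parameters", {
  set.seed(11)
  mk <- function(kind) shuffle_unit(
    block_spec(16, 16, stride = 1, attention = attention_config(kind, 4)))
  p0 <- shufflecerv:::count_params(mk("none"))
  pse <- shufflecerv:::count_params(mk("se"))
  psk <- shufflecerv:::count_params(mk("sk"))
  expect_gt(pse, p0)
  expect_gt(psk, p0)
  # SE excess is the closed-form excitation count on the branch width (C/2)
  expect_equal(pse - p0, se_param_count(8, 4))
})

test_that("pinned attention reproduces the plain unit's forward output", {
  set.seed(12)
  u0 <- shuffle_unit(block_spec(8, 8, stride = 1))
  use <- shuffle_unit(block_spec(8, 8, stride = 1,
                                 attention = attention_config("se", 4)))
  # copy the shared weights, then pin the SE gates to 1 by forcing the
  # excitation output to saturate: sigmoid(large bias) -> 1
  use$children[names(u0$children)] <- u0$children
  use$children$attn$params$W1[] <- 0
  use$children$attn$params$W2[] <- 0
  use$children$attn$params$b2[] <- 1e4
  x <- array(rnorm(6 * 6 * 8 * 2), c(6, 6, 8, 2))
  expect_equal(unit_forward(use, x), unit_forward(u0, x), tolerance = 1e-9)
})
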