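# Functional tensor operations on feature maps.
#
# A feature map is a numeric array with dim (H, W, C) for a single image or
# (H, W, C, N) for a batch; the channel axis is always the third.

as_batch <- function(x) {
  d <- dim(x)
  if (is.null(d) || !length(d) %in% c(3L, 4L))
    stop("feature maps must be 3-d (H,W,C) or 4-d (H,W,C,N) arrays")
  if (length(d) == 3L) {
    dim(x) <- c(d, 1L)
    attr(x, "was_3d") <- TRUE
  }
  x
}

un_batch <- function(y, was_3d) {
  if (isTRUE(was_3d)) {
    d <- dim(y)
    dim(y) <- d[1:3]
  }
  y
}

# (H,W,C,N) -> (H*W*N) x C matrix and back; channel-major matrix layout used
# by the pointwise convolution and batch-norm internals.
fmap_to_mat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1L, 2L, 4L, 3L)), ncol = d[3L])
}

mat_to_fmap <- function(m, H, W, N) {
  aperm(array(m, c(H, W, N, ncol(m))), c(1L, 2L, 4L, 3L))
}

#' Split a feature map along the channel axis
#'
#' Divides the input into two channel batches `x1` (the first
#' `floor(C * fractions[1])` channels) and `x2` (the remainder), as done at
#' the entry of every stride-1 inverted residual unit.  Concatenating the two
#' parts with [channel_concat()] restores the input exactly.
#'
#' @param x Feature map, `(H, W, C)` or `(H, W, C, N)` array with `C >= 2`.
#' @param fractions Two positive fractions summing to 1; default an even split.
#' @return List with elements `x1` and `x2`.
#' @export
channel_split <- function(x, fractions = c(0.5, 0.5)) {
  xb <- as_batch(x)
  was3 <- isTRUE(attr(xb, "was_3d"))
  C <- dim(xb)[3L]
  if (C < 2L) stop("channel_split: channel count must be >= 2")
  if (length(fractions) != 2L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("channel_split: fractions must be two positives summing to 1")
  n1 <- as.integer(floor(C * fractions[1L]))
  n1 <- max(min(n1, C - 1L), 1L)
  x1 <- xb[, , seq_len(n1), , drop = FALSE]
  x2 <- xb[, , (n1 + 1L):C, , drop = FALSE]
  list(x1 = un_batch(x1, was3), x2 = un_batch(x2, was3))
}

#' Concatenate two feature maps along the channel axis
#'
#' @param x1,x2 Feature maps agreeing in all non-channel dims.
#' @return The channel-concatenated feature map.
#' @export
channel_concat <- function(x1, x2) {
  a <- as_batch(x1); b <- as_batch(x2)
  was3 <- isTRUE(attr(a, "was_3d"))
  da <- dim(a); db <- dim(b)
  if (!all(da[c(1L, 2L, 4L)] == db[c(1L, 2L, 4L)]))
    stop("channel_concat: non-channel dims must agree")
  out <- array(0, c(da[1L], da[2L], da[3L] + db[3L], da[4L]))
  out[, , seq_len(da[3L]), ] <- a
  out[, , da[3L] + seq_len(db[3L]), ] <- b
  un_batch(out, was3)
}

shuffle_perm <- function(C, groups) {
  # output position i*G+g takes input channel g*n+i (0-based), n = C/G;
  # i.e. reshape to (n, G) read as (G, n): the group-transposing permutation
  n <- C %/% groups
  p <- integer(C)
  for (pos in 0:(C - 1L)) {
    g <- pos %% groups
    i <- pos %/% groups
    p[pos + 1L] <- g * n + i + 1L
  }
  p
}

#' Channel shuffle
#'
#' The deterministic channel permutation that mixes information across `G`
#' channel groups: the channel axis is reshaped to `(G, n)`, transposed to
#' `(n, G)` and flattened.  Spatial content is untouched.  Shuffling with
#' `C / G` groups inverts a shuffle with `G` groups.
#'
#' @param x Feature map whose channel count is divisible by `groups`.
#' @param groups Positive integer number of groups `G`.
#' @return Feature map with permuted channels.
#' @export
channel_shuffle <- function(x, groups) {
  xb <- as_batch(x)
  was3 <- isTRUE(attr(xb, "was_3d"))
  C <- dim(xb)[3L]
  groups <- as.integer(groups)
  if (groups < 1L || C %% groups != 0L)
    stop("channel_shuffle: channel count must be divisible by groups")
  y <- xb[, , shuffle_perm(C, groups), , drop = FALSE]
  un_batch(y, was3)
}

#' Standard 2-d convolution (same padding)
#'
#' Dense cross-channel convolution used for the stem and as a reference
#' operation.  Padding is `dilation * (K - 1) / 2` per side so output spatial
#' dims are `ceiling(dim / stride)`.
#'
#' @param x Feature map.
#' @param w Kernel array `(K, K, C_in, C_out)`.
#' @param stride,dilation Integers.
#' @return Feature map with `C_out` channels.
#' @export
conv2d <- function(x, w, stride = 1L, dilation = 1L) {
  xb <- as_batch(x)
  was3 <- isTRUE(attr(xb, "was_3d"))
  d <- dim(xb); wd <- dim(w)
  if (length(wd) != 4L || wd[1L] != wd[2L])
    stop("conv2d: w must be a (K, K, C_in, C_out) array")
  if (d[3L] != wd[3L]) stop("conv2d: channel mismatch")
  K <- wd[1L]
  cols <- im2col_cpp(xb, K, as.integer(stride), as.integer(dilation))
  ym <- cols %*% matrix(w, K * K * wd[3L], wd[4L])
  Ho <- ceiling(d[1L] / stride); Wo <- ceiling(d[2L] / stride)
  y <- aperm(array(ym, c(Ho, Wo, d[4L], wd[4L])), c(1L, 2L, 4L, 3L))
  un_batch(y, was3)
}

#' Depthwise convolution (same padding)
#'
#' Each channel is convolved independently with its own `K x K` kernel.
#'
#' @param x Feature map with `C` channels.
#' @param w Kernel array `(K, K, C)`.
#' @param stride,dilation Integers.
#' @return Feature map, same channel count, spatial dims `ceiling(dim/stride)`.
#' @export
depthwise_conv <- function(x, w, stride = 1L, dilation = 1L) {
  xb <- as_batch(x)
  was3 <- isTRUE(attr(xb, "was_3d"))
  wd <- dim(w)
  if (length(wd) != 3L || wd[1L] != wd[2L])
    stop("depthwise_conv: w must be a (K, K, C) array")
  if (dim(xb)[3L] != wd[3L]) stop("depthwise_conv: channel mismatch")
  y <- dw_conv_fwd_cpp(xb, w, as.integer(stride), as.integer(dilation))
  un_batch(y, was3)
}

#' Pointwise (1 x 1) convolution
#'
#' @param x Feature map with `C_in` channels.
#' @param w Weight matrix `(C_in, C_out)`.
#' @return Feature map with `C_out` channels.
#' @export
pointwise_conv <- function(x, w) {
  xb <- as_batch(x)
  was3 <- isTRUE(attr(xb, "was_3d"))
  d <- dim(xb)
  if (!is.matrix(w) || nrow(w) != d[3L])
    stop("pointwise_conv: w must be a (C_in, C_out) matrix")
  ym <- fmap_to_mat(xb) %*% w
  un_batch(mat_to_fmap(ym, d[1L], d[2L], d[4L]), was3)
}

#' Depthwise separable convolution
#'
#' A per-channel depthwise stage followed by a 1x1 pointwise stage — the
#' factorization whose multiplication cost is
#' `W*H*C_in*N^2 + W*H*C_in*C_out` against `W*H*C_in*C_out*N^2` for the
#' dense convolution (see [dws_mults()], [conv_mults()]).
#'
#' @param x Feature map with `C_in` channels.
#' @param dw_kernel Depthwise kernels `(N, N, C_in)`.
#' @param pw_kernel Pointwise weights `(C_in, C_out)`.
#' @param stride,dilation Depthwise-stage stride and dilation.
#' @return Feature map with `C_out` channels.
#' @export
dws_conv <- function(x, dw_kernel, pw_kernel, stride = 1L, dilation = 1L) {
  mid <- depthwise_conv(x, dw_kernel, stride = stride, dilation = dilation)
  pointwise_conv(mid, pw_kernel)
}

#' Squeeze: global average pooling to a channel descriptor
#'
#' `z_c = mean(U_c)` over all spatial positions, per channel.
#'
#' @param U Feature map.
#' @return For 3-d input, a numeric vector of length `C`; for a batch, a
#'   `C x N` matrix.
#' @export
se_squeeze <- function(U) {
  Ub <- as_batch(U)
  was3 <- isTRUE(attr(Ub, "was_3d"))
  d <- dim(Ub)
  z <- matrix(colMeans(matrix(Ub, nrow = d[1L] * d[2L])), d[3L], d[4L])
  if (was3) drop(z) else z
}

#' Initialize excitation weights
#'
#' Two linear maps with a ReLU between and a sigmoid after, bottleneck width
#' `max(ceiling(C / r), 1)`.  With `init = "zero"` the gates are 0.5
#' everywhere; `init = "random"` draws scaled-normal weights from the current
#' RNG state.
#'
#' @param channels Channel count C.
#' @param reduction_ratio Bottleneck divisor r.
#' @param init `"zero"` or `"random"`.
#' @return List with `W1 (h x C)`, `b1`, `W2 (C x h)`, `b2`.
#' @export
se_weights <- function(channels, reduction_ratio = 16L,
                       init = c("random", "zero")) {
  init <- match.arg(init)
  h <- bottleneck_width(channels, reduction_ratio)
  if (init == "zero") {
    list(W1 = matrix(0, h, channels), b1 = numeric(h),
         W2 = matrix(0, channels, h), b2 = numeric(channels))
  } else {
    list(W1 = matrix(rnorm(h * channels, sd = sqrt(2 / channels)), h, channels),
         b1 = numeric(h),
         W2 = matrix(rnorm(channels * h, sd = sqrt(2 / h)), channels, h),
         b2 = numeric(channels))
  }
}

#' Excitation: channel gates from a squeezed descriptor
#'
#' `s = sigmoid(W2 %*% relu(W1 %*% z + b1) + b2)`; every gate lies strictly
#' in (0, 1).
#'
#' @param z Channel vector (length C) or `C x N` matrix from [se_squeeze()].
#' @param reduction_ratio Bottleneck divisor used when `weights` is `NULL`.
#' @param weights Excitation weights as from [se_weights()]; when `NULL`,
#'   zero weights are used (all gates 0.5).
#' @return Gates with the shape of `z`.
#' @export
se_excite <- function(z, reduction_ratio = 16L, weights = NULL) {
  zm <- if (is.matrix(z)) z else matrix(z, ncol = 1L)
  C <- nrow(zm)
  if (is.null(weights)) weights <- se_weights(C, reduction_ratio, init = "zero")
  a <- pmax(weights$W1 %*% zm + weights$b1, 0)
  s <- plogis(weights$W2 %*% a + weights$b2)
  if (is.matrix(z)) s else drop(s)
}

#' Apply squeeze-and-excitation channel attention
#'
#' Computes channel gates by global average pooling plus the excitation
#' bottleneck and rescales each channel of `U` by its gate.  Because gates
#' lie in (0, 1), the output never exceeds the input in per-channel
#' magnitude.
#'
#' @param U Feature map.
#' @param attention An [attention_config()] with `kind = "se"`.
#' @param weights Optional excitation weights ([se_weights()]).
#' @param gates Optional explicit gates (length C or `C x N`), overriding the
#'   computed ones — e.g. pin to 1 for an identity check.
#' @return Feature map of the same shape as `U`.
#' @export
se_apply <- function(U, attention = attention_config("se"),
                     weights = NULL, gates = NULL) {
  if (attention$kind != "se") stop("se_apply: attention kind must be 'se'")
  Ub <- as_batch(U)
  was3 <- isTRUE(attr(Ub, "was_3d"))
  d <- dim(Ub)
  if (is.null(gates)) {
    z <- matrix(colMeans(matrix(Ub, nrow = d[1L] * d[2L])), d[3L], d[4L])
    gates <- se_excite(z, attention$reduction_ratio, weights)
  }
  g <- if (is.matrix(gates)) gates else matrix(gates, d[3L], d[4L])
  y <- Ub * rep(as.vector(g), each = d[1L] * d[2L])
  dim(y) <- d
  un_batch(y, was3)
}

#' Initialize selective-kernel attention weights
#'
#' Two depthwise-separable 3x3 branches (dilation 1 and 2), a shared
#' squeeze bottleneck, and one linear head per branch.
#'
#' @param channels Channel count C.
#' @param reduction_ratio Bottleneck divisor r.
#' @param init `"zero"` or `"random"` (current RNG state).
#' @return Named list of branch kernels and attention weights.
#' @export
sk_weights <- function(channels, reduction_ratio = 16L,
                       init = c("random", "zero")) {
  init <- match.arg(init)
  h <- bottleneck_width(channels, reduction_ratio)
  C <- channels
  mk <- function(dims, fan_in) {
    if (init == "zero") array(0, dims)
    else array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
  }
  list(dw1 = mk(c(3L, 3L, C), 9), pw1 = matrix(mk(c(C, C), C), C, C),
       dw2 = mk(c(3L, 3L, C), 9), pw2 = matrix(mk(c(C, C), C), C, C),
       Wz = matrix(mk(c(h, C), C), h, C), bz = numeric(h),
       Wa = matrix(mk(c(C, h), h), C, h), ba = numeric(C),
       Wb = matrix(mk(c(C, h), h), C, h), bb = numeric(C))
}

#' Apply selective-kernel attention
#'
#' Two depthwise-separable 3x3 branches at dilation 1 and 2 (same padding so
#' both keep spatial dims) are summed, squeezed by global average pooling,
#' passed through the shared bottleneck, and per-branch channel weights are
#' produced.  Under the default softmax normalization the two weights sum to
#' 1 per channel; under `"sigmoid"` they are independent gates.  The output
#' is the weighted sum of the branches.
#'
#' @param U Feature map.
#' @param attention An [attention_config()] with `kind = "sk"`.
#' @param weights Optional weights ([sk_weights()]).
#' @param branch_weights Optional explicit pair of gate matrices
#'   `list(w1, w2)` (each C x N or length C), overriding the computed ones.
#' @return Feature map of the same shape as `U`.
#' @export
sk_apply <- function(U, attention = attention_config("sk"),
                     weights = NULL, branch_weights = NULL) {
  if (attention$kind != "sk") stop("sk_apply: attention kind must be 'sk'")
  Ub <- as_batch(U)
  was3 <- isTRUE(attr(Ub, "was_3d"))
  d <- dim(Ub)
  K <- 3L
  if (d[1L] < 1L || d[2L] < 1L)
    stop("sk_apply: spatial dims too small")
  C <- d[3L]
  if (is.null(weights)) weights <- sk_weights(C, attention$reduction_ratio)
  b1 <- pointwise_conv(depthwise_conv(Ub, weights$dw1, 1L, 1L), weights$pw1)
  b2 <- pointwise_conv(depthwise_conv(Ub, weights$dw2, 1L, 2L), weights$pw2)
  if (is.null(branch_weights)) {
    fused <- b1 + b2
    z <- matrix(colMeans(matrix(fused, nrow = d[1L] * d[2L])), C, d[4L])
    a <- pmax(weights$Wz %*% z + weights$bz, 0)
    e1 <- weights$Wa %*% a + weights$ba
    e2 <- weights$Wb %*% a + weights$bb
    if (attention$sk_norm == "softmax") {
      w1 <- plogis(e1 - e2); w2 <- 1 - w1
    } else {
      w1 <- plogis(e1); w2 <- plogis(e2)
    }
  } else {
    w1 <- branch_weights[[1L]]; w2 <- branch_weights[[2L]]
    if (!is.matrix(w1)) w1 <- matrix(w1, C, d[4L])
    if (!is.matrix(w2)) w2 <- matrix(w2, C, d[4L])
  }
  hw <- d[1L] * d[2L]
  y <- b1 * rep(as.vector(w1), each = hw) + b2 * rep(as.vector(w2), each = hw)
  dim(y) <- d
  un_batch(y, was3)
}
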