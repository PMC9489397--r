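# Trainable layer framework.
#
# A layer is a list(type, name, conf, params, buffers, children).  Forward
# passes return list(y, cache, layer) — the layer comes back because batch
# norm updates its running statistics in training mode.  Backward passes
# return list(dx, grads) where grads mirrors the layer's params/children
# structure.  Feature maps are (H, W, C, N) arrays throughout; the head
# operates on C x N matrices.

new_layer <- function(type, name, conf = list(), params = NULL,
                      buffers = NULL, children = NULL) {
  structure(list(type = type, name = name, conf = conf, params = params,
                 buffers = buffers, children = children),
            class = "scx_layer")
}

kaiming <- function(dims, fan_in) {
  array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

layer_conv <- function(name, K, cin, cout, stride = 1L, dilation = 1L) {
  new_layer("conv", name,
            conf = list(K = K, cin = cin, cout = cout,
                        stride = as.integer(stride),
                        dilation = as.integer(dilation)),
            params = list(W = kaiming(c(K, K, cin, cout), K * K * cin)))
}

layer_pw <- function(name, cin, cout) {
  new_layer("pw", name, conf = list(cin = cin, cout = cout),
            params = list(W = matrix(kaiming(c(cin, cout), cin), cin, cout)))
}

layer_dw <- function(name, K, C, stride = 1L, dilation = 1L) {
  new_layer("dw", name,
            conf = list(K = K, C = C, stride = as.integer(stride),
                        dilation = as.integer(dilation)),
            params = list(W = kaiming(c(K, K, C), K * K)))
}

layer_bn <- function(name, C, momentum = 0.1, eps = 1e-5) {
  new_layer("bn", name, conf = list(C = C, momentum = momentum, eps = eps),
            params = list(gamma = rep(1, C), beta = rep(0, C)),
            buffers = list(rm = rep(0, C), rv = rep(1, C)))
}

layer_relu <- function(name) new_layer("relu", name)

layer_maxpool <- function(name, K = 3L, stride = 2L) {
  new_layer("maxpool", name, conf = list(K = K, stride = as.integer(stride)))
}

layer_gap <- function(name) new_layer("gap", name)

layer_linear <- function(name, cin, cout) {
  new_layer("linear", name, conf = list(cin = cin, cout = cout),
            params = list(W = matrix(kaiming(c(cout, cin), cin), cout, cin),
                          b = numeric(cout)))
}

layer_shuffle <- function(name, groups = 2L) {
  new_layer("shuffle", name, conf = list(groups = as.integer(groups)))
}

layer_se <- function(name, C, reduction_ratio) {
  h <- bottleneck_width(C, reduction_ratio)
  new_layer("se", name, conf = list(C = C, h = h),
            params = list(W1 = matrix(kaiming(c(h, C), C), h, C),
                          b1 = numeric(h),
                          W2 = matrix(kaiming(c(C, h), h), C, h),
                          b2 = numeric(C)))
}

layer_sk <- function(name, C, reduction_ratio, sk_norm = "softmax") {
  h <- bottleneck_width(C, reduction_ratio)
  new_layer("sk", name, conf = list(C = C, h = h, norm = sk_norm),
            params = list(Wz = matrix(kaiming(c(h, C), C), h, C),
                          bz = numeric(h),
                          Wa = matrix(kaiming(c(C, h), h), C, h),
                          ba = numeric(C),
                          Wb = matrix(kaiming(c(C, h), h), C, h),
                          bb = numeric(C)),
            children = list(dw1 = layer_dw("dw1", 3L, C, 1L, 1L),
                            pw1 = layer_pw("pw1", C, C),
                            dw2 = layer_dw("dw2", 3L, C, 1L, 2L),
                            pw2 = layer_pw("pw2", C, C)))
}

attention_layer <- function(name, C, attention) {
  switch(attention$kind,
         none = NULL,
         se = layer_se(name, C, attention$reduction_ratio),
         sk = layer_sk(name, C, attention$reduction_ratio, attention$sk_norm))
}

# ---------------------------------------------------------------------------
# forward

ly_forward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    conv = {
      cf <- layer$conf
      d <- dim(x)
      if (d[3L] != cf$cin)
        stop(sprintf("layer %s: expected %d channels, got %d",
                     layer$name, cf$cin, d[3L]))
      cols <- im2col_cpp(x, cf$K, cf$stride, cf$dilation)
      ym <- cols %*% matrix(layer$params$W, cf$K * cf$K * cf$cin, cf$cout)
      Ho <- ceiling(d[1L] / cf$stride); Wo <- ceiling(d[2L] / cf$stride)
      y <- aperm(array(ym, c(Ho, Wo, d[4L], cf$cout)), c(1L, 2L, 4L, 3L))
      list(y = y, cache = list(cols = cols, d = d), layer = layer)
    },
    pw = {
      d <- dim(x)
      xm <- fmap_to_mat(x)
      ym <- xm %*% layer$params$W
      list(y = mat_to_fmap(ym, d[1L], d[2L], d[4L]),
           cache = list(xm = xm, d = d), layer = layer)
    },
    dw = {
      cf <- layer$conf
      y <- dw_conv_fwd_cpp(x, layer$params$W, cf$stride, cf$dilation)
      list(y = y, cache = list(x = x), layer = layer)
    },
    bn = {
      cf <- layer$conf
      d <- dim(x)
      hw <- d[1L] * d[2L]
      m <- hw * d[4L]
      if (training) {
        cs <- colMeans(matrix(x, nrow = hw))          # C*N channel means
        mu <- rowMeans(matrix(cs, d[3L], d[4L]))
        cs2 <- colMeans(matrix(x * x, nrow = hw))
        v <- rowMeans(matrix(cs2, d[3L], d[4L])) - mu^2
        v <- pmax(v, 0)
        layer$buffers$rm <- (1 - cf$momentum) * layer$buffers$rm + cf$momentum * mu
        layer$buffers$rv <- (1 - cf$momentum) * layer$buffers$rv + cf$momentum * v
      } else {
        mu <- layer$buffers$rm
        v <- layer$buffers$rv
      }
      invstd <- 1 / sqrt(v + cf$eps)
      bc <- function(vec) rep(rep(vec, each = hw), times = d[4L])
      xhat <- (x - bc(mu)) * bc(invstd)
      y <- xhat * bc(layer$params$gamma) + bc(layer$params$beta)
      dim(y) <- d
      list(y = y,
           cache = list(xhat = xhat, invstd = invstd, d = d,
                        training = training),
           layer = layer)
    },
    relu = {
      mask <- x > 0
      list(y = x * mask, cache = list(mask = mask), layer = layer)
    },
    maxpool = {
      cf <- layer$conf
      r <- maxpool_fwd_cpp(x, cf$K, cf$stride)
      list(y = r$y, cache = list(idx = r$idx, d = dim(x)), layer = layer)
    },
    gap = {
      d <- dim(x)
      z <- matrix(colMeans(matrix(x, nrow = d[1L] * d[2L])), d[3L], d[4L])
      list(y = z, cache = list(d = d), layer = layer)
    },
    linear = {
      y <- layer$params$W %*% x + layer$params$b
      list(y = y, cache = list(x = x), layer = layer)
    },
    shuffle = {
      C <- dim(x)[3L]
      p <- shuffle_perm(C, layer$conf$groups)
      list(y = x[, , p, , drop = FALSE], cache = list(p = p), layer = layer)
    },
    se = {
      d <- dim(x); hw <- d[1L] * d[2L]
      pr <- layer$params
      z <- matrix(colMeans(matrix(x, nrow = hw)), d[3L], d[4L])
      a <- pr$W1 %*% z + pr$b1
      ar <- pmax(a, 0)
      s <- plogis(pr$W2 %*% ar + pr$b2)
      y <- x * rep(as.vector(s), each = hw)
      dim(y) <- d
      list(y = y, cache = list(x = x, z = z, a = a, ar = ar, s = s, d = d),
           layer = layer)
    },
    sk = {
      ch <- layer$children
      pr <- layer$params
      f1 <- ly_forward(ch$dw1, x, training)
      g1 <- ly_forward(ch$pw1, f1$y, training)
      f2 <- ly_forward(ch$dw2, x, training)
      g2 <- ly_forward(ch$pw2, f2$y, training)
      b1 <- g1$y; b2 <- g2$y
      d <- dim(b1); hw <- d[1L] * d[2L]
      fused <- b1 + b2
      z <- matrix(colMeans(matrix(fused, nrow = hw)), d[3L], d[4L])
      a <- pr$Wz %*% z + pr$bz
      ar <- pmax(a, 0)
      e1 <- pr$Wa %*% ar + pr$ba
      e2 <- pr$Wb %*% ar + pr$bb
      if (layer$conf$norm == "softmax") {
        w1 <- plogis(e1 - e2); w2 <- 1 - w1
      } else {
        w1 <- plogis(e1); w2 <- plogis(e2)
      }
      y <- b1 * rep(as.vector(w1), each = hw) +
           b2 * rep(as.vector(w2), each = hw)
      dim(y) <- d
      list(y = y,
           cache = list(c1 = list(dw = f1$cache, pw = g1$cache),
                        c2 = list(dw = f2$cache, pw = g2$cache),
                        b1 = b1, b2 = b2, z = z, a = a, ar = ar,
                        w1 = w1, w2 = w2, d = d),
           layer = layer)
    },
    stop(sprintf("unsupported layer type '%s' (layer %s)",
                 layer$type, layer$name)))
}

# ---------------------------------------------------------------------------
# backward

ly_backward <- function(layer, cache, dy) {
  switch(layer$type,
    conv = {
      cf <- layer$conf
      d <- cache$d
      dym <- matrix(aperm(dy, c(1L, 2L, 4L, 3L)), ncol = cf$cout)
      Wm <- matrix(layer$params$W, cf$K * cf$K * cf$cin, cf$cout)
      dW <- crossprod(cache$cols, dym)
      dim(dW) <- c(cf$K, cf$K, cf$cin, cf$cout)
      dcols <- tcrossprod(dym, Wm)
      dx <- col2im_cpp(dcols, d[1L], d[2L], d[3L], d[4L],
                       cf$K, cf$stride, cf$dilation)
      list(dx = dx, grads = list(params = list(W = dW)))
    },
    pw = {
      d <- cache$d
      dym <- fmap_to_mat(dy)
      dW <- crossprod(cache$xm, dym)
      dxm <- tcrossprod(dym, layer$params$W)
      list(dx = mat_to_fmap(dxm, d[1L], d[2L], d[4L]),
           grads = list(params = list(W = dW)))
    },
    dw = {
      cf <- layer$conf
      r <- dw_conv_bwd_cpp(cache$x, layer$params$W, dy, cf$stride, cf$dilation)
      list(dx = r$dx, grads = list(params = list(W = r$dw)))
    },
    bn = {
      d <- cache$d; hw <- d[1L] * d[2L]; m <- hw * d[4L]
      bc <- function(vec) rep(rep(vec, each = hw), times = d[4L])
      chsum <- function(v) rowSums(matrix(colSums(matrix(v, nrow = hw)),
                                          d[3L], d[4L]))
      dgamma <- chsum(dy * cache$xhat)
      dbeta <- chsum(dy)
      g_is <- layer$params$gamma * cache$invstd
      if (cache$training) {
        dx <- bc(g_is) * (dy - bc(dbeta / m) - cache$xhat * bc(dgamma / m))
      } else {
        dx <- bc(g_is) * dy
      }
      dim(dx) <- d
      list(dx = dx,
           grads = list(params = list(gamma = dgamma, beta = dbeta)))
    },
    relu = list(dx = dy * cache$mask, grads = NULL),
    maxpool = {
      d <- cache$d
      dx <- maxpool_bwd_cpp(dy, cache$idx, d[1L], d[2L])
      list(dx = dx, grads = NULL)
    },
    gap = {
      d <- cache$d; hw <- d[1L] * d[2L]
      dx <- array(rep(as.vector(dy) / hw, each = hw), d)
      list(dx = dx, grads = NULL)
    },
    linear = {
      dW <- tcrossprod(dy, cache$x)
      db <- rowSums(dy)
      dx <- crossprod(layer$params$W, dy)
      list(dx = dx, grads = list(params = list(W = dW, b = db)))
    },
    shuffle = {
      invp <- order(cache$p)
      list(dx = dy[, , invp, , drop = FALSE], grads = NULL)
    },
    se = {
      pr <- layer$params
      d <- cache$d; hw <- d[1L] * d[2L]
      s <- cache$s
      ds <- matrix(colSums(matrix(dy * cache$x, nrow = hw)), d[3L], d[4L])
      dx <- dy * rep(as.vector(s), each = hw)
      dpre2 <- ds * s * (1 - s)
      dW2 <- tcrossprod(dpre2, cache$ar)
      db2 <- rowSums(dpre2)
      dar <- crossprod(pr$W2, dpre2)
      dpre1 <- dar * (cache$a > 0)
      dW1 <- tcrossprod(dpre1, cache$z)
      db1 <- rowSums(dpre1)
      dz <- crossprod(pr$W1, dpre1)
      dx <- dx + rep(as.vector(dz) / hw, each = hw)
      dim(dx) <- d
      list(dx = dx,
           grads = list(params = list(W1 = dW1, b1 = db1,
                                      W2 = dW2, b2 = db2)))
    },
    sk = {
      pr <- layer$params; ch <- layer$children
      d <- cache$d; hw <- d[1L] * d[2L]
      w1 <- cache$w1; w2 <- cache$w2
      dg1 <- matrix(colSums(matrix(dy * cache$b1, nrow = hw)), d[3L], d[4L])
      dg2 <- matrix(colSums(matrix(dy * cache$b2, nrow = hw)), d[3L], d[4L])
      if (layer$conf$norm == "softmax") {
        de1 <- (dg1 - dg2) * w1 * w2
        de2 <- -de1
      } else {
        de1 <- dg1 * w1 * (1 - w1)
        de2 <- dg2 * w2 * (1 - w2)
      }
      dWa <- tcrossprod(de1, cache$ar); dba <- rowSums(de1)
      dWb <- tcrossprod(de2, cache$ar); dbb <- rowSums(de2)
      dar <- crossprod(pr$Wa, de1) + crossprod(pr$Wb, de2)
      dpre <- dar * (cache$a > 0)
      dWz <- tcrossprod(dpre, cache$z); dbz <- rowSums(dpre)
      dz <- crossprod(pr$Wz, dpre)
      dfused <- rep(as.vector(dz) / hw, each = hw)
      db1 <- dy * rep(as.vector(w1), each = hw) + dfused
      db2 <- dy * rep(as.vector(w2), each = hw) + dfused
      dim(db1) <- d; dim(db2) <- d
      r1p <- ly_backward(ch$pw1, cache$c1$pw, db1)
      r1d <- ly_backward(ch$dw1, cache$c1$dw, r1p$dx)
      r2p <- ly_backward(ch$pw2, cache$c2$pw, db2)
      r2d <- ly_backward(ch$dw2, cache$c2$dw, r2p$dx)
      dx <- r1d$dx + r2d$dx
      list(dx = dx,
           grads = list(params = list(Wz = dWz, bz = dbz, Wa = dWa, ba = dba,
                                      Wb = dWb, bb = dbb),
                        children = list(dw1 = r1d$grads, pw1 = r1p$grads,
                                        dw2 = r2d$grads, pw2 = r2p$grads)))
    },
    stop(sprintf("unsupported layer type '%s' in backward (layer %s)",
                 layer$type, layer$name)))
}

# recursive parameter count
count_params <- function(layer) {
  n <- 0
  if (!is.null(layer$params))
    n <- n + sum(vapply(layer$params, length, numeric(1)))
  if (!is.null(layer$children))
    n <- n + sum(vapply(layer$children, count_params, numeric(1)))
  n
}
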