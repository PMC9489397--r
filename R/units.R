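# Inverted residual units: the stride-1 split unit and the stride-2
# downsampling unit, composed from the primitive layers.  The stride-1 unit
# splits channels in half, transforms one half (1x1 conv/BN/ReLU, depthwise
# conv/BN, optional channel attention on the depthwise output, 1x1
# conv/BN/ReLU), concatenates with the untouched half and channel-shuffles
# with G = 2 so deep and non-deep features mix.

new_shuffle_unit <- function(name, spec) {
  stopifnot(inherits(spec, "block_spec"))
  if (spec$stride == 1L) {
    C <- spec$channels_in
    if (C %% 2L != 0L)
      stop("shuffle unit: stride-1 units require an even channel count")
    cb <- C %/% 2L                       # branch width (second half)
    ch <- list(pw1 = layer_pw("pw1", cb, cb),
               bn1 = layer_bn("bn1", cb),
               dw  = layer_dw("dw", spec$kernel_size, cb, 1L, 1L),
               bn2 = layer_bn("bn2", cb),
               pw2 = layer_pw("pw2", cb, cb),
               bn3 = layer_bn("bn3", cb))
    at <- attention_layer("attn", cb, spec$attention)
    if (!is.null(at)) ch$attn <- at
    new_layer("unit", name, conf = list(spec = spec), children = ch)
  } else {
    cin <- spec$channels_in
    half <- spec$channels_out %/% 2L
    if (spec$channels_out %% 2L != 0L)
      stop("shuffle unit: stride-2 units require an even channels_out")
    ch <- list(a_dw  = layer_dw("a_dw", spec$kernel_size, cin, 2L, 1L),
               a_bn1 = layer_bn("a_bn1", cin),
               a_pw  = layer_pw("a_pw", cin, half),
               a_bn2 = layer_bn("a_bn2", half),
               b_pw1 = layer_pw("b_pw1", cin, half),
               b_bn1 = layer_bn("b_bn1", half),
               b_dw  = layer_dw("b_dw", spec$kernel_size, half, 2L, 1L),
               b_bn2 = layer_bn("b_bn2", half),
               b_pw2 = layer_pw("b_pw2", half, half),
               b_bn3 = layer_bn("b_bn3", half))
    at <- attention_layer("attn", half, spec$attention)
    if (!is.null(at)) ch$attn <- at
    new_layer("dunit", name, conf = list(spec = spec), children = ch)
  }
}

# run a named sub-chain of children; returns y, caches (named), layer
run_chain <- function(layer, names_, x, training, relu_after = character()) {
  caches <- list()
  for (nm in names_) {
    r <- ly_forward(layer$children[[nm]], x, training)
    layer$children[[nm]] <- r$layer
    caches[[nm]] <- r$cache
    x <- r$y
    if (nm %in% relu_after) {
      mask <- x > 0
      caches[[paste0(nm, "_relu")]] <- mask
      x <- x * mask
    }
  }
  list(y = x, caches = caches, layer = layer)
}

back_chain <- function(layer, names_, caches, dy, relu_after = character()) {
  grads <- list()
  for (nm in rev(names_)) {
    if (nm %in% relu_after) dy <- dy * caches[[paste0(nm, "_relu")]]
    r <- ly_backward(layer$children[[nm]], caches[[nm]], dy)
    grads[[nm]] <- r$grads
    dy <- r$dx
  }
  list(dx = dy, grads = grads)
}

unit_chain_names <- function(layer) {
  has_attn <- !is.null(layer$children$attn)
  if (layer$type == "unit") {
    c("pw1", "bn1", "dw", "bn2", if (has_attn) "attn", "pw2", "bn3")
  } else {
    list(a = c("a_dw", "a_bn1", "a_pw", "a_bn2"),
         b = c("b_pw1", "b_bn1", "b_dw", "b_bn2", if (has_attn) "attn",
               "b_pw2", "b_bn3"))
  }
}

unit_forward_impl <- function(layer, x, training) {
  if (layer$type == "unit") {
    d <- dim(x)
    C <- d[3L]
    n1 <- C %/% 2L
    x1 <- x[, , seq_len(n1), , drop = FALSE]
    x2 <- x[, , (n1 + 1L):C, , drop = FALSE]
    nms <- unit_chain_names(layer)
    r <- run_chain(layer, nms, x2, training,
                   relu_after = c("bn1", "bn3"))
    y0 <- channel_concat(x1, r$y)
    p <- shuffle_perm(C, 2L)
    y <- y0[, , p, , drop = FALSE]
    list(y = y, cache = list(caches = r$caches, n1 = n1, p = p, d = d),
         layer = r$layer)
  } else {
    nms <- unit_chain_names(layer)
    ra <- run_chain(layer, nms$a, x, training, relu_after = "a_bn2")
    layer <- ra$layer
    rb <- run_chain(layer, nms$b, x, training,
                    relu_after = c("b_bn1", "b_bn3"))
    layer <- rb$layer
    y0 <- channel_concat(ra$y, rb$y)
    C <- dim(y0)[3L]
    p <- shuffle_perm(C, 2L)
    y <- y0[, , p, , drop = FALSE]
    list(y = y,
         cache = list(ca = ra$caches, cb = rb$caches, p = p,
                      na = dim(ra$y)[3L]),
         layer = layer)
  }
}

unit_backward_impl <- function(layer, cache, dy) {
  if (layer$type == "unit") {
    invp <- order(cache$p)
    dy0 <- dy[, , invp, , drop = FALSE]
    n1 <- cache$n1
    C <- dim(dy0)[3L]
    dx1 <- dy0[, , seq_len(n1), , drop = FALSE]
    dh <- dy0[, , (n1 + 1L):C, , drop = FALSE]
    nms <- unit_chain_names(layer)
    r <- back_chain(layer, nms, cache$caches, dh,
                    relu_after = c("bn1", "bn3"))
    dx <- channel_concat(dx1, r$dx)
    list(dx = dx, grads = list(children = r$grads))
  } else {
    invp <- order(cache$p)
    dy0 <- dy[, , invp, , drop = FALSE]
    na <- cache$na
    C <- dim(dy0)[3L]
    da <- dy0[, , seq_len(na), , drop = FALSE]
    db <- dy0[, , (na + 1L):C, , drop = FALSE]
    nms <- unit_chain_names(layer)
    ra <- back_chain(layer, nms$a, cache$ca, da, relu_after = "a_bn2")
    rb <- back_chain(layer, nms$b, cache$cb, db,
                     relu_after = c("b_bn1", "b_bn3"))
    list(dx = ra$dx + rb$dx,
         grads = list(children = c(ra$grads, rb$grads)))
  }
}

#' Build an inverted residual unit
#'
#' Constructs a stride-1 split unit or a stride-2 downsampling unit from a
#' [block_spec()], with weights drawn from the current RNG state.
#'
#' @param spec A [block_spec()].
#' @return A unit object usable with [unit_forward()].
#' @export
shuffle_unit <- function(spec) {
  new_shuffle_unit(if (spec$stride == 1L) "unit" else "dunit", spec)
}

#' Run a unit forward
#'
#' @param unit A unit from [shuffle_unit()].
#' @param x Feature map `(H, W, C)` or `(H, W, C, N)`.
#' @param training Use batch statistics in the norm layers if `TRUE`.
#' @return The output feature map.  A stride-1 unit preserves shape; a
#'   stride-2 unit halves spatial dims (ceiling) and outputs
#'   `spec$channels_out` channels.
#' @export
unit_forward <- function(unit, x, training = FALSE) {
  xb <- as_batch(x)
  was3 <- isTRUE(attr(xb, "was_3d"))
  spec <- unit$conf$spec
  if (dim(xb)[3L] != spec$channels_in)
    stop(sprintf("unit_forward: expected %d input channels, got %d",
                 spec$channels_in, dim(xb)[3L]))
  if (unit$type == "dunit") {
    reach <- spec$kernel_size
    if (dim(xb)[1L] < 2L || dim(xb)[2L] < 2L)
      stop("unit_forward: input spatial dims too small to downsample")
  }
  r <- unit_forward_impl(unit, xb, training)
  un_batch(r$y, was3)
}

#' Stride-1 inverted residual unit, functional form
#'
#' Convenience wrapper that builds a stride-1 unit for `spec` (weights from
#' the current RNG state) and applies it.  Use [shuffle_unit()] +
#' [unit_forward()] to keep the weights.
#'
#' @param x Feature map.
#' @param spec A [block_spec()] with `stride = 1`.
#' @return Feature map of identical shape.
#' @export
inverted_residual_unit <- function(x, spec) {
  if (spec$stride != 1L)
    stop("inverted_residual_unit: stride must be 1; use downsample_unit")
  unit_forward(shuffle_unit(spec), x)
}

#' Stride-2 downsampling unit, functional form
#'
#' @param x Feature map.
#' @param spec A [block_spec()] with `stride = 2`.
#' @return Feature map with halved (ceiling) spatial dims and
#'   `spec$channels_out` channels.
#' @export
downsample_unit <- function(x, spec) {
  if (spec$stride != 2L)
    stop("downsample_unit: stride must be 2; use inverted_residual_unit")
  unit_forward(shuffle_unit(spec), x)
}
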