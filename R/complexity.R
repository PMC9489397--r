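# Analytic convolution-cost model: multiplication counts, parameter counts
# and serialized size.  The counting convention is multiplications only (no
# additions, no bias multiplies), evaluated at the layer's OUTPUT spatial
# dims under the same-padding convention.  Batch norm contributes parameters
# but no counted multiplications; attention contributes its linear-map and
# rescaling multiplications plus its parameters.

#' Multiplication count of a standard convolution
#'
#' `W * H * C_in * C_out * N^2` where `W`, `H` are the output spatial dims
#' (equal to the input dims at stride 1 under same padding).
#'
#' @param fmap A [feature_map_spec()] giving the input extent; its
#'   `channels` is `C_in`.
#' @param spec A [conv_spec()] with `depthwise = FALSE`.
#' @return Non-negative multiplication count.
#' @export
conv_mults <- function(fmap, spec) {
  stopifnot(inherits(fmap, "feature_map_spec"), inherits(spec, "conv_spec"))
  if (spec$depthwise) stop("conv_mults: use dws_mults for depthwise factorizations")
  if (fmap$channels != spec$in_channels)
    stop("conv_mults: fmap channels must equal spec in_channels")
  Ho <- ceiling(fmap$height / spec$stride)
  Wo <- ceiling(fmap$width / spec$stride)
  Wo * Ho * spec$in_channels * spec$out_channels * spec$kernel_size^2
}

#' Multiplication count of a depthwise separable convolution
#'
#' Depthwise term `W*H*C_in*N^2` plus pointwise term `W*H*C_in*C_out`.
#'
#' @param fmap A [feature_map_spec()]; its `channels` is `C_in`.
#' @param N Depthwise kernel size.
#' @param C_out Pointwise output channels.
#' @param stride Depthwise-stage stride (output dims used for both terms).
#' @return List-free numeric total; the two terms are available via
#'   `attr(, "terms")`.
#' @export
dws_mults <- function(fmap, N, C_out, stride = 1L) {
  stopifnot(inherits(fmap, "feature_map_spec"))
  Ho <- ceiling(fmap$height / stride)
  Wo <- ceiling(fmap$width / stride)
  depthwise <- Wo * Ho * fmap$channels * N^2
  pointwise <- Wo * Ho * fmap$channels * C_out
  structure(depthwise + pointwise,
            terms = c(depthwise = depthwise, pointwise = pointwise))
}

#' Cost ratio of depthwise separable to standard convolution
#'
#' `1 / C_out + 1 / N^2`; the spatial extent and input channels cancel, so
#' the saving depends only on the kernel size and output width.  Note the
#' ratio exceeds 1 (the factorization costs more) when `N = 1` and `C_out`
#' is small.
#'
#' @param N Kernel size.
#' @param C_out Output channels.
#' @return Positive numeric ratio.
#' @export
reduction_ratio <- function(N, C_out) {
  if (N < 1 || C_out < 1) stop("reduction_ratio: N and C_out must be >= 1")
  1 / C_out + 1 / N^2
}

# closure holding the per-layer complexity walker; fm = c(H, W, C)
complexity_walker <- function() {
  rows <- list()
  add <- function(path, mults, params) {
    rows[[length(rows) + 1L]] <<- data.frame(layer = path, mults = mults,
                                             params = params,
                                             stringsAsFactors = FALSE)
  }
  walk <- function(layer, fm, path) {
    H <- fm[1L]; W <- fm[2L]; C <- fm[3L]
    switch(layer$type,
      conv = {
        cf <- layer$conf
        Ho <- ceiling(H / cf$stride); Wo <- ceiling(W / cf$stride)
        add(path, Wo * Ho * cf$cin * cf$cout * cf$K^2,
            cf$K^2 * cf$cin * cf$cout)
        c(Ho, Wo, cf$cout)
      },
      pw = {
        cf <- layer$conf
        add(path, H * W * cf$cin * cf$cout, cf$cin * cf$cout)
        c(H, W, cf$cout)
      },
      dw = {
        cf <- layer$conf
        Ho <- ceiling(H / cf$stride); Wo <- ceiling(W / cf$stride)
        add(path, Wo * Ho * cf$C * cf$K^2, cf$K^2 * cf$C)
        c(Ho, Wo, cf$C)
      },
      bn = {
        add(path, 0, 2 * layer$conf$C)
        fm
      },
      relu = fm,
      maxpool = {
        cf <- layer$conf
        c(ceiling(H / cf$stride), ceiling(W / cf$stride), C)
      },
      gap = c(1L, 1L, C),
      linear = {
        cf <- layer$conf
        add(path, cf$cin * cf$cout, cf$cin * cf$cout + cf$cout)
        c(1L, 1L, cf$cout)
      },
      shuffle = fm,
      se = {
        cf <- layer$conf
        # two linear maps on the squeezed vector + per-element rescale
        add(path, cf$h * cf$C * 2 + H * W * cf$C,
            2 * cf$C * cf$h + cf$h + cf$C)
        fm
      },
      sk = {
        cf <- layer$conf
        for (nm in c("dw1", "pw1", "dw2", "pw2"))
          fm2 <- walk(layer$children[[nm]], fm, paste(path, nm, sep = "/"))
        add(paste(path, "attn", sep = "/"),
            cf$h * cf$C + 2 * cf$h * cf$C + 2 * H * W * cf$C,
            cf$C * cf$h + cf$h + 2 * (cf$h * cf$C + cf$C))
        fm
      },
      unit = {
        cb <- layer$conf$spec$channels_in %/% 2L
        fmb <- c(H, W, cb)
        for (nm in names(layer$children))
          fmb <- walk(layer$children[[nm]], fmb, paste(path, nm, sep = "/"))
        c(H, W, layer$conf$spec$channels_in)
      },
      dunit = {
        spec <- layer$conf$spec
        half <- spec$channels_out %/% 2L
        fma <- fm
        for (nm in c("a_dw", "a_bn1", "a_pw", "a_bn2"))
          fma <- walk(layer$children[[nm]], fma, paste(path, nm, sep = "/"))
        fmb <- fm
        bnames <- c("b_pw1", "b_bn1", "b_dw", "b_bn2",
                    if (!is.null(layer$children$attn)) "attn",
                    "b_pw2", "b_bn3")
        for (nm in bnames)
          fmb <- walk(layer$children[[nm]], fmb, paste(path, nm, sep = "/"))
        c(fma[1L], fma[2L], spec$channels_out)
      },
      stop(sprintf("model_complexity: unsupported layer type '%s' at %s",
                   layer$type, path)))
  }
  list(walk = walk, rows = function() rows)
}

#' Analytic complexity report for an assembled network
#'
#' Walks every layer of the network applying the analytic multiplication
#' formulas ([conv_mults()], [dws_mults()] terms) and parameter arithmetic,
#' and reports per-layer and total counts plus the serialized parameter
#' size.
#'
#' @param model An `scx_model` from [build_model()].
#' @param input A [feature_map_spec()] describing the input image
#'   (e.g. `feature_map_spec(224, 224, 3)`).
#' @param precision_bytes Bytes per stored parameter (default 4,
#'   single precision).
#' @return An object of class `complexity_report`: list with `per_layer`
#'   data.frame, `total_mults`, `total_params`, `size_bytes`.
#' @export
model_complexity <- function(model, input = feature_map_spec(224, 224, 3),
                             precision_bytes = 4L) {
  stopifnot(inherits(model, "scx_model"), inherits(input, "feature_map_spec"))
  ctx <- complexity_walker()
  fm <- c(input$height, input$width, input$channels)
  for (nm in names(model$layers))
    fm <- ctx$walk(model$layers[[nm]], fm, nm)
  per_layer <- do.call(rbind, c(list(
    data.frame(layer = character(), mults = numeric(), params = numeric(),
               stringsAsFactors = FALSE)), ctx$rows()))
  structure(list(per_layer = per_layer,
                 total_mults = sum(per_layer$mults),
                 total_params = sum(per_layer$params),
                 size_bytes = sum(per_layer$params) * precision_bytes),
            class = "complexity_report")
}

#' @export
print.complexity_report <- function(x, ...) {
  cat("Complexity report\n")
  cat(sprintf("  layers counted : %d\n", nrow(x$per_layer)))
  cat(sprintf("  total mults    : %s\n", format(x$total_mults, big.mark = ",")))
  cat(sprintf("  total params   : %s\n", format(x$total_params, big.mark = ",")))
  cat(sprintf("  size           : %.2f MB\n", x$size_bytes / 2^20))
  invisible(x)
}

#' Closed-form parameter count of one excitation bottleneck
#'
#' `2 * C * h + h + C` with `h = max(ceiling(C / r), 1)` — the exact
#' per-module parameter excess an SE-fused unit carries over the plain unit.
#'
#' @param channels Channel count the module gates.
#' @param reduction_ratio Bottleneck divisor.
#' @return Integer parameter count.
#' @export
se_param_count <- function(channels, reduction_ratio = 16L) {
  h <- bottleneck_width(channels, reduction_ratio)
  2 * channels * h + h + channels
}
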