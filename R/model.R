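# Network assembly: stem conv + max pool, staged inverted-residual trunk,
# final 1x1 conv, global average pool, linear classifier.

#' Assemble a classification network
#'
#' Builds the backbone described by a [model_config()]: a 3x3 stride-2 stem
#' convolution (BN + ReLU) and 3x3/2 max pool, then for each stage one
#' stride-2 downsampling unit followed by `repeats - 1` stride-1 split
#' units, then a final 1x1 convolution (BN + ReLU), global average pooling
#' and a linear head with `num_classes` outputs.  Weights are drawn from the
#' current RNG state (Kaiming-style for convolutions, unit scale / zero
#' shift for batch norm), so seed the RNG for reproducible builds.
#'
#' @param config A [model_config()].
#' @param in_channels Input image channels (default 3, RGB).
#' @return An object of class `scx_model`.
#' @export
build_model <- function(config = model_config(), in_channels = 3L) {
  stopifnot(inherits(config, "model_config"))
  layers <- list(
    stem_conv = layer_conv("stem_conv", 3L, in_channels,
                           config$stem_channels, stride = 2L),
    stem_bn = layer_bn("stem_bn", config$stem_channels),
    stem_relu = layer_relu("stem_relu"),
    stem_pool = layer_maxpool("stem_pool"))
  cin <- config$stem_channels
  for (s in seq_along(config$stage_repeats)) {
    cout <- config$stage_channels[s]
    nm <- sprintf("stage%d_down", s)
    layers[[nm]] <- new_shuffle_unit(nm,
      block_spec(cin, cout, stride = 2L, attention = config$attention))
    for (u in seq_len(config$stage_repeats[s] - 1L)) {
      nm <- sprintf("stage%d_unit%d", s, u)
      layers[[nm]] <- new_shuffle_unit(nm,
        block_spec(cout, cout, stride = 1L, attention = config$attention))
    }
    cin <- cout
  }
  layers$final_pw <- layer_pw("final_pw", cin, config$final_channels)
  layers$final_bn <- layer_bn("final_bn", config$final_channels)
  layers$final_relu <- layer_relu("final_relu")
  layers$gap <- layer_gap("gap")
  layers$fc <- layer_linear("fc", config$final_channels, config$num_classes)
  structure(list(config = config, in_channels = as.integer(in_channels),
                 layers = layers),
            class = "scx_model")
}

model_forward <- function(model, x, training = FALSE, keep_caches = FALSE) {
  caches <- if (keep_caches) vector("list", length(model$layers)) else NULL
  if (keep_caches) names(caches) <- names(model$layers)
  for (nm in names(model$layers)) {
    ly <- model$layers[[nm]]
    r <- if (ly$type %in% c("unit", "dunit"))
      unit_forward_impl(ly, x, training)
    else
      ly_forward(ly, x, training)
    model$layers[[nm]] <- r$layer
    if (keep_caches) caches[[nm]] <- r$cache
    x <- r$y
  }
  list(logits = x, model = model, caches = caches)
}

model_backward <- function(model, caches, dlogits) {
  grads <- vector("list", length(model$layers))
  names(grads) <- names(model$layers)
  dy <- dlogits
  for (nm in rev(names(model$layers))) {
    ly <- model$layers[[nm]]
    r <- if (ly$type %in% c("unit", "dunit"))
      unit_backward_impl(ly, caches[[nm]], dy)
    else
      ly_backward(ly, caches[[nm]], dy)
    grads[[nm]] <- r$grads
    dy <- r$dx
  }
  grads
}

softmax_rows <- function(L) {
  # L: K x N logits; column-wise softmax (per sample)
  m <- apply(L, 2L, max)
  e <- exp(sweep(L, 2L, m))
  sweep(e, 2L, colSums(e), "/")
}

#' Predict classes and probabilities for a batch of images
#'
#' Runs the network in inference mode (running batch-norm statistics) and
#' returns softmax probabilities and argmax classes; ties break to the
#' lowest class index.
#'
#' @param model An `scx_model`.
#' @param images A `(H, W, C)` array, `(H, W, C, N)` array, or list of
#'   `(H, W, C)` arrays.
#' @return List with `class` (integer labels, 0-based), `prob`
#'   (`N x num_classes` matrix) and `logits`.
#' @export
predict_batch <- function(model, images) {
  x <- stack_images(images, model$in_channels)
  r <- model_forward(model, x, training = FALSE)
  L <- r$logits                       # K x N
  P <- softmax_rows(L)
  cls <- apply(L, 2L, which.max) - 1L
  list(class = as.integer(cls), prob = t(P), logits = t(L))
}

stack_images <- function(images, in_channels = 3L) {
  if (is.list(images)) {
    d <- dim(images[[1L]])
    x <- array(0, c(d[1L], d[2L], d[3L], length(images)))
    for (i in seq_along(images)) x[, , , i] <- images[[i]]
    x
  } else {
    d <- dim(images)
    if (length(d) == 3L) { dim(images) <- c(d, 1L); images }
    else images
  }
}

#' Total trainable parameter count of a network
#'
#' @param model An `scx_model`.
#' @return Number of trainable scalars (convolution, linear, batch-norm and
#'   attention weights; running statistics excluded).
#' @export
model_params <- function(model) {
  sum(vapply(model$layers, count_params, numeric(1)))
}

#' Structural layer listing
#'
#' Flat listing of every parameterized leaf layer with its path and type;
#' two builds that differ only in attention differ exactly by the attention
#' entries.
#'
#' @param model An `scx_model`.
#' @return data.frame with columns `path`, `type`, `params`.
#' @export
model_structure <- function(model) {
  rows <- list()
  walk <- function(layer, path) {
    np <- if (is.null(layer$params)) 0 else
      sum(vapply(layer$params, length, numeric(1)))
    rows[[length(rows) + 1L]] <<- data.frame(path = path, type = layer$type,
                                             params = np,
                                             stringsAsFactors = FALSE)
    if (!is.null(layer$children))
      for (nm in names(layer$children))
        walk(layer$children[[nm]], paste(path, nm, sep = "/"))
  }
  for (nm in names(model$layers)) walk(model$layers[[nm]], nm)
  do.call(rbind, rows)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is an RDS file carrying the weights plus the
#' [model_config()] serialized as JSON metadata, so a checkpoint is
#' self-describing.
#'
#' @param model An `scx_model` (or `shufflecerv` fit; its best model is saved).
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   restored object.
#' @export
save_model <- function(model, path) {
  plain <- function(cfg) {
    cfg <- unclass(cfg)
    cfg$attention <- unclass(cfg$attention)
    cfg
  }
  if (inherits(model, "shufflecerv")) {
    obj <- list(kind = "fit", fit = model,
                config_json = jsonlite::toJSON(plain(model$model$config),
                                               auto_unbox = TRUE))
  } else {
    obj <- list(kind = "model", model = model,
                config_json = jsonlite::toJSON(plain(model$config),
                                               auto_unbox = TRUE))
  }
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (identical(obj$kind, "fit")) obj$fit else obj$model
}
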