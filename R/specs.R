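#' Feature-map shape descriptor
#'
#' A plain record of the spatial and channel extent of an activation tensor.
#' It carries the `W`, `H` and channel symbols used throughout the analytic
#' convolution-cost formulas.
#'
#' @param height,width Positive integer spatial dims (pixels/activations).
#' @param channels Positive integer channel count.
#' @return An object of class `feature_map_spec`.
#' @export
feature_map_spec <- function(height, width, channels) {
  stopifnot(is.numeric(height), is.numeric(width), is.numeric(channels))
  height <- as.integer(height); width <- as.integer(width)
  channels <- as.integer(channels)
  if (height < 1L || width < 1L || channels < 1L)
    stop("feature_map_spec: all fields must be >= 1")
  structure(list(height = height, width = width, channels = channels),
            class = "feature_map_spec")
}

#' Convolution configuration
#'
#' @param kernel_size Positive odd integer kernel size N.
#' @param in_channels,out_channels Positive integers.
#' @param stride 1 or 2.
#' @param dilation Integer >= 1; the effective receptive field is
#'   `dilation * (kernel_size - 1) + 1`.
#' @param depthwise If `TRUE`, one kernel per channel
#'   (requires `out_channels == in_channels`).
#' @return An object of class `conv_spec`.
#' @export
conv_spec <- function(kernel_size, in_channels, out_channels,
                      stride = 1L, dilation = 1L, depthwise = FALSE) {
  kernel_size <- as.integer(kernel_size)
  in_channels <- as.integer(in_channels)
  out_channels <- as.integer(out_channels)
  stride <- as.integer(stride); dilation <- as.integer(dilation)
  if (kernel_size < 1L || kernel_size %% 2L == 0L)
    stop("conv_spec: kernel_size must be a positive odd integer")
  if (!stride %in% c(1L, 2L)) stop("conv_spec: stride must be 1 or 2")
  if (dilation < 1L) stop("conv_spec: dilation must be >= 1")
  if (in_channels < 1L || out_channels < 1L)
    stop("conv_spec: channel counts must be >= 1")
  if (depthwise && out_channels != in_channels)
    stop("conv_spec: depthwise requires out_channels == in_channels")
  structure(list(kernel_size = kernel_size, in_channels = in_channels,
                 out_channels = out_channels, stride = stride,
                 dilation = dilation, depthwise = isTRUE(depthwise)),
            class = "conv_spec")
}

#' Channel-attention configuration
#'
#' @param kind One of `"none"`, `"se"` (squeeze-and-excitation) or `"sk"`
#'   (selective kernel).
#' @param reduction_ratio Positive integer `r`; the excitation bottleneck
#'   width is `max(ceiling(channels / r), 1)`.
#' @param sk_norm How SK branch weights are normalized across the two
#'   branches: `"softmax"` (weights sum to 1 per channel, the default) or
#'   `"sigmoid"` (independent per-branch gates).
#' @return An object of class `attention_config`.
#' @export
attention_config <- function(kind = c("none", "se", "sk"),
                             reduction_ratio = 16L,
                             sk_norm = c("softmax", "sigmoid")) {
  kind <- match.arg(kind)
  sk_norm <- match.arg(sk_norm)
  reduction_ratio <- as.integer(reduction_ratio)
  if (reduction_ratio < 1L) stop("attention_config: reduction_ratio must be >= 1")
  structure(list(kind = kind, reduction_ratio = reduction_ratio,
                 sk_norm = sk_norm),
            class = "attention_config")
}

bottleneck_width <- function(channels, reduction_ratio) {
  max(as.integer(ceiling(channels / reduction_ratio)), 1L)
}

#' Inverted-residual unit configuration
#'
#' @param channels_in,channels_out Positive integers.  A stride-1 unit
#'   requires `channels_out == channels_in` (the split-and-concat topology
#'   preserves width); a stride-2 unit may change width.
#' @param stride 1 (split unit) or 2 (downsampling unit).
#' @param kernel_size Odd depthwise kernel size, default 3.
#' @param attention An [attention_config()].
#' @return An object of class `block_spec`.
#' @export
block_spec <- function(channels_in, channels_out = channels_in, stride = 1L,
                       kernel_size = 3L, attention = attention_config("none")) {
  channels_in <- as.integer(channels_in)
  channels_out <- as.integer(channels_out)
  stride <- as.integer(stride); kernel_size <- as.integer(kernel_size)
  if (!stride %in% c(1L, 2L)) stop("block_spec: stride must be 1 or 2")
  if (stride == 1L && channels_out != channels_in)
    stop("block_spec: stride-1 units require channels_out == channels_in")
  if (kernel_size < 1L || kernel_size %% 2L == 0L)
    stop("block_spec: kernel_size must be odd")
  if (channels_in < 2L) stop("block_spec: channels_in must be >= 2")
  stopifnot(inherits(attention, "attention_config"))
  structure(list(channels_in = channels_in, channels_out = channels_out,
                 stride = stride, kernel_size = kernel_size,
                 attention = attention),
            class = "block_spec")
}

#' Backbone configuration
#'
#' The default schedule is the canonical 1.0x layout for this unit family:
#' stem 24 channels, three stages of 4/8/4 units at 116/232/464 channels,
#' a final 1024-channel 1x1 convolution, and a 5-class linear head.
#'
#' @param stem_channels Stem convolution width.
#' @param stage_repeats,stage_channels Equal-length integer vectors; each
#'   stage is one stride-2 unit followed by `repeats - 1` stride-1 units.
#' @param final_channels Width of the last 1x1 convolution.
#' @param num_classes Number of output classes (>= 2), default 5.
#' @param attention An [attention_config()] applied inside every unit.
#' @param dropout Dropout probability before the classifier (default 0).
#' @return An object of class `model_config`.
#' @export
model_config <- function(stem_channels = 24L,
                         stage_repeats = c(4L, 8L, 4L),
                         stage_channels = c(116L, 232L, 464L),
                         final_channels = 1024L,
                         num_classes = 5L,
                         attention = attention_config("none"),
                         dropout = 0) {
  stage_repeats <- as.integer(stage_repeats)
  stage_channels <- as.integer(stage_channels)
  if (length(stage_repeats) != length(stage_channels))
    stop("model_config: stage_repeats and stage_channels must have equal length")
  if (any(stage_repeats < 1L) || any(stage_channels < 2L))
    stop("model_config: invalid stage schedule")
  if (any(stage_channels %% 2L != 0L))
    stop("model_config: stage_channels must be even (channel split in halves)")
  num_classes <- as.integer(num_classes)
  if (num_classes < 2L) stop("model_config: num_classes must be >= 2")
  stopifnot(inherits(attention, "attention_config"))
  structure(list(stem_channels = as.integer(stem_channels),
                 stage_repeats = stage_repeats,
                 stage_channels = stage_channels,
                 final_channels = as.integer(final_channels),
                 num_classes = num_classes,
                 attention = attention,
                 dropout = dropout),
            class = "model_config")
}

#' Reduced-width backbone for CPU-scale experiments
#'
#' A shallow, narrow schedule (stages 2/2/2 at 48/96/192 channels, final 512)
#' used for desk-scale runs on small images; same topology, far fewer
#' parameters than the default schedule.
#'
#' @param attention An [attention_config()].
#' @param num_classes Number of classes.
#' @return A [model_config()].
#' @export
model_config_small <- function(attention = attention_config("none"),
                               num_classes = 5L) {
  model_config(stage_repeats = c(2L, 2L, 2L),
               stage_channels = c(48L, 96L, 192L),
               final_channels = 512L, num_classes = num_classes,
               attention = attention)
}

#' Training-control configuration
#'
#' Defaults follow the experimental recipe: SGD with Nesterov momentum 0.9,
#' weight decay 1e-4, batch size 32, initial learning rate 0.05, 100 epochs.
#'
#' @param initial_lr Initial learning rate.
#' @param momentum Nesterov momentum.
#' @param weight_decay L2 penalty coefficient.
#' @param batch_size Minibatch size.
#' @param epochs Number of passes over the training set (>= 1).
#' @param lr_schedule `"linear_decay"` (default), `"cosine"` or `"constant"`.
#' @param seed Integer seed driving init, batching and augmentation.
#' @return An object of class `train_control`.
#' @export
train_control <- function(initial_lr = 0.05, momentum = 0.9,
                          weight_decay = 1e-4, batch_size = 32L,
                          epochs = 100L,
                          lr_schedule = c("linear_decay", "cosine", "constant"),
                          seed = 1L) {
  lr_schedule <- match.arg(lr_schedule)
  epochs <- as.integer(epochs)
  if (initial_lr <= 0 || momentum < 0 || weight_decay < 0)
    stop("train_control: rates must be positive")
  if (epochs < 1L) stop("train_control: epochs must be >= 1")
  if (batch_size < 1L) stop("train_control: batch_size must be >= 1")
  structure(list(initial_lr = initial_lr, momentum = momentum,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size), epochs = epochs,
                 lr_schedule = lr_schedule, seed = as.integer(seed)),
            class = "train_control")
}

#' Class-label scheme
#'
#' The default five-class colposcopy scheme: 0 normal, 1 LSIL (CIN1),
#' 2 HSIL (CIN2/3), 3 cervical cancer, 4 cervical neoplasm.
#'
#' @param class_names Character vector naming classes for consecutive
#'   integer labels starting at 0.
#' @return Named character vector; names are the label integers.
#' @export
label_scheme <- function(class_names = c("normal", "LSIL", "HSIL",
                                         "cervical cancer",
                                         "cervical neoplasm")) {
  stats::setNames(as.character(class_names),
                  as.character(seq_along(class_names) - 1L))
}
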