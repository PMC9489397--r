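# SGD-Nesterov training loop with cross-entropy loss.

#' Learning rate at a given epoch
#'
#' `linear_decay` (the default schedule): `initial_lr * (1 - epoch/epochs)`;
#' `cosine`: `initial_lr * (1 + cos(pi * epoch/epochs)) / 2`; `constant`.
#'
#' @param epoch 0-based epoch index.
#' @param control A [train_control()].
#' @return Learning rate.
#' @export
lr_at <- function(epoch, control) {
  switch(control$lr_schedule,
         linear_decay = control$initial_lr * (1 - epoch / control$epochs),
         cosine = control$initial_lr *
           (1 + cos(pi * epoch / control$epochs)) / 2,
         constant = control$initial_lr)
}

# Nesterov SGD step on one layer (recursively); PyTorch-style update:
#   g <- grad + wd * p;  v <- mu * v + g;  p <- p - lr * (g + mu * v)
sgd_update <- function(layer, grads, vel, lr, momentum, weight_decay) {
  if (!is.null(layer$params) && !is.null(grads$params)) {
    if (is.null(vel$params)) vel$params <- list()
    for (nm in names(layer$params)) {
      g <- grads$params[[nm]]
      if (is.null(g)) next
      p <- layer$params[[nm]]
      g <- g + weight_decay * p
      v <- vel$params[[nm]]
      if (is.null(v)) v <- p * 0
      v <- momentum * v + g
      layer$params[[nm]] <- p - lr * (g + momentum * v)
      vel$params[[nm]] <- v
    }
  }
  if (!is.null(layer$children) && !is.null(grads$children)) {
    if (is.null(vel$children)) vel$children <- list()
    for (nm in names(layer$children)) {
      gch <- grads$children[[nm]]
      if (is.null(gch)) next
      r <- sgd_update(layer$children[[nm]], gch,
                      if (is.null(vel$children[[nm]])) list()
                      else vel$children[[nm]],
                      lr, momentum, weight_decay)
      layer$children[[nm]] <- r$layer
      vel$children[[nm]] <- r$vel
    }
  }
  list(layer = layer, vel = vel)
}

cross_entropy <- function(logits, labels) {
  # logits: K x N; labels 0-based
  P <- softmax_rows(logits)
  n <- ncol(logits)
  idx <- cbind(labels + 1L, seq_len(n))
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  Y <- matrix(0, nrow(logits), n)
  Y[idx] <- 1
  list(loss = loss, dlogits = (P - Y) / n, prob = P)
}

assemble_batch <- function(ds, idx, input_size, resize_to, stats, train) {
  x <- array(0, c(input_size, input_size, 3L, length(idx)))
  for (j in seq_along(idx)) {
    img <- get_image(ds, idx[j])
    x[, , , j] <- if (train)
      augment_train(img, crop_size = input_size, resize_to = resize_to,
                    stats = stats)
    else
      augment_eval(img, crop_size = input_size, resize_to = resize_to,
                   stats = stats)
  }
  x
}

eval_accuracy <- function(model, ds, input_size, resize_to, stats,
                          batch_size) {
  n <- length(ds)
  correct <- 0L
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    x <- assemble_batch(ds, idx, input_size, resize_to, stats, train = FALSE)
    r <- model_forward(model, x, training = FALSE)
    pred <- apply(r$logits, 2L, which.max) - 1L
    correct <- correct + sum(pred == ds$labels[idx])
  }
  100 * correct / n
}

#' Fit an attention-augmented ShuffleNet classifier
#'
#' The main fitting entry point.  Trains the configured network with
#' SGD-Nesterov on cross-entropy loss (initial learning rate 0.05, momentum
#' 0.9, weight decay 1e-4, batch size 32 by default), records per-epoch
#' training loss/accuracy and validation accuracy, and retains the weights
#' of the best validation epoch.  Everything — weight init, batch order,
#' augmentation — is driven by `control$seed`.
#'
#' @param train An [image_dataset()] of training records.
#' @param val Optional validation [image_dataset()]; when given, the fitted
#'   model is the best-validation-accuracy checkpoint.
#' @param model A [model_config()].
#' @param control A [train_control()].
#' @param input_size Square input side fed to the network.
#' @param resize_to Shorter-side resize before cropping (`NULL`: images must
#'   already cover the crop).
#' @param stats Normalization statistics; default computed from `train`.
#' @param verbose Print one line per epoch.
#' @return An object of class `shufflecerv` with elements `model` (best
#'   weights), `final_model`, `history` (data.frame epoch, lr, train_loss,
#'   train_accuracy, val_accuracy), `config`, `control`, `stats`,
#'   `input_size`, `resize_to`.
#' @seealso [predict.shufflecerv()], [evaluate()], [model_complexity()]
#' @export
shufflecerv <- function(train, val = NULL, model = model_config(),
                        control = train_control(), input_size = 224L,
                        resize_to = NULL, stats = NULL, verbose = FALSE) {
  stopifnot(inherits(train, "image_dataset"))
  if (length(train) == 0L) stop("shufflecerv: empty training set")
  if (!is.null(val)) stopifnot(inherits(val, "image_dataset"))
  if (is.null(stats)) stats <- compute_norm_stats(train)
  set.seed(control$seed)
  net <- build_model(model)
  vel <- list()
  n <- length(train)
  bs <- min(control$batch_size, n)
  hist_rows <- vector("list", control$epochs)
  best_acc <- -Inf
  best_net <- net
  for (epoch in seq_len(control$epochs)) {
    lr <- lr_at(epoch - 1L, control)
    ord <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0L; ep_n <- 0L
    for (start in seq(1L, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n)]
      x <- assemble_batch(train, idx, input_size, resize_to, stats,
                          train = TRUE)
      fw <- model_forward(net, x, training = TRUE, keep_caches = TRUE)
      net <- fw$model
      ce <- cross_entropy(fw$logits, train$labels[idx])
      if (!is.finite(ce$loss))
        stop(sprintf("training diverged (non-finite loss) at epoch %d",
                     epoch))
      pred <- apply(fw$logits, 2L, which.max) - 1L
      ep_correct <- ep_correct + sum(pred == train$labels[idx])
      ep_loss <- ep_loss + ce$loss * length(idx)
      ep_n <- ep_n + length(idx)
      grads <- model_backward(net, fw$caches, ce$dlogits)
      for (nm in names(net$layers)) {
        if (is.null(grads[[nm]])) next
        r <- sgd_update(net$layers[[nm]], grads[[nm]],
                        if (is.null(vel[[nm]])) list() else vel[[nm]],
                        lr, control$momentum, control$weight_decay)
        net$layers[[nm]] <- r$layer
        vel[[nm]] <- r$vel
      }
    }
    va <- if (!is.null(val))
      eval_accuracy(net, val, input_size, resize_to, stats, bs)
    else NA_real_
    tr_acc <- 100 * ep_correct / ep_n
    hist_rows[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                     train_loss = ep_loss / ep_n,
                                     train_accuracy = tr_acc,
                                     val_accuracy = va)
    track <- if (!is.null(val)) va else tr_acc
    if (track > best_acc) { best_acc <- track; best_net <- net }
    if (verbose)
      message(sprintf(
        "epoch %3d  lr %.4f  loss %.4f  train acc %5.1f  val acc %s",
        epoch, lr, ep_loss / ep_n, tr_acc,
        if (is.na(va)) "-" else sprintf("%5.1f", va)))
  }
  structure(list(model = best_net, final_model = net,
                 history = do.call(rbind, hist_rows),
                 config = model, control = control, stats = stats,
                 input_size = as.integer(input_size), resize_to = resize_to,
                 best_accuracy = best_acc),
            class = "shufflecerv")
}

#' Predict method for fitted classifiers
#'
#' Applies the deterministic evaluation transform and the trained network.
#'
#' @param object A `shufflecerv` fit.
#' @param newdata An [image_dataset()], a list of images, or one image array.
#' @param type `"class"` (0-based labels), `"prob"` (N x K matrix) or
#'   `"both"`.
#' @param batch_size Forward-pass batch size.
#' @param ... Unused.
#' @return Per `type`.
#' @export
predict.shufflecerv <- function(object, newdata,
                                type = c("class", "prob", "both"),
                                batch_size = 32L, ...) {
  type <- match.arg(type)
  ds <- if (inherits(newdata, "image_dataset")) newdata
        else if (is.list(newdata))
          image_dataset(rep(0L, length(newdata)), images = newdata)
        else image_dataset(0L, images = list(newdata))
  n <- length(ds)
  K <- object$config$num_classes
  prob <- matrix(0, n, K)
  cls <- integer(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    x <- assemble_batch(ds, idx, object$input_size, object$resize_to,
                        object$stats, train = FALSE)
    p <- predict_batch(object$model, x)
    prob[idx, ] <- p$prob
    cls[idx] <- p$class
  }
  colnames(prob) <- as.character(seq_len(K) - 1L)
  switch(type, class = cls, prob = prob, both = list(class = cls, prob = prob))
}

#' @export
print.shufflecerv <- function(x, ...) {
  cat("shufflecerv fit\n")
  cat(sprintf("  attention    : %s\n", x$config$attention$kind))
  cat(sprintf("  parameters   : %s\n",
              format(model_params(x$model), big.mark = ",")))
  cat(sprintf("  epochs       : %d (batch %d, lr %.3g %s)\n",
              x$control$epochs, x$control$batch_size, x$control$initial_lr,
              x$control$lr_schedule))
  if (!all(is.na(x$history$val_accuracy)))
    cat(sprintf("  best val acc : %.2f%%\n", x$best_accuracy))
  else
    cat(sprintf("  final train acc : %.2f%%\n",
                x$history$train_accuracy[nrow(x$history)]))
  invisible(x)
}

#' @export
summary.shufflecerv <- function(object, ...) {
  print(object)
  cat("\nlast epochs:\n")
  print(utils::tail(object$history, 5L), row.names = FALSE)
  invisible(object)
}

#' Plot training history
#'
#' Training loss (left axis) and accuracies (right axis) per epoch.
#'
#' @param x A `shufflecerv` fit.
#' @param ... Passed to `plot`.
#' @export
plot.shufflecerv <- function(x, ...) {
  h <- x$history
  op <- par(mar = c(4, 4, 2, 4))
  on.exit(par(op))
  plot(h$epoch, h$train_loss, type = "l", col = "firebrick",
       xlab = "epoch", ylab = "training loss", ...)
  par(new = TRUE)
  plot(h$epoch, h$train_accuracy, type = "l", col = "steelblue",
       axes = FALSE, xlab = "", ylab = "", ylim = c(0, 100))
  if (!all(is.na(h$val_accuracy)))
    lines(h$epoch, h$val_accuracy, col = "darkgreen")
  axis(4)
  legend("bottomright", bty = "n", lty = 1,
         col = c("firebrick", "steelblue", "darkgreen"),
         legend = c("loss", "train acc", "val acc"))
  invisible(x)
}
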