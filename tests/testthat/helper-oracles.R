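# Independent oracles used across the suite.  These are deliberately naive
# (explicit loops, pair counting) and share no code with the implementation.

# naive same-padding convolution, single image (H, W, Cin) -> (Ho, Wo, Cout)
naive_conv <- function(x, w, stride = 1, dilation = 1) {
  d <- dim(x); K <- dim(w)[1]; pad <- dilation * (K - 1) / 2
  Ho <- ceiling(d[1] / stride); Wo <- ceiling(d[2] / stride)
  y <- array(0, c(Ho, Wo, dim(w)[4]))
  for (co in seq_len(dim(w)[4])) for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
    acc <- 0
    for (ci in seq_len(d[3])) for (kh in seq_len(K)) for (kw in seq_len(K)) {
      hi <- (ho - 1) * stride - pad + (kh - 1) * dilation + 1
      wi <- (wo - 1) * stride - pad + (kw - 1) * dilation + 1
      if (hi >= 1 && hi <= d[1] && wi >= 1 && wi <= d[2])
        acc <- acc + x[hi, wi, ci] * w[kh, kw, ci, co]
    }
    y[ho, wo, co] <- acc
  }
  y
}

# expand a confusion matrix back into (true, pred) label pairs
cm_to_pairs <- function(cm) {
  true <- integer(); pred <- integer()
  K <- nrow(cm)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    n <- cm[i, j]
    if (n > 0) {
      true <- c(true, rep(i - 1L, n))
      pred <- c(pred, rep(j - 1L, n))
    }
  }
  list(true = true, pred = pred)
}

# metrics tallied directly from label pairs (percent scale)
pair_metrics <- function(true, pred, K) {
  acc <- 100 * mean(true == pred)
  prec <- rec <- f1 <- numeric(K)
  for (k in 0:(K - 1L)) {
    tp <- sum(true == k & pred == k)
    p <- if (sum(pred == k) > 0) tp / sum(pred == k) else 0
    r <- if (sum(true == k) > 0) tp / sum(true == k) else 0
    prec[k + 1L] <- 100 * p; rec[k + 1L] <- 100 * r
    f1[k + 1L] <- if (p + r > 0) 100 * 2 * p * r / (p + r) else 0
  }
  list(accuracy = acc, precision = prec, recall = rec, f1 = f1)
}

# AUC by exhaustive pair counting: P(s_pos > s_neg) + 0.5 P(tie)
pair_auc <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  if (length(sp) == 0 || length(sn) == 0) return(NA_real_)
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# tiny in-memory synthetic dataset shared by training tests
tiny_synth <- function(n_per_class = 50L, size = 64L, noise = 0,
                       seed = 123L) {
  generate_synthetic_dataset(
    synthetic_config(per_class_counts = rep(n_per_class, 5L),
                     image_size = size, noise_sd = noise, seed = seed))
}

scaled_fit <- function(kind, ds = tiny_synth(), epochs = 10L, seed = 1L) {
  sp <- stratified_split(ds, 0.9, seed = seed)
  fit <- shufflecerv(sp$train, sp$val,
                     model = model_config_small(attention_config(kind)),
                     control = train_control(epochs = epochs, seed = seed),
                     input_size = 64L, resize_to = NULL)
  list(fit = fit, split = sp)
}
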