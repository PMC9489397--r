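# Multiclass evaluation: confusion matrices, accuracy / precision / recall /
# F1 (percent), row normalization, one-vs-rest ROC AUC, repeated-run
# summaries.

#' Tally a confusion matrix from label pairs
#'
#' Rows are true classes, columns predicted classes, both 0-based.
#'
#' @param true,pred Integer label vectors (0-based).
#' @param num_classes Number of classes K (default: inferred).
#' @return K x K integer matrix of class `confusion_matrix` with label
#'   dimnames.
#' @export
confusion_matrix <- function(true, pred, num_classes = NULL) {
  if (length(true) != length(pred))
    stop("confusion_matrix: length mismatch")
  K <- if (is.null(num_classes)) max(true, pred) + 1L
       else as.integer(num_classes)
  cm <- matrix(0L, K, K, dimnames = list(true = as.character(0:(K - 1L)),
                                         pred = as.character(0:(K - 1L))))
  for (i in seq_along(true))
    cm[true[i] + 1L, pred[i] + 1L] <- cm[true[i] + 1L, pred[i] + 1L] + 1L
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Evaluate a fitted classifier on a dataset
#'
#' One prediction per record via the evaluation transform; counts are
#' accumulated at (true, predicted).
#'
#' @param object A `shufflecerv` fit.
#' @param ds An [image_dataset()].
#' @param batch_size Forward-pass batch size.
#' @return A `confusion_matrix`; the per-record probabilities are attached
#'   as `attr(, "prob")` and true labels as `attr(, "labels")` for ROC use.
#' @export
evaluate <- function(object, ds, batch_size = 32L) {
  stopifnot(inherits(object, "shufflecerv"), inherits(ds, "image_dataset"))
  p <- predict(object, ds, type = "both", batch_size = batch_size)
  cm <- confusion_matrix(ds$labels, p$class,
                         num_classes = object$config$num_classes)
  attr(cm, "prob") <- p$prob
  attr(cm, "labels") <- ds$labels
  cm
}

#' Per-class TP/FP/FN/TN marginalization
#'
#' For class `k`: TP is the diagonal cell, FP the rest of column `k`, FN the
#' rest of row `k`, TN everything else; the four always sum to the grand
#' total.
#'
#' @param cm Confusion matrix (rows true, columns predicted).
#' @param k Class label, 0-based.
#' @return Named vector `c(TP, FP, FN, TN)`.
#' @export
per_class_counts <- function(cm, k) {
  i <- as.integer(k) + 1L
  total <- sum(cm)
  TP <- cm[i, i]
  FP <- sum(cm[, i]) - TP
  FN <- sum(cm[i, ]) - TP
  c(TP = TP, FP = FP, FN = FN, TN = total - TP - FP - FN)
}

#' Classification metrics from a confusion matrix
#'
#' Percent-scale metrics: overall accuracy `100 * trace / total`; per class,
#' precision `100 * TP / (TP + FP)`, recall `100 * TP / (TP + FN)` and
#' F1 `100 * 2 P R / (P + R)` (computed on fractions).  Macro averages are
#' unweighted class means; micro averaging pools the counts, so micro
#' precision, micro recall and accuracy coincide for single-label
#' multiclass data.  A class with an empty denominator gets metric 0 with a
#' warning (`zero_division = "zero"`) or is dropped from the macro mean
#' (`"exclude"`).
#'
#' @param cm Confusion matrix.
#' @param zero_division `"zero"` or `"exclude"`.
#' @return Object of class `metrics_report`: list with `accuracy`,
#'   `per_class` data.frame, `macro_precision`, `macro_recall`, `macro_f1`,
#'   `micro_precision`, `micro_recall`, `micro_f1`.
#' @export
cm_metrics <- function(cm, zero_division = c("zero", "exclude")) {
  zero_division <- match.arg(zero_division)
  total <- sum(cm)
  if (total == 0) stop("cm_metrics: empty confusion matrix")
  K <- nrow(cm)
  prec <- rec <- f1 <- numeric(K)
  undef_p <- undef_r <- logical(K)
  for (i in seq_len(K)) {
    TP <- cm[i, i]
    colk <- sum(cm[, i]); rowk <- sum(cm[i, ])
    undef_p[i] <- colk == 0
    undef_r[i] <- rowk == 0
    p <- if (colk > 0) TP / colk else 0
    r <- if (rowk > 0) TP / rowk else 0
    prec[i] <- 100 * p
    rec[i] <- 100 * r
    f1[i] <- if (p + r > 0) 100 * 2 * p * r / (p + r) else 0
  }
  if (any(undef_p | undef_r))
    warning("cm_metrics: undefined precision/recall for some class(es)")
  keep <- if (zero_division == "exclude") !(undef_p | undef_r)
          else rep(TRUE, K)
  TPs <- sum(diag(cm))
  micro_p <- 100 * TPs / total
  per_class <- data.frame(class = rownames(cm) %||% as.character(0:(K - 1L)),
                          precision = prec, recall = rec, f1 = f1,
                          stringsAsFactors = FALSE)
  structure(list(accuracy = 100 * TPs / total,
                 per_class = per_class,
                 macro_precision = mean(prec[keep]),
                 macro_recall = mean(rec[keep]),
                 macro_f1 = mean(f1[keep]),
                 micro_precision = micro_p,
                 micro_recall = micro_p,
                 micro_f1 = micro_p),
            class = "metrics_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy: %.2f%%\n", x$accuracy))
  print(x$per_class, row.names = FALSE, digits = 4)
  cat(sprintf("macro  P/R/F1: %.2f / %.2f / %.2f\n",
              x$macro_precision, x$macro_recall, x$macro_f1))
  cat(sprintf("micro  P/R/F1: %.2f / %.2f / %.2f\n",
              x$micro_precision, x$micro_recall, x$micro_f1))
  invisible(x)
}

#' Row-normalize a confusion matrix
#'
#' Each row is divided by its sum, so the diagonal of the result equals
#' per-class recall (as a fraction).  Empty rows become all-zero and are
#' flagged in `attr(, "empty_rows")`.
#'
#' @param cm Confusion matrix.
#' @return Row-stochastic numeric matrix.
#' @export
normalize_cm <- function(cm) {
  rs <- rowSums(cm)
  out <- sweep(unclass(cm) + 0, 1L, ifelse(rs > 0, rs, 1), "/")
  out[rs == 0, ] <- 0
  attr(out, "empty_rows") <- which(rs == 0)
  out
}

#' One-vs-rest ROC AUC
#'
#' Per-class AUC via the midrank (Mann-Whitney) statistic — the probability
#' a random positive scores above a random negative, ties counted half —
#' equivalent to trapezoidal integration of the ROC curve.  Classes without
#' both a positive and a negative are skipped with a warning.  The macro
#' average is the unweighted mean over valid classes; the micro average
#' pools all binarized (score, indicator) pairs.
#'
#' @param scores N x K matrix of class scores/probabilities.
#' @param labels Integer true labels, 0-based.
#' @return List with `per_class` (length K, NA where skipped), `macro`,
#'   `micro`.
#' @export
roc_auc <- function(scores, labels) {
  if (!is.matrix(scores)) scores <- matrix(scores, ncol = 1L)
  K <- ncol(scores)
  n <- nrow(scores)
  if (length(labels) != n) stop("roc_auc: labels/scores length mismatch")
  auc1 <- function(s, pos) {
    np <- sum(pos); nn <- sum(!pos)
    if (np == 0L || nn == 0L) return(NA_real_)
    r <- rank(s, ties.method = "average")
    (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
  }
  per_class <- vapply(seq_len(K), function(k)
    auc1(scores[, k], labels == (k - 1L)), numeric(1))
  if (anyNA(per_class))
    warning("roc_auc: skipped class(es) without both positives and negatives")
  pooled_s <- as.vector(scores)
  pooled_pos <- as.vector(vapply(seq_len(K),
                                 function(k) labels == (k - 1L),
                                 logical(n)))
  list(per_class = per_class,
       macro = mean(per_class, na.rm = TRUE),
       micro = auc1(pooled_s, pooled_pos))
}

#' Repeated-run mean and standard deviation
#'
#' Runs `run_fn(seed)` for `n_runs` independent seeds; each call must return
#' a named numeric vector of metrics.  Summaries use the sample standard
#' deviation (n - 1 denominator); with a single run the sd is reported as
#' `NA`.
#'
#' @param n_runs Number of repeats.
#' @param run_fn Function of one argument (the seed).
#' @param seeds Optional explicit seeds (default `1:n_runs`).
#' @return data.frame with columns `metric`, `mean`, `sd`, plus the raw runs
#'   as `attr(, "runs")`.
#' @export
repeated_runs <- function(n_runs, run_fn, seeds = NULL) {
  if (is.null(seeds)) seeds <- seq_len(n_runs)
  stopifnot(length(seeds) == n_runs, n_runs >= 1L)
  runs <- do.call(rbind, lapply(seeds, function(s) run_fn(s)))
  out <- data.frame(metric = colnames(runs),
                    mean = apply(runs, 2L, mean),
                    sd = if (n_runs > 1L) apply(runs, 2L, sd)
                         else NA_real_,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "runs") <- runs
  out
}

#' Write evaluation artifacts to a run directory
#'
#' Confusion matrix, normalized matrix and metrics as CSV/JSON.
#'
#' @param cm A confusion matrix from [evaluate()].
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_eval_artifacts <- function(cm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(as.data.frame(unclass(cm)),
            file.path(dir, "confusion_matrix.csv"))
  write.csv(as.data.frame(normalize_cm(cm)),
            file.path(dir, "confusion_matrix_normalized.csv"))
  m <- cm_metrics(cm)
  jsonlite::write_json(
    list(accuracy = m$accuracy,
         per_class = m$per_class,
         macro = list(precision = m$macro_precision,
                      recall = m$macro_recall, f1 = m$macro_f1),
         micro = list(precision = m$micro_precision,
                      recall = m$micro_recall, f1 = m$micro_f1)),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(attr(cm, "prob"))) {
    auc <- roc_auc(attr(cm, "prob"), attr(cm, "labels"))
    jsonlite::write_json(auc, file.path(dir, "auc.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
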