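# Training recipe and the evaluation suite.

test_that("learning-rate schedules match their formulas", {
  ctl <- train_control(epochs = 100L)
  expect_equal(lr_at(0, ctl), 0.05)
  expect_equal(lr_at(100, ctl), 0)
  expect_equal(lr_at(50, ctl), 0.025)
  ctl2 <- train_control(epochs = 10L, lr_schedule = "constant")
  expect_equal(lr_at(7, ctl2), 0.05)
  ctl3 <- train_control(epochs = 10L, lr_schedule = "cosine")
  expect_equal(lr_at(5, ctl3), 0.025)
  expect_error(train_control(epochs = 0), "epochs")
})

test_that("SGD-Nesterov decreases the loss on a fixed batch", {
  set.seed(50)
  sc <- asNamespace("shufflecerv")
  net <- build_model(model_config(stem_channels = 8L,
                                  stage_repeats = c(1L, 1L),
                                  stage_channels = c(16L, 32L),
                                  final_channels = 64L))
  x <- array(rnorm(32 * 32 * 3 * 8), c(32, 32, 3, 8))
  y <- rep(0:3, 2)
  vel <- list()
  losses <- numeric(5)
  for (s in 1:5) {
    fw <- sc$model_forward(net, x, training = TRUE, keep_caches = TRUE)
    net <- fw$model
    ce <- sc$cross_entropy(fw$logits, y)
    losses[s] <- ce$loss
    gr <- sc$model_backward(net, fw$caches, ce$dlogits)
    for (nm in names(net$layers)) {
      if (is.null(gr[[nm]])) next
      r <- sc$sgd_update(net$layers[[nm]], gr[[nm]],
                         if (is.null(vel[[nm]])) list() else vel[[nm]],
                         0.05, 0.9, 1e-4)
      net$layers[[nm]] <- r$layer
      vel[[nm]] <- r$vel
    }
  }
  expect_true(all(diff(losses) < 0))
})

test_that("training is reproducible and guards against misuse", {
  ds <- tiny_synth(n_per_class = 4L, size = 32L, noise = 0.02, seed = 2L)
  ctl <- train_control(epochs = 2L, batch_size = 10L, seed = 3L)
  mc <- model_config(stem_channels = 8L, stage_repeats = c(1L, 1L),
                     stage_channels = c(16L, 32L), final_channels = 64L)
  f1 <- shufflecerv(ds, model = mc, control = ctl, input_size = 32L,
                    resize_to = NULL)
  f2 <- shufflecerv(ds, model = mc, control = ctl, input_size = 32L,
                    resize_to = NULL)
  expect_identical(f1$history, f2$history)
  expect_error(train_control(epochs = 0L), "epochs")
})

test_that("evaluate tallies one prediction per record", {
  # brute-force tally oracle on a hand prediction list
  true <- c(0L, 0L, 1L, 2L, 2L, 2L)
  pred <- c(0L, 1L, 1L, 2L, 0L, 2L)
  cm <- confusion_matrix(true, pred, 3L)
  expect_equal(sum(cm), 6)
  ref <- matrix(0L, 3, 3)
  for (i in seq_along(true))
    ref[true[i] + 1, pred[i] + 1] <- ref[true[i] + 1, pred[i] + 1] + 1L
  expect_equal(unclass(cm), ref, ignore_attr = TRUE)
  # perfect predictor: diagonal with class counts
  cmp <- confusion_matrix(true, true, 3L)
  expect_equal(unname(diag(cmp)), c(2L, 1L, 3L))
  expect_true(all(cmp[upper.tri(cmp) | lower.tri(cmp)] == 0))
})

test_that("per-class marginalization recovers TP/FP/FN/TN", {
  # rows true, cols pred: [[5,1],[2,3]] written row-wise
  cm <- matrix(c(5, 1, 2, 3), 2, 2, byrow = TRUE)
  counts <- per_class_counts(cm, 0)
  expect_equal(unname(counts), c(5, 2, 1, 3))
  for (k in 0:1)
    expect_equal(sum(per_class_counts(cm, k)), sum(cm))
  # diagonal matrix: no confusions
  dg <- diag(c(4, 6))
  expect_equal(unname(per_class_counts(dg, 0)[c("FP", "FN")]), c(0, 0))
})

test_that("metric formulas agree with the tally oracle on random matrices", {
  set.seed(51)
  for (rep in 1:300) {
    K <- sample(2:6, 1)
    cm <- matrix(rpois(K * K, lambda = sample(1:8, 1)), K, K)
    if (sum(cm) == 0) cm[1, 1] <- 1
    pr <- cm_to_pairs(cm)
    ref <- pair_metrics(pr$true, pr$pred, K)
    m <- suppressWarnings(cm_metrics(cm))
    expect_equal(m$accuracy, ref$accuracy, tolerance = 1e-12)
    expect_equal(m$per_class$precision, ref$precision, tolerance = 1e-12)
    expect_equal(m$per_class$recall, ref$recall, tolerance = 1e-12)
    expect_equal(m$per_class$f1, ref$f1, tolerance = 1e-12)
    expect_equal(m$macro_precision, mean(ref$precision), tolerance = 1e-12)
    # micro precision == micro recall == accuracy for single-label data
    expect_equal(m$micro_precision, m$accuracy)
    expect_equal(m$micro_recall, m$accuracy)
  }
  # worked 2x2 example: class-0 precision 71.43, recall 83.33, F1 76.92
  cm <- matrix(c(5, 1, 2, 3), 2, 2, byrow = TRUE)
  m <- cm_metrics(cm)
  expect_equal(round(m$per_class$precision[1], 2), 71.43)
  expect_equal(round(m$per_class$recall[1], 2), 83.33)
  expect_equal(round(m$per_class$f1[1], 2), 76.92)
  # perfect 5-class matrix
  mp <- cm_metrics(diag(5) * 3)
  expect_equal(mp$accuracy, 100)
  expect_equal(mp$macro_f1, 100)
})

test_that("normalized confusion matrix is row-stochastic with recall diagonal", {
  cm <- matrix(c(5, 1, 2, 3), 2, 2, byrow = TRUE)
  ncm <- normalize_cm(cm)
  expect_equal(ncm, matrix(c(5 / 6, 1 / 6, 0.4, 0.6), 2, 2, byrow = TRUE),
               tolerance = 1e-9, ignore_attr = TRUE)
  set.seed(52)
  cm2 <- matrix(rpois(25, 4), 5, 5)
  n2 <- normalize_cm(cm2)
  expect_equal(rowSums(n2), rep(1, 5), tolerance = 1e-9)
  m2 <- cm_metrics(cm2)
  expect_equal(diag(n2), m2$per_class$recall / 100, tolerance = 1e-12)
  # empty row flagged
  cm3 <- cm2; cm3[2, ] <- 0
  n3 <- normalize_cm(cm3)
  expect_equal(unname(n3[2, ]), rep(0, 5))
  expect_equal(unname(attr(n3, "empty_rows")), 2L)
})

test_that("midrank AUC equals the exhaustive pair-count oracle", {
  set.seed(53)
  for (rep in 1:30) {
    n <- sample(5:50, 1)
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(pos) || all(pos)) next
    a <- roc_auc(matrix(s, ncol = 1), ifelse(pos, 0L, 1L))
    expect_equal(a$per_class[1], pair_auc(s, pos), tolerance = 1e-12)
  }
  # perfectly separated scores
  sc <- c(rep(0.9, 5), rep(0.1, 5))
  lb <- c(rep(0L, 5), rep(1L, 5))
  expect_equal(roc_auc(matrix(sc, ncol = 1), lb)$per_class[1], 1)
  # label-independent scores hover near 1/2 (Mann-Whitney null)
  set.seed(54)
  n <- 4000
  s <- runif(n); lb <- sample(0:1, n, replace = TRUE)
  a <- roc_auc(cbind(s, 1 - s), lb)$per_class[1]
  np <- sum(lb == 0); nn <- n - np
  null_sd <- sqrt((np + nn + 1) / (12 * np * nn))
  expect_lt(abs(a - 0.5), 3 * null_sd)
  # degenerate class skipped with warning
  expect_warning(r <- roc_auc(cbind(runif(4), runif(4)), rep(0L, 4)),
                 "skipped")
  expect_true(is.na(r$per_class[2]))
})

test_that("midrank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(55)
  for (rep in 1:10) {
    n <- 60
    s <- runif(n)
    lab <- rbinom(n, 1, plogis(3 * (s - 0.5)))
    a <- roc_auc(cbind(1 - s, s), lab)$per_class[2]
    ref <- as.numeric(pROC::auc(pROC::roc(response = lab, predictor = s,
                                          levels = c(0, 1), direction = "<",
                                          quiet = TRUE)))
    expect_equal(a, ref, tolerance = 1e-12)
  }
})

test_that("repeated runs summarize with sample sd", {
  r <- repeated_runs(3, function(s) c(acc = c(80, 85, 90)[s]))
  expect_equal(r$mean[r$metric == "acc"], 85)
  expect_equal(r$sd[r$metric == "acc"], sd(c(80, 85, 90)))
  # identical deterministic runs: sd 0
  r2 <- repeated_runs(3, function(s) c(acc = 77))
  expect_equal(r2$sd, 0)
  # single run: sd undefined
  r1 <- repeated_runs(1, function(s) c(acc = 50))
  expect_true(is.na(r1$sd))
})

test_that("evaluation artifacts round-trip through disk", {
  cm <- structure(matrix(c(5L, 1L, 2L, 3L), 2, 2, byrow = TRUE),
                  class = c("confusion_matrix", "matrix"))
  attr(cm, "prob") <- matrix(runif(22), 11, 2)
  attr(cm, "labels") <- rep(0:1, c(6, 5))
  out <- tempfile("evalout")
  write_eval_artifacts(cm, out)
  back <- as.matrix(read.csv(file.path(out, "confusion_matrix.csv"),
                             row.names = 1))
  expect_equal(unname(back), unname(unclass(cm)[, ]))
  mj <- jsonlite::read_json(file.path(out, "metrics.json"),
                            simplifyVector = TRUE)
  expect_equal(mj$accuracy, cm_metrics(cm)$accuracy)
  unlink(out, recursive = TRUE)
})
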