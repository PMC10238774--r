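test_that("metric formulas reproduce direct arithmetic from counts", {
  # TP=8, FP=2, TN=5, FN=1
  labels <- c(rep(1, 9), rep(0, 7))
  pred <- c(rep(1, 8), 0, rep(1, 2), rep(0, 5))
  m <- compute_metrics(labels, pred)
  expect_equal(m$tp, 8); expect_equal(m$fp, 2)
  expect_equal(m$tn, 5); expect_equal(m$fn, 1)
  expect_equal(m$accuracy, 13 / 16)
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 8 / 9, tolerance = 1e-4)
  expect_equal(m$specificity, 5 / 7, tolerance = 1e-4)
  expect_equal(m$f1, 2 * 0.8 * (8 / 9) / (0.8 + 8 / 9))
  # internal consistency: F1 is the harmonic mean identity
  expect_equal(m$f1, 2 / (1 / m$precision + 1 / m$recall))
})

test_that("perfect predictions give unit metrics and kappa one", {
  labels <- rep(c(0, 1), 10)
  m <- compute_metrics(labels, labels, scores = labels)
  for (nm in c("accuracy", "precision", "recall", "f1", "specificity",
               "auc", "kappa"))
    expect_equal(m[[nm]], 1)
})

test_that("undefined ratios warn and yield NaN, never silent zero", {
  m <- NULL
  w <- capture_warnings(m <- compute_metrics(c(0, 0), c(0, 0)))
  expect_true(any(grepl("precision", w)))
  expect_true(is.nan(m$precision))
  expect_true(is.nan(m$recall))
  w2 <- capture_warnings(compute_metrics(c(1, 1), c(1, 1)))
  expect_true(any(grepl("specificity", w2)))
  expect_warning(roc_auc(c(1, 1), c(0.2, 0.3)), "one class")
})

test_that("kappa is chance-corrected: near zero for label-independent
           predictions", {
  set.seed(61)
  ks <- replicate(50, {
    labels <- rbinom(200, 1, 0.5)
    pred <- rbinom(200, 1, 0.5)
    compute_metrics(labels, pred, quiet = TRUE)$kappa
  })
  expect_lt(abs(mean(ks)), 0.05)
})

test_that("AUC is the concordant-pair probability, tie-aware and
           rank-invariant", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1)), 0.75)
  expect_equal(roc_auc(c(0, 1, 0, 1), c(0.1, 0.8, 0.2, 0.9)), 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  set.seed(62)
  labels <- rbinom(100, 1, 0.4)
  scores <- rnorm(100)
  a <- roc_auc(labels, scores)
  # strictly monotone transforms leave the AUC unchanged
  expect_equal(roc_auc(labels, exp(scores)), a)
  expect_equal(roc_auc(labels, 3 * scores - 7), a)
  # brute-force pair counting oracle
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  expect_equal(a, mean(pairs))
  # independent implementation cross-check
  skip_if_not_installed("pROC")
  expect_equal(a, as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                 quiet = TRUE,
                                                 direction = "<"))))
})

test_that("a zero learning rate leaves parameters untouched", {
  fx <- make_synth_fixture()
  model <- build_qcsa_network(
    qcsa_config(input_size = c(50L, 50L), block_widths = c(1L, 1L, 2L, 2L),
                attention = attention_config(reduction_ratio = 1L,
                                             spatial_kernel = 3L),
                seed = 2L))
  before <- qcsanet:::qcsa_state(model)
  fit <- train_qcsa(model, fx$manifest,
                    train_config(lr = 0, epochs = 1L, seed = 1L))
  after <- qcsanet:::qcsa_state(fit$model)
  for (i in seq_along(before))
    expect_equal(before[[i]]$par, after[[i]]$par, tolerance = 1e-12)
})

test_that("one epoch of training reduces the loss on a separable set and is
           seed-reproducible", {
  fx <- make_synth_fixture(counts = list(train = c(NORMAL = 16, PNEUMONIA = 16),
                                         val = c(NORMAL = 4, PNEUMONIA = 4)))
  cfg <- qcsa_config(input_size = c(50L, 50L), block_widths = c(1L, 2L, 2L, 4L),
                     attention = attention_config(reduction_ratio = 1L),
                     seed = 6L)
  run <- function() {
    model <- build_qcsa_network(cfg)
    tr <- load_split(fx$manifest, "train")
    # initial loss at the untrained parameters
    p0 <- predict(model, tr$x)
    l0 <- qcsanet:::bce_loss(qcsanet:::qlogis_safe(p0), tr$y,
                             rep(1, length(tr$y)))
    fit <- train_qcsa(model, fx$manifest, train_config(epochs = 2L, seed = 4L))
    list(l0 = l0, hist = fit$history, best = fit$best_epoch,
         state = qcsanet:::qcsa_state(fit$model))
  }
  r1 <- run()
  expect_lt(r1$hist$train_loss[2], r1$hist$train_loss[1])
  expect_equal(nrow(r1$hist), 2L)
  expect_true(all(c("train_loss", "val_loss", "train_f1", "val_f1")
                  %in% names(r1$hist)))
  r2 <- run()
  expect_identical(r1$hist, r2$hist)
  expect_equal(r1$state, r2$state, tolerance = 1e-15)
})

test_that("class weights reweight the loss by inverse frequency", {
  fx <- make_synth_fixture(counts = list(train = c(NORMAL = 4, PNEUMONIA = 12),
                                         val = c(NORMAL = 2, PNEUMONIA = 2)))
  w <- balance(fx$manifest[fx$manifest$split == "train", ])
  expect_equal(unname(w["PNEUMONIA"]), 16 / 24)
  model <- build_qcsa_network(
    qcsa_config(input_size = c(50L, 50L), block_widths = c(1L, 1L, 1L, 1L),
                attention = NULL, seed = 3L))
  fit <- train_qcsa(model, fx$manifest, train_config(epochs = 1L, seed = 2L),
                    class_weights = w)
  expect_equal(nrow(fit$history), 1L)
})

test_that("the architecture comparison emits the ten-column table", {
  fx <- make_synth_fixture(counts = list(train = c(NORMAL = 12, PNEUMONIA = 12),
                                         val = c(NORMAL = 4, PNEUMONIA = 4),
                                         test = c(NORMAL = 6, PNEUMONIA = 6)))
  cfg <- qcsa_config(input_size = c(50L, 50L), block_widths = c(1L, 1L, 2L, 2L),
                     attention = attention_config(reduction_ratio = 1L),
                     seed = 5L)
  res <- compare_architectures(fx$manifest, cfg,
                               train_config(epochs = 1L, seed = 5L))
  expect_equal(nrow(res$table), 2L)
  expect_named(res$table,
               c("architecture", "epochs", "total_parameters",
                 "trainable_parameters", "test_accuracy", "precision",
                 "recall", "f1", "auc", "kappa"))
  expect_false(any(is.na(res$table$test_accuracy)))
  # attention adds parameters relative to the plain twin (parameterized mode)
  expect_gt(res$table$trainable_parameters[2], res$table$trainable_parameters[1])
})

test_that("attention gate maps export as grayscale images", {
  model <- build_qcsa_network(
    qcsa_config(input_size = c(16L, 16L), block_widths = c(1L, 1L, 2L, 2L),
                attention = attention_config(reduction_ratio = 1L,
                                             spatial_kernel = 3L),
                seed = 8L))
  img <- matrix(runif(16 * 16), 16, 16)
  dir <- withr::local_tempdir()
  paths <- export_attention_maps(model, img, dir)
  expect_length(paths, 8L)
  expect_true(all(file.exists(paths)))
  g <- png::readPNG(paths[1])
  expect_true(all(g >= 0 & g <= 1))
})
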