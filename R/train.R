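# Training loop (Adam, binary cross-entropy) and the binary-classifier
# metric suite.

#' Training configuration
#'
#' Defaults: Adam with learning rate 0.001 and per-step decay 1e-6
#' (effective rate `lr / (1 + decay * step)`), batch size 16, 40 epochs,
#' binary cross-entropy loss.
#'
#' @param lr Learning rate.
#' @param decay Per-step learning-rate decay.
#' @param batch_size Mini-batch size.
#' @param epochs Number of epochs.
#' @param beta1,beta2,eps Adam moment coefficients.
#' @param seed Seed controlling shuffling (and nothing else; model
#'   parameters are seeded by the model config).
#' @return A list of class `train_config`.
#' @export
train_config <- function(lr = 0.001, decay = 1e-6, batch_size = 16L,
                         epochs = 40L, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8, seed = 1L) {
  stopifnot(lr >= 0, decay >= 0, batch_size >= 1, epochs >= 1)
  structure(list(optimizer = "adam", loss = "binary cross-entropy",
                 lr = lr, decay = decay, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), beta1 = beta1, beta2 = beta2,
                 eps = eps, seed = as.integer(seed)),
            class = "train_config")
}

bce_loss <- function(logit, y, w) {
  # stable: log(1 + exp(-|l|)) + max(l, 0) - l*y
  l <- logit
  mean(w * (pmax(l, 0) - l * y + log1p(exp(-abs(l)))))
}

adam_step <- function(layers, cfg, t) {
  lr_t <- cfg$lr / (1 + cfg$decay * t)
  corr <- sqrt(1 - cfg$beta2^t) / (1 - cfg$beta1^t)
  for (ly in layers) {
    if (length(ly$par) == 0L) next
    if (is.null(ly$opt)) ly$opt <- list()
    for (nm in names(ly$par)) {
      g <- ly$grad[[nm]]
      if (is.null(g)) next
      st <- ly$opt[[nm]]
      if (is.null(st)) st <- list(m = g * 0, v = g * 0)
      st$m <- cfg$beta1 * st$m + (1 - cfg$beta1) * g
      st$v <- cfg$beta2 * st$v + (1 - cfg$beta2) * g^2
      ly$opt[[nm]] <- st
      ly$par[[nm]] <- ly$par[[nm]] - lr_t * corr * st$m / (sqrt(st$v) + cfg$eps)
    }
  }
}

#' Train a QCSA network
#'
#' Seeded shuffled mini-batches, sigmoid + binary cross-entropy (optionally
#' class-weighted), per-epoch train and validation metrics, and a
#' best-validation-loss checkpoint: training runs the full epoch budget and
#' the returned model carries the parameters of the epoch with the lowest
#' validation loss.
#'
#' @param model A `qcsa_network`.
#' @param data Either a `dataset_manifest` with train and val splits (images
#'   are loaded and encoded via [load_split()]) or a list
#'   `list(x, y, xval, yval)` of pre-encoded `qfmap` batches and 0/1 labels.
#' @param cfg A [train_config()].
#' @param class_weights Optional `c(PNEUMONIA = , NORMAL = )` loss weights,
#'   e.g. from [balance()].
#' @param preprocess_cfg Used when `data` is a manifest.
#' @param verbose Print one line per epoch?
#' @param stop_val_acc Optional early-exit threshold: stop after the first
#'   epoch whose validation accuracy reaches this value (the epoch budget in
#'   `cfg` remains the upper bound).
#' @return List with `model` (best checkpoint) and `history` (one row per
#'   epoch: train/val loss, accuracy, precision, recall, f1).
#' @export
train_qcsa <- function(model, data, cfg = train_config(), class_weights = NULL,
                       preprocess_cfg = preprocess_config(), verbose = FALSE,
                       stop_val_acc = NULL) {
  if (inherits(data, "dataset_manifest")) {
    tr <- load_split(data, "train", preprocess_cfg)
    va <- load_split(data, "val", preprocess_cfg)
    data <- list(x = tr$x, y = tr$y, xval = va$x, yval = va$y)
  }
  x <- unclass(data$x); y <- data$y
  n <- dim(x)[4]
  if (n == 0L) stop("empty train split")
  wts <- rep(1, n)
  if (!is.null(class_weights))
    wts <- ifelse(y == 1L, class_weights[["PNEUMONIA"]],
                  class_weights[["NORMAL"]])
  layers <- qcsa_layers(model)
  hist <- list()
  best <- list(val_loss = Inf, state = NULL, epoch = NA_integer_)
  step <- 0L
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(n)
    tr_loss <- 0; tr_probs <- numeric(n); tr_y <- y[ord]
    done <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      xb <- x[, , , idx, drop = FALSE]
      yb <- y[idx]; wb <- wts[idx]
      logit <- qcsa_forward(model, xb, training = TRUE)
      p <- sigmoid(logit)
      tr_loss <- tr_loss + bce_loss(logit, yb, wb) * length(idx)
      tr_probs[(done + 1L):(done + length(idx))] <- p
      done <- done + length(idx)
      step <- step + 1L
      dlogit <- wb * (p - yb) / length(idx)
      qcsa_backward(model, dlogit)
      adam_step(layers, cfg, step)
    }
    tr_m <- compute_metrics(tr_y, as.integer(tr_probs >= 0.5), quiet = TRUE)
    val_probs <- predict(model, data$xval)
    val_logit <- qlogis_safe(val_probs)
    val_loss <- bce_loss(val_logit, data$yval, rep(1, length(data$yval)))
    val_m <- compute_metrics(data$yval, as.integer(val_probs >= 0.5),
                             quiet = TRUE)
    hist[[epoch]] <- data.frame(
      epoch = epoch, train_loss = tr_loss / n, val_loss = val_loss,
      train_accuracy = tr_m$accuracy, val_accuracy = val_m$accuracy,
      train_precision = tr_m$precision, val_precision = val_m$precision,
      train_recall = tr_m$recall, val_recall = val_m$recall,
      train_f1 = tr_m$f1, val_f1 = val_m$f1)
    if (val_loss < best$val_loss)
      best <- list(val_loss = val_loss, state = qcsa_state(model),
                   epoch = epoch)
    if (verbose)
      message(sprintf(
        "epoch %2d  train loss %.4f acc %.3f | val loss %.4f acc %.3f",
        epoch, tr_loss / n, tr_m$accuracy, val_loss, val_m$accuracy))
    if (!is.null(stop_val_acc) && !is.na(val_m$accuracy) &&
        val_m$accuracy >= stop_val_acc) break
  }
  if (!is.null(best$state)) qcsa_set_state(model, best$state)
  list(model = model, history = do.call(rbind, hist),
       best_epoch = best$epoch)
}

qlogis_safe <- function(p, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  log(p / (1 - p))
}

#' Binary classification metrics from labels and predictions
#'
#' Positive class is pneumonia (label 1). Computes the confusion counts and
#' accuracy `(TP+TN)/total`, precision `TP/(TP+FP)`, recall (sensitivity)
#' `TP/(TP+FN)`, F1 `2PR/(P+R)`, specificity `TN/(TN+FP)`, rank-based ROC
#' AUC (when scores are supplied), and Cohen's kappa
#' `(p_o - p_e)/(1 - p_e)`. A zero denominator yields `NaN` with a warning,
#' never a silent 0.
#'
#' @param labels True 0/1 labels.
#' @param predicted Predicted 0/1 labels.
#' @param scores Optional real scores for the AUC (higher = more positive).
#' @param quiet Suppress the zero-denominator warnings.
#' @return A list of class `metrics_report`.
#' @export
compute_metrics <- function(labels, predicted, scores = NULL, quiet = FALSE) {
  stopifnot(length(labels) == length(predicted),
            all(labels %in% 0:1), all(predicted %in% 0:1))
  tp <- sum(labels == 1 & predicted == 1)
  tn <- sum(labels == 0 & predicted == 0)
  fp <- sum(labels == 0 & predicted == 1)
  fn <- sum(labels == 1 & predicted == 0)
  ratio <- function(num, den, what) {
    if (den == 0) {
      if (!quiet) warning(what, " undefined: zero denominator", call. = FALSE)
      return(NaN)
    }
    num / den
  }
  precision <- ratio(tp, tp + fp, "precision")
  recall <- ratio(tp, tp + fn, "recall")
  f1 <- if (is.nan(precision) || is.nan(recall) || precision + recall == 0) {
    if (!quiet) warning("F1 undefined", call. = FALSE)
    NaN
  } else 2 * precision * recall / (precision + recall)
  n <- tp + tn + fp + fn
  po <- (tp + tn) / n
  pe <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / n^2
  kappa <- if (pe == 1) {
    if (!quiet) warning("kappa undefined: expected agreement is 1", call. = FALSE)
    NaN
  } else (po - pe) / (1 - pe)
  auc <- if (!is.null(scores)) roc_auc(labels, scores, quiet = quiet) else NA_real_
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 accuracy = po, precision = precision, recall = recall,
                 f1 = f1,
                 specificity = ratio(tn, tn + fp, "specificity"),
                 auc = auc, kappa = kappa),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("confusion  TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  for (nm in c("accuracy", "precision", "recall", "f1", "specificity",
               "auc", "kappa"))
    cat(sprintf("%-12s %.4f\n", nm, x[[nm]]))
  invisible(x)
}

#' Rank-based ROC AUC
#'
#' The Mann-Whitney statistic: the probability that a uniformly drawn
#' positive outranks a uniformly drawn negative, ties counting one half.
#' Invariant under any strictly monotone transform of the scores.
#'
#' @param labels 0/1 labels.
#' @param scores Real scores, higher meaning more positive.
#' @param quiet Suppress the single-class warning.
#' @return AUC in \[0, 1\], or `NaN` (with a warning) if only one class is
#'   present.
#' @export
roc_auc <- function(labels, scores, quiet = FALSE) {
  stopifnot(length(labels) == length(scores))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    if (!quiet) warning("AUC undefined: only one class present", call. = FALSE)
    return(NaN)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Train and compare the attention and attention-free architectures
#'
#' Builds the QCSA network and its attention-free twin from the same seed
#' and hyperparameters, trains both on the same data, evaluates on the test
#' split, and returns a two-row comparison table (architecture, epochs,
#' parameter counts, test accuracy, precision, recall, F1, AUC, kappa).
#'
#' @param manifest A `dataset_manifest` with train/val/test splits, or a
#'   list `list(train = list(x, y), val = ..., test = ...)` of pre-encoded
#'   batches.
#' @param model_cfg A [qcsa_config()] (its `attention` field defines the
#'   attention row; the twin drops it).
#' @param train_cfg A [train_config()].
#' @param preprocess_cfg Used when `manifest` is a manifest.
#' @param verbose,stop_val_acc Passed to [train_qcsa()].
#' @return List with `reports` (two `metrics_report`s), `table` (the
#'   comparison data frame) and `histories`.
#' @export
compare_architectures <- function(manifest, model_cfg = qcsa_miniature_config(),
                                  train_cfg = train_config(),
                                  preprocess_cfg = preprocess_config(),
                                  verbose = FALSE, stop_val_acc = NULL) {
  if (inherits(manifest, "dataset_manifest")) {
    manifest <- list(train = load_split(manifest, "train", preprocess_cfg),
                     val = load_split(manifest, "val", preprocess_cfg),
                     test = load_split(manifest, "test", preprocess_cfg))
  }
  data <- list(x = manifest$train$x, y = manifest$train$y,
               xval = manifest$val$x, yval = manifest$val$y)
  cfg_plain <- model_cfg
  cfg_plain$attention <- NULL
  rows <- list(); reports <- list(); histories <- list()
  for (variant in c("quaternion residual network",
                    "quaternion residual attention network")) {
    cfg <- if (variant == "quaternion residual network") cfg_plain else model_cfg
    model <- build_qcsa_network(cfg)
    fit <- train_qcsa(model, data, train_cfg, verbose = verbose,
                      stop_val_acc = stop_val_acc)
    probs <- predict(fit$model, manifest$test$x)
    rep_ <- compute_metrics(manifest$test$y, as.integer(probs >= 0.5),
                            scores = probs, quiet = TRUE)
    cnt <- count_parameters(model)
    rows[[variant]] <- data.frame(
      architecture = variant, epochs = train_cfg$epochs,
      total_parameters = unname(cnt["total"]),
      trainable_parameters = unname(cnt["trainable"]),
      test_accuracy = rep_$accuracy, precision = rep_$precision,
      recall = rep_$recall, f1 = rep_$f1, auc = rep_$auc,
      kappa = rep_$kappa, stringsAsFactors = FALSE)
    reports[[variant]] <- rep_
    histories[[variant]] <- fit$history
  }
  list(reports = reports,
       table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       histories = histories)
}

#' Export attention gate maps of one image as grayscale PNGs
#'
#' Runs a forward pass and writes, per residual block, the spatial gate as
#' an image and the channel gate as a one-row strip, for visual inspection
#' of what the network attends to.
#'
#' @param model A `qcsa_network` built with attention.
#' @param image A preprocessed \[0, 1\] image matrix.
#' @param dir Output directory.
#' @return Invisibly, the written file paths.
#' @export
export_attention_maps <- function(model, image, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  x <- unclass(encode_image(image))
  h <- nn_forward(model$stem$conv, x)
  h <- nn_forward(model$stem$bn, h)
  h <- nn_forward(model$stem$relu, h)
  paths <- character(0)
  for (b in seq_along(model$blocks)) {
    blk <- model$blocks[[b]]
    if (is.null(blk$chatt)) stop("model was built without attention")
    hh <- nn_forward(blk$conv1, h); hh <- nn_forward(blk$bn1, hh)
    hh <- nn_forward(blk$relu1, hh); hh <- nn_forward(blk$conv2, hh)
    hh <- nn_forward(blk$bn2, hh)
    nn_forward(blk$chatt, hh, training = TRUE)
    cg <- blk$chatt$cache$gate
    hh2 <- nn_forward(blk$chatt, hh)
    nn_forward(blk$spatt, hh2, training = TRUE)
    sg <- blk$spatt$cache$gate
    d <- dim(hh2)
    p1 <- file.path(dir, sprintf("block%d_spatial_gate.png", b))
    png::writePNG(matrix(sg, d[1], d[2]), p1)
    p2 <- file.path(dir, sprintf("block%d_channel_gate.png", b))
    png::writePNG(matrix(as.numeric(cg), nrow = 1L), p2)
    paths <- c(paths, p1, p2)
    h <- block_forward(blk, h, FALSE)
  }
  invisible(paths)
}
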