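# The QCSA classifier: a quaternion stem convolution, four quaternion
# residual blocks each carrying a channel-attention and a spatial-attention
# gate, global average pooling, and a real dense sigmoid head for binary
# classification.
#
# Block layout (widths in quaternion channels):
#   conv(3x3, stride s) -> BN -> ReLU -> conv(3x3) -> BN -> [attention]
#   -> + skip (1x1 conv + BN projection when width or stride changes)
#   -> ReLU
# Blocks 2-4 downsample 2x via stride on their first convolution.

#' Model configuration
#'
#' @param input_size Integer (H, W) of the input images; both must be >= 8.
#' @param block_widths Quaternion-channel widths of the four residual
#'   blocks. Default `c(8, 16, 32, 64)`.
#' @param conv_variant Only `"hamilton"` is used inside the model; the
#'   rotation form is available as the standalone op [rotation_conv2d()].
#' @param attention An [attention_config()], or `NULL` to build the
#'   attention-free twin network.
#' @param head `"flatten"`: global-average-pooled quaternion components feed
#'   a real dense layer; `"quaternion-norm"`: per-quaternion magnitudes feed
#'   the dense layer.
#' @param init Weight initialization scheme for the quaternion convolutions.
#' @param seed Integer seed; fully determines the initial parameters.
#' @return A list of class `qcsa_config`.
#' @export
qcsa_config <- function(input_size = c(50L, 50L),
                        block_widths = c(8L, 16L, 32L, 64L),
                        conv_variant = "hamilton",
                        attention = attention_config(),
                        head = c("flatten", "quaternion-norm"),
                        init = "quaternion-polar",
                        seed = 1L) {
  head <- match.arg(head)
  if (length(block_widths) != 4L)
    stop("config field 'block_widths' must list exactly 4 block widths")
  if (length(input_size) != 2L || any(input_size < 8L))
    stop("config field 'input_size' must be two integers >= 8")
  if (!identical(conv_variant, "hamilton"))
    stop("config field 'conv_variant' must be \"hamilton\" inside the model")
  if (!is.null(attention) && !inherits(attention, "attention_config"))
    stop("config field 'attention' must be an attention_config() or NULL")
  structure(list(input_size = as.integer(input_size),
                 block_widths = as.integer(block_widths),
                 conv_variant = conv_variant, attention = attention,
                 head = head, init = init, seed = as.integer(seed),
                 num_classes = 2L),
            class = "qcsa_config")
}

#' A small configuration for desk-scale experiments
#'
#' Widths `c(2, 4, 8, 16)` quaternion channels with a reduction-ratio-2
#' attention bottleneck: small enough to train in seconds per epoch on one
#' CPU at 50 x 50 input while retaining the full four-block
#' residual-attention structure.
#'
#' @param seed Integer seed.
#' @param attention `TRUE` for the attention-augmented network (default),
#'   `FALSE` for the attention-free twin.
#' @param parameterized Passed to [attention_config()].
#' @return A `qcsa_config`.
#' @export
qcsa_miniature_config <- function(seed = 1L, attention = TRUE,
                                  parameterized = TRUE) {
  qcsa_config(input_size = c(50L, 50L), block_widths = c(2L, 4L, 8L, 16L),
              attention = if (attention)
                attention_config(reduction_ratio = 2L,
                                 parameterized = parameterized)
              else NULL,
              seed = seed)
}

build_resblock <- function(in_q, out_q, stride, cfg, att_seed) {
  att <- cfg$attention
  block <- list(conv1 = ly_qconv(in_q, out_q, 3L, stride, cfg$init),
                bn1 = ly_bn(4L * out_q),
                relu1 = ly_relu(),
                conv2 = ly_qconv(out_q, out_q, 3L, 1L, cfg$init),
                bn2 = ly_bn(4L * out_q))
  if (in_q != out_q || stride != 1L) {
    block$proj <- ly_qconv(in_q, out_q, 1L, stride, cfg$init, bias = FALSE)
    block$bnp <- ly_bn(4L * out_q)
  }
  if (!is.null(att)) {
    # attention parameters are drawn from their own derived stream so that
    # the attention-free twin of the same seed has identical conv weights
    block[c("chatt", "spatt")] <- with_seed(att_seed, list(
      ly_chatt(4L * out_q, att), ly_spatt(4L * out_q, att)))
  }
  block$relu_out <- ly_relu()
  structure(block, class = "qcsa_block", order = if (is.null(att)) NULL else att$order)
}

block_forward <- function(blk, x, training) {
  h <- nn_forward(blk$conv1, x, training)
  h <- nn_forward(blk$bn1, h, training)
  h <- nn_forward(blk$relu1, h, training)
  h <- nn_forward(blk$conv2, h, training)
  h <- nn_forward(blk$bn2, h, training)
  if (!is.null(blk$chatt)) {
    seqn <- if (identical(attr(blk, "order"), "spatial-channel"))
      c("spatt", "chatt") else c("chatt", "spatt")
    for (nm in seqn) h <- nn_forward(blk[[nm]], h, training)
  }
  s <- if (!is.null(blk$proj)) {
    nn_forward(blk$bnp, nn_forward(blk$proj, x, training), training)
  } else x
  nn_forward(blk$relu_out, h + s, training)
}

block_backward <- function(blk, dy) {
  dsum <- nn_backward(blk$relu_out, dy)
  dh <- dsum
  ds <- dsum
  if (!is.null(blk$chatt)) {
    seqn <- if (identical(attr(blk, "order"), "spatial-channel"))
      c("chatt", "spatt") else c("spatt", "chatt")
    for (nm in seqn) dh <- nn_backward(blk[[nm]], dh)
  }
  dh <- nn_backward(blk$bn2, dh)
  dh <- nn_backward(blk$conv2, dh)
  dh <- nn_backward(blk$relu1, dh)
  dh <- nn_backward(blk$bn1, dh)
  dx <- nn_backward(blk$conv1, dh)
  if (!is.null(blk$proj)) {
    ds <- nn_backward(blk$bnp, ds)
    ds <- nn_backward(blk$proj, ds)
  }
  dx + ds
}

block_layers <- function(blk) Filter(function(l) inherits(l, "qlayer"), blk)

#' Build a QCSA network
#'
#' Stem quaternion convolution, four residual(-attention) blocks with 2x
#' downsampling in blocks 2-4, global average pooling, head transition, and
#' a single-unit real dense layer with sigmoid output. Deterministic under
#' `cfg$seed`: the same seed and config give bit-identical parameters.
#'
#' @param cfg A [qcsa_config()].
#' @return An object of class `qcsa_network`.
#' @export
build_qcsa_network <- function(cfg) {
  stopifnot(inherits(cfg, "qcsa_config"))
  w <- cfg$block_widths
  net <- with_seed(cfg$seed, {
    stem <- list(conv = ly_qconv(1L, w[1], 3L, 1L, cfg$init, first = TRUE),
                 bn = ly_bn(4L * w[1]),
                 relu = ly_relu())
    blocks <- lapply(1:4, function(b) {
      build_resblock(if (b == 1L) w[1] else w[b - 1L], w[b],
                     if (b == 1L) 1L else 2L, cfg,
                     att_seed = (cfg$seed %% 65536L) * 16384L + b)
    })
    n_feat <- if (cfg$head == "flatten") 4L * w[4] else w[4]
    list(stem = stem, blocks = blocks, gap = ly_gap(),
         head = ly_dense(n_feat, 1L))
  })
  structure(list(stem = net$stem, blocks = net$blocks, gap = net$gap,
                 head = net$head, config = cfg),
            class = "qcsa_network")
}

qcsa_layers <- function(model) {
  c(list(model$stem$conv, model$stem$bn),
    unlist(lapply(model$blocks, block_layers), use.names = FALSE),
    list(model$head))
}

#' @export
count_parameters.qcsa_network <- function(x) {
  counts <- vapply(qcsa_layers(x), count_parameters, c(total = 0, trainable = 0))
  c(total = sum(counts["total", ]), trainable = sum(counts["trainable", ]))
}

qcsa_forward <- function(model, x, training = FALSE) {
  h <- nn_forward(model$stem$conv, x, training)
  h <- nn_forward(model$stem$bn, h, training)
  h <- nn_forward(model$stem$relu, h, training)
  for (blk in model$blocks) h <- block_forward(blk, h, training)
  feats <- nn_forward(model$gap, h, training)          # (C, N)
  if (model$config$head == "quaternion-norm") {
    C <- nrow(feats)
    fq <- feats; dim(fq) <- c(4L, C %/% 4L, ncol(feats))
    qn <- sqrt(colSums(fq^2) + 1e-12)
    model$head$.norm_cache <- list(fq = fq, qn = qn)
    feats <- matrix(qn, C %/% 4L, ncol(feats))
  }
  logit <- nn_forward(model$head, feats, training)     # (1, N)
  drop(logit)
}

qcsa_backward <- function(model, dlogit) {
  dfeats <- nn_backward(model$head, matrix(dlogit, nrow = 1L))
  if (model$config$head == "quaternion-norm") {
    hc <- model$head$.norm_cache
    dq <- array(rep(as.numeric(dfeats) / as.numeric(hc$qn), each = 4L),
                dim(hc$fq)) * hc$fq
    dfeats <- matrix(dq, nrow = 4L * dim(hc$fq)[2])
  }
  dh <- nn_backward(model$gap, dfeats)
  for (blk in rev(model$blocks)) dh <- block_backward(blk, dh)
  dh <- nn_backward(model$stem$relu, dh)
  dh <- nn_backward(model$stem$bn, dh)
  nn_backward(model$stem$conv, dh)
  invisible(NULL)
}

#' Predict class probabilities
#'
#' Batched, order-preserving forward pass in evaluation mode (batch-norm
#' running statistics). Probabilities are the sigmoid head output in (0, 1);
#' the predicted class is positive (pneumonia-like) when probability >= 0.5.
#'
#' @param object A `qcsa_network`.
#' @param images A `qfmap` batch (H, W, 4, N), or a list of \[0, 1\] image
#'   matrices which are encoded with [encode_batch()].
#' @param batch_size Forward-pass batch size.
#' @param ... Unused.
#' @return Numeric vector of probabilities, one per image.
#' @export
predict.qcsa_network <- function(object, images, batch_size = 32L, ...) {
  if (is.list(images) && !is.array(images)) images <- encode_batch(images)
  x <- unclass(qfmap(images))
  d <- dim(x)
  hw <- object$config$input_size
  if (d[1] != hw[1] || d[2] != hw[2] || d[3] != 4L)
    stop("expected input of size (", hw[1], ", ", hw[2], ", 4, N), got (",
         paste(d, collapse = ", "), ")")
  n <- d[4]
  probs <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    logit <- qcsa_forward(object, x[, , , idx, drop = FALSE], training = FALSE)
    probs[idx] <- sigmoid(logit)
  }
  probs
}

#' Force every attention gate in a network to a constant
#'
#' Ablation hook: with all gates forced to 1 the network computes exactly
#' the same function as its attention-free twin (same seed). `NULL` restores
#' learned gating.
#'
#' @param model A `qcsa_network`.
#' @param value Constant gate value in (0, 1\], or `NULL` to unforce.
#' @return The model, invisibly (layers are mutated in place).
#' @export
force_attention_gates <- function(model, value = 1) {
  for (blk in model$blocks) {
    if (!is.null(blk$chatt)) {
      blk$chatt$force <- value
      blk$spatt$force <- value
    }
  }
  invisible(model)
}

#' Per-layer parameter table
#'
#' @param model A `qcsa_network`.
#' @return A data frame with one row per layer: name, kind, total and
#'   trainable parameter counts.
#' @export
inspect_qcsa <- function(model) {
  rows <- list(c(name = "stem.conv", kind = "qconv"),
               c(name = "stem.bn", kind = "bn"))
  lys <- list(model$stem$conv, model$stem$bn)
  for (b in seq_along(model$blocks)) {
    blk <- model$blocks[[b]]
    for (nm in names(blk)) {
      if (!inherits(blk[[nm]], "qlayer")) next
      rows[[length(rows) + 1L]] <- c(name = paste0("block", b, ".", nm),
                                     kind = blk[[nm]]$kind)
      lys[[length(lys) + 1L]] <- blk[[nm]]
    }
  }
  rows[[length(rows) + 1L]] <- c(name = "head.dense", kind = "dense")
  lys[[length(lys) + 1L]] <- model$head
  counts <- t(vapply(lys, count_parameters, c(total = 0, trainable = 0)))
  df <- data.frame(do.call(rbind, rows), counts, row.names = NULL,
                   stringsAsFactors = FALSE)
  df$total <- as.integer(df$total)
  df$trainable <- as.integer(df$trainable)
  df
}

# snapshot / restore all parameters and buffers (used for best-checkpoint
# tracking and for save/load)
qcsa_state <- function(model) {
  lapply(qcsa_layers(model), function(ly) list(par = ly$par, buf = ly$buf))
}

qcsa_set_state <- function(model, state) {
  lys <- qcsa_layers(model)
  stopifnot(length(lys) == length(state))
  for (i in seq_along(lys)) {
    lys[[i]]$par <- state[[i]]$par
    lys[[i]]$buf <- state[[i]]$buf
  }
  invisible(model)
}

#' Save / load a trained network
#'
#' The checkpoint is a plain R list: the `qcsa_config` plus one entry per
#' layer holding its parameter arrays (quaternion components in
#' (r, x, y, z) order) and buffers.
#'
#' @param model A `qcsa_network`.
#' @param path File path.
#' @return `load_qcsa` returns the restored `qcsa_network`.
#' @export
save_qcsa <- function(model, path) {
  saveRDS(list(config = model$config, state = qcsa_state(model),
               component_order = c("r", "x", "y", "z")), path)
}

#' @rdname save_qcsa
#' @export
load_qcsa <- function(path) {
  obj <- readRDS(path)
  model <- build_qcsa_network(obj$config)
  qcsa_set_state(model, obj$state)
  model
}
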