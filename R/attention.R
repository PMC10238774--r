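# Channel and spatial attention.
#
# Channel attention squeezes each attended channel to two global descriptors
# (spatial average pool and spatial max pool), maps them through a shared
# two-layer bottleneck (or, in parameter-free mode, standardizes and sums
# them), and applies a sigmoid; the resulting per-channel gate in (0, 1)
# reweights the feature map. Spatial attention pools along the channel axis
# (mean and max), runs the two pooled maps through a single k x k
# convolution (or a fixed uniform filter in parameter-free mode), and
# applies a sigmoid to obtain a per-pixel gate. With granularity
# "per-quaternion-channel" the four real components of a quaternion channel
# share one channel-gate value, so a quaternion is gated as a unit.

#' Attention configuration
#'
#' @param reduction_ratio Bottleneck ratio of the shared channel MLP; must
#'   divide the attended channel count. Default 8, a standard setting for
#'   channel-spatial gating.
#' @param spatial_kernel Odd kernel size of the spatial-attention
#'   convolution. Default 7.
#' @param parameterized If `TRUE` the gates carry learnable parameters
#'   (bottleneck MLP + spatial convolution). If `FALSE` both gates are
#'   parameter-free: standardized descriptor sums and a fixed uniform
#'   spatial filter, adding exactly zero learnable parameters.
#' @param granularity `"per-quaternion-channel"` (one gate per quaternion,
#'   shared across its four components) or `"per-real-channel"`.
#' @param order Gate application order; default channel then spatial.
#' @return A list of class `attention_config`.
#' @export
attention_config <- function(reduction_ratio = 8L, spatial_kernel = 7L,
                             parameterized = TRUE,
                             granularity = c("per-quaternion-channel",
                                             "per-real-channel"),
                             order = c("channel-spatial", "spatial-channel")) {
  granularity <- match.arg(granularity)
  order <- match.arg(order)
  if (spatial_kernel %% 2L == 0L) stop("spatial_kernel must be odd")
  if (reduction_ratio < 1L) stop("reduction_ratio must be a positive integer")
  structure(list(reduction_ratio = as.integer(reduction_ratio),
                 spatial_kernel = as.integer(spatial_kernel),
                 parameterized = isTRUE(parameterized),
                 granularity = granularity, order = order),
            class = "attention_config")
}

att_group <- function(cfg) if (cfg$granularity == "per-quaternion-channel") 4L else 1L

# expand a per-quaternion gate (Cq, N) to per-real-channel (4*Cq, N);
# component index varies fastest along the real channel axis
gate_to_real <- function(gate, group) {
  if (group == 1L) return(gate)
  gate[rep(seq_len(nrow(gate)), each = 4L), , drop = FALSE]
}

# ---- channel attention layer ----------------------------------------------

ly_chatt <- function(C, cfg) {
  group <- att_group(cfg)
  Catt <- C %/% group
  par <- list()
  if (cfg$parameterized) {
    if (Catt %% cfg$reduction_ratio != 0L)
      stop("reduction_ratio ", cfg$reduction_ratio,
           " does not divide the attended channel count ", Catt)
    hid <- max(1L, Catt %/% cfg$reduction_ratio)
    a1 <- sqrt(6 / (Catt + hid))
    par <- list(W1 = matrix(runif(Catt * hid, -a1, a1), Catt, hid),
                W2 = matrix(runif(Catt * hid, -a1, a1), hid, Catt))
  }
  new_layer("chatt", par = par,
            extras = list(cfg = cfg, group = group, Catt = Catt, force = NULL))
}

#' @export
nn_forward.ly_chatt <- function(ly, x, training = FALSE) {
  d <- dim(x)
  N <- d[4]; Catt <- ly$Catt; g <- ly$group
  if (!is.null(ly$force)) {
    gate <- matrix(ly$force, Catt, N)
    gate_real <- gate_to_real(gate, g)
    if (training)
      ly$cache <- list(d = d, x = x, gate = gate, gate_real = gate_real,
                       forced = TRUE)
    return(cn_scale_cpp(x, gate_real))
  }
  mcn <- cn_mean_cpp(x)                                # (C, N) spatial means
  ml <- cn_max_cpp(x)                                  # spatial max + argmax
  if (g == 4L) {
    a4 <- mcn; dim(a4) <- c(4L, Catt, N)
    avg <- colMeans(a4, dims = 1)                      # mean over HW x comps
    m4 <- ml$max; dim(m4) <- c(4L, Catt, N)
    mx <- matrix(m4[1, , ], Catt, N)
    argc <- matrix(1L, Catt, N)
    for (comp in 2:4) {
      cur <- matrix(m4[comp, , ], Catt, N)
      upd <- cur > mx
      mx[upd] <- cur[upd]; argc[upd] <- comp
    }
  } else {
    avg <- mcn; mx <- ml$max; argc <- NULL
  }
  if (ly$cfg$parameterized) {
    pre_a <- crossprod(ly$par$W1, avg); h_a <- pre_a * (pre_a > 0)
    pre_m <- crossprod(ly$par$W1, mx); h_m <- pre_m * (pre_m > 0)
    logit <- crossprod(ly$par$W2, h_a) + crossprod(ly$par$W2, h_m)
    extra <- list(avg = avg, mx = mx, pre_a = pre_a, pre_m = pre_m,
                  h_a = h_a, h_m = h_m)
  } else {
    za <- zscore_cols(avg); zm <- zscore_cols(mx)
    logit <- za + zm
    extra <- list(za = za, zm = zm)
  }
  gate <- sigmoid(logit)
  gate_real <- gate_to_real(gate, g)
  if (training)
    ly$cache <- c(list(d = d, x = x, gate = gate, gate_real = gate_real,
                       argsp = ml$arg, argc = argc, forced = FALSE), extra)
  cn_scale_cpp(x, gate_real)
}

#' @export
nn_backward.ly_chatt <- function(ly, dy) {
  ca <- ly$cache
  d <- ca$d
  HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  g <- ly$group; Catt <- ly$Catt
  dx <- cn_scale_cpp(dy, ca$gate_real)
  if (!ca$forced) {
    dgate_real <- cn_dot_cpp(dy, ca$x)                 # (C, N)
    if (g == 4L) {
      dg4 <- dgate_real; dim(dg4) <- c(4L, Catt, N)
      dgate <- colSums(dg4, dims = 1)
    } else dgate <- dgate_real
    dlogit <- dgate * ca$gate * (1 - ca$gate)
    if (ly$cfg$parameterized) {
      dh_a <- (ly$par$W2 %*% dlogit) * (ca$pre_a > 0)
      dh_m <- (ly$par$W2 %*% dlogit) * (ca$pre_m > 0)
      ly$grad$W2 <- (ca$h_a + ca$h_m) %*% t(dlogit)
      ly$grad$W1 <- ca$avg %*% t(dh_a) + ca$mx %*% t(dh_m)
      davg <- ly$par$W1 %*% dh_a
      dmax <- ly$par$W1 %*% dh_m
    } else {
      davg <- zscore_cols_bwd(dlogit, ca$za)
      dmax <- zscore_cols_bwd(dlogit, ca$zm)
    }
    dx <- cn_addconst_cpp(dx, gate_to_real(davg, g) / (HW * g))
    creal <- if (g == 4L) {
      matrix(ca$argc + 4L * (row(ca$argc) - 1L), Catt, N)
    } else matrix(seq_len(C), C, N)
    pstar <- matrix(ca$argsp[cbind(as.integer(creal),
                                   rep(seq_len(N), each = Catt))], Catt, N)
    lin <- as.integer(pstar) + HW * (as.integer(creal) - 1L) +
      HW * C * rep(seq_len(N) - 1L, each = Catt)
    dx[lin] <- dx[lin] + as.numeric(dmax)
  }
  dx
}

# ---- spatial attention layer ----------------------------------------------

ly_spatt <- function(C, cfg) {
  k <- cfg$spatial_kernel
  par <- list(); buf <- list()
  if (cfg$parameterized) {
    a <- sqrt(6 / (2 * k * k + k * k))
    par <- list(W = array(runif(2 * k * k, -a, a), c(k, k, 2L, 1L)),
                b = 0)
  }
  new_layer("spatt", par = par, buf = buf,
            extras = list(cfg = cfg, C = C, k = k, force = NULL))
}

spatt_filter <- function(ly) {
  if (ly$cfg$parameterized) list(W = ly$par$W, b = ly$par$b)
  else list(W = array(1 / (2 * ly$k^2), c(ly$k, ly$k, 2L, 1L)), b = numeric(0))
}

# edge-replicate padding for the spatial-attention convolution, so that a
# spatially constant input yields a spatially constant gate (zero padding
# would darken the gate at the borders)
pad_replicate <- function(a, p) {
  d <- dim(a)
  ri <- c(rep(1L, p), seq_len(d[1]), rep(d[1], p))
  ci <- c(rep(1L, p), seq_len(d[2]), rep(d[2], p))
  a[ri, ci, , , drop = FALSE]
}

# adjoint of pad_replicate: scatter-add padded-border gradients back
pad_replicate_bwd <- function(g, p, H, W) {
  d <- dim(g)
  ri <- c(rep(1L, p), seq_len(H), rep(H, p))
  g1 <- rowsum(matrix(g, nrow = d[1]), ri)
  dim(g1) <- c(H, d[2], d[3], d[4])
  ci <- c(rep(1L, p), seq_len(W), rep(W, p))
  g2 <- aperm(g1, c(2L, 1L, 3L, 4L))
  g2 <- rowsum(matrix(g2, nrow = d[2]), ci)
  dim(g2) <- c(W, H, d[3], d[4])
  aperm(g2, c(2L, 1L, 3L, 4L))
}

#' @export
nn_forward.ly_spatt <- function(ly, x, training = FALSE) {
  d <- dim(x)
  HW <- d[1] * d[2]; N <- d[4]
  if (!is.null(ly$force)) {
    gate <- array(ly$force, c(d[1], d[2], N))
    if (training) ly$cache <- list(d = d, x = x, gate = gate, forced = TRUE)
    return(pn_scale_cpp(x, gate))
  }
  mm <- pn_meanmax_cpp(x)                              # channel-axis pools
  meanm <- matrix(mm$mean, HW, N)
  mx <- matrix(mm$max, HW, N)
  if (ly$cfg$parameterized) {
    d1 <- meanm; d2 <- mx
  } else {
    d1 <- zscore_cols(meanm); d2 <- zscore_cols(mx)
  }
  desc <- array(0, c(d[1], d[2], 2L, N))
  desc[, , 1, ] <- d1
  desc[, , 2, ] <- d2
  f <- spatt_filter(ly)
  pdesc <- pad_replicate(desc, ly$k %/% 2L)
  pre <- conv2d_fwd_cpp(pdesc, f$W, f$b, 1L, 0L)       # (H, W, 1, N)
  gate <- array(sigmoid(pre), c(d[1], d[2], N))
  if (training)
    ly$cache <- list(d = d, x = x, gate = gate, pdesc = pdesc, d1 = d1,
                     d2 = d2, amax = mm$arg, forced = FALSE)
  pn_scale_cpp(x, gate)
}

#' @export
nn_backward.ly_spatt <- function(ly, dy) {
  ca <- ly$cache
  d <- ca$d
  HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  dx <- pn_scale_cpp(dy, ca$gate)
  if (!ca$forced) {
    dgate <- pn_dot_cpp(dy, ca$x)                      # (H, W, N)
    dpre <- dgate * ca$gate * (1 - ca$gate)
    dim(dpre) <- c(d[1], d[2], 1L, N)
    f <- spatt_filter(ly)
    res <- conv2d_bwd_cpp(ca$pdesc, f$W, dpre, 1L, 0L, TRUE)
    if (ly$cfg$parameterized) {
      ly$grad$W <- res$gw
      ly$grad$b <- res$gb
    }
    gdesc <- pad_replicate_bwd(res$gx, ly$k %/% 2L, d[1], d[2])
    g1 <- matrix(gdesc[, , 1, ], HW, N)
    g2 <- matrix(gdesc[, , 2, ], HW, N)
    if (!ly$cfg$parameterized) {
      g1 <- zscore_cols_bwd(g1, ca$d1)
      g2 <- zscore_cols_bwd(g2, ca$d2)
    }
    dx <- pn_addconst_cpp(dx, array(g1 / C, c(d[1], d[2], N)))
    lin <- rep(seq_len(HW), N) + HW * (as.integer(ca$amax) - 1L) +
      HW * C * rep(seq_len(N) - 1L, each = HW)
    dx[lin] <- dx[lin] + as.numeric(g2)
  }
  dx
}

# ---- functional interface -------------------------------------------------

#' Channel attention gate
#'
#' Computes the per-channel sigmoid gate of a feature map: spatial average
#' and max pooling to two per-channel descriptors, a shared two-layer
#' bottleneck (parameterized mode) or standardized descriptor sum
#' (parameter-free mode), then a sigmoid. All values lie strictly in (0, 1).
#'
#' @param f A feature map array (H, W, C, N) or (H, W, C).
#' @param cfg An [attention_config()].
#' @param seed Seed for the bottleneck initialization (parameterized mode).
#' @return Matrix (attended_channels, N) of gate values in (0, 1).
#' @export
channel_attention <- function(f, cfg = attention_config(), seed = 1L) {
  if (length(dim(f)) == 3L) dim(f) <- c(dim(f), 1L)
  ly <- with_seed(seed, ly_chatt(dim(f)[3], cfg))
  nn_forward(ly, unclass(f), training = TRUE)
  ly$cache$gate
}

#' Spatial attention gate
#'
#' Channel-axis mean and max pooling, one spatial convolution over the two
#' pooled maps, then a sigmoid; the resulting H x W gate encodes where to
#' highlight or suppress.
#'
#' @inheritParams channel_attention
#' @return Array (H, W, N) of gate values in (0, 1).
#' @export
spatial_attention <- function(f, cfg = attention_config(), seed = 1L) {
  if (length(dim(f)) == 3L) dim(f) <- c(dim(f), 1L)
  d <- dim(f)
  ly <- with_seed(seed, ly_spatt(d[3], cfg))
  nn_forward(ly, unclass(f), training = TRUE)
  g <- ly$cache$gate
  dim(g) <- c(d[1], d[2], d[4])
  g
}

#' Apply a full attention block (channel gate then spatial gate)
#'
#' `f' = channel_gate * f`, then `f'' = spatial_gate(f') * f'`. Shape is
#' always preserved; every output magnitude is bounded by the input
#' magnitude because both gates lie in (0, 1).
#'
#' @inheritParams channel_attention
#' @param force_channel,force_spatial Optional constants overriding the
#'   gates (used for ablation: forcing both to 1 gives the identity).
#' @return A feature map with the same dimensions as `f`.
#' @export
apply_attention_block <- function(f, cfg = attention_config(), seed = 1L,
                                  force_channel = NULL, force_spatial = NULL) {
  had3 <- length(dim(f)) == 3L
  if (had3) dim(f) <- c(dim(f), 1L)
  C <- dim(f)[3]
  lys <- with_seed(seed, list(ch = ly_chatt(C, cfg), sp = ly_spatt(C, cfg)))
  lys$ch$force <- force_channel
  lys$sp$force <- force_spatial
  out <- unclass(f)
  seqn <- if (cfg$order == "channel-spatial") c("ch", "sp") else c("sp", "ch")
  for (nm in seqn) out <- nn_forward(lys[[nm]], out)
  if (had3) dim(out) <- dim(out)[1:3]
  out
}

#' Softmax (dot-product) attention over a sequence
#'
#' Alignment scores `h_i' v` are normalized by a numerically stable softmax
#' (max subtraction) into weights `alpha`, and the context is the weighted
#' sum `O = sum_i alpha_i h_i`.
#'
#' @param h Matrix with one encoded vector per row (n x d), n >= 1.
#' @param v Query vector of length d.
#' @return List with `weights` (length n, sums to 1) and `context`
#'   (length d).
#' @export
softmax_attention <- function(h, v) {
  if (is.null(dim(h))) h <- matrix(h, nrow = 1L)
  if (nrow(h) == 0L) stop("softmax attention needs a nonempty sequence")
  stopifnot(ncol(h) == length(v))
  s <- drop(h %*% v)
  e <- exp(s - max(s))
  alpha <- e / sum(e)
  list(weights = alpha, context = drop(crossprod(h, alpha)))
}

#' @export
count_parameters.attention_config <- function(x) {
  stop("count_parameters needs an instantiated attention block; ",
       "use attention_parameters(C, cfg)")
}

#' Parameter count of an attention block at a given channel width
#'
#' @param C Real channel count of the attended feature map.
#' @param cfg An [attention_config()].
#' @return Named integer vector `c(total, trainable)`; exactly zero in
#'   parameter-free mode.
#' @export
attention_parameters <- function(C, cfg = attention_config()) {
  lys <- with_seed(1L, list(ly_chatt(C, cfg), ly_spatt(C, cfg)))
  cnt <- count_parameters(lys[[1]]) + count_parameters(lys[[2]])
  cnt
}
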