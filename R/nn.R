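# Trainable layer objects.
#
# Every layer is a mutable environment with fields
#   par    named list of parameter arrays (trainable)
#   grad   named list of gradients, same shapes, filled by nn_backward
#   buf    non-trainable buffers (batch-norm running statistics)
#   cache  forward-pass intermediates needed by the backward pass
# and is driven through the S3 generics nn_forward(ly, x, training) and
# nn_backward(ly, dy). Gradients are hand-derived; the test suite checks
# them against central finite differences.

new_layer <- function(kind, par = list(), buf = list(), extras = list()) {
  ly <- new.env(parent = emptyenv())
  ly$kind <- kind
  ly$par <- par
  ly$grad <- list()
  ly$buf <- buf
  ly$cache <- NULL
  for (nm in names(extras)) assign(nm, extras[[nm]], envir = ly)
  class(ly) <- c(paste0("ly_", kind), "qlayer")
  ly
}

nn_forward <- function(ly, x, training = FALSE) UseMethod("nn_forward")
nn_backward <- function(ly, dy) UseMethod("nn_backward")

#' @export
count_parameters.qlayer <- function(x) {
  n <- sum(vapply(x$par, length, 0L))
  b <- sum(vapply(x$buf, length, 0L))
  c(total = n + b, trainable = n)
}

# ---- quaternion convolution layer -----------------------------------------

# draws its quaternion weights from the current RNG stream (the network
# builder seeds the stream once)
ly_qconv <- function(in_q, out_q, k = 3L, stride = 1L,
                     scheme = "quaternion-polar", bias = TRUE,
                     padding = "same", first = FALSE) {
  comp <- draw_quaternion_components(k * k * in_q * out_q, scheme,
                                     fan_in_q = k * k * in_q,
                                     fan_out_q = k * k * out_q)
  shp <- c(k, k, in_q, out_q)
  par <- list(r = array(comp$r, shp), x = array(comp$x, shp),
              y = array(comp$y, shp), z = array(comp$z, shp))
  if (bias) par$b <- matrix(0, out_q, 4L)
  new_layer("qconv", par = par,
            extras = list(stride = as.integer(stride), padding = padding,
                          first = first, in_q = in_q, out_q = out_q))
}

#' @export
nn_forward.ly_qconv <- function(ly, x, training = FALSE) {
  W <- expand_hamilton(ly$par)
  b <- if (is.null(ly$par$b)) numeric(0) else as.numeric(t(ly$par$b))
  ly$cache <- if (training) list(x = x, W = W) else NULL
  conv2d_fwd_cpp(x, W, b, ly$stride, pad_of(ly$padding, dim(W)[1]))
}

#' @export
nn_backward.ly_qconv <- function(ly, dy) {
  ca <- ly$cache
  res <- conv2d_bwd_cpp(ca$x, ca$W, dy, ly$stride,
                        pad_of(ly$padding, dim(ca$W)[1]), !ly$first)
  g <- contract_hamilton(res$gw, ly$in_q, ly$out_q)
  ly$grad <- list(r = g$r, x = g$x, y = g$y, z = g$z)
  if (!is.null(ly$par$b)) ly$grad$b <- t(matrix(res$gb, 4L, ly$out_q))
  if (ly$first) NULL else res$gx
}

# ---- split (component-wise) batch normalization ---------------------------

ly_bn <- function(C, momentum = 0.9, eps = 1e-5) {
  new_layer("bn",
            par = list(gamma = rep(1, C), beta = rep(0, C)),
            buf = list(run_mean = rep(0, C), run_var = rep(1, C)),
            extras = list(momentum = momentum, eps = eps, C = C))
}

#' @export
nn_forward.ly_bn <- function(ly, x, training = FALSE) {
  d <- dim(x)
  if (training) {
    st <- chan_stats_cpp(x)
    mu <- st$mean; v <- st$var
    ly$buf$run_mean <- ly$momentum * ly$buf$run_mean + (1 - ly$momentum) * mu
    ly$buf$run_var <- ly$momentum * ly$buf$run_var + (1 - ly$momentum) * v
  } else {
    mu <- ly$buf$run_mean
    v <- ly$buf$run_var
  }
  invstd <- 1 / sqrt(v + ly$eps)
  xhat <- chan_affine_cpp(x, invstd, -mu * invstd)
  y <- chan_affine_cpp(xhat, ly$par$gamma, ly$par$beta)
  if (training) ly$cache <- list(xhat = xhat, invstd = invstd, d = d)
  y
}

#' @export
nn_backward.ly_bn <- function(ly, dy) {
  ca <- ly$cache
  d <- ca$d
  ly$grad$gamma <- chan_dot_cpp(dy, ca$xhat)
  ly$grad$beta <- chan_dot_cpp(dy, numeric(0))
  M <- d[1] * d[2] * d[4]
  dxhat <- chan_affine_cpp(dy, ly$par$gamma, numeric(0))
  s1 <- chan_dot_cpp(dxhat, numeric(0))
  s2 <- chan_dot_cpp(dxhat, ca$xhat)
  dx <- dxhat - chan_affine_cpp(ca$xhat, s2 / M, s1 / M)
  chan_affine_cpp(dx, ca$invstd, numeric(0))
}

# ---- split ReLU -----------------------------------------------------------

ly_relu <- function() new_layer("relu")

#' @export
nn_forward.ly_relu <- function(ly, x, training = FALSE) {
  y <- x * (x > 0)
  if (training) ly$cache <- list(mask = x > 0)
  y
}

#' @export
nn_backward.ly_relu <- function(ly, dy) dy * ly$cache$mask

# ---- global average pool + real dense head --------------------------------

ly_gap <- function() new_layer("gap")

#' @export
nn_forward.ly_gap <- function(ly, x, training = FALSE) {
  d <- dim(x)
  xr <- x; dim(xr) <- c(d[1] * d[2], d[3], d[4])
  if (training) ly$cache <- list(d = d)
  colMeans(xr, dims = 1)                               # (C, N)
}

#' @export
nn_backward.ly_gap <- function(ly, dy) {
  d <- ly$cache$d
  hw <- d[1] * d[2]
  dx <- rep(as.numeric(dy) / hw, each = hw)
  dim(dx) <- d
  dx
}

ly_dense <- function(n_in, n_out = 1L) {
  a <- sqrt(6 / (n_in + n_out))
  new_layer("dense",
            par = list(W = matrix(runif(n_in * n_out, -a, a), n_in, n_out),
                       b = rep(0, n_out)))
}

#' @export
nn_forward.ly_dense <- function(ly, x, training = FALSE) {
  # x: (n_in, N) feature matrix
  if (training) ly$cache <- list(x = x)
  crossprod(ly$par$W, x) + ly$par$b                    # (n_out, N)
}

#' @export
nn_backward.ly_dense <- function(ly, dy) {
  ly$grad$W <- ly$cache$x %*% t(dy)
  ly$grad$b <- rowSums(dy)
  ly$par$W %*% dy
}

# ---- shared helpers -------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

# column-wise z-score (population sd); constant columns map to zero
zscore_cols <- function(m, eps = 1e-12) {
  mu <- colMeans(m)
  sdv <- sqrt(pmax(colMeans(m^2) - mu^2, 0))
  z <- sweep(m, 2L, mu, `-`)
  live <- sdv > eps
  z[, live] <- sweep(z[, live, drop = FALSE], 2L, sdv[live], `/`)
  z[, !live] <- 0
  attr(z, "sd") <- sdv
  attr(z, "live") <- live
  z
}

zscore_cols_bwd <- function(g, z) {
  sdv <- attr(z, "sd"); live <- attr(z, "live")
  n <- nrow(g)
  zz <- z; attributes(zz) <- list(dim = dim(z))
  gd <- sweep(g, 2L, colMeans(g), `-`)
  gd <- gd - sweep(zz, 2L, colMeans(g * zz), `*`)
  gd <- sweep(gd, 2L, ifelse(live, sdv, Inf), `/`)
  gd[, !live] <- 0
  gd
}
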