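# Quaternion-valued layers.
#
# A quaternion feature map is a real 4-d array with dimensions
# (H, W, C, N) where the channel axis groups quaternion components in
# contiguous quadruples, in (r, x, y, z) order: real channels
# 4(c-1)+1 .. 4(c-1)+4 hold quaternion channel c. All layers lower the
# quaternion arithmetic to structured real arithmetic: the Hamilton product
# w (x) q is linear in q, with the 4x4 matrix
#   [[r,-x,-y,-z],[x,r,-z,y],[y,z,r,-x],[z,-y,x,r]],
# so a quaternion convolution is exactly a real convolution whose per
# (in,out)-channel-pair weight block is that matrix. This is what ties the
# four components of every weight across the four components of every input
# and yields the 4-fold parameter saving over an unconstrained real layer.

# component index and sign of the Hamilton block M[a, b] (a = output
# component, b = input component), components numbered r=1, x=2, y=3, z=4
.ham_comp <- matrix(c(1, 2, 3, 4,
                      2, 1, 4, 3,
                      3, 4, 1, 2,
                      4, 3, 2, 1), 4, 4, byrow = TRUE)
.ham_sign <- matrix(c(1, -1, -1, -1,
                      1,  1, -1,  1,
                      1,  1,  1, -1,
                      1, -1,  1,  1), 4, 4, byrow = TRUE)

#' Validate / construct a quaternion feature map
#'
#' @param x A real array of dimension (H, W, C, N) (or (H, W, C), promoted to
#'   batch size 1) whose channel axis length is divisible by 4.
#' @return The array with class `qfmap`; `quaternion_channels()` returns C/4.
#' @export
qfmap <- function(x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 4L)
  if (dim(x)[3] %% 4L != 0L)
    stop("channel axis length must be divisible by 4 (got ", dim(x)[3], ")")
  if (!all(is.finite(x))) stop("feature map contains non-finite values")
  structure(x, class = "qfmap")
}

#' @rdname qfmap
#' @export
quaternion_channels <- function(x) dim(x)[3] %/% 4L

#' Encode an image as a quaternion feature map
#'
#' An RGB pixel (R, G, B) becomes the pure quaternion (0, R, G, B): the three
#' imaginary components carry the three color channels. A grayscale pixel g
#' is replicated, (0, g, g, g), so that all three imaginary axes see the
#' signal. Either way the output has one quaternion channel.
#'
#' @param image Numeric matrix (H x W) or array (H x W x 3) with values in
#'   \[0, 1\].
#' @param mode `"gray-replicate"` or `"rgb-imaginary"`.
#' @return A `qfmap` of dimension (H, W, 4, 1).
#' @export
encode_image <- function(image, mode = c("gray-replicate", "rgb-imaginary")) {
  mode <- match.arg(mode)
  if (min(image) < 0 || max(image) > 1)
    stop("image values must lie in [0, 1]; preprocess() rescales")
  d <- dim(image)
  if (mode == "rgb-imaginary") {
    if (length(d) != 3L || d[3] != 3L)
      stop("rgb-imaginary mode needs an (H, W, 3) array")
    out <- array(0, c(d[1], d[2], 4, 1))
    out[, , 2:4, 1] <- image
  } else {
    if (length(d) == 3L) image <- luminance(image)
    d <- dim(image)
    out <- array(0, c(d[1], d[2], 4, 1))
    for (k in 2:4) out[, , k, 1] <- image
  }
  qfmap(out)
}

#' Stack preprocessed images into one batched quaternion feature map
#'
#' @param images List of (H x W) matrices or (H x W x 3) arrays in \[0, 1\],
#'   all the same size.
#' @param mode Encoding mode, see [encode_image()].
#' @return A `qfmap` of dimension (H, W, 4, N).
#' @export
encode_batch <- function(images, mode = "gray-replicate") {
  maps <- lapply(images, encode_image, mode = mode)
  d <- dim(maps[[1]])
  out <- array(0, c(d[1], d[2], 4, length(maps)))
  for (i in seq_along(maps)) out[, , , i] <- maps[[i]]
  qfmap(out)
}

luminance <- function(img) {
  0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
}

#' Quaternion convolution weights
#'
#' Holds one quaternion per (output channel, input channel, tap): four real
#' arrays `r`, `x`, `y`, `z` of dimension (kh, kw, in_channels, out_channels)
#' in quaternion-channel units, plus an optional quaternion bias per output
#' channel. Real parameter count is `4 * out * in * kh * kw (+ 4 * out)`.
#'
#' @param r,x,y,z Arrays (kh, kw, in_q, out_q) of the weight components.
#' @param bias Matrix (out_q, 4) of quaternion biases, or `NULL`.
#' @param stride Integer stride, applied to both axes.
#' @param padding `"same"` (zero pad by floor(k/2); odd kernels only) or
#'   `"valid"`.
#' @return An object of class `qconv_weights`.
#' @export
qconv_weights <- function(r, x, y, z, bias = NULL, stride = 1L,
                          padding = c("same", "valid")) {
  padding <- match.arg(padding)
  stopifnot(identical(dim(r), dim(x)), identical(dim(r), dim(y)),
            identical(dim(r), dim(z)), length(dim(r)) == 4L)
  if (padding == "same" && (dim(r)[1] %% 2L == 0L || dim(r)[2] %% 2L == 0L))
    stop("'same' padding requires odd kernel sizes")
  if (!is.null(bias)) stopifnot(is.matrix(bias), nrow(bias) == dim(r)[4],
                                ncol(bias) == 4L)
  structure(list(r = r, x = x, y = y, z = z, bias = bias,
                 stride = as.integer(stride), padding = padding),
            class = "qconv_weights")
}

# expand quaternion kernels (kh, kw, Ci, Co) into the structured real kernel
# (kh, kw, 4*Ci, 4*Co) via the Hamilton block
expand_hamilton <- function(w) {
  d <- dim(w$r)
  Ci <- d[3]; Co <- d[4]
  comp <- list(w$r, w$x, w$y, w$z)
  W <- array(0, c(d[1], d[2], 4L * Ci, 4L * Co))
  for (a in 1:4) {
    for (b in 1:4) {
      W[, , b + 4L * (seq_len(Ci) - 1L), a + 4L * (seq_len(Co) - 1L)] <-
        .ham_sign[a, b] * comp[[.ham_comp[a, b]]]
    }
  }
  W
}

# adjoint of expand_hamilton: contract a real-kernel gradient back onto the
# four quaternion components
contract_hamilton <- function(G, Ci, Co) {
  d <- dim(G)
  out <- list(array(0, c(d[1], d[2], Ci, Co)), array(0, c(d[1], d[2], Ci, Co)),
              array(0, c(d[1], d[2], Ci, Co)), array(0, c(d[1], d[2], Ci, Co)))
  for (a in 1:4) {
    for (b in 1:4) {
      k <- .ham_comp[a, b]
      out[[k]] <- out[[k]] + .ham_sign[a, b] *
        G[, , b + 4L * (seq_len(Ci) - 1L), a + 4L * (seq_len(Co) - 1L),
          drop = FALSE]
    }
  }
  names(out) <- c("r", "x", "y", "z")
  out
}

expand_bias <- function(bias, Co) {
  if (is.null(bias)) return(numeric(0))
  as.numeric(t(bias)) # (co, comp) -> real index 4*(co-1)+comp
}

pad_of <- function(padding, kh) if (padding == "same") kh %/% 2L else 0L

#' Hamilton-product quaternion convolution
#'
#' Each output quaternion is the window sum of Hamilton products
#' `w (x) q` over input quaternion channels and kernel taps, plus an optional
#' quaternion bias. Implemented by lowering to a real convolution with the
#' structured 4x4 Hamilton weight blocks (see the layer source header), which
#' is exactly equivalent to the per-pixel quaternion sum.
#'
#' @param input A `qfmap` (or (H, W, C, N) array, C divisible by 4).
#' @param weights A [qconv_weights()].
#' @return A `qfmap` of dimension (Ho, Wo, 4 * out_channels, N).
#' @export
hamilton_conv2d <- function(input, weights) {
  x <- qfmap(input)
  Ci <- dim(weights$r)[3]
  if (quaternion_channels(x) != Ci)
    stop("input has ", quaternion_channels(x),
         " quaternion channels but weights expect ", Ci)
  W <- expand_hamilton(weights)
  b <- expand_bias(weights$bias, dim(weights$r)[4])
  y <- conv2d_fwd_cpp(unclass(x), W, b, weights$stride,
                      pad_of(weights$padding, dim(W)[1]))
  qfmap(y)
}

#' Rotation-and-scaling quaternion convolution
#'
#' The alternative quaternion convolution in which every kernel tap acts on
#' the input quaternion q by a scaled sandwich product
#' `(1/s) w (x) q (x) conj(w)` with `w = s (cos(theta/2) + mu sin(theta/2))`:
#' a rotation of the imaginary (vector) part by angle `theta` about the unit
#' axis `mu`, scaled by `s`. Pure-quaternion inputs stay pure; per-tap norms
#' are preserved when `s = 1`.
#'
#' @param input A `qfmap`.
#' @param weights A [rconv_weights()] in polar parameters.
#' @return A `qfmap` of dimension (Ho, Wo, 4 * out_channels, N).
#' @export
rotation_conv2d <- function(input, weights) {
  x <- qfmap(input)
  d <- dim(weights$s)
  Ci <- d[3]; Co <- d[4]
  if (quaternion_channels(x) != Ci)
    stop("input has ", quaternion_channels(x),
         " quaternion channels but weights expect ", Ci)
  # per-tap real 4x4 block: s * blockdiag(1, R(theta, mu)); for pure input
  # the sandwich (1/s) w q conj(w) = s * (q_r + R q_v)
  W <- array(0, c(d[1], d[2], 4L * Ci, 4L * Co))
  for (ki in seq_len(d[1])) for (kj in seq_len(d[2]))
    for (ci in seq_len(Ci)) for (co in seq_len(Co)) {
      s <- weights$s[ki, kj, ci, co]
      R <- axis_angle_matrix(weights$mu[, ki, kj, ci, co],
                             weights$theta[ki, kj, ci, co])
      blk <- matrix(0, 4, 4)
      blk[1, 1] <- 1
      blk[2:4, 2:4] <- R
      W[ki, kj, 4L * (ci - 1L) + 1:4, 4L * (co - 1L) + 1:4] <- s * t(blk)
    }
  y <- conv2d_fwd_cpp(unclass(x), W, numeric(0), weights$stride,
                      pad_of(weights$padding, d[1]))
  qfmap(y)
}

#' @rdname rotation_conv2d
#' @param s Array (kh, kw, in_q, out_q) of positive per-tap scales.
#' @param theta Array of per-tap rotation angles (radians), same shape.
#' @param mu Array (3, kh, kw, in_q, out_q) of unit rotation axes.
#' @param stride,padding As in [qconv_weights()].
#' @export
rconv_weights <- function(s, theta, mu, stride = 1L,
                          padding = c("same", "valid")) {
  padding <- match.arg(padding)
  stopifnot(identical(dim(s), dim(theta)), length(dim(s)) == 4L,
            identical(dim(mu), c(3L, dim(s))))
  if (any(s == 0)) stop("scale s must be nonzero for every tap")
  norms <- sqrt(colSums(matrix(mu, nrow = 3)^2))
  if (max(abs(norms - 1)) > 1e-9) stop("every rotation axis mu must be unit length")
  structure(list(s = s, theta = theta, mu = mu, stride = as.integer(stride),
                 padding = padding), class = "rconv_weights")
}

axis_angle_matrix <- function(axis, angle) {
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Quaternion dense (fully connected) layer
#'
#' The Hamilton-product analogue of a fully connected layer: input and output
#' are flat vectors of quaternions and every (in, out) pair carries one
#' quaternion weight, so the real parameter count is `4 * n_in * n_out`
#' (plus `4 * n_out` bias). Equivalent to [hamilton_conv2d()] on a 1x1
#' spatial map with a 1x1 kernel.
#'
#' @param input Numeric vector of length `4 * n_in` (components in
#'   (r, x, y, z) order per quaternion), or a matrix (batch, 4 * n_in).
#' @param weights A [qdense_weights()].
#' @return A matrix (batch, 4 * n_out).
#' @export
quaternion_dense <- function(input, weights) {
  if (is.null(dim(input))) input <- matrix(input, nrow = 1L)
  n_in <- dim(weights$r)[1]
  if (ncol(input) != 4L * n_in)
    stop("input length ", ncol(input), " does not match 4 * n_in = ", 4L * n_in)
  W <- qdense_real_matrix(weights)
  out <- input %*% W
  if (!is.null(weights$bias))
    out <- sweep(out, 2L, as.numeric(t(weights$bias)), `+`)
  out
}

qdense_real_matrix <- function(weights) {
  # reuse the conv expansion with a 1x1 "kernel"
  d <- dim(weights$r)
  w4 <- lapply(weights[c("r", "x", "y", "z")], function(a) {
    array(a, c(1L, 1L, d[1], d[2]))
  })
  W <- expand_hamilton(w4)
  matrix(W, nrow = 4L * d[1], ncol = 4L * d[2])
}

#' @rdname quaternion_dense
#' @param r,x,y,z Matrices (n_in, n_out) of quaternion weight components.
#' @param bias Matrix (n_out, 4) or `NULL`.
#' @export
qdense_weights <- function(r, x, y, z, bias = NULL) {
  stopifnot(is.matrix(r), identical(dim(r), dim(x)), identical(dim(r), dim(y)),
            identical(dim(r), dim(z)))
  if (!is.null(bias)) stopifnot(nrow(bias) == ncol(r), ncol(bias) == 4L)
  structure(list(r = r, x = x, y = y, z = z, bias = bias),
            class = "qdense_weights")
}

#' Initialize quaternion convolution weights
#'
#' Two schemes:
#' \describe{
#'   \item{`quaternion-polar`}{draws each weight in polar form: magnitude
#'     from a Rayleigh law with scale `sigma = 1/sqrt(2 * fan_in)` (`fan_in`
#'     counted in quaternion units, `kh * kw * in_q`), angle uniform on
#'     `(-pi, pi]`, and a uniform random pure unit axis. The real component
#'     then has variance `sigma^2 = 1/(2 * fan_in)` and each imaginary
#'     component variance `sigma^2 / 3`.}
#'   \item{`component-glorot`}{draws each of r, x, y, z independently from
#'     the Glorot uniform law on the real-channel fan
#'     (`a = sqrt(6 / (4 * fan_in_q * kh * kw + 4 * out_q * kh * kw))`).}
#' }
#' The seed fully determines the draw; biases start at zero.
#'
#' @param kh,kw Kernel height and width.
#' @param in_q,out_q Input/output channel counts in quaternion units.
#' @param scheme `"quaternion-polar"` or `"component-glorot"`.
#' @param seed Integer seed.
#' @param bias Include a (zero-initialized) quaternion bias per output
#'   channel?
#' @param stride,padding Stored into the returned weights.
#' @return A [qconv_weights()].
#' @export
init_qconv <- function(kh, kw, in_q, out_q,
                       scheme = c("quaternion-polar", "component-glorot"),
                       seed = 1L, bias = TRUE, stride = 1L, padding = "same") {
  scheme <- match.arg(scheme)
  if (in_q < 1L) stop("fan-in must be positive")
  n <- kh * kw * in_q * out_q
  comp <- with_seed(seed, draw_quaternion_components(n, scheme,
                                                     fan_in_q = kh * kw * in_q,
                                                     fan_out_q = kh * kw * out_q))
  shp <- c(kh, kw, in_q, out_q)
  qconv_weights(r = array(comp$r, shp), x = array(comp$x, shp),
                y = array(comp$y, shp), z = array(comp$z, shp),
                bias = if (bias) matrix(0, out_q, 4L) else NULL,
                stride = stride, padding = padding)
}

draw_quaternion_components <- function(n, scheme, fan_in_q, fan_out_q) {
  if (scheme == "quaternion-polar") {
    sigma <- 1 / sqrt(2 * fan_in_q)
    rho <- sigma * sqrt(-2 * log(runif(n)))
    theta <- runif(n, -pi, pi)
    ax <- matrix(rnorm(3L * n), 3L)
    ax <- sweep(ax, 2L, sqrt(colSums(ax^2)), `/`)
    list(r = rho * cos(theta),
         x = rho * sin(theta) * ax[1, ],
         y = rho * sin(theta) * ax[2, ],
         z = rho * sin(theta) * ax[3, ])
  } else {
    a <- sqrt(6 / (4 * fan_in_q + 4 * fan_out_q))
    list(r = runif(n, -a, a), x = runif(n, -a, a),
         y = runif(n, -a, a), z = runif(n, -a, a))
  }
}

#' Count parameters
#'
#' Returns the exact real-valued parameter counts of a weight object, layer,
#' or whole network as `c(total, trainable)`. Batch-normalization running
#' statistics count as non-trainable; everything else is trainable. A
#' quaternion convolution holds exactly 1/4 of the kernel parameters of an
#' unconstrained real convolution over the same real channel shape, because
#' each 4x4 real block is generated by 4 numbers instead of 16.
#'
#' @param x A `qconv_weights`, `qdense_weights`, layer, or `qcsa_network`.
#' @return Named integer vector `c(total = , trainable = )`.
#' @export
count_parameters <- function(x) UseMethod("count_parameters")

#' @export
count_parameters.qconv_weights <- function(x) {
  n <- 4L * prod(dim(x$r)) + if (is.null(x$bias)) 0L else length(x$bias)
  c(total = n, trainable = n)
}

#' @export
count_parameters.qdense_weights <- function(x) {
  n <- 4L * prod(dim(x$r)) + if (is.null(x$bias)) 0L else length(x$bias)
  c(total = n, trainable = n)
}

#' @export
count_parameters.list <- function(x) {
  if (length(x) == 0L) return(c(total = 0L, trainable = 0L))
  counts <- vapply(x, count_parameters, c(total = 0, trainable = 0))
  c(total = sum(counts["total", ]), trainable = sum(counts["trainable", ]))
}

#' @export
count_parameters.NULL <- function(x) c(total = 0L, trainable = 0L)
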