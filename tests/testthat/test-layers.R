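test_that("image encoding maps pixels to pure quaternions", {
  img <- matrix(c(0, 0.5, 1, 0.25), 2, 2)
  f <- encode_image(img, "gray-replicate")
  expect_equal(dim(f), c(2L, 2L, 4L, 1L))
  expect_equal(unclass(f)[1, 2, , 1], c(0, 1, 1, 1))   # g -> (0, g, g, g)
  expect_equal(unclass(f)[, , 1, 1], matrix(0, 2, 2))  # real part zero
  rgb <- array(runif(2 * 2 * 3), c(2, 2, 3))
  fr <- encode_image(rgb, "rgb-imaginary")
  expect_equal(unclass(fr)[1, 1, , 1], c(0, rgb[1, 1, ]))  # (0, R, G, B)
  expect_equal(unclass(encode_image(matrix(0, 3, 3))),
               array(0, c(3, 3, 4, 1)))
  expect_error(encode_image(matrix(2, 2, 2)), "\\[0, 1\\]")
  expect_error(qfmap(array(0, c(2, 2, 3, 1))), "divisible by 4")
})

test_that("hamilton_conv2d equals the brute-force window loop and the
           structured real convolution", {
  set.seed(21)
  shapes <- list(c(H = 4, W = 4, Ci = 1, Co = 1, k = 3, s = 1),
                 c(5, 4, 2, 3, 3, 1),
                 c(6, 6, 2, 2, 3, 2),
                 c(4, 4, 3, 1, 1, 1),
                 c(7, 5, 1, 2, 5, 1))
  for (sh in shapes) {
    x <- array(rnorm(sh[1] * sh[2] * 4 * sh[3] * 2), c(sh[1], sh[2], 4 * sh[3], 2))
    w <- init_qconv(sh[5], sh[5], sh[3], sh[4], seed = sum(sh), stride = sh[6])
    y <- hamilton_conv2d(x, w)
    expect_lt(max(abs(unclass(y) - brute_hamilton_conv(x, w))), 1e-5)
    # structured real convolution route
    W <- qcsanet:::expand_hamilton(w)
    y2 <- qcsanet:::conv2d_fwd_cpp(x, W, as.numeric(t(w$bias)), w$stride,
                                   sh[5] %/% 2)
    expect_equal(unclass(y), y2, tolerance = 1e-12)
  }
})

test_that("degenerate and identity kernels behave as expected", {
  set.seed(22)
  # 1x1 spatial input, 1x1 kernel: reduces to a single Hamilton product
  q <- rnorm(4); wq <- rnorm(4)
  x <- array(q, c(1, 1, 4, 1))
  w <- qconv_weights(r = array(wq[1], c(1, 1, 1, 1)), x = array(wq[2], c(1, 1, 1, 1)),
                     y = array(wq[3], c(1, 1, 1, 1)), z = array(wq[4], c(1, 1, 1, 1)),
                     bias = NULL)
  y <- hamilton_conv2d(x, w)
  expect_equal(as.numeric(y),
               as.numeric(unclass(quat_prod(quat(wq[1], wq[2], wq[3], wq[4]),
                                            quat(q[1], q[2], q[3], q[4])))),
               tolerance = 1e-12)
  # identity quaternion at the kernel center passes the input through
  kr <- array(0, c(3, 3, 1, 1)); kr[2, 2, 1, 1] <- 1
  zero <- array(0, c(3, 3, 1, 1))
  wid <- qconv_weights(r = kr, x = zero, y = zero, z = zero, bias = NULL)
  xin <- array(rnorm(5 * 5 * 4), c(5, 5, 4, 1))
  expect_equal(unclass(hamilton_conv2d(xin, wid)), xin, tolerance = 1e-12)
})

test_that("convolution is linear in its input", {
  set.seed(23)
  w <- init_qconv(3, 3, 2, 2, seed = 9, bias = FALSE)
  x1 <- array(rnorm(6 * 6 * 8), c(6, 6, 8, 1))
  x2 <- array(rnorm(6 * 6 * 8), c(6, 6, 8, 1))
  a <- 0.7; b <- -1.3
  lhs <- unclass(hamilton_conv2d(a * x1 + b * x2, w))
  rhs <- a * unclass(hamilton_conv2d(x1, w)) + b * unclass(hamilton_conv2d(x2, w))
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("rotation_conv2d matches the sandwich-product oracle and preserves
           pure inputs", {
  set.seed(24)
  for (rep in 1:5) {
    Ci <- sample(1:2, 1); Co <- sample(1:2, 1); k <- sample(c(1, 3), 1)
    x <- array(rnorm(5 * 5 * 4 * Ci), c(5, 5, 4 * Ci, 1))
    x[, , seq(1, 4 * Ci, by = 4), ] <- 0                 # pure quaternions
    w <- rand_rconv_weights(k, Ci, Co)
    y <- rotation_conv2d(x, w)
    expect_lt(max(abs(unclass(y) - brute_rotation_conv(x, w))), 1e-5)
    # pure inputs stay pure
    expect_lt(max(abs(unclass(y)[, , seq(1, 4 * Co, by = 4), ])), 1e-10)
  }
  # unit-scale single-tap kernel with theta = 0 is the identity
  mu <- array(c(1, 0, 0), c(3, 1, 1, 1, 1))
  wid <- rconv_weights(s = array(1, c(1, 1, 1, 1)), theta = array(0, c(1, 1, 1, 1)),
                       mu = mu)
  xin <- array(rnorm(4 * 4 * 4), c(4, 4, 4, 1))
  expect_equal(unclass(rotation_conv2d(xin, wid)), xin, tolerance = 1e-12)
  # unit w on a pure input preserves the per-pixel norm
  wunit <- rand_rconv_weights(1, 1, 1)
  wunit$s[] <- 1
  xp <- array(rnorm(4 * 4 * 4), c(4, 4, 4, 1)); xp[, , 1, ] <- 0
  yp <- unclass(rotation_conv2d(xp, wunit))
  n_in <- sqrt(apply(xp^2, c(1, 2, 4), sum))
  n_out <- sqrt(apply(yp^2, c(1, 2, 4), sum))
  expect_equal(n_out, n_in, tolerance = 1e-9)
  expect_error(rconv_weights(s = array(0, c(1, 1, 1, 1)),
                             theta = array(0, c(1, 1, 1, 1)), mu = mu),
               "nonzero")
})

test_that("quaternion_dense equals the dense loop and a 1x1 convolution", {
  set.seed(25)
  n_in <- 3L; n_out <- 2L
  w <- qdense_weights(r = matrix(rnorm(n_in * n_out), n_in),
                      x = matrix(rnorm(n_in * n_out), n_in),
                      y = matrix(rnorm(n_in * n_out), n_in),
                      z = matrix(rnorm(n_in * n_out), n_in),
                      bias = matrix(rnorm(n_out * 4), n_out))
  xin <- rnorm(4 * n_in)
  got <- quaternion_dense(xin, w)
  # loop oracle over quaternion pairs
  want <- rep(0, 4 * n_out)
  for (co in seq_len(n_out)) {
    acc <- w$bias[co, ]
    for (ci in seq_len(n_in)) {
      q <- quat(xin[4 * (ci - 1) + 1], xin[4 * (ci - 1) + 2],
                xin[4 * (ci - 1) + 3], xin[4 * (ci - 1) + 4])
      wq <- quat(w$r[ci, co], w$x[ci, co], w$y[ci, co], w$z[ci, co])
      acc <- acc + as.numeric(unclass(quat_prod(wq, q)))
    }
    want[4 * (co - 1) + 1:4] <- acc
  }
  expect_equal(as.numeric(got), want, tolerance = 1e-10)
  # equivalence with hamilton_conv2d on a 1x1 spatial map
  wc <- qconv_weights(r = array(w$r, c(1, 1, n_in, n_out)),
                      x = array(w$x, c(1, 1, n_in, n_out)),
                      y = array(w$y, c(1, 1, n_in, n_out)),
                      z = array(w$z, c(1, 1, n_in, n_out)),
                      bias = w$bias)
  yc <- hamilton_conv2d(array(xin, c(1, 1, 4 * n_in, 1)), wc)
  expect_equal(as.numeric(yc), want, tolerance = 1e-10)
  # identity 1 -> 1 layer passes through
  wi <- qdense_weights(r = matrix(1), x = matrix(0), y = matrix(0),
                       z = matrix(0))
  expect_equal(as.numeric(quaternion_dense(c(1, 2, 3, 4), wi)), c(1, 2, 3, 4))
  expect_error(quaternion_dense(rnorm(8), wi), "does not match")
})

test_that("initialization is seed-deterministic with the documented variance", {
  w1 <- init_qconv(3, 3, 4, 4, seed = 77)
  w2 <- init_qconv(3, 3, 4, 4, seed = 77)
  expect_identical(w1$r, w2$r)
  expect_identical(w1$z, w2$z)
  w3 <- init_qconv(3, 3, 4, 4, seed = 78)
  expect_false(identical(w1$r, w3$r))
  # law-of-large-numbers check on the quaternion-polar law: the real
  # component has variance 1/(2 fan_in), imaginary components 1/(6 fan_in)
  fan_in <- 5L
  comp <- qcsanet:::with_seed(5, qcsanet:::draw_quaternion_components(
    1e5, "quaternion-polar", fan_in_q = fan_in, fan_out_q = 5L))
  expect_equal(var(comp$r), 1 / (2 * fan_in), tolerance = 0.1)
  expect_equal(var(comp$x), 1 / (6 * fan_in), tolerance = 0.1)
  expect_equal(mean(comp$r), 0, tolerance = 0.01)
  g <- qcsanet:::with_seed(5, qcsanet:::draw_quaternion_components(
    1e5, "component-glorot", fan_in_q = fan_in, fan_out_q = 5L))
  a <- sqrt(6 / (4 * fan_in + 4 * 5))
  expect_equal(var(g$r), a^2 / 3, tolerance = 0.1)
  expect_error(init_qconv(3, 3, 0, 4), "fan-in")
})

test_that("parameter counts follow the 4x-sharing formula", {
  w <- init_qconv(3, 3, 2, 4, seed = 1)
  expect_equal(count_parameters(w), c(total = 304, trainable = 304))
  # same real shape (8 -> 16 channels, 3x3) unconstrained: 16*8*9 = 1152
  real_kernel_params <- 16 * 8 * 3 * 3
  wq <- init_qconv(3, 3, 2, 4, seed = 1, bias = FALSE)
  expect_equal(unname(count_parameters(wq)["total"]) * 4, real_kernel_params)
  expect_equal(count_parameters(list()), c(total = 0L, trainable = 0L))
})

test_that("conv layer gradients match finite differences", {
  set.seed(26)
  ly <- qcsanet:::with_seed(8, qcsanet:::ly_qconv(2L, 2L, 3L, 1L))
  x <- array(rnorm(5 * 5 * 8 * 2), c(5, 5, 8, 2))
  tgt <- array(rnorm(5 * 5 * 8 * 2), c(5, 5, 8, 2))
  loss <- function() sum(qcsanet:::nn_forward(ly, x, TRUE) * tgt)
  loss()
  dx <- qcsanet:::nn_backward(ly, tgt)
  for (nm in c("r", "x", "y", "z", "b")) {
    g <- ly$grad[[nm]]
    idx <- sample(length(ly$par[[nm]]), 4)
    for (i in idx) {
      eps <- 1e-6
      orig <- ly$par[[nm]][i]
      ly$par[[nm]][i] <- orig + eps; lp <- loss()
      ly$par[[nm]][i] <- orig - eps; lm <- loss()
      ly$par[[nm]][i] <- orig
      fd <- (lp - lm) / (2 * eps)
      expect_lt(abs(fd - g[i]) / max(1e-6, abs(fd) + abs(g[i])), 1e-4)
    }
  }
  # input gradient
  idx <- sample(length(x), 6)
  for (i in idx) {
    eps <- 1e-6
    xp <- x; xp[i] <- x[i] + eps
    xm <- x; xm[i] <- x[i] - eps
    x0 <- x
    x <- xp; lp <- loss(); x <- xm; lm <- loss(); x <- x0
    fd <- (lp - lm) / (2 * eps)
    expect_lt(abs(fd - dx[i]) / max(1e-6, abs(fd) + abs(dx[i])), 1e-4)
  }
})
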