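# Independent oracles and small fixture builders shared across tests.

rand_quat <- function(n = 1L) {
  quat(rnorm(n), rnorm(n), rnorm(n), rnorm(n))
}

# brute-force quaternion convolution: explicit loop over output pixels,
# kernel taps and channels, using only quat_prod (never the conv code path)
brute_hamilton_conv <- function(x, w) {
  k <- dim(w$r)[1]
  p <- if (w$padding == "same") k %/% 2 else 0L
  s <- w$stride
  Ci <- dim(w$r)[3]; Co <- dim(w$r)[4]
  d <- dim(x); H <- d[1]; W <- d[2]; N <- d[4]
  Ho <- (H + 2 * p - k) %/% s + 1L
  Wo <- (W + 2 * p - k) %/% s + 1L
  out <- array(0, c(Ho, Wo, 4 * Co, N))
  for (n in seq_len(N)) for (co in seq_len(Co)) for (i in seq_len(Ho))
    for (j in seq_len(Wo)) {
      acc <- c(0, 0, 0, 0)
      for (ci in seq_len(Ci)) for (ki in seq_len(k)) for (kj in seq_len(k)) {
        xi <- (i - 1L) * s + ki - p
        xj <- (j - 1L) * s + kj - p
        if (xi < 1 || xi > H || xj < 1 || xj > W) next
        q <- quat(x[xi, xj, 4 * (ci - 1) + 1, n], x[xi, xj, 4 * (ci - 1) + 2, n],
                  x[xi, xj, 4 * (ci - 1) + 3, n], x[xi, xj, 4 * (ci - 1) + 4, n])
        wq <- quat(w$r[ki, kj, ci, co], w$x[ki, kj, ci, co],
                   w$y[ki, kj, ci, co], w$z[ki, kj, ci, co])
        acc <- acc + as.numeric(unclass(quat_prod(wq, q)))
      }
      if (!is.null(w$bias)) acc <- acc + w$bias[co, ]
      out[i, j, 4 * (co - 1) + 1:4, n] <- acc
    }
  out
}

# brute-force rotation convolution: per-tap scaled sandwich product
# (1/s) w q conj(w), built from quat_prod only
brute_rotation_conv <- function(x, w) {
  k <- dim(w$s)[1]
  p <- if (w$padding == "same") k %/% 2 else 0L
  st <- w$stride
  Ci <- dim(w$s)[3]; Co <- dim(w$s)[4]
  d <- dim(x); H <- d[1]; W <- d[2]; N <- d[4]
  Ho <- (H + 2 * p - k) %/% st + 1L
  Wo <- (W + 2 * p - k) %/% st + 1L
  out <- array(0, c(Ho, Wo, 4 * Co, N))
  for (n in seq_len(N)) for (co in seq_len(Co)) for (i in seq_len(Ho))
    for (j in seq_len(Wo)) {
      acc <- c(0, 0, 0, 0)
      for (ci in seq_len(Ci)) for (ki in seq_len(k)) for (kj in seq_len(k)) {
        xi <- (i - 1L) * st + ki - p
        xj <- (j - 1L) * st + kj - p
        if (xi < 1 || xi > H || xj < 1 || xj > W) next
        q <- quat(x[xi, xj, 4 * (ci - 1) + 1, n], x[xi, xj, 4 * (ci - 1) + 2, n],
                  x[xi, xj, 4 * (ci - 1) + 3, n], x[xi, xj, 4 * (ci - 1) + 4, n])
        sc <- w$s[ki, kj, ci, co]
        th <- w$theta[ki, kj, ci, co]
        mu <- w$mu[, ki, kj, ci, co]
        wq <- quat(sc * cos(th / 2), sc * sin(th / 2) * mu[1],
                   sc * sin(th / 2) * mu[2], sc * sin(th / 2) * mu[3])
        sandwich <- quat_prod(quat_prod(wq, q), quat_conj(wq))
        acc <- acc + as.numeric(unclass(sandwich)) / sc
      }
      out[i, j, 4 * (co - 1) + 1:4, n] <- acc
    }
  out
}

rand_rconv_weights <- function(k, Ci, Co, stride = 1L, padding = "same") {
  shp <- c(k, k, Ci, Co)
  mu <- array(rnorm(3 * prod(shp)), c(3, shp))
  mu <- sweep(mu, 2:5, sqrt(colSums(mu^2, dims = 1)), "/")
  rconv_weights(s = array(runif(prod(shp), 0.5, 2), shp),
                theta = array(runif(prod(shp), -pi, pi), shp),
                mu = mu, stride = stride, padding = padding)
}

# 3x3 axis-angle rotation matrix (Rodrigues), independent of the package's
# quaternion sandwich implementation
rotation_matrix_oracle <- function(axis, angle) {
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

make_synth_fixture <- function(counts = list(train = c(NORMAL = 6, PNEUMONIA = 6),
                                             val = c(NORMAL = 3, PNEUMONIA = 3),
                                             test = c(NORMAL = 3, PNEUMONIA = 3)),
                               seed = 42L, ...) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  man <- generate_synthetic_dataset(synth_config(counts = counts, seed = seed,
                                                 ...), dir)
  list(dir = dir, manifest = man)
}
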