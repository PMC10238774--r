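#' Construct a quaternion
#'
#' A quaternion is the four-dimensional hypercomplex number
#' \eqn{Q = r + xi + yj + zk}. Throughout this package the component order is
#' fixed as `(r, x, y, z)`: `r` is the real (scalar) part and `(x, y, z)` the
#' imaginary (vector) part.
#'
#' @param r,x,y,z Real components. All recycled to a common length, so the
#'   constructor also builds vectors of quaternions.
#' @return An object of class `quaternion`: a numeric matrix with one row per
#'   quaternion and columns `r`, `x`, `y`, `z`.
#' @examples
#' quat(1, 2, 3, 4)
#' quat_prod(quat(0, 1, 0, 0), quat(0, 0, 1, 0)) # ij = k
#' @export
quat <- function(r = 0, x = 0, y = 0, z = 0) {
  m <- cbind(r = as.numeric(r), x = as.numeric(x),
             y = as.numeric(y), z = as.numeric(z))
  structure(m, class = "quaternion")
}

#' @export
print.quaternion <- function(x, ...) {
  m <- unclass(x)
  for (i in seq_len(nrow(m))) {
    cat(sprintf("%g %+gi %+gj %+gk\n", m[i, 1], m[i, 2], m[i, 3], m[i, 4]))
  }
  invisible(x)
}

as_quat_matrix <- function(q) {
  if (inherits(q, "quaternion")) return(unclass(q))
  if (is.numeric(q) && is.null(dim(q)) && length(q) == 4L) return(matrix(q, 1L))
  if (is.matrix(q) && ncol(q) == 4L) return(q)
  stop("not a quaternion: expected class 'quaternion' or a length-4 numeric")
}

#' Hamilton product of two quaternions
#'
#' The non-commutative quaternion multiplication
#' \deqn{a \otimes b = (r_1 r_2 - x_1 x_2 - y_1 y_2 - z_1 z_2)
#'   + (r_1 x_2 + x_1 r_2 + y_1 z_2 - z_1 y_2)\,i
#'   + (r_1 y_2 - x_1 z_2 + y_1 r_2 + z_1 x_2)\,j
#'   + (r_1 z_2 + x_1 y_2 - y_1 x_2 + z_1 r_2)\,k.}
#' This product is the primitive that quaternion layers use in place of the
#' real-valued multiply: its four outputs each mix all four components of both
#' operands, which is what gives quaternion networks their within-feature
#' weight sharing.
#'
#' @param a,b Quaternions (vectorized; rows are recycled if one has 1 row).
#' @return A `quaternion` with `a %q% b` rowwise.
#' @export
quat_prod <- function(a, b) {
  a <- as_quat_matrix(a); b <- as_quat_matrix(b)
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  stopifnot(nrow(a) == nrow(b))
  r1 <- a[, 1]; x1 <- a[, 2]; y1 <- a[, 3]; z1 <- a[, 4]
  r2 <- b[, 1]; x2 <- b[, 2]; y2 <- b[, 3]; z2 <- b[, 4]
  quat(r1 * r2 - x1 * x2 - y1 * y2 - z1 * z2,
       r1 * x2 + x1 * r2 + y1 * z2 - z1 * y2,
       r1 * y2 - x1 * z2 + y1 * r2 + z1 * x2,
       r1 * z2 + x1 * y2 - y1 * x2 + z1 * r2)
}

#' @rdname quat_prod
#' @export
`%q%` <- function(a, b) quat_prod(a, b)

#' Quaternion conjugate
#'
#' `Q* = r - xi - yj - zk`. Conjugation is an involution and satisfies
#' `Q (x) Q* = (||Q||^2, 0, 0, 0)`.
#'
#' @param q A quaternion (vectorized).
#' @return The conjugate quaternion(s).
#' @export
quat_conj <- function(q) {
  m <- as_quat_matrix(q)
  quat(m[, 1], -m[, 2], -m[, 3], -m[, 4])
}

#' Quaternion norm (magnitude)
#'
#' `||Q|| = sqrt(r^2 + x^2 + y^2 + z^2)`. The norm is multiplicative:
#' `||a (x) b|| = ||a|| ||b||`.
#'
#' @param q A quaternion (vectorized).
#' @return Numeric vector of magnitudes, one per row.
#' @export
quat_norm <- function(q) {
  m <- as_quat_matrix(q)
  sqrt(rowSums(m^2))
}

#' Quaternion inverse
#'
#' `Q^-1 = Q* / ||Q||^2`, so `Q (x) Q^-1 = (1,0,0,0)`.
#'
#' @param q A nonzero quaternion (vectorized).
#' @return The inverse quaternion(s).
#' @export
quat_inv <- function(q) {
  m <- as_quat_matrix(q)
  n2 <- rowSums(m^2)
  if (any(n2 == 0)) stop("cannot invert the zero quaternion")
  quat(m[, 1] / n2, -m[, 2] / n2, -m[, 3] / n2, -m[, 4] / n2)
}

#' Polar form of a quaternion
#'
#' Any nonzero quaternion can be written
#' \eqn{Q = \rho(\cos\theta + s\sin\theta)} with magnitude \eqn{\rho = ||Q||},
#' a real angle \eqn{\theta} and a pure unit quaternion \eqn{s} (the axis).
#' For a real quaternion (zero imaginary part) the axis is undefined; the
#' convention here is `s = i` and `theta` in `{0, pi}` by sign of `r`.
#'
#' @param q A single nonzero quaternion.
#' @return For `quat_to_polar`, a list with `rho` (magnitude), `theta`
#'   (radians, in `[0, pi]`) and `s` (pure unit `quaternion` axis). For
#'   `quat_from_polar`, the Cartesian `quaternion`.
#' @export
quat_to_polar <- function(q) {
  m <- as_quat_matrix(q)
  stopifnot(nrow(m) == 1L)
  rho <- sqrt(sum(m^2))
  if (rho == 0) stop("polar form is undefined for the zero quaternion")
  vnorm <- sqrt(sum(m[1, 2:4]^2))
  if (vnorm == 0) {
    s <- quat(0, 1, 0, 0)
    theta <- if (m[1, 1] >= 0) 0 else pi
  } else {
    s <- quat(0, m[1, 2] / vnorm, m[1, 3] / vnorm, m[1, 4] / vnorm)
    theta <- atan2(vnorm, m[1, 1])
  }
  list(rho = rho, theta = theta, s = s)
}

#' @rdname quat_to_polar
#' @param p A list with fields `rho`, `theta`, `s` as returned by
#'   `quat_to_polar()`.
#' @export
quat_from_polar <- function(p) {
  stopifnot(is.list(p), all(c("rho", "theta", "s") %in% names(p)))
  s <- as_quat_matrix(p$s)
  if (abs(s[1, 1]) > 1e-12 || abs(sqrt(sum(s^2)) - 1) > 1e-9)
    stop("axis 's' must be a pure unit quaternion")
  quat(p$rho * cos(p$theta),
       p$rho * sin(p$theta) * s[1, 2],
       p$rho * sin(p$theta) * s[1, 3],
       p$rho * sin(p$theta) * s[1, 4])
}

#' Rotate a 3-vector with a quaternion sandwich product
#'
#' Embeds `v` as the pure quaternion `Q^ = v1 i + v2 j + v3 k` and computes
#' `p^ = w^ (x) Q^ (x) conj(w^)` with the half-angle unit quaternion
#' `w^ = cos(angle/2) + sin(angle/2)(w1 i + w2 j + w3 k)`. This is the
#' standard axis-angle rotation; the output norm always equals the input
#' norm.
#'
#' @param v Numeric length-3 vector to rotate.
#' @param axis Unit-length numeric length-3 rotation axis. A non-unit axis is
#'   an error; use [normalize_axis()] first if needed.
#' @param angle Rotation angle in radians.
#' @return The rotated length-3 numeric vector.
#' @export
rotate_vec3 <- function(v, axis, angle) {
  stopifnot(length(v) == 3L, length(axis) == 3L, length(angle) == 1L)
  if (abs(sqrt(sum(axis^2)) - 1) > 1e-9)
    stop("rotation axis must have unit length (see normalize_axis())")
  w <- quat(cos(angle / 2),
            sin(angle / 2) * axis[1],
            sin(angle / 2) * axis[2],
            sin(angle / 2) * axis[3])
  p <- quat_prod(quat_prod(w, quat(0, v[1], v[2], v[3])), quat_conj(w))
  as.numeric(unclass(p)[1, 2:4])
}

#' @rdname rotate_vec3
#' @export
normalize_axis <- function(axis) {
  n <- sqrt(sum(axis^2))
  if (n == 0) stop("cannot normalize a zero axis")
  axis / n
}

#' Run the quaternion identity suite
#'
#' Checks the defining identities (`i^2 = j^2 = k^2 = ijk = -1`, `ij = k`,
#' `ji = -k`), conjugate involution, norm multiplicativity, inverse,
#' polar-form round trips, rotation norm preservation, and agreement of the
#' Hamilton product with its 4x4 real-matrix representation on random cases.
#' Used by the `algebra-check` CLI subcommand.
#'
#' @param n_random Number of random cases per numeric check.
#' @param tol Maximum absolute deviation allowed on the numeric checks.
#' @param seed RNG seed for the random cases.
#' @return Invisibly, a named logical vector (all `TRUE` on success); prints
#'   a pass/fail line per identity.
#' @export
quat_identity_check <- function(n_random = 1000L, tol = 1e-9, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  i <- quat(0, 1, 0, 0); j <- quat(0, 0, 1, 0); k <- quat(0, 0, 0, 1)
  m1 <- quat(-1, 0, 0, 0)
  res <- c(
    "i^2 = -1"  = identical(unclass(quat_prod(i, i)), unclass(m1)),
    "j^2 = -1"  = identical(unclass(quat_prod(j, j)), unclass(m1)),
    "k^2 = -1"  = identical(unclass(quat_prod(k, k)), unclass(m1)),
    "ijk = -1"  = identical(unclass(quat_prod(quat_prod(i, j), k)), unclass(m1)),
    "ij = k"    = identical(unclass(quat_prod(i, j)), unclass(k)),
    "ji = -k"   = identical(unclass(quat_prod(j, i)), unclass(quat(0, 0, 0, -1)))
  )
  a <- quat(rnorm(n_random), rnorm(n_random), rnorm(n_random), rnorm(n_random))
  b <- quat(rnorm(n_random), rnorm(n_random), rnorm(n_random), rnorm(n_random))
  ab <- quat_prod(a, b)
  res["matrix representation"] <- max(abs(unclass(ab) -
    t(vapply(seq_len(n_random), function(r) {
      drop(quat_matrix_rep(unclass(a)[r, ]) %*% unclass(b)[r, ])
    }, numeric(4))))) < tol
  res["norm multiplicativity"] <-
    max(abs(quat_norm(ab) - quat_norm(a) * quat_norm(b))) < tol * 100
  res["conjugate involution"] <-
    identical(unclass(quat_conj(quat_conj(a))), unclass(a))
  qa <- quat_prod(a, quat_inv(a))
  res["q * q^-1 = 1"] <- max(abs(unclass(qa) -
    matrix(rep(c(1, 0, 0, 0), each = n_random), ncol = 4))) < 1e-12 * 100
  rt <- vapply(seq_len(min(n_random, 200L)), function(r) {
    q1 <- quat(unclass(a)[r, 1], unclass(a)[r, 2], unclass(a)[r, 3], unclass(a)[r, 4])
    max(abs(unclass(quat_from_polar(quat_to_polar(q1))) - unclass(q1)))
  }, numeric(1))
  res["polar round trip"] <- max(rt) < 1e-9
  rot <- vapply(seq_len(min(n_random, 200L)), function(r) {
    v <- rnorm(3); ax <- normalize_axis(rnorm(3)); th <- runif(1, -pi, pi)
    abs(sqrt(sum(rotate_vec3(v, ax, th)^2)) - sqrt(sum(v^2)))
  }, numeric(1))
  res["rotation preserves norm"] <- max(rot) < 1e-9
  for (nm in names(res)) {
    cat(sprintf("%-24s %s\n", nm, if (res[[nm]]) "PASS" else "FAIL"))
  }
  invisible(res)
}

#' 4x4 real-matrix representation of a quaternion
#'
#' Left multiplication by a quaternion is a linear map on the four
#' components; this returns the matrix `M` such that
#' `q (x) p == M %*% p` (components as a column in `(r, x, y, z)` order).
#' Useful as an independent check of the Hamilton product.
#'
#' @param q A single quaternion (or length-4 numeric).
#' @return A 4x4 numeric matrix.
#' @export
quat_matrix_rep <- function(q) {
  m <- as_quat_matrix(q)
  stopifnot(nrow(m) == 1L)
  r <- m[1, 1]; x <- m[1, 2]; y <- m[1, 3]; z <- m[1, 4]
  matrix(c(r, x, y, z,
           -x, r, z, -y,
           -y, -z, r, x,
           -z, y, -x, r), 4L, 4L)
}

# save/restore global RNG state so seeded helpers do not disturb the caller
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

with_seed <- function(seed, code) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  code
}
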