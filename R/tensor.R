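# Vectorized 3x3 tensor algebra.
#
# Second-order tensors at n evaluation points are stored as n x 9 matrices in
# column-major component order (11, 21, 31, 12, 22, 32, 13, 23, 33), i.e.
# row k of the matrix is as.vector() of the k-th 3x3 tensor.  Vectors are
# n x 3 matrices.  All operations are elementwise over rows.

#' Stack of identity tensors
#'
#' @param n number of evaluation points.
#' @return an `n x 9` matrix, each row the identity tensor.
#' @keywords internal
t3_eye <- function(n) {
  out <- matrix(0, n, 9)
  out[, c(1L, 5L, 9L)] <- 1
  out
}

#' @keywords internal
t3_det <- function(A) {
  A[, 1L] * (A[, 5L] * A[, 9L] - A[, 8L] * A[, 6L]) -
    A[, 4L] * (A[, 2L] * A[, 9L] - A[, 8L] * A[, 3L]) +
    A[, 7L] * (A[, 2L] * A[, 6L] - A[, 5L] * A[, 3L])
}

#' @keywords internal
t3_transpose <- function(A) A[, c(1L, 4L, 7L, 2L, 5L, 8L, 3L, 6L, 9L), drop = FALSE]

#' Rowwise matrix product C = A %*% B
#' @keywords internal
t3_mul <- function(A, B) {
  C <- matrix(0, nrow(A), 9)
  for (i in 1:3) for (j in 1:3) {
    cj <- i + 3L * (j - 1L)
    C[, cj] <- A[, i] * B[, 1L + 3L * (j - 1L)] +
      A[, i + 3L] * B[, 2L + 3L * (j - 1L)] +
      A[, i + 6L] * B[, 3L + 3L * (j - 1L)]
  }
  C
}

#' Rowwise inverse via the adjugate
#' @keywords internal
t3_inv <- function(A) {
  d <- t3_det(A)
  if (any(!is.finite(d)) || any(abs(d) < .Machine$double.xmin)) {
    stop("singular tensor in t3_inv()")
  }
  inv <- matrix(0, nrow(A), 9)
  inv[, 1L] <- (A[, 5L] * A[, 9L] - A[, 8L] * A[, 6L])
  inv[, 2L] <- -(A[, 2L] * A[, 9L] - A[, 8L] * A[, 3L])
  inv[, 3L] <- (A[, 2L] * A[, 6L] - A[, 5L] * A[, 3L])
  inv[, 4L] <- -(A[, 4L] * A[, 9L] - A[, 7L] * A[, 6L])
  inv[, 5L] <- (A[, 1L] * A[, 9L] - A[, 7L] * A[, 3L])
  inv[, 6L] <- -(A[, 1L] * A[, 6L] - A[, 4L] * A[, 3L])
  inv[, 7L] <- (A[, 4L] * A[, 8L] - A[, 7L] * A[, 5L])
  inv[, 8L] <- -(A[, 1L] * A[, 8L] - A[, 7L] * A[, 2L])
  inv[, 9L] <- (A[, 1L] * A[, 5L] - A[, 4L] * A[, 2L])
  inv / d
}

#' Rowwise outer product u (x) v
#' @keywords internal
t3_outer <- function(u, v) {
  C <- matrix(0, nrow(u), 9)
  for (i in 1:3) for (j in 1:3) C[, i + 3L * (j - 1L)] <- u[, i] * v[, j]
  C
}

#' Rowwise matrix-vector product A v
#' @keywords internal
t3_matvec <- function(A, v) {
  cbind(A[, 1L] * v[, 1L] + A[, 4L] * v[, 2L] + A[, 7L] * v[, 3L],
        A[, 2L] * v[, 1L] + A[, 5L] * v[, 2L] + A[, 8L] * v[, 3L],
        A[, 3L] * v[, 1L] + A[, 6L] * v[, 2L] + A[, 9L] * v[, 3L])
}

#' Rowwise double contraction A : B
#' @keywords internal
t3_ddot <- function(A, B) rowSums(A * B)

#' Rowwise trace
#' @keywords internal
t3_trace <- function(A) A[, 1L] + A[, 5L] + A[, 9L]

#' Coerce a single 3x3 matrix (or n x 9 matrix) to stack form
#' @keywords internal
as_t3 <- function(A, n = NULL) {
  if (is.matrix(A) && ncol(A) == 3L && nrow(A) == 3L) {
    A <- matrix(as.vector(A), 1L, 9L)
  }
  stopifnot(is.matrix(A), ncol(A) == 9L)
  if (!is.null(n) && nrow(A) == 1L && n > 1L) {
    A <- A[rep(1L, n), , drop = FALSE]
  }
  A
}
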