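# Small 3-D geometry helpers shared across the package. All rotation
# matrices map segment-frame vectors into the global frame (columns are the
# segment axes expressed globally).

#' Cross product of two 3-vectors
#'
#' @param a,b numeric length-3 vectors.
#' @return numeric length-3 vector `a x b`.
#' @export
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Skew-symmetric (cross-product) matrix of a 3-vector
#' @param a numeric length-3 vector.
#' @return 3x3 matrix `S` with `S %*% b == cross3(a, b)`.
#' @export
skew3 <- function(a) {
  matrix(c(0, a[3], -a[2],
           -a[3], 0, a[1],
           a[2], -a[1], 0), 3, 3)
}

# Elementary rotation about a named axis, angle in radians.
rot_axis <- function(axis, theta) {
  ct <- cos(theta); st <- sin(theta)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, ct, st, 0, -st, ct), 3, 3),
    y = matrix(c(ct, 0, -st, 0, 1, 0, st, 0, ct), 3, 3),
    z = matrix(c(ct, st, 0, -st, ct, 0, 0, 0, 1), 3, 3),
    stop("unknown rotation axis: ", axis)
  )
}

#' Euler angles to rotation matrix
#'
#' Composes elementary rotations in the order given, i.e. for
#' `order = c("z","x","y")` the result is `Rz %*% Rx %*% Ry` (intrinsic
#' rotations applied in listed order, the BVH convention).
#'
#' @param angles numeric angles in radians, same length as `order`.
#' @param order character vector of axis names in application order.
#' @return 3x3 rotation matrix.
#' @export
euler_to_rot <- function(angles, order = c("z", "x", "y")) {
  stopifnot(length(angles) == length(order))
  R <- diag(3)
  for (k in seq_along(order)) R <- R %*% rot_axis(order[k], angles[k])
  R
}

#' Rotation matrix to Euler angles
#'
#' Inverse of [euler_to_rot()] for the orders used by the BVH writer.
#' Returns angles in radians. Supported orders: "yxz" and "zxy".
#'
#' @param R 3x3 rotation matrix.
#' @param order character scalar, e.g. "yxz".
#' @return numeric length-3 angles in the same order as `order`.
#' @export
rot_to_euler <- function(R, order = "yxz") {
  clamp <- function(x) max(-1, min(1, x))
  if (order == "yxz") {
    # R = Ry(a) Rx(b) Rz(c):  R[2,3] = -sin(b)
    b <- asin(clamp(-R[2, 3]))
    if (abs(cos(b)) > 1e-9) {
      a <- atan2(R[1, 3], R[3, 3])
      c <- atan2(R[2, 1], R[2, 2])
    } else {                             # gimbal: fold everything into a
      a <- atan2(R[1, 2], R[1, 1])
      c <- 0
    }
    c(a, b, c)
  } else if (order == "zxy") {
    # R = Rz(a) Rx(b) Ry(c)
    b <- asin(clamp(R[3, 2]))
    if (abs(cos(b)) > 1e-9) {
      a <- atan2(-R[1, 2], R[2, 2])
      c <- atan2(-R[3, 1], R[3, 3])
    } else {
      a <- atan2(R[2, 1], R[1, 1])
      c <- 0
    }
    c(a, b, c)
  } else {
    stop("unsupported Euler order: ", order)
  }
}

# check near-orthonormality of a rotation matrix
is_rotation <- function(R, tol = 1e-6) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) < tol
}

vnorm <- function(v) sqrt(sum(v * v))

# row-wise norms of an n x 3 matrix
rownorms <- function(m) sqrt(rowSums(m * m))

#' Verify Euler-to-rotation round trip helper used internally
#' @noRd
mat3 <- function(...) matrix(c(...), 3, 3)
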