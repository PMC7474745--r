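# Rigid-transform algebra: the currency of all frame math in the package.
# A rigid_transform is a list(rotation = 3x3 orthonormal, translation = 3-vec),
# mapping points from the local frame into the parent frame.

#' Construct a rigid transform
#'
#' A rigid transform is the pair of a 3x3 rotation matrix and a 3-vector
#' translation (metres).  It maps a point `x` expressed in the child frame to
#' `rotation %*% x + translation` in the parent frame.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation numeric 3-vector (m).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L))) {
    stop("rotation must be a 3x3 matrix", call. = FALSE)
  }
  if (length(translation) != 3L) {
    stop("translation must have length 3", call. = FALSE)
  }
  err <- max(abs(crossprod(rotation) - diag(3)))
  if (!is.finite(err) || err > 1e-8 || abs(det(rotation) - 1) > 1e-8) {
    stop("rotation must be orthonormal with determinant +1", call. = FALSE)
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  m <- cbind(rbind(x$rotation, 0), c(x$translation, 1))
  print(signif(m, 6))
  invisible(x)
}

#' Compose two rigid transforms
#'
#' `rt_compose(a, b)` is the transform that first applies `b`, then `a`
#' (matrix convention `a %*% b`).
#'
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
rt_compose <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param tf A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
rt_inverse <- function(tf) {
  rt <- t(tf$rotation)
  rigid_transform(rt, as.numeric(-rt %*% tf$translation))
}

#' Apply a rigid transform to one or more points
#' @param tf A `rigid_transform`.
#' @param x A 3-vector or a 3-row matrix of points in the child frame.
#' @return Points in the parent frame, same shape as `x`.
#' @export
rt_apply <- function(tf, x) {
  if (is.matrix(x)) {
    tf$rotation %*% x + tf$translation
  } else {
    as.numeric(tf$rotation %*% x) + tf$translation
  }
}

#' Serialize / deserialize a rigid transform as 16 row-major numbers
#'
#' The 4x4 homogeneous matrix is flattened row-major, the conventional
#' interchange format for pose logs.
#'
#' @param tf A `rigid_transform`.
#' @return `rt_flatten`: numeric vector of length 16. `rt_unflatten`: a
#'   `rigid_transform` rebuilt from such a vector.
#' @export
rt_flatten <- function(tf) {
  m <- cbind(rbind(tf$rotation, 0), c(tf$translation, 1))
  as.numeric(t(m))
}

#' @rdname rt_flatten
#' @param v numeric vector of length 16 (row-major homogeneous matrix).
#' @export
rt_unflatten <- function(v) {
  stopifnot(length(v) == 16L)
  m <- matrix(v, 4, 4, byrow = TRUE)
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}

#' Elementary rotations and axis-angle rotation matrices
#'
#' @param theta rotation angle (rad).
#' @return 3x3 rotation matrix.
#' @export
rot_x <- function(theta) {
  c1 <- cos(theta); s1 <- sin(theta)
  matrix(c(1, 0, 0, 0, c1, -s1, 0, s1, c1), 3, 3, byrow = TRUE)
}

#' @rdname rot_x
#' @export
rot_y <- function(theta) {
  c1 <- cos(theta); s1 <- sin(theta)
  matrix(c(c1, 0, s1, 0, 1, 0, -s1, 0, c1), 3, 3, byrow = TRUE)
}

#' @rdname rot_x
#' @export
rot_z <- function(theta) {
  c1 <- cos(theta); s1 <- sin(theta)
  matrix(c(c1, -s1, 0, s1, c1, 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

#' @rdname rot_x
#' @param axis unit 3-vector (normalized internally).
#' @export
rot_axis_angle <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  k <- skew3(a)
  diag(3) + sin(theta) * k + (1 - cos(theta)) * (k %*% k)
}

# Skew-symmetric (cross-product) matrix of a 3-vector.
skew3 <- function(v) {
  matrix(c(0, -v[3], v[2],
           v[3], 0, -v[1],
           -v[2], v[1], 0), 3, 3, byrow = TRUE)
}

# Cross product of 3-vectors.
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Axis-angle (rotation vector) of a rotation matrix; used by the IK error.
rotation_log <- function(r) {
  ct <- (sum(diag(r)) - 1) / 2
  ct <- min(1, max(-1, ct))
  theta <- acos(ct)
  if (theta < 1e-12) return(c(0, 0, 0))
  if (abs(pi - theta) < 1e-6) {
    # near pi: extract axis from the symmetric part
    b <- (r + diag(3)) / 2
    axis <- sqrt(pmax(diag(b), 0))
    # fix signs from off-diagonals
    i <- which.max(axis)
    if (i == 1L) {
      axis <- c(axis[1], b[1, 2] / axis[1], b[1, 3] / axis[1])
    } else if (i == 2L) {
      axis <- c(b[1, 2] / axis[2], axis[2], b[2, 3] / axis[2])
    } else {
      axis <- c(b[1, 3] / axis[3], b[2, 3] / axis[3], axis[3])
    }
    return(theta * axis / sqrt(sum(axis^2)))
  }
  v <- c(r[3, 2] - r[2, 3], r[1, 3] - r[3, 1], r[2, 1] - r[1, 2])
  theta / (2 * sin(theta)) * v
}
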