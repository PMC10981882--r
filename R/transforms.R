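#' Rigid transform (proper rotation + translation)
#'
#' A rigid motion of 3-D space, \code{p -> R p + t}, with \code{R} a proper
#' rotation (orthonormal, determinant +1; reflections are rejected because
#' anatomy cannot mirror) and \code{t} a translation in millimetres.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric translation (mm).
#' @return An object of class \code{rigid_transform} with fields
#'   \code{rotation} and \code{translation}.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || any(!is.finite(rotation)))
    .np_stopf("rotation must be a finite 3x3 matrix")
  if (length(translation) != 3L || any(!is.finite(translation)))
    .np_stopf("translation must be a finite length-3 vector")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    .np_stopf("rotation is not orthonormal (max |R'R - I| = %.3g)",
              max(abs(crossprod(rotation) - diag(3))))
  if (det(rotation) < 0)
    .np_stopf("rotation has determinant %.3f: reflections are not rigid motions",
              det(rotation))
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x)
  cat(sprintf("<rigid_transform> rotation %.4f deg, translation (%.4f, %.4f, %.4f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' @rdname rigid_transform
#' @export
identity_transform <- function() rigid_transform()

#' Rotation angle of a rigid transform, in degrees
#' @param t A \code{rigid_transform}.
#' @return Rotation angle in [0, 180] degrees.
#' @export
rotation_angle_deg <- function(t) {
  tr <- sum(diag(t$rotation))
  acos(max(-1, min(1, (tr - 1) / 2))) * 180 / pi
}

#' Compose and invert rigid transforms
#'
#' \code{compose_transform(a, b)} returns the transform applying \code{b}
#' first, then \code{a} (the matrix convention).
#'
#' @param a,b,t \code{rigid_transform} objects.
#' @return A \code{rigid_transform}.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname compose_transform
#' @export
invert_transform <- function(t) {
  rigid_transform(t(t$rotation), as.numeric(-t(t$rotation) %*% t$translation))
}

#' Apply a rigid transform to points, a point cloud or a mesh
#'
#' @param t A \code{rigid_transform}.
#' @param x An n x 3 matrix, a \code{point_cloud} or a \code{tri_mesh}.
#' @return Object of the same type with every point mapped to
#'   \code{R p + t}. Pairwise distances are preserved.
#' @export
apply_transform <- function(t, x) UseMethod("apply_transform", x)

#' @export
apply_transform.default <- function(t, x) {
  x <- as.matrix(x)
  if (ncol(x) != 3L) .np_stopf("points must be an n x 3 matrix")
  sweep(x %*% t(t$rotation), 2L, t$translation, "+")
}

#' @export
apply_transform.point_cloud <- function(t, x) {
  x$points <- apply_transform.default(t, x$points)
  x
}

#' @export
apply_transform.tri_mesh <- function(t, x) {
  x$vertices <- apply_transform.default(t, x$vertices)
  x
}

#' Closed-form least-squares rigid fit (Kabsch)
#'
#' Finds the proper rigid transform minimizing
#' \code{sum_i || R p_i + t - q_i ||^2} for paired points, via SVD of the
#' cross-covariance with determinant correction so that reflections are never
#' returned even for mirrored configurations.
#'
#' @param p,q n x 3 matrices of corresponding points (source, target).
#' @return A list with \code{transform} (\code{rigid_transform}) and
#'   \code{rms_mm}, the root-mean-square residual at the optimum.
#' @export
fit_rigid <- function(p, q) {
  p <- as.matrix(p); q <- as.matrix(q)
  if (!all(dim(p) == dim(q)) || ncol(p) != 3L)
    .np_stopf("p and q must be n x 3 matrices of equal size")
  if (nrow(p) < 3L) .np_stopf("at least 3 point pairs are required")
  cp <- colMeans(p); cq <- colMeans(q)
  pc <- sweep(p, 2L, cp); qc <- sweep(q, 2L, cq)
  H <- crossprod(pc, qc)                       # sum p_c q_c'
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- cq - as.numeric(R %*% cp)
  tf <- rigid_transform(R, tr)
  res <- apply_transform(tf, p) - q
  list(transform = tf, rms_mm = sqrt(mean(rowSums(res^2))))
}

#' Serialize a rigid transform as a 4x4 homogeneous matrix
#' @param t A \code{rigid_transform}.
#' @return A 4x4 matrix (last row 0 0 0 1).
#' @export
as_homogeneous <- function(t) {
  m <- diag(4)
  m[1:3, 1:3] <- t$rotation
  m[1:3, 4] <- t$translation
  m
}

#' @rdname as_homogeneous
#' @param m A 4x4 homogeneous matrix.
#' @export
from_homogeneous <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(4L, 4L))) .np_stopf("expected a 4x4 matrix")
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}

# Rodrigues rotation about unit axis by angle (radians)
rotation_about_axis <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
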