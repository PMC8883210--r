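#' Rigid transforms in millimeter space
#'
#' A rigid transform maps points `p` as `R p + t`, with `R` a proper rotation
#' (orthonormal, determinant +1) and `t` a translation in millimeters. These
#' transforms carry every frame change in the pipeline: scanner-to-camera
#' camera poses, the object pose recovered by registration, and calibration
#' target poses.
#'
#' @param rotation 3x3 orthonormal rotation matrix (determinant +1).
#' @param translation length-3 numeric translation (mm).
#' @return An object of class `rigid_transform` with fields `rotation` and
#'   `translation`.
#' @examples
#' tr <- rigid_transform(rot_axis_angle(c(0, 0, 1), 90), c(10, 0, 0))
#' rt_apply(tr, matrix(c(1, 0, 0), 1))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- as.numeric(translation)
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3)
  if (!all(is.finite(rotation)) || !all(is.finite(translation)))
    stop("rigid_transform: non-finite entries")
  err <- max(abs(crossprod(rotation) - diag(3)))
  if (err > 1e-6)
    stop(sprintf("rotation is not orthonormal (max |R'R - I| = %.2e)", err))
  if (det(rotation) < 0)
    stop("rotation has determinant -1 (improper rotation)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>  angle", sprintf("%.3f", rotation_angle(x$rotation)),
      "deg,  t = [", paste(sprintf("%.3f", x$translation), collapse = ", "),
      "] mm\n")
  invisible(x)
}

#' Identity transform
#' @return A `rigid_transform` that leaves points unchanged.
#' @export
rt_identity <- function() rigid_transform()

#' Compose two rigid transforms
#'
#' `rt_compose(a, b)` is the transform that applies `b` first, then `a`
#' (function composition `a o b`).
#' @param a,b `rigid_transform` objects.
#' @return The composed `rigid_transform`.
#' @export
rt_compose <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param a A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
rt_inverse <- function(a) {
  rigid_transform(t(a$rotation), as.numeric(-t(a$rotation) %*% a$translation))
}

#' Apply a rigid transform to points
#' @param a A `rigid_transform`.
#' @param points N x 3 matrix of points (mm); a length-3 vector is accepted.
#' @return N x 3 matrix of transformed points.
#' @export
rt_apply <- function(a, points) {
  if (is.null(dim(points))) points <- matrix(points, 1)
  sweep(points %*% t(a$rotation), 2, a$translation, "+")
}

#' Rotation matrix from axis and angle
#' @param axis length-3 axis (need not be unit).
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix (Rodrigues' formula).
#' @export
rot_axis_angle <- function(axis, angle_deg) {
  n <- sqrt(sum(axis^2))
  if (n == 0) stop("zero rotation axis")
  k <- axis / n
  th <- angle_deg * pi / 180
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotation angle of a rotation matrix
#' @param R 3x3 rotation matrix.
#' @return The rotation angle in degrees, in \[0, 180\].
#' @export
rotation_angle <- function(R) {
  acos(min(1, max(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

# Rodrigues vector <-> rotation matrix (used by the calibration refiner).
rodrigues_to_rot <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  rot_axis_angle(w, th * 180 / pi)
}

rot_to_rodrigues <- function(R) {
  th <- acos(min(1, max(-1, (sum(diag(R)) - 1) / 2)))
  if (th < 1e-12) return(c(0, 0, 0))
  if (th > pi - 1e-6) {
    # near 180 deg: extract axis from R + I
    M <- (R + diag(3)) / 2
    axis <- sqrt(pmax(diag(M), 0))
    i <- which.max(axis)
    axis <- M[, i] / axis[i]
    return(axis / sqrt(sum(axis^2)) * th)
  }
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  v / (2 * sin(th)) * th
}

# Nearest proper rotation to an arbitrary 3x3 matrix (orthogonal Procrustes).
project_to_rotation <- function(M) {
  s <- svd(M)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  R
}
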