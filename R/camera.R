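#' Pinhole camera model with radial-tangential distortion
#'
#' The camera maps scanner-frame points to pixels in three steps: the rigid
#' `pose` (scanner frame to camera frame), perspective division, then a
#' 5-parameter polynomial distortion and the intrinsic matrix. Pixel
#' coordinates are 0-based with pixel centers at integer coordinates, so the
#' principal point of a `width x height` sensor lies near
#' `((width-1)/2, (height-1)/2)`.
#'
#' The distortion vector is ordered `(k1, k2, k3, p1, p2)`: three polynomial
#' radial coefficients and two tangential ones.
#'
#' @param name camera identifier (string).
#' @param fx,fy focal lengths in pixels (positive).
#' @param cx,cy principal point in pixels (inside the sensor).
#' @param width,height sensor size in pixels.
#' @param distortion length-5 numeric `(k1, k2, k3, p1, p2)`.
#' @param pose `rigid_transform` mapping scanner-frame points into the camera
#'   frame.
#' @return An object of class `camera_model`.
#' @examples
#' cam <- camera_model("ir0", fx = 800, fy = 800, cx = 320, cy = 256,
#'                     width = 640, height = 512)
#' project_points(matrix(c(0, 0, 500), 1), cam)
#' @export
camera_model <- function(name, fx, fy, cx, cy, width, height,
                         distortion = rep(0, 5), pose = rt_identity()) {
  stopifnot(fx > 0, fy > 0, length(distortion) == 5,
            inherits(pose, "rigid_transform"))
  if (cx < 0 || cx >= width || cy < 0 || cy >= height)
    stop("principal point outside sensor bounds")
  structure(list(name = as.character(name), fx = fx, fy = fy, cx = cx,
                 cy = cy, width = as.integer(width),
                 height = as.integer(height),
                 distortion = as.numeric(distortion), pose = pose),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model> %s  %dx%d  f=(%.1f, %.1f) c=(%.1f, %.1f)\n",
              x$name, x$width, x$height, x$fx, x$fy, x$cx, x$cy))
  invisible(x)
}

# Apply the radial-tangential distortion polynomial to normalized coords.
distort_normalized <- function(xy, distortion) {
  k1 <- distortion[1]; k2 <- distortion[2]; k3 <- distortion[3]
  p1 <- distortion[4]; p2 <- distortion[5]
  x <- xy[, 1]; y <- xy[, 2]
  r2 <- x^2 + y^2
  radial <- 1 + k1 * r2 + k2 * r2^2 + k3 * r2^3
  cbind(x * radial + 2 * p1 * x * y + p2 * (r2 + 2 * x^2),
        y * radial + p1 * (r2 + 2 * y^2) + 2 * p2 * x * y)
}

#' Project camera-frame points to pixels
#'
#' @param points N x 3 matrix of camera-frame points (mm); all depths must be
#'   strictly positive.
#' @param cam A `camera_model`.
#' @return N x 2 matrix of pixel coordinates `(u, v)`.
#' @export
project_points <- function(points, cam) {
  if (is.null(dim(points))) points <- matrix(points, 1)
  z <- points[, 3]
  if (any(z <= 0))
    stop("point behind camera: non-positive depth in camera frame")
  nd <- distort_normalized(cbind(points[, 1] / z, points[, 2] / z),
                           cam$distortion)
  cbind(u = cam$fx * nd[, 1] + cam$cx, v = cam$fy * nd[, 2] + cam$cy)
}

#' Back-project pixels to unit rays in the camera frame
#'
#' Inverts the distortion polynomial by fixed-point iteration (at most
#' `max_iter` sweeps, convergence 1e-12 in normalized coordinates) and
#' returns the unit direction of the viewing ray through each pixel. The ray
#' origin is the camera center (0, 0, 0 in camera frame).
#'
#' @param pixels N x 2 matrix of pixel coordinates inside the sensor bounds.
#' @param cam A `camera_model`.
#' @param max_iter iteration cap for distortion inversion.
#' @return N x 3 matrix of unit ray directions in the camera frame.
#' @export
unproject_pixels <- function(pixels, cam, max_iter = 50) {
  if (is.null(dim(pixels))) pixels <- matrix(pixels, 1)
  xd <- (pixels[, 1] - cam$cx) / cam$fx
  yd <- (pixels[, 2] - cam$cy) / cam$fy
  x <- xd; y <- yd
  if (any(cam$distortion != 0)) {
    k1 <- cam$distortion[1]; k2 <- cam$distortion[2]; k3 <- cam$distortion[3]
    p1 <- cam$distortion[4]; p2 <- cam$distortion[5]
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      r2 <- x^2 + y^2
      radial <- 1 + k1 * r2 + k2 * r2^2 + k3 * r2^3
      nx <- (xd - (2 * p1 * x * y + p2 * (r2 + 2 * x^2))) / radial
      ny <- (yd - (p1 * (r2 + 2 * y^2) + 2 * p2 * x * y)) / radial
      delta <- max(abs(nx - x), abs(ny - y))
      x <- nx; y <- ny
      if (delta < 1e-12) { converged <- TRUE; break }
    }
    if (!converged)
      stop(sprintf("distortion inversion did not converge in %d iterations",
                   max_iter))
  }
  d <- cbind(x, y, 1)
  d / sqrt(rowSums(d^2))
}

#' Scanner-frame viewing rays through pixels
#'
#' @param pixels N x 2 pixel coordinates.
#' @param cam A `camera_model`.
#' @return List with `origins` (N x 3, all the camera center, mm) and
#'   `directions` (N x 3 unit vectors), both in the scanner frame.
#' @export
pixel_rays <- function(pixels, cam) {
  dirs_cam <- unproject_pixels(pixels, cam)
  inv <- rt_inverse(cam$pose)
  center <- matrix(inv$translation, nrow(dirs_cam), 3, byrow = TRUE)
  list(origins = center, directions = dirs_cam %*% cam$pose$rotation)
}

#' Camera center and optical axis in the scanner frame
#' @param cam A `camera_model`.
#' @return `camera_center`: length-3 position (mm); `optical_axis`: unit
#'   direction of the camera Z-axis.
#' @export
camera_center <- function(cam) {
  as.numeric(-t(cam$pose$rotation) %*% cam$pose$translation)
}

#' @rdname camera_center
#' @export
optical_axis <- function(cam) {
  as.numeric(t(cam$pose$rotation) %*% c(0, 0, 1))
}

#' Incident angle between the optical axis and a surface normal
#'
#' The reliability score used when fusing multi-camera observations: the
#' angle between the camera optical axis (camera Z-axis, scanner frame) and
#' the surface normal at the observed point. The absolute dot product is
#' used, so the angle is invariant to the normal's sign and lies in
#' \[0, 90\] degrees; 0 means the surface faces the camera head-on.
#'
#' @param cam A `camera_model`.
#' @param normals N x 3 matrix of unit surface normals in the scanner frame.
#' @return Numeric vector of angles in degrees.
#' @export
incident_angle <- function(cam, normals) {
  if (is.null(dim(normals))) normals <- matrix(normals, 1)
  n <- sqrt(rowSums(normals^2))
  if (any(n < 1e-12)) stop("zero-length surface normal")
  axis <- optical_axis(cam)
  d <- abs(as.numeric(normals %*% axis)) / n
  acos(pmin(1, d)) * 180 / pi
}
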