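#' Scene point cloud
#'
#' Points measured by the 3D scanner, in millimeters in the scanner frame.
#' Non-finite points are dropped with a message at construction.
#'
#' @param points N x 3 numeric matrix (mm).
#' @param normals optional N x 3 unit normals.
#' @return An object of class `scene_cloud`.
#' @export
scene_cloud <- function(points, normals = NULL) {
  points <- unname(as.matrix(points))
  stopifnot(ncol(points) == 3)
  ok <- apply(is.finite(points), 1, all)
  if (!all(ok)) {
    message(sum(!ok), " non-finite point(s) dropped")
    points <- points[ok, , drop = FALSE]
    if (!is.null(normals)) normals <- normals[ok, , drop = FALSE]
  }
  if (nrow(points) == 0) stop("empty point cloud")
  structure(list(points = points, normals = normals), class = "scene_cloud")
}

#' @export
print.scene_cloud <- function(x, ...) {
  cat(sprintf("<scene_cloud> %d points\n", nrow(x$points)))
  invisible(x)
}

#' Localize an object by mesh-to-cloud ICP registration
#'
#' Estimates the object pose (rotation and translation, object frame to
#' scanner frame) by point-to-plane iterative closest point between the
#' scene cloud and the mesh surface. Correspondences are exact closest
#' points on the triangulated surface (not vertex nearest neighbors), so
#' coarse tessellation does not bias the fit. The solve requires an initial
#' pose inside the convergence basin; global pose retrieval is out of
#' scope.
#'
#' Registration is declared failed (an error of class
#' `thermaltouch_localization_failure`) when fewer than `min_inlier_fraction`
#' of the cloud points lie within `correspondence_radius` of the surface at
#' convergence — the analogue of a localization miss on an object the scan
#' does not actually match.
#'
#' @param mesh A `triangle_mesh` in object coordinates.
#' @param cloud A `scene_cloud` in scanner coordinates.
#' @param initial initial `rigid_transform` (object to scanner frame).
#' @param max_iterations iteration cap.
#' @param correspondence_radius correspondence rejection radius (mm).
#' @param convergence_tol pose-update size below which the solve stops (mm).
#' @param min_inlier_fraction failure threshold on the inlier fraction.
#' @return An object of class `object_pose`: `transform`
#'   (`rigid_transform`, object to scanner), `rms_residual` (mm, inliers),
#'   `inlier_fraction`, `iterations`, `converged`, and `history` (RMS
#'   point-to-plane residual per accepted iteration).
#' @export
register_mesh <- function(mesh, cloud, initial = rt_identity(),
                          max_iterations = 50, correspondence_radius = 10,
                          convergence_tol = 1e-3,
                          min_inlier_fraction = 0.3) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(cloud, "scene_cloud"),
            inherits(initial, "rigid_transform"))
  pts <- cloud$points
  sv <- svd(sweep(pts, 2, colMeans(pts)), nu = 0, nv = 0)$d
  if (nrow(pts) < 4 || sv[3] < 1e-6 * max(sv[1], 1))
    stop("degenerate point cloud: rank < 3")
  pose <- initial
  rms <- Inf
  history <- numeric()
  converged <- FALSE
  for (it in seq_len(max_iterations)) {
    q <- rt_apply(rt_inverse(pose), pts)           # cloud in object frame
    cp <- cpp_closest_point(q, mesh$vertices, mesh$faces - 1L)
    inl <- cp$dist <= correspondence_radius
    if (sum(inl) < 6)
      rlang::abort(sprintf(
        "localization failure: only %d correspondences within %.1f mm",
        sum(inl), correspondence_radius),
        class = "thermaltouch_localization_failure",
        inlier_fraction = mean(inl))
    n <- mesh$face_normals[cp$face[inl], , drop = FALSE]
    qi <- q[inl, , drop = FALSE]
    ci <- cp$points[inl, , drop = FALSE]
    r <- rowSums(n * (qi - ci))
    rms <- sqrt(mean(r^2))
    history <- c(history, rms)
    cxn <- cbind(qi[, 2] * n[, 3] - qi[, 3] * n[, 2],
                 qi[, 3] * n[, 1] - qi[, 1] * n[, 3],
                 qi[, 1] * n[, 2] - qi[, 2] * n[, 1])
    A <- cbind(cxn, n)
    xi <- tryCatch(solve(crossprod(A), -crossprod(A, r)),
                   error = function(e) stop(
                     "degenerate geometry: normal equations singular"))
    xi <- as.numeric(xi)
    delta <- rigid_transform(rodrigues_to_rot(xi[1:3]), xi[4:6])
    # update acts on object-frame points, so fold its inverse into the pose
    pose <- rt_compose(pose, rt_inverse(delta))
    step <- sqrt(sum(xi[4:6]^2)) +
      sqrt(sum(xi[1:3]^2)) * max(sqrt(rowSums(qi^2)))
    if (step < convergence_tol) { converged <- TRUE; break }
  }
  if (!converged)
    rlang::abort(sprintf(
      "ICP did not converge in %d iterations (last RMS %.3f mm)",
      max_iterations, rms),
      class = "thermaltouch_icp_nonconvergence", rms_residual = rms)
  q <- rt_apply(rt_inverse(pose), pts)
  cp <- cpp_closest_point(q, mesh$vertices, mesh$faces - 1L)
  inl <- cp$dist <= correspondence_radius
  inlier_fraction <- mean(inl)
  n <- mesh$face_normals[cp$face[inl], , drop = FALSE]
  r <- rowSums(n * (q[inl, , drop = FALSE] - cp$points[inl, , drop = FALSE]))
  rms <- sqrt(mean(r^2))
  if (inlier_fraction < min_inlier_fraction)
    rlang::abort(sprintf(
      "localization failure: inlier fraction %.2f below %.2f",
      inlier_fraction, min_inlier_fraction),
      class = "thermaltouch_localization_failure",
      inlier_fraction = inlier_fraction)
  structure(list(transform = pose, rms_residual = rms,
                 inlier_fraction = inlier_fraction, iterations = it,
                 converged = TRUE, history = history),
            class = "object_pose")
}

#' Construct an object pose directly
#'
#' Wraps a known object-to-scanner transform in the pose container used by
#' the mapping stage (the alternative path when the pose is known without
#' registration).
#'
#' @param transform `rigid_transform`, object to scanner frame.
#' @param rms_residual,inlier_fraction optional diagnostics.
#' @return An `object_pose`.
#' @export
object_pose <- function(transform, rms_residual = 0, inlier_fraction = 1) {
  stopifnot(inherits(transform, "rigid_transform"),
            rms_residual >= 0, inlier_fraction >= 0, inlier_fraction <= 1)
  structure(list(transform = transform, rms_residual = rms_residual,
                 inlier_fraction = inlier_fraction, iterations = 0L,
                 converged = TRUE),
            class = "object_pose")
}

#' @export
print.object_pose <- function(x, ...) {
  cat(sprintf("<object_pose> rms %.4f mm, inliers %.0f%%, %d iteration(s)\n",
              x$rms_residual, 100 * x$inlier_fraction, x$iterations))
  print(x$transform)
  invisible(x)
}

#' @rdname register_mesh
#' @param x An `object_pose`.
#' @param ... unused.
#' @method glance object_pose
#' @export
glance.object_pose <- function(x, ...) {
  tibble::tibble(rms_residual_mm = x$rms_residual,
                 inlier_fraction = x$inlier_fraction,
                 iterations = x$iterations, converged = x$converged)
}
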