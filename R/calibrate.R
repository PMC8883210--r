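#' Calibrate a multi-camera rig from circle-grid observations
#'
#' Solves per-camera intrinsics by planar-target calibration (closed-form
#' homography decomposition followed by joint nonlinear refinement of
#' intrinsics and per-pose extrinsics), then chains relative poses through
#' shared target poses so that every camera's pose is expressed relative to
#' a designated reference camera, which stands in for the 3D scanner frame.
#'
#' Every camera needs at least three target poses; cameras are linked into
#' one rig through poses observed by more than one camera, and the pose
#' graph must be connected.
#'
#' @param observations list of `target_observation` objects (see
#'   [detect_target()]); each carries its `camera_name` and `pose_id`.
#' @param reference name of the reference camera (default: first seen).
#' @param width,height sensor size recorded into the recovered cameras (px).
#' @return An object of class `rig_calibration`: `cameras` (named list of
#'   [camera_model()] with poses mapping reference-frame points to each
#'   camera frame), `mean_reprojection_error` (px), `per_camera` (tibble of
#'   intrinsics and errors), `reference`.
#' @export
calibrate_rig <- function(observations, reference = NULL,
                          width = 640L, height = 512L) {
  stopifnot(length(observations) > 0,
            all(vapply(observations, inherits, TRUE, "target_observation")))
  cams <- vapply(observations, function(o) o$camera_name, "")
  poses <- vapply(observations, function(o) o$pose_id, "")
  cam_names <- unique(cams)
  if (is.null(reference)) reference <- cam_names[1]
  if (!reference %in% cam_names) stop("reference camera has no observations")

  per_cam <- lapply(cam_names, function(cn) {
    obs <- observations[cams == cn]
    if (length(obs) < 3)
      stop(sprintf("camera %s has %d pose(s); at least 3 required",
                   cn, length(obs)))
    calibrate_single(obs, width, height)
  })
  names(per_cam) <- cam_names

  # T[pose][camera]: target-frame -> camera-frame transforms
  pose_tab <- split(seq_along(observations), poses)
  rel_to_ref <- chain_poses(per_cam, cams, poses, cam_names, reference)

  cameras <- lapply(cam_names, function(cn) {
    k <- per_cam[[cn]]$K
    camera_model(cn, fx = k[1], fy = k[2], cx = k[3], cy = k[4],
                 width = width, height = height,
                 pose = rel_to_ref[[cn]])
  })
  names(cameras) <- cam_names
  errs <- vapply(per_cam, function(x) x$reproj_error, 0)
  structure(list(
    cameras = cameras,
    reference = reference,
    mean_reprojection_error = mean(errs),
    per_camera = tibble::tibble(
      camera = cam_names,
      fx = vapply(per_cam, function(x) x$K[1], 0),
      fy = vapply(per_cam, function(x) x$K[2], 0),
      cx = vapply(per_cam, function(x) x$K[3], 0),
      cy = vapply(per_cam, function(x) x$K[4], 0),
      n_poses = vapply(per_cam, function(x) length(x$extrinsics), 0L),
      reproj_error_px = errs)),
    class = "rig_calibration")
}

#' @export
print.rig_calibration <- function(x, ...) {
  cat(sprintf("<rig_calibration> %d cameras (reference %s), mean reprojection %.4f px\n",
              length(x$cameras), x$reference, x$mean_reprojection_error))
  print(x$per_camera)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname calibrate_rig
#' @param x A `rig_calibration`.
#' @param ... unused.
#' @method tidy rig_calibration
#' @export
tidy.rig_calibration <- function(x, ...) x$per_camera

#' @rdname calibrate_rig
#' @method glance rig_calibration
#' @export
glance.rig_calibration <- function(x, ...) {
  tibble::tibble(n_cameras = length(x$cameras),
                 reference = x$reference,
                 mean_reprojection_error_px = x$mean_reprojection_error)
}

# Zhang-style planar calibration of one camera from >=3 target views.
calibrate_single <- function(obs, width, height) {
  Hs <- lapply(obs, function(o)
    fit_homography(o$target_points[, 1:2], o$image_points))
  vij <- function(H, i, j) {
    c(H[1, i] * H[1, j],
      H[1, i] * H[2, j] + H[2, i] * H[1, j],
      H[2, i] * H[2, j],
      H[3, i] * H[1, j] + H[1, i] * H[3, j],
      H[3, i] * H[2, j] + H[2, i] * H[3, j],
      H[3, i] * H[3, j])
  }
  V <- do.call(rbind, lapply(Hs, function(H)
    rbind(vij(H, 1, 2), vij(H, 1, 1) - vij(H, 2, 2))))
  # zero-skew prior keeps the 3-view minimal case well conditioned
  V <- rbind(V, c(0, 1, 0, 0, 0, 0) * max(abs(V)))
  b <- svd(V, nu = 0)$v[, 6]
  B <- matrix(c(b[1], b[2], b[4], b[2], b[3], b[5], b[4], b[5], b[6]), 3, 3)
  if (B[1, 1] < 0) B <- -B
  v0 <- (B[1, 2] * B[1, 3] - B[1, 1] * B[2, 3]) /
    (B[1, 1] * B[2, 2] - B[1, 2]^2)
  lam <- B[3, 3] - (B[1, 3]^2 + v0 * (B[1, 2] * B[1, 3] -
                                        B[1, 1] * B[2, 3])) / B[1, 1]
  fx <- sqrt(lam / B[1, 1])
  fy <- sqrt(lam * B[1, 1] / (B[1, 1] * B[2, 2] - B[1, 2]^2))
  u0 <- -B[1, 3] * fx^2 / lam
  K0 <- c(fx, fy, u0, v0)
  Kmat <- function(k) rbind(c(k[1], 0, k[3]), c(0, k[2], k[4]), c(0, 0, 1))

  extr0 <- lapply(Hs, function(H) {
    A <- solve(Kmat(K0), H)
    s <- 1 / sqrt(sum(A[, 1]^2))
    if (s * A[3, 3] < 0) s <- -s      # target must sit in front of the camera
    r1 <- s * A[, 1]; r2 <- s * A[, 2]
    R <- project_to_rotation(cbind(r1, r2, pracma_cross(r1, r2)))
    list(R = R, t = s * A[, 3])
  })

  # joint refinement: intrinsics + per-pose rodrigues/translation
  p0 <- c(K0, unlist(lapply(extr0, function(e)
    c(rot_to_rodrigues(e$R), e$t))))
  resid_fun <- function(p) {
    K <- p[1:4]
    unlist(lapply(seq_along(obs), function(i) {
      q <- p[4 + (i - 1) * 6 + 1:6]
      R <- rodrigues_to_rot(q[1:3])
      pc <- sweep(obs[[i]]$target_points %*% t(R), 2, q[4:6], "+")
      uv <- cbind(K[1] * pc[, 1] / pc[, 3] + K[3],
                  K[2] * pc[, 2] / pc[, 3] + K[4])
      as.numeric(uv - obs[[i]]$image_points)
    }))
  }
  fit <- minpack.lm::nls.lm(p0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-14, ptol = 1e-14))
  p <- fit$par
  res <- matrix(resid_fun(p), ncol = 2)
  extr <- lapply(seq_along(obs), function(i) {
    q <- p[4 + (i - 1) * 6 + 1:6]
    rigid_transform(rodrigues_to_rot(q[1:3]), q[4:6])
  })
  names(extr) <- vapply(obs, function(o) o$pose_id, "")
  list(K = p[1:4], extrinsics = extr,
       reproj_error = sqrt(mean(rowSums(res^2))))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Chain per-(camera, pose) extrinsics into camera-to-reference transforms by
# breadth-first traversal of the shared-pose graph, averaging over all
# shared poses of an edge.
chain_poses <- function(per_cam, cams, poses, cam_names, reference) {
  seen_poses <- function(cn) names(per_cam[[cn]]$extrinsics)
  rel <- list()
  rel[[reference]] <- rt_identity()
  frontier <- reference
  remaining <- setdiff(cam_names, reference)
  while (length(frontier) > 0 && length(remaining) > 0) {
    nxt <- character()
    for (a in frontier) {
      for (b in remaining) {
        if (!is.null(rel[[b]])) next
        shared <- intersect(seen_poses(a), seen_poses(b))
        if (length(shared) == 0) next
        # T_b<-a averaged over shared target poses
        Rs <- matrix(0, 3, 3); ts <- c(0, 0, 0)
        for (p in shared) {
          Ta <- per_cam[[a]]$extrinsics[[p]]   # target -> a
          Tb <- per_cam[[b]]$extrinsics[[p]]   # target -> b
          Tba <- rt_compose(Tb, rt_inverse(Ta))
          Rs <- Rs + Tba$rotation; ts <- ts + Tba$translation
        }
        Tba <- rigid_transform(project_to_rotation(Rs),
                               ts / length(shared))
        rel[[b]] <- rt_compose(Tba, rel[[a]])  # ref -> b
        nxt <- c(nxt, b)
      }
      remaining <- setdiff(remaining, nxt)
    }
    frontier <- nxt
  }
  if (length(remaining) > 0)
    stop("pose graph disconnected; no shared poses for camera(s): ",
         paste(remaining, collapse = ", "))
  rel
}
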