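#' Specify a synthetic finger contact
#'
#' A contact is a point on the object surface (object frame) that was
#' touched and therefore carries a transient heat signature. Defaults match
#' resting skin against a room-temperature scene: peak 29.1 degC on an
#' ambient of about 25.4 degC, i.e. an excess of roughly 3.7 degC.
#'
#' @param center length-3 surface point (mm, object frame).
#' @param radius contact radius (mm).
#' @param peak_temperature peak surface temperature at the contact (degC).
#' @param decay spatial falloff sigma as a fraction of `radius`.
#' @return An object of class `contact_spec`.
#' @export
contact_spec <- function(center, radius = 5, peak_temperature = 29.1,
                         decay = 0.5) {
  stopifnot(length(center) == 3, radius > 0, decay > 0)
  structure(list(center = as.numeric(center), radius = radius,
                 peak_temperature = peak_temperature, decay = decay),
            class = "contact_spec")
}

#' Ground-truth container for a synthetic scene
#'
#' Bundles everything the generator needs to render a measurement scene:
#' the object mesh and its true pose, the contacts, the camera rig, ambient
#' temperature, sensor noise, and the seed that makes every derived output
#' deterministic. Contact centers must lie on the mesh surface (within
#' 0.5 mm) or construction fails.
#'
#' @param mesh `triangle_mesh` (object frame).
#' @param pose `object_pose` or `rigid_transform` (object to scanner).
#' @param contacts list of [contact_spec()].
#' @param rig named list of [camera_model()].
#' @param ambient ambient temperature (degC).
#' @param noise_sigma i.i.d. per-pixel sensor noise (degC).
#' @param seed integer seed; fixed seed gives byte-identical outputs.
#' @param mesh_name optional name of the built-in mesh used.
#' @return An object of class `scene_truth`.
#' @export
scene_truth <- function(mesh, pose, contacts, rig, ambient = 25.4,
                        noise_sigma = 0.05, seed = 1L, mesh_name = NA) {
  if (inherits(pose, "rigid_transform")) pose <- object_pose(pose)
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(pose, "object_pose"),
            all(vapply(contacts, inherits, TRUE, "contact_spec")),
            all(vapply(rig, inherits, TRUE, "camera_model")))
  if (length(contacts) > 0) {
    centers <- do.call(rbind, lapply(contacts, function(ct) ct$center))
    d <- cpp_closest_point(centers, mesh$vertices, mesh$faces - 1L)$dist
    if (any(d > 0.5))
      stop(sprintf("contact center %d is %.2f mm off the mesh surface",
                   which.max(d), max(d)))
    if (any(vapply(contacts, function(ct) ct$peak_temperature, 0) <= ambient))
      stop("contact peak temperature must exceed ambient")
  }
  if (is.null(names(rig)))
    names(rig) <- vapply(rig, function(cm) cm$name, "")
  structure(list(mesh = mesh, object_pose = pose, contacts = contacts,
                 rig = rig, ambient = ambient, noise_sigma = noise_sigma,
                 seed = as.integer(seed), mesh_name = mesh_name),
            class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> %s, %d contact(s), %d camera(s), ambient %.1f degC, seed %d\n",
              ifelse(is.na(x$mesh_name), "custom mesh", x$mesh_name),
              length(x$contacts), length(x$rig), x$ambient, x$seed))
  invisible(x)
}

#' True contact centers of a scene as a tibble
#' @param truth A `scene_truth`.
#' @return Tibble with `X`, `Y`, `Z` (mm, object frame) and `radius_mm`.
#' @export
truth_contacts <- function(truth) {
  if (length(truth$contacts) == 0)
    return(tibble::tibble(X = numeric(), Y = numeric(), Z = numeric(),
                          radius_mm = numeric()))
  m <- do.call(rbind, lapply(truth$contacts, function(ct) ct$center))
  tibble::tibble(X = m[, 1], Y = m[, 2], Z = m[, 3],
                 radius_mm = vapply(truth$contacts, function(ct) ct$radius, 0))
}

# Face normal of the mesh surface at an on-surface point.
contact_normal <- function(mesh, p) {
  cp <- cpp_closest_point(matrix(p, 1), mesh$vertices, mesh$faces - 1L)
  mesh$face_normals[cp$face[1], ]
}

# Small deterministic sub-seed, kept well below 2^31.
sub_seed <- function(seed, salt) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(salt)
}

#' Standard 4-camera synthetic rig
#'
#' Cameras evenly spaced on a circle above the table, all looking at the
#' scanner origin where the object sits. Image convention: z forward,
#' x right, y down.
#'
#' @param n_cameras number of cameras.
#' @param radius circle radius (mm).
#' @param height camera height above the table plane (mm).
#' @param width,height_px sensor size (px).
#' @param fx focal length (px; also used for fy).
#' @param azimuth0 azimuth of the first camera (degrees).
#' @return Named list of `camera_model` ("ir0", "ir1", ...).
#' @export
make_rig <- function(n_cameras = 4, radius = 520, height = 380,
                     width = 320L, height_px = 256L, fx = 800,
                     azimuth0 = 0) {
  az <- azimuth0 * pi / 180 + 2 * pi * (seq_len(n_cameras) - 1) / n_cameras
  rig <- lapply(seq_len(n_cameras), function(i) {
    C <- c(radius * cos(az[i]), radius * sin(az[i]), height)
    fwd <- -C / sqrt(sum(C^2))                       # look at origin
    right <- pracma_cross(fwd, c(0, 0, 1))
    right <- right / sqrt(sum(right^2))
    down <- pracma_cross(fwd, right)
    R <- rbind(right, down, fwd)                     # scanner -> camera
    camera_model(paste0("ir", i - 1), fx = fx, fy = fx,
                 cx = (width - 1) / 2, cy = (height_px - 1) / 2,
                 width = width, height = height_px,
                 pose = rigid_transform(R, as.numeric(-R %*% C)))
  })
  names(rig) <- vapply(rig, function(cm) cm$name, "")
  rig
}

#' Render the synthetic infrared frame seen by one camera
#'
#' Renders the object depth map, fills object pixels with ambient
#' temperature, and adds, for each contact whose surface point is visible
#' from this camera (unoccluded per the depth map within 1 mm depth
#' tolerance), a Gaussian temperature bump centered at the contact's
#' projected pixel. The image-space sigma is `decay * radius * fx / depth`
#' pixels and the amplitude is `peak_temperature - ambient`. The bump is
#' clipped to pixels whose Z-buffer depth lies within the patch's own
#' depth extent (`3 * decay * radius + 1` mm of the contact depth): heat
#' is local to the touched surface patch, so it must not bleed across
#' depth discontinuities onto unrelated surfaces of the same silhouette,
#' and at grazing incidence the painted region must not span the hugely
#' foreshortened surface behind the patch. Background pixels stay at
#' ambient; i.i.d. Gaussian sensor noise is added last. Deterministic for
#' a fixed scene seed.
#'
#' @param truth A `scene_truth`.
#' @param camera_name camera to render (must be in the rig).
#' @return A `radiometric_frame`.
#' @export
render_ir_frame <- function(truth, camera_name) {
  if (!camera_name %in% names(truth$rig))
    stop("camera not in rig: ", camera_name)
  cam <- truth$rig[[camera_name]]
  depth <- render_depth(truth$mesh, truth$object_pose, cam)
  px <- matrix(truth$ambient, cam$height, cam$width)
  onobj <- is.finite(depth$depths)
  U <- matrix(rep(0:(cam$width - 1), each = cam$height),
              cam$height, cam$width)
  V <- matrix(rep(0:(cam$height - 1), cam$width), cam$height, cam$width)
  to_cam <- rt_compose(cam$pose, truth$object_pose$transform)
  for (ct in truth$contacts) {
    p_cam <- as.numeric(rt_apply(to_cam, ct$center))
    if (p_cam[3] <= 0) next
    uv <- project_points(p_cam, cam)
    ui <- round(uv[1]); vi <- round(uv[2])
    if (ui < 0 || ui > cam$width - 1 || vi < 0 || vi > cam$height - 1) next
    if (!is.finite(depth$depths[vi + 1, ui + 1]) ||
        abs(depth$depths[vi + 1, ui + 1] - p_cam[3]) > 1.0) next  # occluded
    # project the tangent-plane Gaussian patch: image covariance J S J'
    n_obj <- contact_normal(truth$mesh, ct$center)
    n_cam <- as.numeric(to_cam$rotation %*% n_obj)
    seed_axis <- if (abs(n_cam[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    t1 <- pracma_cross(seed_axis, n_cam); t1 <- t1 / sqrt(sum(t1^2))
    t2 <- pracma_cross(n_cam, t1)
    jac <- function(t) c(cam$fx * (t[1] * p_cam[3] - p_cam[1] * t[3]),
                         cam$fy * (t[2] * p_cam[3] - p_cam[2] * t[3])) /
      p_cam[3]^2
    A <- cbind(jac(t1), jac(t2))
    sig_mm <- ct$decay * ct$radius
    S <- sig_mm^2 * (A %*% t(A)) + diag(1e-6, 2)
    Sinv <- solve(S)
    amp <- ct$peak_temperature - truth$ambient
    d1 <- U - uv[1]; d2 <- V - uv[2]
    q <- Sinv[1, 1] * d1^2 + 2 * Sinv[1, 2] * d1 * d2 + Sinv[2, 2] * d2^2
    bump <- amp * exp(-q / 2)
    win <- 3 * ct$decay * ct$radius + 1
    patch <- onobj & abs(depth$depths - p_cam[3]) <= win
    px[patch] <- px[patch] + bump[patch]
  }
  if (truth$noise_sigma > 0) {
    set.seed(sub_seed(truth$seed, match(camera_name, names(truth$rig))))
    px <- px + matrix(stats::rnorm(length(px), 0, truth$noise_sigma),
                      nrow(px), ncol(px))
  }
  radiometric_frame(px, camera_name = camera_name)
}

#' Render all rig frames of a scene
#' @param truth A `scene_truth`.
#' @return Named list of `radiometric_frame`.
#' @export
render_scene_frames <- function(truth) {
  out <- lapply(names(truth$rig), function(cn) render_ir_frame(truth, cn))
  names(out) <- names(truth$rig)
  out
}

#' Sample the scanner point cloud of a scene
#'
#' Area-weighted uniform samples of the mesh surface, transformed by the
#' true object pose into the scanner frame, optionally perturbed by
#' Gaussian noise along the surface normals. Deterministic for a fixed
#' scene seed.
#'
#' @param truth A `scene_truth`.
#' @param n_points number of samples.
#' @param noise_mm normal-direction noise standard deviation (mm).
#' @return A `scene_cloud`.
#' @export
sample_cloud <- function(truth, n_points = 3000, noise_mm = 0) {
  stopifnot(n_points > 0)
  set.seed(sub_seed(truth$seed, 7777L))
  s <- mesh_sample_surface(truth$mesh, n_points)
  pts <- s$points
  if (noise_mm > 0)
    pts <- pts + s$normals * stats::rnorm(n_points, 0, noise_mm)
  scene_cloud(rt_apply(truth$object_pose$transform, pts),
              normals = s$normals %*% t(truth$object_pose$transform$rotation))
}

#' Render synthetic calibration-target views
#'
#' Renders the warm-background / cold-circle thermal appearance of the
#' calibration target: the coated board sits about `contrast` degrees above
#' room temperature while the bare circles reflect the ambient surroundings.
#' Rendering is analytic ray-plane intersection with 2x2 supersampling, and
#' the true projected circle centers are returned for oracle use.
#'
#' @param spec A `target_spec`.
#' @param rig named list of `camera_model`.
#' @param poses list of `rigid_transform` mapping target frame to scanner
#'   frame (one per target placement).
#' @param contrast board temperature above ambient (degC).
#' @param ambient ambient temperature (degC).
#' @param noise_sigma per-pixel sensor noise (degC).
#' @param seed RNG seed for the noise.
#' @param board_margin board border beyond the grid, per side (mm). The
#'   default makes the warm board fill the field of view at working
#'   distances, which keeps the frame median on the board as the ambient
#'   reference for cold-circle detection.
#' @return List of views, each `list(camera, pose_id, frame, true_centers)`
#'   where `true_centers` is (rows*cols) x 2 in canonical order.
#' @export
render_calibration_views <- function(spec, rig, poses, contrast = 10.0,
                                     ambient = 25.4, noise_sigma = 0,
                                     seed = 1L, board_margin = 250) {
  tp <- target_points(spec)
  grid_w <- (spec$cols - 1) * spec$spacing
  grid_h <- (spec$rows - 1) * spec$spacing + spec$spacing / 2
  views <- list()
  for (p in seq_along(poses)) {
    for (cn in names(rig)) {
      cam <- rig[[cn]]
      to_cam <- rt_compose(cam$pose, poses[[p]])      # target -> camera
      pc <- rt_apply(to_cam, tp)
      if (any(pc[, 3] <= 0))
        stop("target behind camera ", cn, " at pose ", p)
      centers <- project_points(pc, cam)
      # each circle must fit inside the frame, not just its center
      r_px <- (spec$circle_diameter / 2) * cam$fx / pc[, 3]
      marg <- r_px + 2
      if (any(centers[, 1] < marg) || any(centers[, 1] > cam$width - 1 - marg) ||
          any(centers[, 2] < marg) || any(centers[, 2] > cam$height - 1 - marg))
        stop("target not fully visible from ", cn, " at pose ", p)
      inv <- rt_inverse(to_cam)                       # camera -> target
      h <- cam$height; w <- cam$width
      acc <- matrix(0, h, w)
      for (du in c(-0.25, 0.25)) for (dv in c(-0.25, 0.25)) {
        gridpix <- cbind(rep(0:(w - 1), each = h) + du,
                         rep(0:(h - 1), w) + dv)
        d <- unproject_pixels(gridpix, cam) %*% t(inv$rotation)
        tz <- -inv$translation[3] / d[, 3]
        xt <- inv$translation[1] + tz * d[, 1]
        yt <- inv$translation[2] + tz * d[, 2]
        on_board <- tz > 0 &
          xt >= -board_margin & xt <= grid_w + board_margin &
          yt >= -board_margin & yt <= grid_h + board_margin
        d2min <- rep(Inf, length(xt))
        for (k in seq_len(nrow(tp))) {
          d2 <- (xt - tp[k, 1])^2 + (yt - tp[k, 2])^2
          d2min <- pmin(d2min, d2)
        }
        temp <- rep(ambient, length(xt))
        warm <- on_board & d2min > (spec$circle_diameter / 2)^2
        temp[warm] <- ambient + contrast
        acc <- acc + matrix(temp, h, w)
      }
      px <- acc / 4
      if (noise_sigma > 0) {
        set.seed(sub_seed(seed, p * 100L + match(cn, names(rig))))
        px <- px + matrix(stats::rnorm(length(px), 0, noise_sigma), h, w)
      }
      views[[length(views) + 1]] <- list(
        camera = cn, pose_id = paste0("pose", p),
        frame = radiometric_frame(px, camera_name = cn),
        true_centers = centers)
    }
  }
  views
}

#' Generate a randomized benchmark suite of scenes
#'
#' Randomized desk-scale scenes for end-to-end validation: a 4-camera rig
#' on a circle looking at the origin, one of the built-in asymmetric
#' meshes at a random pose (rotation within +/-30 degrees, translation
#' within +/-30 mm), and 3-6 contacts at random surface points separated
#' by more than 20 mm, each visible from at least `min_visible` cameras at
#' a viewing angle steeper than `max_view_angle` (grazing views do not
#' produce a usable signature).
#'
#' @param n_scenes number of scenes.
#' @param seed master seed; the suite is a pure function of it.
#' @param noise_sigma per-pixel sensor noise (degC).
#' @param min_visible minimum number of cameras that must see each contact.
#' @return List of `scene_truth`.
#' @export
make_benchmark_suite <- function(n_scenes = 20, seed = 1L,
                                 noise_sigma = 0.05, min_visible = 2,
                                 max_view_angle = 70) {
  stopifnot(n_scenes > 0)
  mesh_names <- c("box_notch", "l_bracket", "jug")
  lapply(seq_len(n_scenes), function(i) {
    set.seed(sub_seed(seed, i))
    mesh_name <- mesh_names[(i - 1) %% 3 + 1]
    mesh <- builtin_mesh(mesh_name)
    # center the mesh near its centroid so the pose translation is small
    ctr <- colMeans(mesh$vertices)
    mesh <- mesh_transform(mesh, rigid_transform(diag(3), -ctr))
    rig <- make_rig(azimuth0 = stats::runif(1, 0, 90))
    axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
    pose <- rigid_transform(rot_axis_angle(axis, stats::runif(1, -30, 30)),
                            stats::runif(3, -30, 30))
    opose <- object_pose(pose)
    depths <- lapply(rig, function(cam) render_depth(mesh, opose, cam))
    n_contacts <- sample(3:6, 1)
    centers <- matrix(numeric(0), 0, 3)
    contacts <- list()
    tries <- 0
    while (length(contacts) < n_contacts && tries < 500) {
      tries <- tries + 1
      s <- mesh_sample_surface(mesh, 1)
      p <- s$points[1, ]
      if (nrow(centers) > 0 &&
          min(sqrt(rowSums(sweep(centers, 2, p)^2))) <= 20) next
      if (count_visible(p, s$normals[1, ], mesh, opose, rig, depths,
                        max_view_angle) < min_visible) next
      centers <- rbind(centers, p)
      contacts[[length(contacts) + 1]] <-
        contact_spec(p, radius = stats::runif(1, 4, 6),
                     peak_temperature = 29.1, decay = 0.5)
    }
    scene_truth(mesh, opose, contacts, rig, ambient = 25.4,
                noise_sigma = noise_sigma, seed = sub_seed(seed, i),
                mesh_name = mesh_name)
  })
}

# Number of rig cameras from which an object-frame surface point is usable:
# projects in-bounds, is the nearest surface per the depth map, and is not
# viewed at grazing incidence (normal-to-view-ray angle above the cap).
count_visible <- function(p_obj, n_obj, mesh, pose, rig, depths,
                          max_view_angle = 70) {
  n <- 0L
  n_scan <- as.numeric(pose$transform$rotation %*% n_obj)
  p_scan <- as.numeric(rt_apply(pose$transform, p_obj))
  for (cn in names(rig)) {
    cam <- rig[[cn]]
    p_cam <- rt_apply(rt_compose(cam$pose, pose$transform), p_obj)
    if (p_cam[3] <= 0) next
    uv <- project_points(p_cam, cam)
    ui <- round(uv[1]); vi <- round(uv[2])
    if (ui < 3 || ui > cam$width - 4 || vi < 3 || vi > cam$height - 4) next
    d <- depths[[cn]]$depths[vi + 1, ui + 1]
    if (!is.finite(d) || abs(d - p_cam[3]) > 1.0) next
    view <- camera_center(cam) - p_scan
    cosang <- abs(sum(view * n_scan)) / sqrt(sum(view^2))
    if (acos(min(1, cosang)) * 180 / pi > max_view_angle) next
    n <- n + 1L
  }
  n
}
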