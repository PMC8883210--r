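#' Render the object's depth map (Z-buffer) for a camera
#'
#' Transforms the mesh from object frame through the object pose into the
#' camera frame and computes, per pixel, the camera-frame Z depth of the
#' nearest surface along the viewing ray (first-hit ray casting at the
#' sensor resolution). Pixels the object does not cover are `+Inf`. The
#' depth map is the occlusion reference: a contact observation is visible
#' to a camera only if its surface point is the nearest surface at its
#' pixel.
#'
#' @param mesh A `triangle_mesh` (object frame).
#' @param pose An `object_pose` (or `rigid_transform`) mapping object to
#'   scanner frame.
#' @param cam A `camera_model`.
#' @return An object of class `depth_map`: `depths` (height x width matrix,
#'   mm, `+Inf` off-object) and `camera_name`.
#' @export
render_depth <- function(mesh, pose, cam) {
  tr <- if (inherits(pose, "object_pose")) pose$transform else pose
  to_cam <- rt_compose(cam$pose, tr)
  vcam <- rt_apply(to_cam, mesh$vertices)
  if (all(vcam[, 3] <= 0)) {
    warning("mesh entirely behind camera ", cam$name)
    return(structure(list(depths = matrix(Inf, cam$height, cam$width),
                          camera_name = cam$name), class = "depth_map"))
  }
  grid <- cbind(rep(0:(cam$width - 1), each = cam$height),
                rep(0:(cam$height - 1), cam$width))
  dirs <- unproject_pixels(grid, cam)
  hit <- cpp_ray_cast(matrix(0, nrow(dirs), 3), dirs,
                      vcam, mesh$faces - 1L)
  depths <- matrix(hit$t * dirs[, 3], cam$height, cam$width)
  structure(list(depths = depths, camera_name = cam$name),
            class = "depth_map")
}

#' @export
print.depth_map <- function(x, ...) {
  cov <- mean(is.finite(x$depths))
  cat(sprintf("<depth_map> %s  %dx%d, %.1f%% covered\n", x$camera_name,
              ncol(x$depths), nrow(x$depths), 100 * cov))
  invisible(x)
}

# Bilinear depth lookup over the finite neighbors of a sub-pixel location.
# Returns NA when no finite neighbor exists (off-object).
depth_lookup <- function(depth, u, v) {
  h <- nrow(depth$depths); w <- ncol(depth$depths)
  u0 <- floor(u); v0 <- floor(v)
  us <- pmin(pmax(c(u0, u0 + 1, u0, u0 + 1), 0), w - 1)
  vs <- pmin(pmax(c(v0, v0, v0 + 1, v0 + 1), 0), h - 1)
  wts <- c((1 - (u - u0)) * (1 - (v - v0)), (u - u0) * (1 - (v - v0)),
           (1 - (u - u0)) * (v - v0), (u - u0) * (v - v0))
  d <- depth$depths[cbind(vs + 1, us + 1)]
  ok <- is.finite(d) & wts > 0
  if (!any(is.finite(d))) return(NA_real_)
  if (!any(ok)) { ok <- is.finite(d); wts[ok] <- 1 }
  sum(d[ok] * wts[ok]) / sum(wts[ok])
}

#' Project a blob detection onto the object surface
#'
#' Looks up the Z-buffer depth at the blob center (bilinear over finite
#' neighbors), back-projects along the pixel's viewing ray to a
#' scanner-frame point, snaps it to the nearest point on the mesh surface,
#' transforms it to the object frame, and scores it with the incident angle
#' between the camera optical axis and the containing face's normal. The
#' image radius converts to millimeters by similar triangles:
#' `r_prime = r * depth / fx`.
#'
#' Two rejection paths implement the boundary-discard rule: a blob center
#' whose depth neighborhood is entirely off-object, and a back-projected
#' point farther than `snap_tol` from the surface (a grazing or background
#' hit).
#'
#' @param blob one-row tibble (or list) with `u`, `v`, `r`, `camera`.
#' @param depth `depth_map` for the same camera.
#' @param mesh `triangle_mesh` (object frame).
#' @param pose `object_pose`.
#' @param cam `camera_model`.
#' @param snap_tol surface-snapping tolerance (mm).
#' @return A list with `point` (one-row contact tibble or `NULL`) and
#'   `status` (`"ok"`, `"boundary"` or `"snap"`).
#' @export
project_blob <- function(blob, depth, mesh, pose, cam, snap_tol = 2.0) {
  u <- blob$u; v <- blob$v
  if (u < 0 || u > cam$width - 1 || v < 0 || v > cam$height - 1)
    stop("blob center outside sensor bounds")
  d <- depth_lookup(depth, u, v)
  if (!is.finite(d)) return(list(point = NULL, status = "boundary"))
  dir_cam <- unproject_pixels(c(u, v), cam)
  p_cam <- dir_cam * (d / dir_cam[, 3])
  p_scan <- rt_apply(rt_inverse(cam$pose), p_cam)
  p_obj <- rt_apply(rt_inverse(pose$transform), p_scan)
  cp <- cpp_closest_point(p_obj, mesh$vertices, mesh$faces - 1L)
  if (cp$dist[1] > snap_tol) return(list(point = NULL, status = "snap"))
  n_obj <- mesh$face_normals[cp$face[1], ]
  n_scan <- as.numeric(pose$transform$rotation %*% n_obj)
  ang <- incident_angle(cam, n_scan)
  list(point = tibble::tibble(
    X = cp$points[1, 1], Y = cp$points[1, 2], Z = cp$points[1, 3],
    r_prime = blob$r * d / cam$fx,
    incident_angle = ang, camera = blob$camera),
    status = "ok")
}

#' Fuse multi-camera contact candidates
#'
#' The same physical contact is typically observed by several cameras.
#' Candidates are clustered by single-linkage on object-frame Euclidean
#' distance with threshold `merge_radius`; from each cluster the candidate
#' with the smallest incident angle is retained (ties broken by camera
#' name, then by smaller `r_prime`). Single linkage realizes the
#' "within `merge_radius` of each other" rule deterministically and
#' independently of input order.
#'
#' @param candidates tibble with columns `X`, `Y`, `Z`, `r_prime`,
#'   `incident_angle`, `camera` (object frame).
#' @param merge_radius merge distance (mm); default 9.
#' @return The retained contacts, sorted by `(X, Y, Z)` ascending.
#' @export
fuse_contacts <- function(candidates, merge_radius = 9.0) {
  if (nrow(candidates) == 0) return(candidates)
  if (nrow(candidates) == 1) cl <- 1L
  else cl <- stats::cutree(
    stats::hclust(stats::dist(candidates[, c("X", "Y", "Z")]),
                  method = "single"),
    h = merge_radius)
  candidates |>
    dplyr::mutate(.cluster = cl) |>
    dplyr::arrange(.data$incident_angle, .data$camera, .data$r_prime) |>
    dplyr::group_by(.data$.cluster) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select(-".cluster") |>
    dplyr::arrange(.data$X, .data$Y, .data$Z)
}

#' Map a full multi-camera scene to fused contact points
#'
#' Runs the whole post-interaction measurement for one scene: per camera,
#' detect heat-signature blobs, render the object Z-buffer, and project
#' each blob onto the localized object surface; then fuse all surviving
#' candidates across cameras. Contacts are reported in object coordinates
#' (X, Y, Z, r') in millimeters.
#'
#' @param frames named list of `radiometric_frame`, one per camera.
#' @param rig named list of `camera_model` (names matching `frames`).
#' @param mesh `triangle_mesh` of the object.
#' @param pose `object_pose` (object to scanner frame).
#' @param threshold_excess,min_area,max_area,min_circularity blob-detector
#'   settings (see [detect_blobs()]).
#' @param merge_radius fusion distance (mm).
#' @param snap_tol surface-snapping tolerance (mm).
#' @return An object of class `contact_map`: `contacts` (fused tibble),
#'   `candidates` (pre-fusion tibble), `log` (per-camera stage counts).
#' @export
map_scene <- function(frames, rig, mesh, pose,
                      threshold_excess = 1.0, min_area = 9,
                      max_area = NULL, min_circularity = 0.5,
                      merge_radius = 9.0, snap_tol = 2.0) {
  stopifnot(all(names(frames) %in% names(rig)))
  cand <- list(); logs <- list()
  for (cn in names(frames)) {
    res <- tryCatch({
      blobs <- detect_blobs(frames[[cn]], threshold_excess = threshold_excess,
                            min_area = min_area, max_area = max_area,
                            min_circularity = min_circularity)
      depth <- render_depth(mesh, pose, rig[[cn]])
      pts <- list(); n_bound <- 0L; n_snap <- 0L
      for (i in seq_len(nrow(blobs))) {
        pr <- project_blob(blobs[i, ], depth, mesh, pose, rig[[cn]],
                           snap_tol = snap_tol)
        if (pr$status == "ok") pts[[length(pts) + 1]] <- pr$point
        else if (pr$status == "boundary") n_bound <- n_bound + 1L
        else n_snap <- n_snap + 1L
      }
      list(pts = dplyr::bind_rows(pts),
           log = tibble::tibble(camera = cn, blobs = nrow(blobs),
                                rejected_boundary = n_bound,
                                rejected_snap = n_snap))
    }, error = function(e) stop("camera ", cn, ": ", conditionMessage(e),
                                call. = FALSE))
    cand[[cn]] <- res$pts; logs[[cn]] <- res$log
  }
  candidates <- dplyr::bind_rows(cand)
  if (nrow(candidates) == 0)
    candidates <- tibble::tibble(X = numeric(), Y = numeric(), Z = numeric(),
                                 r_prime = numeric(),
                                 incident_angle = numeric(),
                                 camera = character())
  contacts <- fuse_contacts(candidates, merge_radius = merge_radius)
  structure(list(contacts = contacts, candidates = candidates,
                 log = dplyr::bind_rows(logs)),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %d contact(s) from %d candidate(s) across %d camera(s)\n",
              nrow(x$contacts), nrow(x$candidates), nrow(x$log)))
  print(x$contacts)
  invisible(x)
}

#' @rdname map_scene
#' @param x A `contact_map`.
#' @param ... unused.
#' @method tidy contact_map
#' @export
tidy.contact_map <- function(x, ...) x$contacts

#' @rdname map_scene
#' @method glance contact_map
#' @export
glance.contact_map <- function(x, ...) {
  tibble::tibble(n_contacts = nrow(x$contacts),
                 n_candidates = nrow(x$candidates),
                 n_rejected_boundary = sum(x$log$rejected_boundary),
                 n_rejected_snap = sum(x$log$rejected_snap),
                 n_merged = nrow(x$candidates) - nrow(x$contacts))
}
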