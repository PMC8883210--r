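# Shared fixtures: small cameras, canonical calibration pose set, and a
# brute-force R ray caster used as the independent rendering oracle.

test_camera <- function(name = "cam", fx = 800, fy = 800, cx = 320, cy = 256,
                        width = 640, height = 512, distortion = rep(0, 5),
                        pose = rt_identity()) {
  camera_model(name, fx = fx, fy = fy, cx = cx, cy = cy, width = width,
               height = height, distortion = distortion, pose = pose)
}

# target poses that keep every circle visible from the whole standard rig
calibration_poses <- function() {
  base <- rigid_transform(diag(3), c(-100, -45, 0))
  mk <- function(axis, ang, t = c(0, 0, 0), zrot = 0)
    rt_compose(rigid_transform(rot_axis_angle(axis, ang), t),
               rt_compose(rigid_transform(rot_axis_angle(c(0, 0, 1), zrot)),
                          base))
  list(base,
       mk(c(1, 0, 0), 18, c(0, 0, 10), 12),
       mk(c(0, 1, 0), -18, c(5, 5, 15), -12),
       mk(c(1, 1, 0), 18, c(-5, 5, 25), 15),
       mk(c(0, 1, 1), -15, c(5, -5, 30), -15))
}

# exact zero-noise observations: ideal projected circle centers
exact_observations <- function(rig, poses, spec = target_spec()) {
  tp <- target_points(spec)
  obs <- list()
  for (p in seq_along(poses)) {
    for (cn in names(rig)) {
      cam <- rig[[cn]]
      pc <- rt_apply(rt_compose(cam$pose, poses[[p]]), tp)
      obs[[length(obs) + 1]] <- structure(
        list(image_points = project_points(pc, cam), target_points = tp,
             camera_name = cn, pose_id = paste0("pose", p)),
        class = "target_observation")
    }
  }
  obs
}

# independent brute-force ray caster: solve the plane/barycentric system
# per triangle with plain linear algebra (no shared code with src/)
oracle_ray_cast <- function(mesh, origin, dir) {
  best <- Inf
  for (f in seq_len(nrow(mesh$faces))) {
    a <- mesh$vertices[mesh$faces[f, 1], ]
    b <- mesh$vertices[mesh$faces[f, 2], ]
    c_ <- mesh$vertices[mesh$faces[f, 3], ]
    M <- cbind(b - a, c_ - a, -dir)
    if (abs(det(M)) < 1e-12) next
    sol <- solve(M, origin - a)
    if (sol[1] >= -1e-9 && sol[2] >= -1e-9 && sol[1] + sol[2] <= 1 + 1e-9 &&
        sol[3] > 1e-9)
      best <- min(best, sol[3])
  }
  best
}

# independent single-linkage fusion oracle: transitive closure of the
# within-radius graph, then minimal-incident-angle retention
oracle_fuse <- function(cand, merge_radius) {
  n <- nrow(cand)
  if (n == 0) return(cand)
  D <- as.matrix(stats::dist(cand[, c("X", "Y", "Z")]))
  adj <- D <= merge_radius
  reach <- adj
  for (k in seq_len(n)) reach <- reach | (reach %*% reach > 0)
  cl <- rep(NA_integer_, n)
  next_id <- 0
  for (i in seq_len(n)) {
    if (is.na(cl[i])) {
      next_id <- next_id + 1
      cl[which(reach[i, ])] <- next_id
    }
  }
  keep <- vapply(seq_len(next_id), function(k) {
    idx <- which(cl == k)
    ord <- order(cand$incident_angle[idx], cand$camera[idx],
                 cand$r_prime[idx])
    idx[ord[1]]
  }, 0L)
  out <- cand[keep, , drop = FALSE]
  out[order(out$X, out$Y, out$Z), , drop = FALSE]
}

random_candidates <- function(n, spread = 30) {
  tibble::tibble(
    X = stats::runif(n, -spread, spread),
    Y = stats::runif(n, -spread, spread),
    Z = stats::runif(n, -spread, spread),
    r_prime = stats::runif(n, 2, 6),
    incident_angle = stats::runif(n, 0, 90),
    camera = sample(paste0("ir", 0:3), n, replace = TRUE))
}
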