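#' Asymmetric circle-grid calibration target
#'
#' The rig is calibrated against a planar asymmetric circle grid that is
#' visible in the thermal band: warm coated background with bare-metal
#' circles that reflect the colder surroundings, so the circles image as
#' cold disks. The default geometry is a 4 x 11 grid with 20.0 mm spacing
#' and 15.0 mm circle diameter.
#'
#' Lattice convention: column `c` (0-based, 0..cols-1) lies at
#' `x = c * spacing`; row `r` at `y = r * spacing`, with odd columns offset
#' by `+spacing/2` in y. The canonical point ordering is row-major
#' (`index = r * cols + c`), which the asymmetry makes unique: no rigid
#' motion maps the lattice onto itself.
#'
#' @param rows,cols grid size (circles per column, number of columns).
#' @param spacing lattice pitch (mm).
#' @param circle_diameter circle diameter (mm).
#' @return An object of class `target_spec`.
#' @export
target_spec <- function(rows = 4, cols = 11, spacing = 20.0,
                        circle_diameter = 15.0) {
  stopifnot(rows >= 2, cols >= 2, spacing > circle_diameter / 2)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 spacing = spacing, circle_diameter = circle_diameter),
            class = "target_spec")
}

#' Canonical 3D circle centers of a target
#' @param spec A `target_spec`.
#' @return (rows*cols) x 3 matrix of circle centers in the target plane
#'   frame (Z = 0), in canonical row-major order.
#' @export
target_points <- function(spec) {
  g <- expand.grid(c = seq_len(spec$cols) - 1L, r = seq_len(spec$rows) - 1L)
  cbind(g$c * spec$spacing,
        g$r * spec$spacing + (g$c %% 2) * spec$spacing / 2,
        0)
}

# Direct linear transform homography fit (normalized), src/dst N x 2.
fit_homography <- function(src, dst) {
  norm_pts <- function(p) {
    mu <- colMeans(p)
    sc <- sqrt(2) / mean(sqrt(rowSums(sweep(p, 2, mu)^2)))
    T <- rbind(c(sc, 0, -sc * mu[1]), c(0, sc, -sc * mu[2]), c(0, 0, 1))
    list(T = T, p = cbind(sc * (p[, 1] - mu[1]), sc * (p[, 2] - mu[2])))
  }
  a <- norm_pts(src); b <- norm_pts(dst)
  n <- nrow(src)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- a$p[i, 1]; y <- a$p[i, 2]; u <- b$p[i, 1]; v <- b$p[i, 2]
    A[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2 * i, ] <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  h <- svd(A, nu = 0)$v[, 9]
  H <- solve(b$T) %*% matrix(h, 3, 3, byrow = TRUE) %*% a$T
  H / H[3, 3]
}

apply_homography <- function(H, p) {
  q <- cbind(p[, 1], p[, 2], 1) %*% t(H)
  q[, 1:2] / q[, 3]
}

# Order detected circle centers into the canonical grid ordering.
# Whitening-based alignment search, then homography refinement with optimal
# assignment; the grid's asymmetry makes the minimum-cost labeling unique.
order_grid_points <- function(centers, spec) {
  canon <- target_points(spec)[, 1:2]
  whiten <- function(p) {
    mu <- colMeans(p)
    C <- stats::cov(p)
    e <- eigen(C, symmetric = TRUE)
    W <- e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12))) %*% t(e$vectors)
    sweep(p, 2, mu) %*% W
  }
  wi <- whiten(centers); wc <- whiten(canon)
  best <- NULL; best_cost <- Inf
  for (th in seq(0, 2 * pi, length.out = 73)[-73]) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    for (fl in c(1, -1)) {
      wr <- wc %*% (R * c(1, fl, 1, fl))
      D2 <- outer(rowSums(wr^2), rowSums(wi^2), "+") - 2 * wr %*% t(wi)
      asg <- cpp_hungarian(sqrt(pmax(D2, 0)))
      cost <- sum(sqrt(pmax(D2[cbind(seq_len(nrow(wr)), asg)], 0)))
      if (cost < best_cost) { best_cost <- cost; best <- asg }
    }
  }
  # refine with a projective model and re-assign (twice is enough)
  asg <- best
  refit <- function(asg) {
    H <- fit_homography(canon, centers[asg, , drop = FALSE])
    proj <- apply_homography(H, canon)
    D2 <- outer(rowSums(proj^2), rowSums(centers^2), "+") -
      2 * proj %*% t(centers)
    list(H = H, D2 = D2, asg = cpp_hungarian(sqrt(pmax(D2, 0))))
  }
  for (it in 1:2) { r <- refit(asg); asg <- r$asg }
  # the lattice is mirror-symmetric left-right, so a reversed-orientation
  # homography fits a mirrored labeling exactly; the physical target is
  # always seen from its front face, which fixes the orientation sign.
  ctr <- colMeans(canon)
  hmap <- function(p) as.numeric(apply_homography(r$H, matrix(p, 1)))
  J <- cbind(hmap(ctr + c(1, 0)) - hmap(ctr), hmap(ctr + c(0, 1)) - hmap(ctr))
  if (det(J) > 0) {
    g <- expand.grid(c = seq_len(spec$cols) - 1L, r = seq_len(spec$rows) - 1L)
    mirror <- g$r * spec$cols + (spec$cols - 1L - g$c) + 1L
    asg <- asg[mirror]
    r <- refit(asg); asg <- r$asg
  }
  D2 <- r$D2
  resid <- sqrt(pmax(D2[cbind(seq_along(asg), asg)], 0))
  Dc <- as.matrix(stats::dist(centers))
  diag(Dc) <- Inf
  scale_px <- stats::median(apply(Dc, 1, min))
  if (max(resid) > 0.35 * scale_px || anyDuplicated(asg))
    stop("circle grid ordering failed: residual lattice mismatch")
  asg
}

#' Detect the calibration target in an infrared frame
#'
#' Detects the circle centers with the blob detector (inverted polarity for
#' cold circles on a warm background), orders them into the canonical
#' asymmetric-grid ordering, and pairs them with the ideal target
#' coordinates. Exactly `rows * cols` circles must survive filtering;
#' partial grids are a detection failure.
#'
#' Circle centers are approximated by blob centroids; the perspective
#' eccentricity bias of projected circles is below 0.1 px at working
#' distances of a few hundred millimeters and is accepted.
#'
#' @param frame A `radiometric_frame`.
#' @param spec A `target_spec`.
#' @param polarity `"cold_circles_on_warm"` (default, thermal target) or
#'   `"warm_circles_on_cold"`.
#' @param pose_id identifier of the target pose this view belongs to (used
#'   to group views in [calibrate_rig()]).
#' @param threshold_excess,min_area,min_circularity blob-detector settings
#'   for the circle detection.
#' @return An object of class `target_observation`: `image_points`
#'   (rows*cols x 2, canonical order), `target_points` (rows*cols x 3),
#'   `camera_name`, `pose_id`.
#' @export
detect_target <- function(frame, spec = target_spec(),
                          polarity = c("cold_circles_on_warm",
                                       "warm_circles_on_cold"),
                          pose_id = "pose",
                          threshold_excess = 1.0, min_area = 9,
                          min_circularity = 0.6) {
  polarity <- match.arg(polarity)
  blobs <- detect_blobs(frame,
                        threshold_excess = threshold_excess,
                        min_area = min_area, max_area = 0.05 * length(frame$pixels),
                        min_circularity = min_circularity,
                        polarity = if (polarity == "cold_circles_on_warm")
                          "cold" else "warm",
                        exclude_border = TRUE)
  n_expect <- spec$rows * spec$cols
  if (nrow(blobs) != n_expect)
    stop(sprintf("target detection failure: %d candidate circles, expected %d",
                 nrow(blobs), n_expect))
  centers <- cbind(blobs$u, blobs$v)
  ord <- order_grid_points(centers, spec)
  structure(list(image_points = centers[ord, , drop = FALSE],
                 target_points = target_points(spec),
                 camera_name = frame$camera_name,
                 pose_id = as.character(pose_id)),
            class = "target_observation")
}
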