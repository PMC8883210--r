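#' Triangle mesh in object coordinates
#'
#' Object surfaces are plain triangle meshes in millimeter units. On
#' construction degenerate (near-zero-area) faces are dropped with a message,
#' and per-face unit normals and areas are computed from the vertex winding.
#'
#' @param vertices V x 3 numeric matrix (mm).
#' @param faces F x 3 integer matrix of 1-based vertex indices.
#' @return An object of class `triangle_mesh` with fields `vertices`,
#'   `faces`, `face_normals` (F x 3 unit vectors) and `face_areas` (mm^2).
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- unname(as.matrix(vertices))
  faces <- unname(matrix(as.integer(as.matrix(faces)), ncol = 3))
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinates")
  if (min(faces) < 1 || max(faces) > nrow(vertices))
    stop("face indices out of range")
  a <- vertices[faces[, 1], , drop = FALSE]
  e1 <- vertices[faces[, 2], , drop = FALSE] - a
  e2 <- vertices[faces[, 3], , drop = FALSE] - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area2 <- sqrt(rowSums(cr^2))
  keep <- area2 > 1e-9
  if (!all(keep)) {
    message(sum(!keep), " degenerate face(s) dropped")
    faces <- faces[keep, , drop = FALSE]
    cr <- cr[keep, , drop = FALSE]
    area2 <- area2[keep]
  }
  if (nrow(faces) == 0) stop("mesh has no non-degenerate faces")
  structure(list(vertices = vertices, faces = faces,
                 face_normals = cr / area2, face_areas = area2 / 2),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d faces, area %.1f mm^2\n",
              nrow(x$vertices), nrow(x$faces), sum(x$face_areas)))
  invisible(x)
}

#' Transform a mesh by a rigid transform
#' @param mesh A `triangle_mesh`.
#' @param transform A `rigid_transform`.
#' @return The transformed `triangle_mesh`.
#' @export
mesh_transform <- function(mesh, transform) {
  triangle_mesh(rt_apply(transform, mesh$vertices), mesh$faces)
}

#' Closest surface points on a mesh
#' @param mesh A `triangle_mesh`.
#' @param points N x 3 query points in the mesh frame.
#' @return List with `points` (N x 3 closest surface points), `face`
#'   (1-based containing face index) and `dist` (mm).
#' @export
mesh_closest_point <- function(mesh, points) {
  if (is.null(dim(points))) points <- matrix(points, 1)
  cpp_closest_point(points, mesh$vertices, mesh$faces - 1L)
}

#' First-hit ray casting against a mesh
#' @param mesh A `triangle_mesh`.
#' @param origins,directions N x 3 ray origins and directions (mesh frame).
#' @return List with `t` (ray parameter, `Inf` when the ray misses) and
#'   `face` (1-based index of the hit face, `NA` on miss).
#' @export
mesh_ray_cast <- function(mesh, origins, directions) {
  if (is.null(dim(origins))) origins <- matrix(origins, 1)
  if (is.null(dim(directions))) directions <- matrix(directions, 1)
  cpp_ray_cast(origins, directions, mesh$vertices, mesh$faces - 1L)
}

# Append mesh b to mesh a (no boolean union; overlapping shells allowed).
mesh_append <- function(a, b) {
  triangle_mesh(rbind(a$vertices, b$vertices),
                rbind(a$faces, b$faces + nrow(a$vertices)))
}

# Axis-aligned box mesh with outward windings.
mesh_box <- function(dims = c(40, 30, 20), origin = c(0, 0, 0)) {
  d <- dims
  v <- cbind(c(0, d[1], d[1], 0, 0, d[1], d[1], 0),
             c(0, 0, d[2], d[2], 0, 0, d[2], d[2]),
             c(0, 0, 0, 0, d[3], d[3], d[3], d[3]))
  v <- sweep(v, 2, origin, "+")
  f <- rbind(c(1, 3, 2), c(1, 4, 3),    # bottom (-z)
             c(5, 6, 7), c(5, 7, 8),    # top (+z)
             c(1, 2, 6), c(1, 6, 5),    # -y
             c(3, 4, 8), c(3, 8, 7),    # +y
             c(2, 3, 7), c(2, 7, 6),    # +x
             c(4, 1, 5), c(4, 5, 8))    # -x
  triangle_mesh(v, f)
}

# Extrude a CCW 2D profile polygon along +z; cap_tris triangulates the
# profile (CCW, 1-based into the profile points).
mesh_extrude <- function(profile, cap_tris, height) {
  n <- nrow(profile)
  v <- rbind(cbind(profile, 0), cbind(profile, height))
  side <- do.call(rbind, lapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    rbind(c(i, j, j + n), c(i, j + n, i + n))
  }))
  bottom <- cap_tris[, c(1, 3, 2), drop = FALSE]
  top <- cap_tris + n
  triangle_mesh(v, rbind(side, bottom, top))
}

#' Built-in asymmetric test meshes
#'
#' Procedurally generated desk-scale objects used by the synthetic scene
#' generator: a box with an off-center notch, an L-bracket, and a low-poly
#' jug (lathe body with an attached handle block). All three are
#' rotationally asymmetric so registration has a unique solution.
#'
#' @param name one of `"box_notch"`, `"l_bracket"`, `"jug"`.
#' @return A `triangle_mesh` centered near its own centroid.
#' @export
builtin_mesh <- function(name = c("box_notch", "l_bracket", "jug")) {
  name <- match.arg(name)
  m <- switch(name,
    box_notch = {
      prof <- cbind(c(0, 80, 80, 45, 45, 20, 20, 0),
                    c(0, 0, 60, 60, 40, 40, 60, 60))
      caps <- rbind(c(1, 2, 3), c(1, 3, 4), c(1, 4, 5), c(1, 5, 6),
                    c(6, 7, 8), c(6, 8, 1))
      mesh_extrude(prof, caps, 40)
    },
    l_bracket = {
      prof <- cbind(c(0, 70, 70, 25, 25, 0),
                    c(0, 0, 20, 20, 55, 55))
      caps <- rbind(c(1, 2, 3), c(1, 3, 4), c(1, 4, 5), c(1, 5, 6))
      mesh_extrude(prof, caps, 30)
    },
    jug = {
      radii <- c(20, 26, 30, 24, 14, 18)
      heights <- c(0, 16, 32, 48, 64, 80)
      nseg <- 8
      ang <- seq(0, 2 * pi, length.out = nseg + 1)[-(nseg + 1)]
      rings <- do.call(rbind, lapply(seq_along(radii), function(k)
        cbind(radii[k] * cos(ang), radii[k] * sin(ang), heights[k])))
      idx <- function(k, s) (k - 1L) * nseg + ((s - 1L) %% nseg) + 1L
      side <- do.call(rbind, lapply(seq_len(length(radii) - 1), function(k)
        do.call(rbind, lapply(seq_len(nseg), function(s)
          rbind(c(idx(k, s), idx(k, s + 1), idx(k + 1, s + 1)),
                c(idx(k, s), idx(k + 1, s + 1), idx(k + 1, s)))))))
      nv <- nrow(rings)
      centers <- rbind(c(0, 0, 0), c(0, 0, 80))
      caps <- do.call(rbind, lapply(seq_len(nseg), function(s)
        rbind(c(nv + 1L, idx(1, s + 1), idx(1, s)),
              c(nv + 2L, idx(length(radii), s), idx(length(radii), s + 1)))))
      body <- triangle_mesh(rbind(rings, centers), rbind(side, caps))
      handle <- mesh_box(c(34, 12, 14), origin = c(18, -6, 33))
      mesh_append(body, handle)
    })
  m
}

#' Area-weighted uniform sampling of a mesh surface
#'
#' @param mesh A `triangle_mesh`.
#' @param n number of samples.
#' @return List with `points` (n x 3), `face` (1-based source face) and
#'   `normals` (n x 3 face normals). Uses the current RNG state.
#' @export
mesh_sample_surface <- function(mesh, n) {
  stopifnot(n > 0)
  f <- sample.int(nrow(mesh$faces), n, replace = TRUE,
                  prob = mesh$face_areas)
  r1 <- sqrt(stats::runif(n)); r2 <- stats::runif(n)
  a <- mesh$vertices[mesh$faces[f, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[f, 2], , drop = FALSE]
  c_ <- mesh$vertices[mesh$faces[f, 3], , drop = FALSE]
  pts <- (1 - r1) * a + r1 * (1 - r2) * b + r1 * r2 * c_
  list(points = pts, face = f,
       normals = mesh$face_normals[f, , drop = FALSE])
}
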