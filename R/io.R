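#' @keywords internal
#' @useDynLib thermaltouch, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom rlang .data
"_PACKAGE"

#' Read a triangle mesh from PLY or OBJ
#'
#' Supports ASCII and binary little-endian PLY (vertex x/y/z as float or
#' double, triangulated or fan-triangulatable face lists) and Wavefront
#' OBJ (v/f records). Degenerate faces are dropped by the mesh
#' constructor.
#'
#' @param path file path ending in `.ply` or `.obj`.
#' @return A `triangle_mesh`.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = {
           p <- read_ply(path)
           if (is.null(p$faces)) stop("PLY has no faces: ", path)
           triangle_mesh(p$vertices, p$faces)
         },
         obj = read_obj(path),
         stop("unknown mesh extension '", ext, "'; supported: ply, obj"))
}

#' Read a scene point cloud from PLY
#' @param path `.ply` file (ASCII or binary little-endian).
#' @return A `scene_cloud` (non-finite points dropped with a message).
#' @export
read_cloud <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  p <- read_ply(path)
  scene_cloud(p$vertices, normals = p$normals)
}

#' Write a mesh or point cloud to ASCII PLY
#' @param x A `triangle_mesh` or `scene_cloud`.
#' @param path output `.ply` path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(x, path) {
  if (inherits(x, "triangle_mesh")) {
    v <- x$vertices; f <- x$faces
    hdr <- c("ply", "format ascii 1.0",
             paste("element vertex", nrow(v)),
             "property double x", "property double y", "property double z",
             paste("element face", nrow(f)),
             "property list uchar int vertex_indices", "end_header")
    writeLines(c(hdr,
                 apply(v, 1, function(r) paste(format(r, digits = 17),
                                               collapse = " ")),
                 apply(f - 1L, 1, function(r) paste(c(3L, r),
                                                    collapse = " "))),
               path)
  } else if (inherits(x, "scene_cloud")) {
    v <- x$points
    has_n <- !is.null(x$normals)
    hdr <- c("ply", "format ascii 1.0",
             paste("element vertex", nrow(v)),
             "property double x", "property double y", "property double z",
             if (has_n) c("property double nx", "property double ny",
                          "property double nz"),
             "end_header")
    body <- if (has_n) cbind(v, x$normals) else v
    writeLines(c(hdr, apply(body, 1, function(r)
      paste(format(r, digits = 17), collapse = " "))), path)
  } else stop("write_ply: unsupported object")
  invisible(path)
}

# Minimal PLY reader: ASCII and binary_little_endian, vertex properties
# x/y/z (+nx/ny/nz), face list property.
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, 1)
    if (length(line) == 0) stop("malformed PLY header (no end_header): ", path)
    hdr <- c(hdr, line)
    if (line == "end_header") break
  }
  if (hdr[1] != "ply") stop("not a PLY file: ", path)
  fmt <- strsplit(grep("^format", hdr, value = TRUE)[1], "\\s+")[[1]][2]
  elements <- list(); cur <- NULL
  for (line in hdr) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "element") {
      cur <- tok[2]
      elements[[cur]] <- list(n = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      elements[[cur]]$props[[length(elements[[cur]]$props) + 1]] <- tok[-1]
    }
  }
  type_size <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1, short = 2,
                 ushort = 2, int16 = 2, uint16 = 2, int = 4, uint = 4,
                 int32 = 4, uint32 = 4, float = 4, float32 = 4,
                 double = 8, float64 = 8)
  read_scalar <- function(type) {
    sz <- type_size[[type]]
    if (type %in% c("float", "float32", "double", "float64"))
      readBin(con, "double", 1, size = sz, endian = "little")
    else readBin(con, "integer", 1, size = sz,
                 signed = !(sz < 4 && grepl("^u", type)), endian = "little")
  }
  vertices <- NULL; normals <- NULL; faces <- NULL
  for (el in names(elements)) {
    e <- elements[[el]]
    is_list <- vapply(e$props, function(p) p[1] == "list", TRUE)
    if (fmt == "ascii") {
      rows <- readLines(con, e$n)
      if (el == "vertex") {
        pn <- vapply(e$props, function(p) p[length(p)], "")
        m <- do.call(rbind, lapply(rows, function(r)
          as.numeric(strsplit(trimws(r), "\\s+")[[1]])))
        vertices <- m[, match(c("x", "y", "z"), pn), drop = FALSE]
        if (all(c("nx", "ny", "nz") %in% pn))
          normals <- m[, match(c("nx", "ny", "nz"), pn), drop = FALSE]
      } else if (el == "face") {
        faces <- do.call(rbind, lapply(rows, function(r) {
          v <- as.integer(strsplit(trimws(r), "\\s+")[[1]])
          k <- v[1]; idx <- v[2:(k + 1)] + 1L
          if (k == 3) matrix(idx, 1)
          else do.call(rbind, lapply(2:(k - 1), function(j)
            c(idx[1], idx[j], idx[j + 1])))
        }))
      }
    } else if (fmt == "binary_little_endian") {
      if (el == "vertex") {
        pn <- vapply(e$props, function(p) p[length(p)], "")
        m <- matrix(NA_real_, e$n, length(e$props))
        for (i in seq_len(e$n))
          for (j in seq_along(e$props))
            m[i, j] <- read_scalar(e$props[[j]][1])
        vertices <- m[, match(c("x", "y", "z"), pn), drop = FALSE]
        if (all(c("nx", "ny", "nz") %in% pn))
          normals <- m[, match(c("nx", "ny", "nz"), pn), drop = FALSE]
      } else if (el == "face") {
        fl <- list()
        for (i in seq_len(e$n)) {
          for (j in seq_along(e$props)) {
            p <- e$props[[j]]
            if (p[1] == "list") {
              k <- read_scalar(p[2])
              idx <- vapply(seq_len(k), function(q) read_scalar(p[3]), 0) + 1
              if (k == 3) fl[[length(fl) + 1]] <- matrix(idx, 1)
              else for (q in 2:(k - 1))
                fl[[length(fl) + 1]] <- matrix(c(idx[1], idx[q], idx[q + 1]), 1)
            } else read_scalar(p[1])
          }
        }
        faces <- do.call(rbind, fl)
      } else {
        # skip unknown fixed-size element
        for (i in seq_len(e$n))
          for (j in seq_along(e$props)) read_scalar(e$props[[j]][1])
      }
    } else stop("unsupported PLY format: ", fmt)
  }
  if (is.null(vertices)) stop("PLY has no vertex element: ", path)
  list(vertices = vertices, normals = normals, faces = faces)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  if (length(vl) == 0 || length(fl) == 0)
    stop("OBJ missing v/f records: ", path)
  v <- do.call(rbind, lapply(vl, function(r)
    as.numeric(strsplit(trimws(r), "\\s+")[[1]][2:4])))
  f <- do.call(rbind, lapply(fl, function(r) {
    tok <- strsplit(trimws(r), "\\s+")[[1]][-1]
    idx <- as.integer(vapply(strsplit(tok, "/"), `[`, "", 1))
    if (length(idx) == 3) matrix(idx, 1)
    else do.call(rbind, lapply(2:(length(idx) - 1), function(j)
      c(idx[1], idx[j], idx[j + 1])))
  }))
  triangle_mesh(v, f)
}

#' Read and write radiometric frames as 16-bit rasters
#'
#' Frames are stored as 16-bit grayscale TIFF or PNG with a linear
#' counts-to-temperature calibration: `temperature = gain * counts +
#' offset`. The default mapping (gain 0.01 degC/count, offset 0) covers
#' 0-655 degC at centi-degree resolution.
#'
#' @param path image path (`.tif`, `.tiff` or `.png`).
#' @param frame A `radiometric_frame` (for writing).
#' @param gain,offset linear calibration (degC per count, degC).
#' @param camera_name camera identifier attached on read.
#' @return `read_frame`: a `radiometric_frame`; `write_frame`: `path`,
#'   invisibly.
#' @export
read_frame <- function(path, gain = 0.01, offset = 0, camera_name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                tif = , tiff = tiff::readTIFF(path),
                png = png::readPNG(path),
                stop("unknown frame extension '", ext,
                     "'; supported: tif, tiff, png"))
  if (length(dim(img)) == 3) img <- img[, , 1]
  counts <- round(img * 65535)
  if (is.null(camera_name))
    camera_name <- sub("\\.(tif|tiff|png)$", "", basename(path),
                       ignore.case = TRUE)
  radiometric_frame(gain * counts + offset, camera_name = camera_name)
}

#' @rdname read_frame
#' @export
write_frame <- function(frame, path, gain = 0.01, offset = 0) {
  counts <- round((frame$pixels - offset) / gain)
  if (any(counts < 0) || any(counts > 65535))
    stop("temperatures outside the representable range of the mapping")
  img <- counts / 65535
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tif = , tiff = tiff::writeTIFF(img, path, bits.per.sample = 16),
         png = png::writePNG(img, path),
         stop("unknown frame extension '", ext, "'"))
  invisible(path)
}

#' Read and write camera-rig configurations
#'
#' The rig config is YAML: per camera `name`, `fx`, `fy`, `cx`, `cy`,
#' `distortion` (5 values: k1, k2, k3, p1, p2), `rotation` (9 values,
#' row-major), `translation` (3 values, mm), `width`, `height`. Rotation
#' and translation map scanner-frame points to camera-frame points.
#'
#' @param path YAML file path.
#' @param rig named list of `camera_model` (for writing).
#' @return `read_rig`: named list of `camera_model`; `write_rig`: `path`,
#'   invisibly.
#' @export
read_rig <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$cameras)) stop("rig config has no 'cameras' list: ", path)
  rig <- lapply(cfg$cameras, function(cc)
    camera_model(cc$name, fx = cc$fx, fy = cc$fy, cx = cc$cx, cy = cc$cy,
                 width = cc$width, height = cc$height,
                 distortion = as.numeric(cc$distortion),
                 pose = rigid_transform(
                   matrix(as.numeric(cc$rotation), 3, 3, byrow = TRUE),
                   as.numeric(cc$translation))))
  names(rig) <- vapply(rig, function(cm) cm$name, "")
  rig
}

#' @rdname read_rig
#' @export
write_rig <- function(rig, path) {
  cams <- lapply(rig, function(cm) list(
    name = cm$name, fx = cm$fx, fy = cm$fy, cx = cm$cx, cy = cm$cy,
    distortion = cm$distortion,
    rotation = as.numeric(t(cm$pose$rotation)),
    translation = cm$pose$translation,
    width = cm$width, height = cm$height))
  yaml::write_yaml(list(
    comment = paste("rotation/translation map scanner-frame points to",
                    "camera-frame points; rotation row-major;",
                    "distortion k1 k2 k3 p1 p2"),
    cameras = unname(cams)), path, precision = 15)
  invisible(path)
}

#' Read and write object poses as JSON
#'
#' Pose JSON: `rotation` (9 values row-major, object to scanner),
#' `translation` (3, mm), plus `rms_residual` and `inlier_fraction`
#' diagnostics.
#'
#' @param path JSON path.
#' @param pose An `object_pose` (for writing).
#' @return `read_pose`: an `object_pose`; `write_pose`: `path`, invisibly.
#' @export
read_pose <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  object_pose(rigid_transform(matrix(j$rotation, 3, 3, byrow = TRUE),
                              j$translation),
              rms_residual = j$rms_residual %||% 0,
              inlier_fraction = j$inlier_fraction %||% 1)
}

#' @rdname read_pose
#' @export
write_pose <- function(pose, path) {
  jsonlite::write_json(list(
    rotation = as.numeric(t(pose$transform$rotation)),
    translation = pose$transform$translation,
    rms_residual = pose$rms_residual,
    inlier_fraction = pose$inlier_fraction),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a contact table to CSV
#'
#' Columns `X_mm,Y_mm,Z_mm,r_mm,incident_deg,camera`.
#' @param contacts contact tibble (from [map_scene()] / [fuse_contacts()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_contacts_csv <- function(contacts, path) {
  out <- data.frame(X_mm = contacts$X, Y_mm = contacts$Y, Z_mm = contacts$Z,
                    r_mm = contacts$r_prime,
                    incident_deg = contacts$incident_angle,
                    camera = contacts$camera)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_contacts_csv
#' @export
read_contacts_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path)
  tibble::tibble(X = d$X_mm, Y = d$Y_mm, Z = d$Z_mm, r_prime = d$r_mm,
                 incident_angle = d$incident_deg, camera = d$camera)
}

#' Export a synthetic scene to a directory
#'
#' Writes everything the pipeline consumes: per-camera 16-bit TIFF frames,
#' the scene cloud and object mesh as PLY, the rig config (YAML), the true
#' object pose (JSON) and the ground-truth contacts (JSON).
#'
#' @param truth A `scene_truth`.
#' @param dir output directory (created if needed).
#' @param n_cloud_points,cloud_noise_mm cloud sampling settings.
#' @return `dir`, invisibly.
#' @export
export_scene <- function(truth, dir, n_cloud_points = 3000,
                         cloud_noise_mm = 0) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  frames <- render_scene_frames(truth)
  for (cn in names(frames))
    write_frame(frames[[cn]], file.path(dir, paste0(cn, ".tif")))
  write_ply(sample_cloud(truth, n_cloud_points, cloud_noise_mm),
            file.path(dir, "cloud.ply"))
  write_ply(truth$mesh, file.path(dir, "mesh.ply"))
  write_rig(truth$rig, file.path(dir, "rig.yaml"))
  write_pose(truth$object_pose, file.path(dir, "pose.json"))
  tc <- truth_contacts(truth)
  jsonlite::write_json(list(
    mesh = truth$mesh_name, ambient = truth$ambient,
    noise_sigma = truth$noise_sigma, seed = truth$seed,
    contacts = as.data.frame(tc)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
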