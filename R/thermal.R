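#' Radiometric infrared frame
#'
#' A frame is an H x W raster of per-pixel temperatures in degrees Celsius
#' (or linearly calibrated counts). Pixel `(u, v)` in 0-based image
#' coordinates is stored at matrix entry `[v + 1, u + 1]`.
#'
#' @param pixels numeric H x W matrix of temperatures (degC); all finite.
#' @param camera_name identifier of the source camera.
#' @param timestamp acquisition time in seconds (informational).
#' @return An object of class `radiometric_frame`.
#' @export
radiometric_frame <- function(pixels, camera_name = "cam", timestamp = 0) {
  pixels <- unname(as.matrix(pixels))
  if (nrow(pixels) == 0 || ncol(pixels) == 0) stop("empty frame")
  if (!all(is.finite(pixels))) stop("non-finite pixel values")
  structure(list(pixels = pixels, camera_name = as.character(camera_name),
                 timestamp = timestamp),
            class = "radiometric_frame")
}

#' @export
print.radiometric_frame <- function(x, ...) {
  cat(sprintf("<radiometric_frame> %s  %dx%d px, %.2f-%.2f degC\n",
              x$camera_name, ncol(x$pixels), nrow(x$pixels),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Robust ambient-temperature estimate
#'
#' The scene background dominates the image area, so the per-pixel median is
#' a robust estimate of ambient temperature even with heated regions
#' present.
#'
#' @param frame A `radiometric_frame`.
#' @return Ambient temperature (degC).
#' @export
estimate_ambient <- function(frame) {
  stats::median(frame$pixels)
}

#' Detect post-contact heat signatures (blobs)
#'
#' Thresholds the frame at `ambient + threshold_excess`, labels 8-connected
#' components, filters them by area and circularity
#' (`4 * pi * area / perimeter^2`, perimeter counted as boundary pixels),
#' and reports one detection per surviving component. The blob center is
#' the intensity-weighted centroid (weights = excess over the threshold)
#' and the radius is the equivalent-disk radius `sqrt(area / pi)`.
#'
#' Defaults are tuned for fingertip-scale contacts: `threshold_excess` 1.0
#' degC admits the ~3-4 degC signatures skin contact leaves while rejecting
#' sensor noise, and the circularity floor rejects elongated specular
#' streaks from reflective surfaces.
#'
#' @param frame A `radiometric_frame` (temperatures in degC).
#' @param threshold_excess detection threshold above ambient (degC).
#' @param min_area,max_area component area bounds (px^2); `max_area`
#'   defaults to 10 percent of the frame.
#' @param min_circularity circularity floor in (0, 1\].
#' @param polarity `"warm"` detects regions warmer than ambient (contact
#'   signatures); `"cold"` detects colder regions (calibration circles).
#' @param exclude_border drop components touching the image border (used by
#'   target detection, where a clipped circle is never a valid candidate).
#' @return A tibble with one row per detection: `camera`, `u`, `v`
#'   (sub-pixel center, 0-based px), `r` (px) and `peak_excess` (degC),
#'   sorted by decreasing `peak_excess` (ties by `u` then `v`).
#' @examples
#' px <- matrix(25, 64, 96)
#' px[20:26, 40:46] <- 25 + 3 * exp(-outer((-3:3)^2, (-3:3)^2, "+") / 8)
#' detect_blobs(radiometric_frame(px))
#' @export
detect_blobs <- function(frame, threshold_excess = 1.0, min_area = 9,
                         max_area = NULL, min_circularity = 0.5,
                         polarity = c("warm", "cold"),
                         exclude_border = FALSE) {
  polarity <- match.arg(polarity)
  stopifnot(threshold_excess > 0, min_area > 0, min_circularity >= 0)
  px <- frame$pixels
  if (is.null(max_area)) max_area <- 0.1 * length(px)
  stopifnot(min_area < max_area)
  ambient <- estimate_ambient(frame)
  excess <- if (polarity == "warm") px - ambient else ambient - px
  mask <- excess > threshold_excess
  if (all(mask))
    stop("all pixels above threshold: ambient estimation failure")
  empty <- tibble::tibble(camera = character(), u = numeric(),
                          v = numeric(), r = numeric(),
                          peak_excess = numeric())
  if (!any(mask)) return(empty)
  lab <- cpp_label_components(mask)
  h <- nrow(px); w <- ncol(px)
  # boundary pixels: any 4-neighbour outside the component (or the image)
  pad <- matrix(0L, h + 2, w + 2); pad[2:(h + 1), 2:(w + 1)] <- lab
  core <- pad[2:(h + 1), 2:(w + 1)]
  boundary <- (core > 0) &
    (pad[1:h, 2:(w + 1)] != core | pad[3:(h + 2), 2:(w + 1)] != core |
     pad[2:(h + 1), 1:w] != core | pad[2:(h + 1), 3:(w + 2)] != core)
  ids <- seq_len(max(lab))
  area <- tabulate(lab[lab > 0], nbins = max(lab))
  perim <- tabulate(core[boundary], nbins = max(lab))
  on_border <- rep(FALSE, max(lab))
  edge <- unique(c(lab[1, ], lab[h, ], lab[, 1], lab[, w]))
  on_border[edge[edge > 0]] <- TRUE
  rows <- lapply(ids, function(k) {
    if (area[k] < min_area || area[k] > max_area) return(NULL)
    if (exclude_border && on_border[k]) return(NULL)
    circ <- 4 * pi * area[k] / perim[k]^2
    if (circ < min_circularity) return(NULL)
    sel <- which(lab == k, arr.ind = TRUE)
    wgt <- excess[lab == k] - threshold_excess
    if (sum(wgt) <= 0) wgt <- rep(1, length(wgt))
    tibble::tibble(camera = frame$camera_name,
                   u = sum(wgt * (sel[, 2] - 1)) / sum(wgt),
                   v = sum(wgt * (sel[, 1] - 1)) / sum(wgt),
                   r = sqrt(area[k] / pi),
                   peak_excess = max(excess[lab == k]))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(empty)
  dplyr::arrange(out, dplyr::desc(.data$peak_excess), .data$u, .data$v)
}
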