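#' Plot a radiometric frame with optional blob overlays
#'
#' @param frame A `radiometric_frame`.
#' @param blobs optional tibble from [detect_blobs()] to overlay.
#' @return A ggplot object (temperature raster, image orientation: v grows
#'   downwards).
#' @export
plot_frame <- function(frame, blobs = NULL) {
  df <- expand.grid(v = seq_len(nrow(frame$pixels)) - 1,
                    u = seq_len(ncol(frame$pixels)) - 1)
  df$temp <- as.numeric(frame$pixels)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$u, .data$v,
                                        fill = .data$temp)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = "degC") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = frame$camera_name, x = "u (px)", y = "v (px)")
  if (!is.null(blobs) && nrow(blobs) > 0)
    p <- p + ggplot2::geom_point(
      data = blobs, ggplot2::aes(.data$u, .data$v, size = .data$r),
      inherit.aes = FALSE, shape = 1, colour = "cyan") +
    ggplot2::scale_size_identity()
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot fused contact points in object coordinates
#'
#' Orthographic X-Y view of the recovered contacts, sized by contact
#' radius and colored by winning camera.
#'
#' @param object A `contact_map`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot contact_map
#' @export
autoplot.contact_map <- function(object, ...) {
  ggplot2::ggplot(object$contacts,
                  ggplot2::aes(.data$X, .data$Y, size = .data$r_prime,
                               colour = .data$camera)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "X (mm)", y = "Y (mm)", size = "r' (mm)",
                  title = "Recovered contact points (object frame)")
}
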