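#' Plot a particle track on the detector
#'
#' Detector-coordinate view of the fiducial trajectory, coloured by
#' projection angle. A tilted rotation axis shows up as an ellipse or an
#' inclined line; an aligned axis as a flat horizontal track.
#'
#' @param object a `particle_track`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.particle_track <- function(object, ...) {
  df <- object[object$in_fov, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v,
                                   colour = .data$angle)) +
    ggplot2::geom_path(alpha = 0.6) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "u (px)", y = "v (px)", colour = "angle (deg)") +
    ggplot2::theme_minimal()
}

#' Plot projection images from a stack
#'
#' @param object a `projection_stack`.
#' @param angles subset of angles to show (defaults to up to 4, evenly
#'   spaced through the stack).
#' @param ... unused.
#' @return A ggplot object (faceted raster images).
#' @export
autoplot.projection_stack <- function(object, angles = NULL, ...) {
  if (is.null(angles)) {
    idx <- unique(round(seq(1, length(object$angles),
                            length.out = min(4, length(object$angles)))))
  } else {
    idx <- match(angles, object$angles)
    idx <- idx[!is.na(idx)]
  }
  df <- purrr::map_dfr(idx, function(i) {
    img <- object$images[[i]]
    tibble(angle = object$angles[i],
           u = rep(0:(ncol(img) - 1), each = nrow(img)),
           v = rep(0:(nrow(img) - 1), times = ncol(img)),
           intensity = as.vector(img))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~angle, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "u (px)", y = "v (px)") +
    ggplot2::theme_minimal()
}

#' Plot an alignment report
#'
#' For GA fine stages, the per-generation best/mean fitness; for the coarse
#' axis stage, the before/after particle tracks.
#'
#' @param object an `alignment_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.alignment_report <- function(object, ...) {
  if (!is.null(object$history)) {
    return(autoplot(object$ga) +
             ggplot2::ggtitle(paste("fitness history:", object$stage)))
  }
  if (!is.null(object$track_before)) {
    df <- dplyr::bind_rows(
      dplyr::mutate(object$track_before, when = "before"),
      dplyr::mutate(object$track_after, when = "after"))
    df <- df[df$in_fov, ]
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v,
                                       colour = .data$when)) +
        ggplot2::geom_path() +
        ggplot2::scale_y_reverse() +
        ggplot2::coord_equal() +
        ggplot2::labs(x = "u (px)", y = "v (px)", colour = NULL,
                      title = "fiducial trajectory: coarse axis alignment") +
        ggplot2::theme_minimal())
  }
  stop_bad("nothing to plot for this report", "plot_error")
}
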