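#' Plot a topographic aperture-overlay map
#'
#' Color-wash of the per-pixel overlay counts, the map from which
#' threshold apertures are cut.
#'
#' @param object A `topographic_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.topographic_map <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$x_mm, y = .data$y_mm,
                               fill = .data$count)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "overlap") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "BEV x (mm)", y = "BEV y (mm)",
                  title = sprintf("Top-aperture overlay (%d apertures)",
                                  object$n_apertures))
}

#' Plot an MI shift surface
#'
#' @param object An `mi_surface`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mi_surface <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$dx_mm, y = .data$dy_mm,
                               fill = .data$mi)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "MI (nats)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "shift x (mm)", y = "shift y (mm)",
                  title = "MI under simulated shifts")
}

#' Plot per-control-point repositioning errors
#'
#' Boxplots of the 2D (beam's-eye-view) and 3D (couch-axis) disagreement
#' between the two detection methods.
#'
#' @param object An `error_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.error_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(
    filter(object$per_point, .data$ok),
    cols = c("err2d_mm", "err3d_mm"),
    names_to = "kind", values_to = "error_mm")
  long$kind <- ifelse(long$kind == "err2d_mm", "2D (BEV)", "3D (couch)")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$kind, y = .data$error_mm)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.4) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "error vs BB tracking (mm)",
                  title = "Repositioning error")
}

#' Scatter of aperture information metrics
#'
#' The good/bad feature scatter: normalized polar-histogram variance
#' against mean MI difference, sized by aperture area.
#'
#' @param features Tibble from [aperture_features()].
#' @return A ggplot.
#' @export
plot_feature_scatter <- function(features) {
  ggplot2::ggplot(features,
                  ggplot2::aes(x = .data$mi_mean_diff,
                               y = .data$polar_var_norm,
                               color = .data$label,
                               size = .data$area_cm2)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_color_manual(values = c(good = "black", bad = "red",
                                           neither = "grey60")) +
    ggplot2::labs(x = "mean MI difference (nats)",
                  y = "normalized polar variance",
                  color = "aperture", size = expression(area ~ (cm^2)))
}
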