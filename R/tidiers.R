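#' Tidy an imaging plan
#'
#' @param x An `imaging_plan`.
#' @param ... Unused.
#' @return One row per control point with the geometry and aperture.
#' @export
tidy.imaging_plan <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' @rdname tidy.imaging_plan
#' @export
glance.imaging_plan <- function(x, ...) {
  tibble(n_control_points = nrow(x),
         threshold = as.character(attr(x, "threshold")),
         seed = attr(x, "seed"),
         mean_area_cm2 = mean(x$area_cm2),
         min_area_cm2 = min(x$area_cm2),
         max_area_cm2 = max(x$area_cm2),
         n_fallback = sum(x$fallback))
}

#' Tidy a topographic map
#'
#' @param x A `topographic_map`.
#' @param ... Unused.
#' @return Long tibble with columns `x_mm`, `y_mm`, `count`.
#' @export
tidy.topographic_map <- function(x, ...) {
  tibble(x_mm = rep(x$x_mm, times = length(x$y_mm)),
         y_mm = rep(x$y_mm, each = length(x$x_mm)),
         count = as.integer(x$counts))
}

#' Tidy an MI shift surface
#'
#' @param x An `mi_surface`.
#' @param ... Unused.
#' @return Long tibble with columns `dx_mm`, `dy_mm`, `mi`.
#' @export
tidy.mi_surface <- function(x, ...) {
  tibble(dx_mm = rep(x$shift_x, times = length(x$shift_y)),
         dy_mm = rep(x$shift_y, each = length(x$shift_x)),
         mi = as.numeric(x$values))
}

#' Tidy a registration-error study
#'
#' @param x A `registration_error_study`.
#' @param ... Unused.
#' @return The per-registration error table.
#' @export
tidy.registration_error_study <- function(x, ...) x$errors

#' @rdname tidy.registration_error_study
#' @export
glance.registration_error_study <- function(x, ...) x$summary

#' Tidy an anatomy-vs-BB error summary
#'
#' @param x An `error_summary`.
#' @param ... Unused.
#' @return The per-control-point error table.
#' @export
tidy.error_summary <- function(x, ...) x$per_point

#' @rdname tidy.error_summary
#' @export
glance.error_summary <- function(x, ...) x$summary
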