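#' Digital registration-error study
#'
#' The grid-shifting experiment that validates an imaging plan: at every
#' control point the reference DRR content is translated over a grid of
#' known in-plane shifts (windowed Fourier resampling around the
#' aperture), each shifted crop is registered back to the unshifted crop,
#' and the per-axis absolute error |detected - applied| is recorded. The
#' headline statistic is the 99th percentile of the pooled per-axis
#' errors.
#'
#' @param volume The phantom [ct_volume()]; the BB region is replaced with
#'   fill material first if still present.
#' @param plan An `imaging_plan` from [build_imaging_plan()].
#' @param shifts Shift grid; the default spans +/-2.5 mm on an 11 x 11
#'   grid.
#' @param interp Subpixel resampler for the registrations (default cubic,
#'   the high-accuracy mode).
#' @param bound Registration search bound (mm); default covers the largest
#'   applied shift plus 1.5 mm.
#' @param tol,bins Registration settings.
#' @param mu_water Attenuation calibration.
#' @param bb_fill_hu,bb_neighborhood Passed to [remove_bb_region()].
#' @param verbose Per-control-point progress messages.
#' @return An object of class `registration_error_study`: `errors` (one
#'   row per control point x shift: applied and detected shifts, per-axis
#'   errors) and `summary` (percentiles of the pooled absolute error).
#' @export
registration_error_study <- function(volume, plan,
                                     shifts = shift_grid(2.5, 11),
                                     interp = "cubic", bound = NULL,
                                     tol = 0.01, bins = 50L,
                                     mu_water = 0.00505,
                                     bb_fill_hu = 36.1,
                                     bb_neighborhood = c(60, 60, 40),
                                     verbose = FALSE) {
  if (!is.null(volume$bb))
    volume <- remove_bb_region(volume, bb_neighborhood, bb_fill_hu)
  detector <- attr(plan, "detector") %||% detector_spec()
  if (is.null(bound)) bound <- max(abs(c(shifts$dx_mm, shifts$dy_mm))) + 1.5

  rows <- purrr::map(seq_len(nrow(plan)), function(i) {
    cpr <- plan[i, ]
    if (verbose)
      message(sprintf("error study: control point %d/%d", i, nrow(plan)))
    drr <- compute_drr(volume, cpr, detector, mu_water)
    win <- aperture_window(drr, cpr)
    fixed <- drr$intensity[win$rows, win$cols, drop = FALSE]
    pad <- ceiling(bound / drr$pitch) + 6L
    purrr::map_dfr(seq_len(nrow(shifts)), function(s) {
      moving <- shift_window(drr$intensity, win$rows, win$cols,
                             shifts$dx_mm[s] / drr$pitch,
                             shifts$dy_mm[s] / drr$pitch, pad = pad)
      res <- register_translation(fixed, moving, drr$pitch, bound = bound,
                                  tol = tol, bins = bins, interp = interp,
                                  max_samples = 2500L)
      tibble(cp = cpr$cp, gantry = cpr$gantry, couch = cpr$couch,
             applied_dx = shifts$dx_mm[s], applied_dy = shifts$dy_mm[s],
             detected_dx = res$dx_mm, detected_dy = res$dy_mm,
             err_x = abs(res$dx_mm - shifts$dx_mm[s]),
             err_y = abs(res$dy_mm - shifts$dy_mm[s]),
             converged = res$converged)
    })
  })
  errors <- bind_rows(rows)
  pooled <- c(errors$err_x, errors$err_y)
  summary <- tibble(
    n_registrations = nrow(errors),
    n_failed = sum(!errors$converged),
    mean_err = mean(pooled, na.rm = TRUE),
    median_err = median(pooled, na.rm = TRUE),
    p95_err = quantile(pooled, 0.95, na.rm = TRUE, names = FALSE),
    p99_err = quantile(pooled, 0.99, na.rm = TRUE, names = FALSE),
    max_err = max(pooled, na.rm = TRUE)
  )
  structure(list(errors = errors, summary = summary),
            class = "registration_error_study")
}

#' @export
print.registration_error_study <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<registration_error_study> %d registrations (%d failed)\n",
    s$n_registrations, s$n_failed))
  cat(sprintf(
    "  |error| mean %.4f, median %.4f, p95 %.4f, p99 %.4f, max %.4f mm\n",
    s$mean_err, s$median_err, s$p95_err, s$p99_err, s$max_err))
  invisible(x)
}
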