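#' Couch correction from a beam's-eye-view displacement
#'
#' Converts an in-plane displacement `(dx, dy)` observed in the
#' beam's-eye-view at gantry angle `theta` and couch angle `phi` into the
#' lateral/longitudinal/vertical couch-axis triple:
#' \deqn{\Delta Lat = \cos\phi \, dx \cos\theta - \sin\phi \, dy}
#' \deqn{\Delta Lng = \sin\phi \, dx \cos\theta + \cos\phi \, dy}
#' \deqn{\Delta Vrt = dx \sin\theta}
#' The map has orthonormal columns, so the 3D norm always equals
#' `sqrt(dx^2 + dy^2)`: a single planar view recovers exactly the
#' component of motion visible in that view and nothing along the
#' beamline.
#'
#' @param dx_mm,dy_mm BEV displacement (mm, isocenter plane).
#' @param gantry Gantry angle in degrees.
#' @param couch Couch angle in degrees (planning-system scale, 0 = axial).
#' @return A tibble with columns `lat_mm`, `lng_mm`, `vrt_mm` (one row per
#'   input).
#' @export
derive_couch_shift <- function(dx_mm, dy_mm, gantry, couch = 0) {
  th <- gantry * pi / 180
  ph <- couch * pi / 180
  tibble(lat_mm = cos(ph) * dx_mm * cos(th) - sin(ph) * dy_mm,
         lng_mm = sin(ph) * dx_mm * cos(th) + cos(ph) * dy_mm,
         vrt_mm = dx_mm * sin(th))
}

#' Intrafraction motion traces
#'
#' True phantom offset at every control point for the two simulated motion
#' patterns: a linear drift reaching `magnitude` mm on each couch axis at
#' the final control point (the first has none), or a sudden persistent
#' step of `magnitude` mm on each axis at the onset control point
#' (default: halfway through the first, axial, arc). `kind = "none"` gives
#' a static phantom.
#'
#' @param kind `"linear"`, `"sudden"`, or `"none"`.
#' @param control_points Tibble from [control_points_from_arcs()].
#' @param magnitude Per-axis magnitude in mm.
#' @param onset Control-point index (1-based) at which the sudden step
#'   appears; ignored for other kinds.
#' @return A `motion_trace` tibble: `cp`, `lat_mm`, `lng_mm`, `vrt_mm`.
#' @export
make_motion_trace <- function(kind = c("linear", "sudden", "none"),
                              control_points, magnitude = 1.5,
                              onset = NULL) {
  kind <- match.arg(kind)
  if (!nrow(control_points)) abort("control-point list is empty")
  if (!is.finite(magnitude)) abort("`magnitude` must be finite")
  n <- nrow(control_points)
  f <- switch(kind,
    none = rep(0, n),
    linear = if (n == 1) 0 else (seq_len(n) - 1) / (n - 1),
    sudden = {
      if (is.null(onset)) {
        n1 <- sum(control_points$arc == control_points$arc[1])
        onset <- floor(n1 / 2) + 1L
      }
      as.numeric(seq_len(n) >= onset)
    })
  out <- tibble(cp = control_points$cp,
                lat_mm = magnitude * f, lng_mm = magnitude * f,
                vrt_mm = magnitude * f)
  attr(out, "kind") <- kind
  class(out) <- c("motion_trace", class(out))
  out
}

#' Simulate an EPID image under a phantom offset
#'
#' The megavoltage portal image at one control point: a DRR of the volume
#' rigidly translated by the room-frame offset, restricted to the aperture
#' pixels. The BB is left in place — portal images contain the fiducial,
#' unlike the BB-free reference DRRs. Optional Poisson-like detector noise
#' scales the unit-intensity photon count by `noise_photons`.
#'
#' @param volume A [ct_volume()] (with BB).
#' @param geometry A [beam_geometry()] or control-point row.
#' @param offset Length-3 room offset (lat, lng, vrt) in mm.
#' @param aperture One-row aperture tibble (the imaging field).
#' @param detector A [detector_spec()].
#' @param mu_water Attenuation calibration.
#' @param noise_photons Photons per pixel at intensity 1; `NULL` disables
#'   noise.
#' @param noise_seed Seed for the noise draw (required when noise is on).
#' @return A [drr_image()] covering the aperture.
#' @export
simulate_epid_image <- function(volume, geometry, offset = c(0, 0, 0),
                                aperture = NULL,
                                detector = detector_spec(),
                                mu_water = 0.00505,
                                noise_photons = NULL, noise_seed = 1L) {
  moved <- translate_volume(volume, offset)
  img <- compute_drr(moved, geometry, detector, mu_water, aperture)
  if (!is.null(noise_photons)) {
    withr::with_seed(as.integer(noise_seed), {
      counts <- rpois(length(img$intensity),
                      pmax(img$intensity, 0) * noise_photons)
    })
    img$intensity <- matrix(counts / noise_photons,
                            nrow(img$intensity), ncol(img$intensity))
  }
  img
}

#' Simulate image-guided delivery along a plan
#'
#' Walks the imaging plan control point by control point: at each point
#' the phantom sits at the motion trace's true offset, an EPID image is
#' simulated, the in-plane displacement is detected — by BB tracking
#' through a small square jaw field, or by MI registration of the
#' preprocessed aperture crop against the BB-free reference DRR — and
#' converted to a couch-axis triple with [derive_couch_shift()]. Detection
#' is open-loop (no correction is fed back), so the detected shifts can be
#' compared directly with the known trace and between methods.
#'
#' Per-point detection failures are flagged (`ok = FALSE`) and the run
#' continues.
#'
#' @param volume The phantom [ct_volume()] including the BB.
#' @param plan An `imaging_plan` from [build_imaging_plan()].
#' @param trace A [make_motion_trace()] over the same control points.
#' @param method `"bb"` or `"anatomy"`.
#' @param jaw_mm Side of the square jaw field used for BB tracking (mm).
#' @param mu_water Attenuation calibration.
#' @param bound,tol,bins,interp Registration settings (anatomy method).
#' @param bb_diameter BB diameter for the matched detection kernel.
#' @param noise_photons,noise_seed EPID noise model (see
#'   [simulate_epid_image()]).
#' @param bb_fill_hu,bb_neighborhood BB removal used for the reference
#'   DRRs.
#' @return A `delivery_run` tibble: per control point the geometry, true
#'   offset, detected BEV displacement `dx_mm`/`dy_mm`, couch triple
#'   `lat_mm`/`lng_mm`/`vrt_mm`, and an `ok` flag.
#' @export
simulate_delivery <- function(volume, plan, trace,
                              method = c("bb", "anatomy"),
                              jaw_mm = 25, mu_water = 0.00505,
                              bound = 4, tol = 0.01, bins = 50L,
                              interp = "cubic", bb_diameter = NULL,
                              noise_photons = NULL, noise_seed = 1L,
                              bb_fill_hu = 36.1,
                              bb_neighborhood = c(60, 60, 40)) {
  method <- match.arg(method)
  if (nrow(plan) != nrow(trace))
    abort("plan and trace must cover the same control points")
  detector <- attr(plan, "detector") %||% detector_spec()
  if (is.null(bb_diameter))
    bb_diameter <- if (!is.null(volume$bb)) volume$bb$diameter else 2
  reference <- if (method == "anatomy")
    remove_bb_region(volume, bb_neighborhood, bb_fill_hu) else NULL

  rows <- purrr::map(seq_len(nrow(plan)), function(i) {
    cpr <- plan[i, ]
    offset <- c(trace$lat_mm[i], trace$lng_mm[i], trace$vrt_mm[i])
    ap <- if (method == "bb") aperture(0, 0, jaw_mm, jaw_mm) else cpr
    base <- tibble(cp = cpr$cp, arc = cpr$arc, gantry = cpr$gantry,
                   couch = cpr$couch, method = method,
                   true_lat = offset[1], true_lng = offset[2],
                   true_vrt = offset[3])
    det <- tryCatch({
      epid <- simulate_epid_image(volume, cpr, offset, ap, detector,
                                  mu_water, noise_photons,
                                  noise_seed = as.integer(noise_seed) + i)
      if (method == "bb") {
        hit <- detect_bb(epid, bb_diameter)
        c(hit$x_mm, hit$y_mm)
      } else {
        ref <- compute_drr(reference, cpr, detector, mu_water, ap)
        res <- register_translation(preprocess_image(ref$intensity),
                                    preprocess_image(epid$intensity),
                                    detector$pitch_iso, bound = bound,
                                    tol = tol, bins = bins, interp = interp)
        if (!res$converged) abort("registration failed")
        c(res$dx_mm, res$dy_mm)
      }
    }, error = function(e) {
      warn(sprintf("control point %d (%s): %s", cpr$cp, method,
                   conditionMessage(e)))
      NULL
    })
    if (is.null(det)) {
      return(mutate(base, dx_mm = NA_real_, dy_mm = NA_real_,
                    lat_mm = NA_real_, lng_mm = NA_real_, vrt_mm = NA_real_,
                    ok = FALSE))
    }
    shift <- derive_couch_shift(det[1], det[2], cpr$gantry, cpr$couch)
    dplyr::bind_cols(mutate(base, dx_mm = det[1], dy_mm = det[2]),
                     shift, tibble(ok = TRUE))
  })
  out <- bind_rows(rows)
  attr(out, "method") <- method
  attr(out, "trace_kind") <- attr(trace, "kind")
  class(out) <- c("delivery_run", class(out))
  out
}

#' Compare anatomy-derived and BB-derived corrections
#'
#' Per-control-point disagreement between two detection runs (typically
#' anatomy registration versus the gold-standard BB tracking): the 2D
#' error is the norm of the BEV displacement difference, the 3D error the
#' norm of the couch-triple difference. Points flagged as failed in either
#' run are excluded from the summaries and counted separately.
#'
#' @param run_a,run_b Two `delivery_run` tibbles over the same control
#'   points (conventionally anatomy first, BB second).
#' @return An object of class `error_summary` with the per-point table and
#'   summary statistics (medians, means, the fraction of points with 2D
#'   error below 1 mm).
#' @export
evaluate_errors <- function(run_a, run_b) {
  if (nrow(run_a) != nrow(run_b) || !all(run_a$cp == run_b$cp))
    abort("runs must cover the same control points in the same order")
  per_point <- tibble(
    cp = run_a$cp, arc = run_a$arc,
    gantry = run_a$gantry, couch = run_a$couch,
    ok = run_a$ok & run_b$ok,
    err2d_mm = sqrt((run_a$dx_mm - run_b$dx_mm)^2 +
                    (run_a$dy_mm - run_b$dy_mm)^2),
    err3d_mm = sqrt((run_a$lat_mm - run_b$lat_mm)^2 +
                    (run_a$lng_mm - run_b$lng_mm)^2 +
                    (run_a$vrt_mm - run_b$vrt_mm)^2)
  )
  good <- filter(per_point, .data$ok)
  summary <- tibble(
    n = nrow(per_point), n_ok = nrow(good),
    n_flagged = nrow(per_point) - nrow(good),
    median_2d = median(good$err2d_mm), mean_2d = mean(good$err2d_mm),
    median_3d = median(good$err3d_mm), mean_3d = mean(good$err3d_mm),
    p95_3d = quantile(good$err3d_mm, 0.95, names = FALSE),
    frac_2d_lt_1mm = mean(good$err2d_mm < 1)
  )
  structure(list(per_point = per_point, summary = summary),
            class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<error_summary> %d control points (%d flagged)\n", s$n, s$n_flagged))
  cat(sprintf("  median 3D %.3f mm, mean 3D %.3f mm, median 2D %.3f mm\n",
              s$median_3d, s$mean_3d, s$median_2d))
  cat(sprintf("  2D error < 1 mm at %.0f%% of points\n",
              100 * s$frac_2d_lt_1mm))
  invisible(x)
}
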