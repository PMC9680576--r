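#' Detector sampling specification
#'
#' The DRR/EPID pixel grid, defined at the isocenter plane (panel pixel
#' pitch times SAD/SID). The grid is centered on the beam central axis with
#' an odd pixel count so the principal point is exactly the central pixel.
#'
#' @param field_mm Field of view edge length at the isocenter plane (mm);
#'   the default 220 mm covers the 22 x 22 cm^2 open imaging field.
#' @param pitch_iso Pixel pitch at the isocenter plane (mm). The default
#'   0.224 mm corresponds to a 0.336 mm panel pitch at SID 1500/SAD 1000;
#'   desk-scale studies typically use 0.5 mm.
#' @return A list of class `detector_spec`.
#' @export
detector_spec <- function(field_mm = 220, pitch_iso = 0.224) {
  if (field_mm <= 0 || pitch_iso <= 0)
    abort("field and pitch must be positive")
  structure(list(field_mm = field_mm, pitch_iso = pitch_iso),
            class = "detector_spec")
}

detector_coords <- function(detector) {
  half <- floor(detector$field_mm / 2 / detector$pitch_iso)
  # shrink by up to a few pixels so the grid edge length has no large
  # prime factor (subpixel shifting uses mixed-radix FFTs)
  lpf <- function(n) {
    for (p in c(2, 3, 5, 7, 11, 13)) while (n %% p == 0) n <- n / p
    n
  }
  while (half > 8 && lpf(2 * half + 1) > 13) half <- half - 1
  (-half:half) * detector$pitch_iso
}

#' Convert Hounsfield units to linear attenuation
#'
#' `mu = mu_water * (1 + HU/1000)`, clamped at zero. The default water
#' attenuation, 0.00505/mm, is representative of the effective energy of a
#' low-MV imaging beam.
#'
#' @param hu HU value(s).
#' @param mu_water Water linear attenuation (1/mm).
#' @return Linear attenuation in 1/mm, same shape as `hu`.
#' @export
hu_to_attenuation <- function(hu, mu_water = 0.00505) {
  pmax(0, mu_water * (1 + hu / 1000))
}

#' Compute a digitally reconstructed radiograph
#'
#' Ray-traces the volume from the point source to each detector pixel with
#' Siddon's parametric voxel traversal (exact per-voxel chord lengths),
#' giving the radiological path `integral mu dl` per pixel; the stored
#' intensity is `exp(-path)`, so rays that miss the volume read 1.
#'
#' @param volume A [ct_volume()]; its `isocenter` is the machine isocenter.
#' @param geometry A [beam_geometry()] or a control-point row from
#'   [control_points_from_arcs()].
#' @param detector A [detector_spec()].
#' @param mu_water Water attenuation passed to [hu_to_attenuation()].
#' @param aperture Optional aperture (see [aperture()]): restricts ray
#'   tracing to the pixels of the full-field grid covered by the aperture.
#'   The result is pixel-identical to cropping a full-field DRR.
#' @return An object of class `drr_image`: intensity matrix (rows = BEV x,
#'   columns = BEV y), per-pixel BEV coordinates `x_mm`/`y_mm`, pixel
#'   pitch, and the geometry.
#' @export
compute_drr <- function(volume, geometry, detector = detector_spec(),
                        mu_water = 0.00505, aperture = NULL) {
  geometry <- as_beam_geometry(geometry)
  d <- dim(volume$values)
  upper <- volume$origin + (d - 1) * volume$spacing
  iso <- volume$isocenter
  if (any(iso < volume$origin) || any(iso > upper))
    abort("isocenter lies outside the volume")

  coords <- detector_coords(detector)
  if (is.null(aperture)) {
    px <- coords
    py <- coords
  } else {
    ap <- as.list(aperture[1, ])
    px <- coords[coords >= ap$cx_mm - ap$w_mm / 2 - 1e-9 &
                 coords <= ap$cx_mm + ap$w_mm / 2 + 1e-9]
    py <- coords[coords >= ap$cy_mm - ap$h_mm / 2 - 1e-9 &
                 coords <= ap$cy_mm + ap$h_mm / 2 + 1e-9]
    if (!length(px) || !length(py))
      abort("aperture covers no detector pixels")
  }

  basis <- bev_basis(geometry)
  src <- iso + geometry$sad * basis$w
  mu <- hu_to_attenuation(volume$values, mu_water)
  path <- cpp_drr_path(mu, dim(volume$values), volume$spacing, volume$origin,
                       src, iso, basis$u, basis$v, px, py,
                       geometry$sid / geometry$sad)
  structure(list(intensity = exp(-path),
                 x_mm = px, y_mm = py,
                 pitch = detector$pitch_iso,
                 geometry = geometry,
                 detector = detector),
            class = "drr_image")
}

#' @export
print.drr_image <- function(x, ...) {
  cat(sprintf(
    "<drr_image> %d x %d px, pitch %.3f mm (isocenter plane), gantry %.1f couch %.1f\n",
    length(x$x_mm), length(x$y_mm), x$pitch, x$geometry$gantry,
    x$geometry$couch))
  invisible(x)
}

#' @export
dim.drr_image <- function(x) dim(x$intensity)

#' Subpixel image translation by Fourier phase shift
#'
#' Translates image content by `(dx, dy)` pixels using the Fourier shift
#' theorem (circular boundary). Used to construct ground-truth shifted
#' images whose interpolation model is independent of the registration's
#' resampler.
#'
#' @param img Numeric matrix.
#' @param dx,dy Content displacement in pixels (row and column directions).
#' @return Matrix of the same shape.
#' @export
fourier_shift <- function(img, dx, dy) {
  n1 <- nrow(img)
  n2 <- ncol(img)
  f1 <- c(0:floor(n1 / 2), -(ceiling(n1 / 2) - 1):-1)[1:n1] / n1
  f2 <- c(0:floor(n2 / 2), -(ceiling(n2 / 2) - 1):-1)[1:n2] / n2
  phase <- exp(-2i * pi * outer(f1 * dx, f2 * dy, `+`))
  Re(fft(fft(img) * phase, inverse = TRUE)) / length(img)
}

# Windowed Fourier translation: shifts only a padded neighborhood of the
# pixel window [rows, cols] and returns the window, so circular wrap stays
# in the discarded pad. Pad is clamped at the image border.
shift_window <- function(img, rows, cols, dx_px, dy_px, pad = NULL) {
  if (is.null(pad)) pad <- ceiling(max(abs(c(dx_px, dy_px)))) + 6L
  r0 <- max(1L, min(rows) - pad)
  r1 <- min(nrow(img), max(rows) + pad)
  c0 <- max(1L, min(cols) - pad)
  c1 <- min(ncol(img), max(cols) + pad)
  sub <- fourier_shift(img[r0:r1, c0:c1, drop = FALSE], dx_px, dy_px)
  sub[rows - r0 + 1L, cols - c0 + 1L, drop = FALSE]
}

# Pixel-index window of an aperture on a DRR grid (pixel centers inside
# the rectangle).
aperture_window <- function(drr, aperture) {
  ap <- as.list(aperture[1, ])
  rows <- which(drr$x_mm >= ap$cx_mm - ap$w_mm / 2 - 1e-9 &
                drr$x_mm <= ap$cx_mm + ap$w_mm / 2 + 1e-9)
  cols <- which(drr$y_mm >= ap$cy_mm - ap$h_mm / 2 - 1e-9 &
                drr$y_mm <= ap$cy_mm + ap$h_mm / 2 + 1e-9)
  if (!length(rows) || !length(cols))
    abort("aperture lies outside the image")
  list(rows = rows, cols = cols)
}

#' Crop a DRR to an aperture
#'
#' @param drr A [drr_image()].
#' @param aperture A one-row aperture tibble (see [aperture()]).
#' @return A `drr_image` restricted to the covered pixels.
#' @export
crop_aperture <- function(drr, aperture) {
  win <- aperture_window(drr, aperture)
  drr$intensity <- drr$intensity[win$rows, win$cols, drop = FALSE]
  drr$x_mm <- drr$x_mm[win$rows]
  drr$y_mm <- drr$y_mm[win$cols]
  drr
}
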