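#' Rectangular imaging aperture
#'
#' An axis-aligned beam's-eye-view rectangle at the isocenter plane,
#' positioned relative to the principal point (beam central axis).
#'
#' @param cx_mm,cy_mm Center (mm, BEV x/y).
#' @param w_mm,h_mm Width and height (mm); must be positive.
#' @return A one-row tibble with an `area_cm2` column.
#' @export
aperture <- function(cx_mm, cy_mm, w_mm, h_mm) {
  if (any(w_mm <= 0) || any(h_mm <= 0))
    abort("aperture width and height must be positive")
  tibble(cx_mm = cx_mm, cy_mm = cy_mm, w_mm = w_mm, h_mm = h_mm,
         area_cm2 = w_mm * h_mm / 100)
}

#' Randomly sample candidate apertures
#'
#' Draws `n` rectangles with area log-uniform over `area_range`, aspect
#' ratio (width/height) uniform over `aspect_range`, and center uniform
#' over the positions at which the rectangle stays entirely inside the
#' square open field. Deterministic for a fixed seed.
#'
#' @param n Number of apertures.
#' @param area_range Area bounds in cm^2 (default the 0.375-37.5 search
#'   range).
#' @param aspect_range Aspect-ratio bounds.
#' @param field_mm Open-field edge length (mm) the apertures must fit in.
#' @param seed Integer seed.
#' @return A tibble of apertures with a `.draw` order column.
#' @export
sample_apertures <- function(n, area_range = c(0.375, 37.5),
                             aspect_range = c(1 / 3, 3),
                             field_mm = 220, seed = 1L) {
  if (n < 1) abort("`n` must be at least 1")
  area_mm2 <- sort(area_range) * 100
  if (sqrt(area_mm2[2]) > field_mm)
    abort("area range infeasible for the field size")
  withr::with_seed(as.integer(seed), {
    area <- exp(runif(n, log(area_mm2[1]), log(area_mm2[2])))
    # clamp the aspect interval per draw so both sides fit in the field
    lo <- pmax(aspect_range[1], area / field_mm^2)
    hi <- pmin(aspect_range[2], field_mm^2 / area)
    aspect <- runif(n, lo, hi)
    w <- sqrt(area * aspect)
    h <- sqrt(area / aspect)
    cx <- runif(n, -(field_mm - w) / 2, (field_mm - w) / 2)
    cy <- runif(n, -(field_mm - h) / 2, (field_mm - h) / 2)
  })
  out <- aperture(cx, cy, w, h)
  out$.draw <- seq_len(n)
  out
}

#' Grid of simulated shifts
#'
#' A uniform `n x n` grid of in-plane anatomy shifts spanning
#' `+/- half_width` mm per axis, used both to score candidate apertures and
#' to measure registration error. With even `n` the grid contains no
#' duplicate zero shift.
#'
#' @param half_width Half-width in mm.
#' @param n Grid points per axis.
#' @return A tibble with columns `dx_mm`, `dy_mm`.
#' @export
shift_grid <- function(half_width = 2, n = 10) {
  s <- seq(-half_width, half_width, length.out = n)
  tidyr::expand_grid(dx_mm = s, dy_mm = s)
}

#' Score apertures by simulated-shift registration error
#'
#' For every shift of the grid, the full DRR content is translated by the
#' shift (windowed Fourier resampling), both images are cropped to each
#' aperture, and the crop of the shifted image is registered back to the
#' unshifted crop. Per-axis errors (detected - applied, mm) are pooled over
#' the grid into summary statistics; the ranking scalar is
#' `mean(|error|) + SD(error)`. An aperture for which any registration
#' fails (e.g. a crop with no contrast) is marked invalid with an infinite
#' score.
#'
#' One shifted image per grid point is shared by all apertures, so the grid
#' is identical for every aperture of a beam's-eye-view.
#'
#' @param drr A full-field [drr_image()].
#' @param apertures Aperture tibble from [sample_apertures()] (or
#'   [aperture()]).
#' @param shifts Shift grid tibble from [shift_grid()].
#' @param bound Registration search bound (mm); defaults to the largest
#'   applied shift plus 1.5 mm.
#' @param interp Subpixel resampler passed to [register_translation()];
#'   bulk scoring defaults to the fast bilinear mode.
#' @param tol,bins Registration settings (scoring uses a slightly coarser
#'   refinement tolerance than the accuracy-mode default).
#' @param max_samples Pixel budget per MI evaluation (see
#'   [register_translation()]); keeps the cost of scoring thousands of
#'   large crops bounded.
#' @return The aperture tibble with columns `mean_ex`, `mean_ey`, `sd_e`,
#'   `range_x`, `range_y`, `range_e`, `score`, `valid`, `n_shifts`.
#' @export
evaluate_apertures <- function(drr, apertures, shifts = shift_grid(),
                               bound = NULL, interp = "bilinear",
                               tol = 0.02, bins = 50L,
                               max_samples = 1200L) {
  n_ap <- nrow(apertures)
  wins <- purrr::map(seq_len(n_ap), function(a)
    aperture_window(drr, apertures[a, ]))
  fixed <- purrr::map(wins, function(w)
    drr$intensity[w$rows, w$cols, drop = FALSE])
  if (is.null(bound)) bound <- max(abs(c(shifts$dx_mm, shifts$dy_mm))) + 1

  ex <- matrix(NA_real_, nrow(shifts), n_ap)
  ey <- matrix(NA_real_, nrow(shifts), n_ap)
  ok <- matrix(FALSE, nrow(shifts), n_ap)
  for (s in seq_len(nrow(shifts))) {
    dx_px <- shifts$dx_mm[s] / drr$pitch
    dy_px <- shifts$dy_mm[s] / drr$pitch
    shifted <- fourier_shift(drr$intensity, dx_px, dy_px)
    for (a in seq_len(n_ap)) {
      w <- wins[[a]]
      res <- register_translation(fixed[[a]],
                                  shifted[w$rows, w$cols, drop = FALSE],
                                  drr$pitch, bound = bound, tol = tol,
                                  bins = bins, interp = interp,
                                  max_samples = max_samples)
      ok[s, a] <- res$converged
      if (res$converged) {
        ex[s, a] <- res$dx_mm - shifts$dx_mm[s]
        ey[s, a] <- res$dy_mm - shifts$dy_mm[s]
      }
    }
  }

  stats <- purrr::map_dfr(seq_len(n_ap), function(a) {
    if (!all(ok[, a])) {
      return(tibble(mean_ex = NA_real_, mean_ey = NA_real_, sd_e = NA_real_,
                    range_x = NA_real_, range_y = NA_real_,
                    range_e = NA_real_, score = Inf, valid = FALSE,
                    n_shifts = nrow(shifts)))
    }
    pooled <- c(ex[, a], ey[, a])
    rx <- diff(quantile(abs(ex[, a]), c(0.05, 0.95), names = FALSE))
    ry <- diff(quantile(abs(ey[, a]), c(0.05, 0.95), names = FALSE))
    tibble(mean_ex = mean(ex[, a]), mean_ey = mean(ey[, a]),
           sd_e = sd(pooled), range_x = rx, range_y = ry,
           range_e = max(rx, ry),
           score = mean(abs(pooled)) + sd(pooled),
           valid = TRUE, n_shifts = nrow(shifts))
  })
  dplyr::bind_cols(apertures, stats)
}

#' @rdname evaluate_apertures
#' @param aperture_row A single aperture (one-row tibble).
#' @export
evaluate_aperture <- function(drr, aperture_row, shifts = shift_grid(), ...) {
  evaluate_apertures(drr, aperture_row[1, , drop = FALSE], shifts, ...)
}

#' Select the best-scoring apertures
#'
#' Keeps the `floor(n * fraction)` apertures with the lowest ranking score.
#' Ties are broken by smaller area, then by sampling order.
#'
#' @param scored Output of [evaluate_apertures()].
#' @param fraction Fraction to keep (default the top 10%).
#' @return The selected subset, ordered by score.
#' @export
select_top <- function(scored, fraction = 0.1) {
  if (!any(scored$valid)) abort("no valid apertures to select from")
  k <- floor(nrow(scored) * fraction)
  if (k < 1) abort("fraction selects no apertures")
  ord <- scored
  if (is.null(ord$.draw)) ord$.draw <- seq_len(nrow(ord))
  ord <- arrange(ord, .data$score, .data$area_cm2, .data$.draw)
  head(ord, k)
}

#' Overlay selected apertures into a topographic map
#'
#' Per-pixel count of how many apertures cover each pixel of the DRR grid:
#' each aperture's binary mask increments the pixels it covers.
#'
#' @param apertures Aperture tibble (typically from [select_top()]).
#' @param drr The [drr_image()] defining the pixel grid.
#' @return An object of class `topographic_map`.
#' @export
build_topographic_map <- function(apertures, drr) {
  if (!nrow(apertures)) abort("`apertures` must be non-empty")
  counts <- matrix(0L, nrow(drr$intensity), ncol(drr$intensity))
  for (a in seq_len(nrow(apertures))) {
    w <- aperture_window(drr, apertures[a, ])
    counts[w$rows, w$cols] <- counts[w$rows, w$cols] + 1L
  }
  structure(list(counts = counts, x_mm = drr$x_mm, y_mm = drr$y_mm,
                 pitch = drr$pitch, n_apertures = nrow(apertures)),
            class = "topographic_map")
}

#' @export
print.topographic_map <- function(x, ...) {
  cat(sprintf("<topographic_map> %d x %d px, %d apertures, max count %d\n",
              nrow(x$counts), ncol(x$counts), x$n_apertures, max(x$counts)))
  invisible(x)
}

#' Extract a threshold aperture from a topographic map
#'
#' The imaging aperture at a threshold level: the axis-aligned bounding
#' rectangle (BEV mm) of the largest connected component of pixels whose
#' overlay count reaches `level`% of the map maximum. Higher levels give
#' smaller (nested) rectangles.
#'
#' @param map A [build_topographic_map()] result.
#' @param level Threshold in percent of the map maximum, in (0, 100].
#' @return A one-row aperture tibble with a `level` column.
#' @export
extract_threshold_aperture <- function(map, level = 60) {
  if (level <= 0 || level > 100) abort("`level` must be in (0, 100]")
  mx <- max(map$counts)
  if (mx <= 0) abort("topographic map is empty")
  mask <- map$counts >= level / 100 * mx - 1e-9
  if (!any(mask)) abort("empty superlevel set at this threshold")
  labels <- EBImage::bwlabel(mask)
  largest <- which.max(tabulate(labels[labels > 0]))
  sel <- which(labels == largest, arr.ind = TRUE)
  rx <- range(map$x_mm[sel[, 1]])
  ry <- range(map$y_mm[sel[, 2]])
  out <- aperture(mean(rx), mean(ry),
                  diff(rx) + map$pitch, diff(ry) + map$pitch)
  out$level <- level
  out
}

#' Scale an aperture to a different skull volume
#'
#' Applies the cube root of the volumetric ratio between the target anatomy
#' and the reference anatomy the aperture was derived on, scaling the
#' width, height, and the center's position vector relative to the
#' principal point.
#'
#' @param ap Aperture tibble.
#' @param reference_volume,target_volume Skull volumes (cm^3).
#' @return The scaled aperture tibble.
#' @export
scale_aperture <- function(ap, reference_volume, target_volume) {
  if (reference_volume <= 0 || target_volume <= 0)
    abort("volumes must be positive")
  s <- (target_volume / reference_volume)^(1 / 3)
  aperture(ap$cx_mm * s, ap$cy_mm * s, ap$w_mm * s, ap$h_mm * s)
}

#' Classify apertures as good, bad, or neither
#'
#' A good aperture keeps the registration-error range (95th - 5th
#' percentile of |error|) below `range_good` and the mean signed error
#' within `+/-mean_good` on both axes; a bad aperture has an error range
#' above `range_bad`. Labels are only assigned to apertures of at least
#' `min_area_cm2`; smaller apertures — and invalid ones, whose errors are
#' undefined — are labelled `"neither"`.
#'
#' @param scored Output of [evaluate_apertures()].
#' @param range_good,mean_good,range_bad Thresholds in mm.
#' @param min_area_cm2 Minimum area for good/bad labelling.
#' @return `scored` with a `label` column.
#' @export
classify_aperture <- function(scored, range_good = 0.1, mean_good = 0.1,
                              range_bad = 1, min_area_cm2 = 4) {
  mutate(scored, label = dplyr::case_when(
    .data$area_cm2 < min_area_cm2 ~ "neither",
    !.data$valid ~ "neither",
    .data$range_x < range_good & .data$range_y < range_good &
      abs(.data$mean_ex) < mean_good & abs(.data$mean_ey) < mean_good ~ "good",
    .data$range_e > range_bad ~ "bad",
    TRUE ~ "neither"
  ))
}
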