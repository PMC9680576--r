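#' Magnitude-weighted gradient polar histogram
#'
#' Characterizes the directional content of the anatomy inside an
#' aperture: the 2D image gradient of the crop is computed with central
#' differences, and each interior pixel contributes its gradient magnitude
#' to one of eight 45-degree direction bins (bin 1 covers \[0, 45) degrees,
#' direction `atan2(gy, gx)` mapped to \[0, 360)). Zero-gradient pixels
#' contribute nothing; a uniform crop yields an all-zero histogram.
#'
#' @param drr A [drr_image()] (or plain matrix with `pitch` ignored).
#' @param aperture One-row aperture tibble; the crop must be at least
#'   8 x 8 pixels.
#' @return An object of class `polar_histogram`: `counts` (8 weights) and
#'   `total` (sum of gradient magnitudes).
#' @export
gradient_polar_histogram <- function(drr, aperture = NULL) {
  crop <- if (inherits(drr, "drr_image")) {
    if (is.null(aperture)) drr$intensity
    else {
      w <- aperture_window(drr, aperture)
      drr$intensity[w$rows, w$cols, drop = FALSE]
    }
  } else drr
  if (nrow(crop) < 8 || ncol(crop) < 8)
    abort("aperture crop smaller than 8 x 8 pixels")
  nx <- nrow(crop)
  ny <- ncol(crop)
  gx <- (crop[3:nx, 2:(ny - 1)] - crop[1:(nx - 2), 2:(ny - 1)]) / 2
  gy <- (crop[2:(nx - 1), 3:ny] - crop[2:(nx - 1), 1:(ny - 2)]) / 2
  mag <- sqrt(gx^2 + gy^2)
  keep <- mag > 0
  ang <- (atan2(gy[keep], gx[keep]) * 180 / pi) %% 360
  bin <- pmin(floor(ang / 45) + 1L, 8L)
  counts <- vapply(1:8, function(b) sum(mag[keep][bin == b]), numeric(1))
  structure(list(counts = counts, total = sum(mag)),
            class = "polar_histogram")
}

#' @export
print.polar_histogram <- function(x, ...) {
  cat("<polar_histogram> bin weights (45-degree bins from 0):\n")
  print(signif(x$counts, 4))
  invisible(x)
}

#' Normalized variance of a polar histogram
#'
#' Population variance of the sum-normalized bin weights (the histogram as
#' proportions): a dimensionless, intensity-scale-invariant measure of
#' directional concentration. It is 0 when gradient weight is spread
#' evenly over all eight directions and reaches its maximum, 7/64
#' (~0.109), when all weight lies in a single 45-degree bin — heavily
#' unidirectional content that can only constrain motion along one axis.
#' An all-zero histogram carries no directional information and returns
#' `Inf`.
#'
#' @param hist A [gradient_polar_histogram()] result, or a numeric vector
#'   of 8 bin weights.
#' @return Dimensionless normalized variance in `[0, 7/64]`.
#' @export
polar_variance <- function(hist) {
  counts <- if (inherits(hist, "polar_histogram")) hist$counts else hist
  s <- sum(counts)
  if (s <= 0) return(Inf)
  p <- counts / s
  mean((p - mean(p))^2)
}

#' Mean MI drop-off of a shift surface
#'
#' Condenses an MI shift surface to the mean difference between the
#' central (zero-shift) element and all other elements — the average MI
#' gradient under shifts. Larger values mean a sharper, better-conditioned
#' registration objective. Invariant to adding a constant to the surface.
#'
#' @param surface A [mi_shift_surface()] result.
#' @return Mean MI difference in nats (non-negative for valid surfaces).
#' @export
mi_mean_difference <- function(surface) {
  v <- surface$values
  ci <- (nrow(v) + 1) / 2
  cj <- (ncol(v) + 1) / 2
  central <- v[ci, cj]
  mean(central - v[-((cj - 1) * nrow(v) + ci)])
}

#' Aperture information features across gantry angles
#'
#' Assembles the good/bad feature analysis: at each requested gantry angle
#' apertures are sampled (restricted to `area_range`), scored on the shift
#' grid, classified, and — for up to `quota_good`/`quota_bad` of each class
#' — reduced to the two information metrics: normalized polar-histogram
#' variance and MI mean difference. Sampling continues in batches until the
#' quotas are met or `max_batches` is exhausted; a shortfall produces a
#' warning and a partial table.
#'
#' @param volume A BB-free [ct_volume()] (BB removed automatically if its
#'   metadata is present).
#' @param gantry Gantry angles (degrees) to analyze.
#' @param couch Couch angle (degrees).
#' @param quota_good,quota_bad Apertures per class per angle.
#' @param batch Apertures sampled per batch.
#' @param max_batches Sampling budget per angle.
#' @param area_range Area bounds in cm^2 (labels need >= 4 cm^2).
#' @param detector,shifts,seed,mu_water,interp Search settings as in
#'   [build_imaging_plan()].
#' @param surface_half_width,surface_step MI surface grid (defaults give
#'   the 121-element surface).
#' @return A tibble with columns `gantry`, `couch`, `area_cm2`,
#'   `polar_var_norm`, `polar_total`, `mi_mean_diff`, `label`.
#' @export
aperture_features <- function(volume, gantry = seq(0, 315, by = 45),
                              couch = 0, quota_good = 30, quota_bad = 30,
                              batch = 150, max_batches = 8,
                              area_range = c(4, 37.5),
                              detector = detector_spec(),
                              shifts = shift_grid(), seed = 1L,
                              mu_water = 0.00505, interp = "bilinear",
                              surface_half_width = 2, surface_step = 0.4) {
  if (!is.null(volume$bb)) volume <- remove_bb_region(volume)
  out <- purrr::map(seq_along(gantry), function(gi) {
    geom <- beam_geometry(gantry[gi], couch)
    drr <- compute_drr(volume, geom, detector, mu_water)
    got <- NULL
    for (b in seq_len(max_batches)) {
      cand <- sample_apertures(batch, area_range,
                               field_mm = detector$field_mm,
                               seed = as.integer(seed) + 1000L * gi + b)
      scored <- classify_aperture(
        evaluate_apertures(drr, cand, shifts, interp = interp))
      got <- bind_rows(got, filter(scored, .data$label %in% c("good", "bad")))
      if (sum(got$label == "good") >= quota_good &&
          sum(got$label == "bad") >= quota_bad) break
    }
    n_good <- sum(got$label == "good")
    n_bad <- sum(got$label == "bad")
    if (n_good < quota_good || n_bad < quota_bad)
      warn(sprintf(
        "gantry %g: quota shortfall (%d good, %d bad); partial table",
        gantry[gi], n_good, n_bad))
    keep <- bind_rows(head(filter(got, .data$label == "good"), quota_good),
                      head(filter(got, .data$label == "bad"), quota_bad))
    if (!nrow(keep)) return(NULL)
    feats <- purrr::map_dfr(seq_len(nrow(keep)), function(a) {
      ap <- keep[a, ]
      ph <- gradient_polar_histogram(drr, ap)
      surf <- mi_shift_surface(drr, ap, surface_half_width, surface_step)
      tibble(gantry = gantry[gi], couch = couch, area_cm2 = ap$area_cm2,
             polar_var_norm = polar_variance(ph), polar_total = ph$total,
             mi_mean_diff = mi_mean_difference(surf), label = ap$label)
    })
    feats
  })
  bind_rows(out)
}
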