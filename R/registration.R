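#' Normalize and histogram-equalize an image
#'
#' Standard preprocessing before anatomy registration: intensities are
#' min-max normalized to `[0, 1]` and then histogram-equalized with a
#' 256-level CDF mapping. A (near-)constant image is returned unchanged
#' with a warning, since equalization is undefined without contrast.
#'
#' @param image Numeric matrix.
#' @param levels Number of equalization levels.
#' @return Matrix with values in `[0, 1]`.
#' @export
preprocess_image <- function(image, levels = 256L) {
  rng <- range(image)
  if (!(rng[2] > rng[1])) {
    warn("image has fewer than 2 distinct values; returned unchanged")
    return(image)
  }
  norm <- (image - rng[1]) / (rng[2] - rng[1])
  idx <- pmin(as.integer(norm * levels) + 1L, levels)
  cdf <- cumsum(tabulate(idx, nbins = levels)) / length(idx)
  cdf0 <- cdf[min(idx)]
  eq <- (cdf[idx] - cdf0) / (1 - cdf0 + 1e-12)
  out <- matrix(eq, nrow(image), ncol(image))
  rng2 <- range(out)
  (out - rng2[1]) / (rng2[2] - rng2[1])
}

#' Mutual information between two images
#'
#' Joint-histogram mutual information in nats:
#' `MI = sum p(i,j) log( p(i,j) / (p(i) p(j)) )` over an equal-width
#' `bins x bins` joint intensity histogram, each image binned over its own
#' range. Always non-negative; `mutual_information(a, a)` equals the
#' marginal entropy of `a` at the same binning.
#'
#' @param a,b Numeric matrices of equal shape.
#' @param bins Number of histogram bins per image (>= 2).
#' @return MI in nats.
#' @export
mutual_information <- function(a, b, bins = 50L) {
  if (!all(dim(a) == dim(b))) abort("images must share dimensions")
  if (bins < 2) abort("`bins` must be at least 2")
  cpp_mi_plain(a, b, as.integer(bins))
}

#' Translation-only registration by mutual information
#'
#' Finds the in-plane translation of `moving` relative to `fixed` that
#' maximizes their mutual information: a deterministic coarse integer-pixel
#' grid search followed by step-halving local refinement with subpixel
#' resampling of the moving image. The joint histogram uses linear
#' spreading of both intensities across neighboring bins so the MI varies
#' smoothly between pixels. If `moving` is `fixed` with its content
#' displaced by `+s`, the detected shift is `+s` (reported in mm at the
#' isocenter plane).
#'
#' @param fixed,moving Numeric matrices of equal shape (already
#'   preprocessed as appropriate for the source of the images).
#' @param pitch Pixel pitch at the isocenter plane (mm).
#' @param bound Search bound on each axis (mm).
#' @param tol Refinement resolution (mm); refinement continues until the
#'   search step falls below it.
#' @param bins Joint-histogram bins.
#' @param interp Subpixel model: `"cubic"` (default; interpolating cubic
#'   B-splines evaluated on a half-pixel supersampled grid for the final
#'   refinement stages, which cancels the grid-locking bias of sampled
#'   joint-histogram MI) or `"bilinear"` (faster, used in bulk aperture
#'   scoring).
#' @param min_overlap Minimum overlapping samples for a shift to be scored.
#' @param max_samples If set, images larger than this are subsampled to at
#'   most this many pixels (equal row/column stride) during coarse and
#'   bilinear evaluations — the bulk-scoring speed knob.
#' @return A one-row tibble: `dx_mm`, `dy_mm`, `mi`, `iterations`,
#'   `converged`. A degenerate pair (no contrast, or no admissible overlap)
#'   returns `converged = FALSE` with `NA` shifts.
#' @export
register_translation <- function(fixed, moving, pitch, bound = 3,
                                 tol = 0.01, bins = 50L,
                                 interp = c("cubic", "bilinear"),
                                 min_overlap = 32L, max_samples = NULL) {
  if (!all(dim(fixed) == dim(moving))) abort("images must share dimensions")
  if (bound <= 0) abort("`bound` must be positive")
  interp <- match.arg(interp)
  stride <- 1L
  if (!is.null(max_samples) && length(fixed) > max_samples)
    stride <- as.integer(ceiling(sqrt(length(fixed) / max_samples)))
  res <- cpp_register_translation(fixed, moving, pitch, bound, tol,
                                  as.integer(bins),
                                  if (interp == "cubic") 2L else 1L,
                                  as.integer(min_overlap), stride)
  tibble(dx_mm = res$dx_mm, dy_mm = res$dy_mm, mi = res$mi,
         iterations = res$iterations, converged = res$converged)
}

#' Mutual-information shift surface of an aperture
#'
#' Evaluates MI between the aperture crop of an image and the identically
#' cropped copy of the image with its content translated over a square grid
#' of shifts. The default +/-2 mm at 0.4 mm steps gives the 11 x 11 grid of
#' 121 MI values; the central (zero-shift) element is the crop's marginal
#' entropy and is always the maximum. Ground-truth shifts use windowed
#' Fourier translation of the surrounding image, so crop edges see real
#' anatomy rather than padding.
#'
#' @param drr A [drr_image()] (full field).
#' @param aperture One-row aperture tibble within the image.
#' @param half_width Grid half-width (mm).
#' @param step Grid step (mm); `2 * half_width / step` must be even so the
#'   edge length is odd and a central element exists.
#' @param bins Histogram bins for [mutual_information()].
#' @return An object of class `mi_surface`: the MI matrix (`values`), the
#'   shift coordinates (`shift_x`, `shift_y`, mm), and grid metadata.
#' @export
mi_shift_surface <- function(drr, aperture, half_width = 2, step = 0.4,
                             bins = 50L) {
  n_side <- round(2 * half_width / step) + 1L
  if (n_side %% 2L == 0L)
    abort("shift grid must have an odd edge length (central element)")
  win <- aperture_window(drr, aperture)
  if (length(win$rows) < 8L || length(win$cols) < 8L)
    abort("aperture crop smaller than 8 x 8 pixels")
  crop <- drr$intensity[win$rows, win$cols, drop = FALSE]
  shifts <- seq(-half_width, half_width, length.out = n_side)
  vals <- matrix(NA_real_, n_side, n_side)
  pad <- ceiling(half_width / drr$pitch) + 6L
  for (j in seq_len(n_side)) {
    for (i in seq_len(n_side)) {
      if (shifts[i] == 0 && shifts[j] == 0) {
        vals[i, j] <- mutual_information(crop, crop, bins)
      } else {
        shifted <- shift_window(drr$intensity, win$rows, win$cols,
                                shifts[i] / drr$pitch, shifts[j] / drr$pitch,
                                pad = pad)
        vals[i, j] <- mutual_information(crop, shifted, bins)
      }
    }
  }
  structure(list(values = vals, shift_x = shifts, shift_y = shifts,
                 step = step, half_width = half_width),
            class = "mi_surface")
}

#' @export
print.mi_surface <- function(x, ...) {
  cat(sprintf("<mi_surface> %d x %d shifts, step %.2f mm, central MI %.3f nats\n",
              nrow(x$values), ncol(x$values), x$step,
              x$values[(nrow(x$values) + 1) / 2, (ncol(x$values) + 1) / 2]))
  invisible(x)
}

#' Detect the BB fiducial in a beam's-eye-view image
#'
#' Locates a small high-attenuation disk: the image is converted to
#' attenuation (negative log intensity), background anatomy larger than
#' the fiducial is removed with a morphological top-hat, and the residue
#' is convolved with a disk kernel matched to the BB size. Candidate
#' response peaks are vetted in turn: a peak is accepted only if the
#' connected component around it (thresholded relative to its own local
#' maximum) has an equivalent diameter no larger than
#' `1.5 * bb_diameter` plus one pixel; larger structures are zeroed and
#' the search continues. The detected center is the attenuation-weighted
#' centroid around the accepted peak, in mm relative to the principal
#' point (BEV x/y).
#'
#' @param image A [drr_image()] or a plain intensity matrix.
#' @param bb_diameter Physical BB diameter (mm).
#' @param pitch Pixel pitch at the isocenter plane (mm); taken from the
#'   image when it is a `drr_image`.
#' @param min_response Minimum mean in-disk top-hat attenuation for a
#'   detection to be accepted; below it the function errors.
#' @return A one-row tibble: `x_mm`, `y_mm`, `response`.
#' @export
detect_bb <- function(image, bb_diameter = 2, pitch = NULL,
                      min_response = 0.005) {
  if (inherits(image, "drr_image")) {
    x_mm <- image$x_mm
    y_mm <- image$y_mm
    pitch <- image$pitch
    img <- image$intensity
  } else {
    if (is.null(pitch)) abort("`pitch` is required for a plain matrix")
    img <- image
    x_mm <- (seq_len(nrow(img)) - (nrow(img) + 1) / 2) * pitch
    y_mm <- (seq_len(ncol(img)) - (ncol(img) + 1) / 2) * pitch
  }
  att <- -log(pmax(img, 1e-12))
  bb_px <- max(bb_diameter / pitch, 1)

  # suppress structures larger than the BB
  brush_size <- 2 * ceiling(bb_px) + 3L
  if (brush_size %% 2L == 0L) brush_size <- brush_size + 1L
  brush <- EBImage::makeBrush(brush_size, shape = "disc")
  tophat <- att - EBImage::opening(att, brush)
  tophat[tophat < 0] <- 0

  # disk-matched response
  kernel_size <- 2 * ceiling(bb_px / 2) + 1L
  kernel <- EBImage::makeBrush(kernel_size, shape = "disc")
  kernel <- kernel / sum(kernel)
  resp <- EBImage::filter2(tophat, kernel)

  # candidate peaks are vetted one by one: a candidate is accepted only if
  # the connected component around it — thresholded relative to its own
  # local peak, so a bright large structure cannot hide behind a global
  # threshold — is no larger than the fiducial (with one pixel of
  # partial-volume allowance). The border band, where the convolution is
  # unreliable, is excluded.
  band <- ceiling(bb_px)
  cand_resp <- matrix(-Inf, nrow(att), ncol(att))
  if (nrow(att) > 2 * band && ncol(att) > 2 * band)
    cand_resp[(band + 1):(nrow(att) - band),
              (band + 1):(ncol(att) - band)] <-
      resp[(band + 1):(nrow(att) - band), (band + 1):(ncol(att) - band)]
  size_limit <- 1.5 * bb_diameter + pitch
  peak <- NULL
  for (k in 1:6) {
    pk <- which(cand_resp == max(cand_resp), arr.ind = TRUE)[1, ]
    if (!is.finite(cand_resp[pk[1], pk[2]]) ||
        cand_resp[pk[1], pk[2]] < min_response) break
    ri <- max(1L, pk[1] - band):min(nrow(att), pk[1] + band)
    ci <- max(1L, pk[2] - band):min(ncol(att), pk[2] + band)
    local_peak <- max(tophat[ri, ci])
    mask <- tophat > 0.4 * local_peak
    labels <- EBImage::bwlabel(mask)
    lab_win <- labels[ri, ci]
    lab <- lab_win[which.max(tophat[ri, ci] * (lab_win > 0))]
    if (lab > 0) {
      eq_diam <- 2 * sqrt(sum(labels == lab) / pi) * pitch
      if (eq_diam <= size_limit) {
        peak <- pk
        break
      }
      # too large: suppress the whole structure and look again
      sel <- which(labels == lab, arr.ind = TRUE)
      rr <- max(1L, min(sel[, 1]) - band):min(nrow(att), max(sel[, 1]) + band)
      cc <- max(1L, min(sel[, 2]) - band):min(ncol(att), max(sel[, 2]) + band)
      cand_resp[rr, cc] <- -Inf
    } else {
      cand_resp[ri, ci] <- -Inf
    }
  }
  if (is.null(peak))
    abort(sprintf(
      "BB detection failed: no disk-like response above threshold %.4f",
      min_response))

  # subpixel centroid in a window around the peak
  r <- ceiling(bb_px) + 1L
  ri <- max(1L, peak[1] - r):min(nrow(att), peak[1] + r)
  ci <- max(1L, peak[2] - r):min(ncol(att), peak[2] + r)
  wts <- tophat[ri, ci, drop = FALSE]
  if (sum(wts) <= 0) wts <- wts + 1
  cx <- sum(outer(x_mm[ri], rep(1, length(ci))) * wts) / sum(wts)
  cy <- sum(outer(rep(1, length(ri)), y_mm[ci]) * wts) / sum(wts)
  tibble(x_mm = cx, y_mm = cy, response = resp[peak[1], peak[2]])
}
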