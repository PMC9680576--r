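#' Specification of the digital skull phantom
#'
#' Parameters of the synthetic cranial phantom: an ellipsoidal bony shell
#' filled with soft-tissue-equivalent material, a small high-Z ball-bearing
#' (BB) fiducial at isocenter, air-filled sinus-like cavities in the
#' anterior-inferior quadrant, and seeded random surface bumps so that no
#' beam's-eye-view is rotationally degenerate.
#'
#' Default HU values follow the physical phantom the method was developed
#' on: a printed shell of roughly 400 HU (low end of cranial bone) and a
#' gelatin fill of 36.1 HU. The BB is given 3000 HU, a metal surrogate high
#' enough to dominate any convolution response. Spacing defaults to
#' 0.625 mm isotropic, matching a high-resolution head CT; desk-scale runs
#' typically use 1 mm.
#'
#' @param semi_axes Outer shell semi-axes (mm), room axes
#'   (lateral, longitudinal, vertical). The default approximates an adult
#'   cranium positioned supine.
#' @param shell_thickness Shell thickness (mm); must be smaller than the
#'   smallest semi-axis.
#' @param skull_hu,fill_hu,bb_hu HU of the shell, interior fill, and BB.
#' @param bb_diameter BB diameter in mm; must be at least twice the
#'   smallest voxel spacing so the fiducial is resolved.
#' @param n_cavities Number of sinus-like air cavities.
#' @param cavity_size Range (mm) of cavity semi-axes.
#' @param n_bumps Number of random bony surface bumps.
#' @param bump_size Range (mm) of bump radii.
#' @param spacing Isotropic voxel spacing (mm), or a length-3 vector.
#' @param margin Air margin (mm) between the shell and the volume boundary.
#' @param noise_sd Standard deviation of additive Gaussian HU noise
#'   (0 disables; the default phantom is noise-free).
#' @param seed Integer seed controlling bumps, cavities and noise.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(semi_axes = c(65, 82, 72),
                         shell_thickness = 6,
                         skull_hu = 400, fill_hu = 36.1,
                         bb_hu = 3000, bb_diameter = 2,
                         n_cavities = 3, cavity_size = c(4, 9),
                         n_bumps = 12, bump_size = c(5, 12),
                         spacing = 0.625, margin = 14,
                         noise_sd = 0, seed = 1L) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spec <- structure(
    list(semi_axes = as.numeric(semi_axes),
         shell_thickness = shell_thickness,
         skull_hu = skull_hu, fill_hu = fill_hu,
         bb_hu = bb_hu, bb_diameter = bb_diameter,
         n_cavities = n_cavities, cavity_size = as.numeric(cavity_size),
         n_bumps = n_bumps, bump_size = as.numeric(bump_size),
         spacing = as.numeric(spacing), margin = margin,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (spec$shell_thickness >= min(spec$semi_axes))
    abort(paste("invalid phantom spec: shell thickness must be smaller",
                "than the smallest semi-axis"))
  if (spec$bb_diameter < 2 * min(spec$spacing))
    abort(paste("invalid phantom spec: bb diameter must be at least twice",
                "the smallest voxel spacing"))
  if (any(spec$spacing <= 0))
    abort("invalid phantom spec: spacing must be strictly positive")
  invisible(spec)
}

#' Generate the digital skull phantom
#'
#' Builds a [ct_volume()] realising a [phantom_spec()]: air (-1000 HU)
#' outside an ellipsoidal high-HU shell, soft-tissue fill inside, a
#' spherical BB centered exactly at isocenter (the room origin), air
#' cavities, and seeded bony surface bumps. Voxel counts are odd on every
#' axis so one voxel center coincides with the isocenter. Generation is
#' deterministic for a fixed seed.
#'
#' @param spec A [phantom_spec()].
#' @return A [ct_volume()] carrying BB metadata.
#' @export
generate_skull_phantom <- function(spec = phantom_spec()) {
  validate_phantom_spec(spec)
  a <- spec$semi_axes
  sp <- spec$spacing
  half_n <- floor((a + spec$margin) / sp)
  n <- 2L * half_n + 1L
  origin <- -half_n * sp
  x <- origin[1] + (seq_len(n[1]) - 1) * sp[1]
  y <- origin[2] + (seq_len(n[2]) - 1) * sp[2]
  z <- origin[3] + (seq_len(n[3]) - 1) * sp[3]

  # squared normalized radius fields for outer and inner ellipsoids
  ai <- a - spec$shell_thickness
  qsum <- function(axes) {
    q <- outer((x / axes[1])^2, (y / axes[2])^2, `+`)
    outer(q, (z / axes[3])^2, `+`)
  }
  q_out <- qsum(a)
  q_in <- qsum(ai)

  vol <- array(-1000, dim = n)
  vol[q_out <= 1] <- spec$skull_hu
  vol[q_in <= 1] <- spec$fill_hu
  rm(q_out)

  withr::with_seed(spec$seed, {
    # bony surface bumps: spheres seated on the outer shell surface,
    # thickening/protruding it; skipped inside the interior fill
    for (b in seq_len(spec$n_bumps)) {
      dir <- rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      surf <- dir / sqrt(sum((dir / a)^2))
      r <- runif(1, spec$bump_size[1], spec$bump_size[2])
      ii <- which(abs(x - surf[1]) <= r)
      jj <- which(abs(y - surf[2]) <= r)
      kk <- which(abs(z - surf[3]) <= r)
      if (!length(ii) || !length(jj) || !length(kk)) next
      dx2 <- (x[ii] - surf[1])^2
      dy2 <- (y[jj] - surf[2])^2
      dz2 <- (z[kk] - surf[3])^2
      d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
      inside <- d2 <= r^2 & q_in[ii, jj, kk, drop = FALSE] > 1
      sub <- vol[ii, jj, kk, drop = FALSE]
      sub[inside] <- spec$skull_hu
      vol[ii, jj, kk] <- sub
    }

    # sinus-like air cavities in the anterior-inferior interior
    for (cv in seq_len(spec$n_cavities)) {
      ctr <- c(runif(1, -0.3, 0.3) * a[1],
               runif(1, -0.6, -0.35) * a[2],
               runif(1, 0.30, 0.55) * a[3])
      ax <- runif(3, spec$cavity_size[1], spec$cavity_size[2])
      ii <- which(abs(x - ctr[1]) <= ax[1])
      jj <- which(abs(y - ctr[2]) <= ax[2])
      kk <- which(abs(z - ctr[3]) <= ax[3])
      if (!length(ii) || !length(jj) || !length(kk)) next
      q <- outer(outer(((x[ii] - ctr[1]) / ax[1])^2,
                       ((y[jj] - ctr[2]) / ax[2])^2, `+`),
                 ((z[kk] - ctr[3]) / ax[3])^2, `+`)
      inside <- q <= 1 & q_in[ii, jj, kk, drop = FALSE] <= 1
      sub <- vol[ii, jj, kk, drop = FALSE]
      sub[inside] <- -1000
      vol[ii, jj, kk] <- sub
    }

    # BB at isocenter
    rbb <- spec$bb_diameter / 2
    ii <- which(abs(x) <= rbb + max(sp))
    jj <- which(abs(y) <= rbb + max(sp))
    kk <- which(abs(z) <= rbb + max(sp))
    d2 <- outer(outer(x[ii]^2, y[jj]^2, `+`), z[kk]^2, `+`)
    sub <- vol[ii, jj, kk, drop = FALSE]
    sub[d2 <= rbb^2] <- spec$bb_hu
    vol[ii, jj, kk] <- sub

    if (spec$noise_sd > 0)
      vol <- vol + array(rnorm(length(vol), 0, spec$noise_sd), dim = n)
  })

  ct_volume(vol, sp, origin, isocenter = c(0, 0, 0),
            bb = list(center = c(0, 0, 0), diameter = spec$bb_diameter))
}

#' Replace the BB neighborhood with fill material
#'
#' Assigns `fill_hu` to all voxels in an axis-aligned, voxel-index-aligned
#' box centered on the BB (isocenter) — the preprocessing applied before
#' reference DRR generation so that anatomy registration never sees the
#' fiducial. The default box is 60 x 60 x 40 voxels.
#'
#' @param volume A [ct_volume()].
#' @param neighborhood Integer length-3 box extent in voxels.
#' @param fill_hu Replacement HU (the measured fill mean).
#' @return The modified [ct_volume()]; BB metadata is dropped.
#' @export
remove_bb_region <- function(volume, neighborhood = c(60, 60, 40),
                             fill_hu = 36.1) {
  neighborhood <- as.integer(neighborhood)
  if (length(neighborhood) != 3L || any(neighborhood <= 0L))
    abort("`neighborhood` must be three positive voxel extents")
  center <- voxel_index(volume, volume$isocenter)
  lo <- center - neighborhood %/% 2L + ifelse(neighborhood %% 2L == 0L, 1L, 0L)
  hi <- lo + neighborhood - 1L
  d <- dim(volume$values)
  if (any(lo < 1L) || any(hi > d)) {
    warn("BB neighborhood clipped to the volume bounds")
    lo <- pmax(lo, 1L)
    hi <- pmin(hi, d)
  }
  volume$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- fill_hu
  volume$bb <- NULL
  volume
}

#' Sample the fill material HU
#'
#' Mean and standard deviation of HU over an axis-aligned voxel box, used to
#' measure the fill value that [remove_bb_region()] substitutes for the BB.
#' The region must not intersect the BB sphere recorded in the volume's
#' metadata.
#'
#' @param volume A [ct_volume()].
#' @param region_center Integer voxel index (1-based) of the box center.
#' @param extent Integer length-3 box extent in voxels (default 20^3).
#' @return A one-row tibble with columns `mean_hu`, `sd_hu`, `n_voxels`.
#' @export
sample_fill_hu <- function(volume, region_center, extent = c(20, 20, 20)) {
  extent <- as.integer(extent)
  region_center <- as.integer(region_center)
  lo <- region_center - extent %/% 2L + ifelse(extent %% 2L == 0L, 1L, 0L)
  hi <- lo + extent - 1L
  d <- dim(volume$values)
  if (any(lo < 1L) || any(hi > d))
    abort("sampling region extends outside the volume")
  if (!is.null(volume$bb)) {
    lo_mm <- volume$origin + (lo - 1) * volume$spacing - volume$spacing / 2
    hi_mm <- volume$origin + (hi - 1) * volume$spacing + volume$spacing / 2
    nearest <- pmin(pmax(volume$bb$center, lo_mm), hi_mm)
    gap <- sqrt(sum((nearest - volume$bb$center)^2))
    if (gap <= volume$bb$diameter / 2)
      abort(sprintf(
        "sampling region overlaps the BB sphere (distance %.2f mm <= radius %.2f mm)",
        gap, volume$bb$diameter / 2))
  }
  vals <- volume$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  tibble(mean_hu = mean(vals),
         sd_hu = if (length(vals) > 1) sd(as.numeric(vals)) else 0,
         n_voxels = length(vals))
}
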