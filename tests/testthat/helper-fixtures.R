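# Shared fixtures, generated once per test run and cached. The tiny phantom
# uses a coarser grid (1.5 mm) and a larger BB (3 mm, >= 2x spacing) so that
# DRRs and registrations stay desk-cheap while every geometric feature of
# the full phantom (shell, fill, BB, cavities, bumps) is present.

.fixtures <- new.env(parent = emptyenv())

tiny_spec <- function(seed = 3L, noise_sd = 0) {
  phantom_spec(semi_axes = c(42, 52, 45), shell_thickness = 5,
               spacing = 1.5, bb_diameter = 3, margin = 9,
               n_bumps = 8, bump_size = c(4, 9),
               cavity_size = c(4, 7),
               noise_sd = noise_sd, seed = seed)
}

tiny_phantom <- function() {
  if (is.null(.fixtures$ph))
    .fixtures$ph <- generate_skull_phantom(tiny_spec())
  .fixtures$ph
}

tiny_detector <- function() detector_spec(field_mm = 130, pitch_iso = 0.8)

tiny_drr <- function(gantry = 90, couch = 0) {
  key <- sprintf("drr_%s_%s", gantry, couch)
  if (is.null(.fixtures[[key]])) {
    vol <- remove_bb_region(tiny_phantom(), c(24, 24, 16), 36.1)
    .fixtures[[key]] <- compute_drr(vol, beam_geometry(gantry, couch),
                                    tiny_detector())
  }
  .fixtures[[key]]
}

# an aperture over the skull rim in the gantry-90 view; information-rich in
# both axes (used as the canonical "good" crop)
good_aperture <- function() aperture(-34, 10, 26, 26)

# independent radiological-path oracle: dense ray marching with
# nearest-voxel lookup (step = step_frac * min voxel size)
march_path <- function(volume, geometry, px, py, step_frac = 0.05) {
  b <- mvroi:::bev_basis(geometry)
  src <- volume$isocenter + geometry$sad * b$w
  q <- volume$isocenter + px * b$u + py * b$v
  p1 <- src + (q - src) * geometry$sid / geometry$sad
  mu <- hu_to_attenuation(volume$values)
  step <- min(volume$spacing) * step_frac
  dirv <- p1 - src
  len <- sqrt(sum(dirv^2))
  ts <- seq(0, 1, by = step / len)
  pts <- outer(ts, dirv) + rep(src, each = length(ts))
  idx <- round(sweep(sweep(pts, 2, volume$origin), 2, volume$spacing, "/")) + 1
  d <- dim(volume$values)
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
        idx[, 2] >= 1 & idx[, 2] <= d[2] &
        idx[, 3] >= 1 & idx[, 3] <= d[3]
  lin <- idx[ok, 1] + d[1] * (idx[ok, 2] - 1) + prod(d[1:2]) * (idx[ok, 3] - 1)
  sum(mu[lin]) * step
}

# crop helper mirroring the internal window logic
crop_of <- function(drr, ap) {
  w <- mvroi:::aperture_window(drr, ap)
  drr$intensity[w$rows, w$cols, drop = FALSE]
}
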