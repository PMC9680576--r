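test_that("phantom spec invariants are enforced with named messages", {
  expect_error(phantom_spec(shell_thickness = 70),
               "shell thickness")
  expect_error(phantom_spec(spacing = 1.25, bb_diameter = 2),
               "bb diameter")
  expect_silent(phantom_spec(spacing = 1, bb_diameter = 2))
})

test_that("generated phantom has the BB at isocenter and fill interior", {
  ph <- tiny_phantom()
  i <- (dim(ph) + 1) / 2
  expect_equal(ph$values[i[1], i[2], i[3]], tiny_spec()$bb_hu)

  # interior region away from BB, cavities and shell averages to fill HU
  s <- sample_fill_hu(ph, i + c(14, 10, 0), extent = c(12, 12, 12))
  expect_equal(s$mean_hu, tiny_spec()$fill_hu, tolerance = 1 / 36.1)
  expect_equal(s$sd_hu, 0)
})

test_that("phantom generation is reproducible for a fixed seed", {
  a <- generate_skull_phantom(tiny_spec(seed = 11))
  b <- generate_skull_phantom(tiny_spec(seed = 11))
  expect_identical(a$values, b$values)
  c <- generate_skull_phantom(tiny_spec(seed = 12))
  expect_false(identical(a$values, c$values))
})

test_that("shell is closed: all 26 axis/diagonal rays cross bone", {
  ph <- tiny_phantom()
  dirs <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  dirs <- dirs[rowSums(abs(dirs)) > 0, ]
  d <- dim(ph)
  half_mm <- (d - 1) / 2 * ph$spacing
  for (r in seq_len(nrow(dirs))) {
    dir <- dirs[r, ] / sqrt(sum(dirs[r, ]^2))
    tmax <- min(half_mm[dirs[r, ] != 0] / abs(dir[dirs[r, ] != 0]))
    ts <- seq(0, tmax, by = min(ph$spacing) / 4)
    pts <- outer(ts, dir)
    idx <- round(sweep(sweep(pts, 2, ph$origin), 2, ph$spacing, "/")) + 1
    idx <- pmin(pmax(idx, 1), matrix(d, nrow(idx), 3, byrow = TRUE))
    lin <- idx[, 1] + d[1] * (idx[, 2] - 1) + prod(d[1:2]) * (idx[, 3] - 1)
    expect_true(any(ph$values[lin] > 300),
                label = sprintf("ray (%d,%d,%d) crosses bone",
                                dirs[r, 1], dirs[r, 2], dirs[r, 3]))
  }
})

test_that("remove_bb_region assigns exactly the requested box", {
  # volume of zeros: every voxel in a fully interior 60x60x40 box changes
  vol <- ct_volume(array(0, dim = c(70, 70, 50)), spacing = c(1, 1, 1),
                   origin = -c(34.5, 34.5, 24.5))
  out <- remove_bb_region(vol, c(60, 60, 40), fill_hu = 36.1)
  expect_equal(sum(out$values != 0), 60 * 60 * 40)
  expect_equal(sum(out$values == 36.1), 144000)

  # identity when the isocenter voxel already equals the fill value
  vol2 <- ct_volume(array(36.1, dim = c(11, 11, 11)), c(1, 1, 1),
                    origin = rep(-5, 3))
  out2 <- remove_bb_region(vol2, c(1, 1, 1), fill_hu = 36.1)
  expect_identical(out2$values, vol2$values)

  # BB region HU replacement at the isocenter voxel of the phantom
  ph <- tiny_phantom()
  rep_ph <- remove_bb_region(ph, c(24, 24, 16), fill_hu = 36.1)
  i <- (dim(ph) + 1) / 2
  expect_equal(rep_ph$values[i[1], i[2], i[3]], 36.1)
  expect_null(rep_ph$bb)

  expect_error(remove_bb_region(ph, c(0, 10, 10)), "positive")
  expect_warning(remove_bb_region(tiny_phantom(), c(500, 10, 10), 36.1),
                 "clipped")
})

test_that("sample_fill_hu computes mean/SD and refuses BB overlap", {
  vol <- ct_volume(array(c(0, 2), dim = c(2, 1, 1)), c(1, 1, 1),
                   origin = c(-0.5, 0, 0))
  s <- sample_fill_hu(vol, c(1, 1, 1), extent = c(2, 1, 1))
  expect_equal(s$mean_hu, 1.0)

  ph <- tiny_phantom()
  i <- (dim(ph) + 1) / 2
  expect_error(sample_fill_hu(ph, i, extent = c(4, 4, 4)), "BB")
  expect_error(sample_fill_hu(ph, c(1, 1, 1), extent = c(40, 4, 4)),
               "outside")
})

test_that("with Gaussian HU noise the sampled SD matches the noise model", {
  # Monte-Carlo over seeds: SD over a 20^3 interior region should sit
  # within [15, 25] HU for sigma = 20 in at least 95% of draws
  hits <- vapply(1:100, function(s) {
    sp <- phantom_spec(semi_axes = c(45, 55, 40), shell_thickness = 5,
                       spacing = 1.5, bb_diameter = 3, margin = 6,
                       n_cavities = 0, noise_sd = 20, seed = s)
    ph <- generate_skull_phantom(sp)
    i <- (dim(ph) + 1) / 2
    est <- sample_fill_hu(ph, i + c(0, 13, 0), extent = c(20, 20, 20))
    est$sd_hu >= 15 && est$sd_hu <= 25
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
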