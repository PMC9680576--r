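test_that("the couch-shift transform matches hand-evaluated cases", {
  expect_equal(unlist(derive_couch_shift(0, 0, 123, 271)),
               c(lat_mm = 0, lng_mm = 0, vrt_mm = 0))

  s <- derive_couch_shift(1.5, 1.5, gantry = 0, couch = 0)
  expect_equal(c(s$lat_mm, s$lng_mm, s$vrt_mm), c(1.5, 1.5, 0),
               tolerance = 1e-12)

  s <- derive_couch_shift(2, 1, gantry = 90, couch = 0)
  expect_equal(c(s$lat_mm, s$lng_mm, s$vrt_mm), c(0, 1, 2),
               tolerance = 1e-12)
})

test_that("the couch-shift transform preserves the displacement norm", {
  set.seed(13)
  d <- matrix(runif(2000, -5, 5), ncol = 2)
  th <- runif(1000, 0, 360)
  ph <- runif(1000, 0, 360)
  s <- derive_couch_shift(d[, 1], d[, 2], th, ph)
  n3 <- sqrt(s$lat_mm^2 + s$lng_mm^2 + s$vrt_mm^2)
  expect_equal(n3, sqrt(d[, 1]^2 + d[, 2]^2), tolerance = 1e-12)
})

test_that("projecting an offset and transforming back recovers the visible part", {
  set.seed(14)
  for (k in 1:50) {
    g <- beam_geometry(runif(1, 0, 360), runif(1, 0, 360))
    b <- mvroi:::bev_basis(g)
    o <- runif(3, -3, 3)
    dx <- sum(o * b$u)
    dy <- sum(o * b$v)
    rec <- derive_couch_shift(dx, dy, g$gantry, g$couch)
    visible <- b$u * dx + b$v * dy
    expect_equal(c(rec$lat_mm, rec$lng_mm, rec$vrt_mm), visible,
                 tolerance = 1e-9)
    # the residual is along the beam axis
    resid <- o - visible
    expect_lt(abs(sum(resid * b$u)) + abs(sum(resid * b$v)), 1e-9)
  }
})

test_that("motion traces reproduce their definitions", {
  cps <- control_points_from_arcs(table1_arcs(15))
  lin <- make_motion_trace("linear", cps, magnitude = 1.5)
  expect_equal(unlist(lin[1, c("lat_mm", "lng_mm", "vrt_mm")]),
               c(lat_mm = 0, lng_mm = 0, vrt_mm = 0))
  expect_equal(unlist(lin[nrow(lin), c("lat_mm", "lng_mm", "vrt_mm")]),
               c(lat_mm = 1.5, lng_mm = 1.5, vrt_mm = 1.5))
  # linear in control-point index
  expect_equal(diff(lin$lat_mm), rep(1.5 / (nrow(cps) - 1), nrow(cps) - 1))

  sud <- make_motion_trace("sudden", cps, magnitude = 1.5, onset = 36)
  expect_equal(sud$lat_mm[35], 0)
  expect_equal(sud$lat_mm[36], 1.5)
  expect_true(all(sud$lat_mm[36:nrow(sud)] == 1.5))

  # default onset: halfway through the first (axial) arc
  sud2 <- make_motion_trace("sudden", cps)
  n1 <- sum(cps$arc == 1)
  expect_equal(min(which(sud2$lat_mm > 0)), floor(n1 / 2) + 1)

  none <- make_motion_trace("none", cps)
  expect_true(all(none$lat_mm == 0))

  expect_error(make_motion_trace("linear", cps[0, ]), "empty")
})

test_that("EPID simulation shifts anatomy and keeps the BB visible", {
  ph <- tiny_phantom()
  det <- tiny_detector()
  g <- beam_geometry(0, 0)
  jaw <- aperture(0, 0, 25, 25)

  ref <- simulate_epid_image(ph, g, c(0, 0, 0), jaw, det)
  plain <- compute_drr(ph, g, det, aperture = jaw)
  expect_equal(ref$intensity, plain$intensity, tolerance = 1e-12)

  # the BB appears in the EPID image but not in the BB-free reference
  noref <- compute_drr(remove_bb_region(ph, c(24, 24, 16), 36.1), g, det,
                       aperture = jaw)
  expect_gt(max(-log(ref$intensity) + log(noref$intensity)), 0.03)

  # a pure lateral 1.5 mm offset moves the detected BB by about 1.5 mm
  hit0 <- detect_bb(ref, bb_diameter = 3)
  moved <- simulate_epid_image(ph, g, c(1.5, 0, 0), jaw, det)
  hit1 <- detect_bb(moved, bb_diameter = 3)
  # centroid quantization at this coarse fixture pitch (0.8 mm) limits
  # per-detection accuracy to a fraction of a pixel
  expect_lt(abs((hit1$x_mm - hit0$x_mm) - 1.5), 0.25)
  expect_lt(abs(hit1$y_mm - hit0$y_mm), 0.25)

  # seeded noise is reproducible
  n1 <- simulate_epid_image(ph, g, c(0, 0, 0), jaw, det,
                            noise_photons = 1e4, noise_seed = 5)
  n2 <- simulate_epid_image(ph, g, c(0, 0, 0), jaw, det,
                            noise_photons = 1e4, noise_seed = 5)
  expect_identical(n1$intensity, n2$intensity)
  expect_false(identical(n1$intensity, ref$intensity))
})

test_that("error evaluation matches norms and handles noise", {
  mk_run <- function(lat, lng, vrt, dx = lat, dy = lng) {
    structure(tibble::tibble(cp = seq_along(lat), arc = 1, gantry = 0,
                             couch = 0, method = "x", dx_mm = dx,
                             dy_mm = dy, lat_mm = lat, lng_mm = lng,
                             vrt_mm = vrt, ok = TRUE),
              class = c("delivery_run", class(tibble::tibble())))
  }
  a <- mk_run(c(1, 0.5), c(0, 0.5), c(0, 0.5))
  ev0 <- evaluate_errors(a, a)
  expect_true(all(ev0$per_point$err3d_mm == 0))
  expect_equal(ev0$summary$median_3d, 0)

  b <- mk_run(c(0, 0.5), c(0, 0.5), c(0, 0.5))
  ev1 <- evaluate_errors(a, b)
  expect_equal(ev1$per_point$err3d_mm[1], 1.0)

  # U(-0.1, 0.1) per-axis disagreement: median 3D error below 0.18 mm
  set.seed(77)
  n <- 10000
  base <- mk_run(runif(n), runif(n), runif(n))
  noisy <- mk_run(base$lat_mm + runif(n, -0.1, 0.1),
                  base$lng_mm + runif(n, -0.1, 0.1),
                  base$vrt_mm + runif(n, -0.1, 0.1),
                  dx = base$dx_mm, dy = base$dy_mm)
  ev2 <- evaluate_errors(noisy, base)
  expect_lt(ev2$summary$median_3d, 0.18)

  expect_error(evaluate_errors(a, mk_run(0, 0, 0)), "same control points")
})

test_that("a static phantom yields near-zero detected shifts (BB method)", {
  ph <- tiny_phantom()
  cps <- control_points_from_arcs(arc_spec(0, 0, 90, "CW", 45))
  plan <- suppressMessages(
    build_imaging_plan(ph, cps, threshold = "open",
                       detector = tiny_detector(), seed = 1))
  trace <- make_motion_trace("none", cps)
  run <- suppressMessages(simulate_delivery(ph, plan, trace, method = "bb"))
  expect_true(all(run$ok))
  # sub-pixel-fraction at the 0.8 mm fixture pitch; scales with pitch
  expect_lt(max(abs(c(run$dx_mm, run$dy_mm))), 0.2)
  expect_lt(max(abs(c(run$lat_mm, run$lng_mm, run$vrt_mm))), 0.2)
})
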