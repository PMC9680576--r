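test_that("preprocessing normalizes and equalizes", {
  expect_warning(out <- preprocess_image(matrix(3, 10, 10)), "distinct")
  expect_identical(out, matrix(3, 10, 10))

  img <- matrix(runif(64 * 64, 5, 9), 64, 64)
  out <- preprocess_image(img)
  expect_equal(range(out), c(0, 1))

  # a linear ramp equalizes to a uniform histogram (chi-square, 16 bins)
  ramp <- matrix(seq(0, 1, length.out = 256 * 256), 256, 256)
  eq <- preprocess_image(ramp)
  counts <- tabulate(pmin(floor(eq * 16) + 1, 16), 16)
  chi2 <- sum((counts - mean(counts))^2 / mean(counts))
  expect_lt(chi2, qchisq(0.999, df = 15))
})

test_that("mutual information satisfies its identities", {
  set.seed(1)
  a <- matrix(runif(256 * 256), 256, 256)

  # I(X;X) = H(X) at matched binning
  h <- local({
    counts <- tabulate(pmin(as.integer((a - min(a)) /
      (max(a) - min(a)) * (16 - 1e-9)) + 1L, 16L), 16L)
    p <- counts / sum(counts)
    -sum(p[p > 0] * log(p[p > 0]))
  })
  expect_equal(mutual_information(a, a, bins = 16), h, tolerance = 1e-10)

  # invariance under intensity inversion (bijective relabeling)
  expect_equal(mutual_information(a, max(a) - a, bins = 16),
               mutual_information(a, a, bins = 16), tolerance = 1e-10)

  # independent images have (bias-level) MI
  mis <- vapply(1:20, function(s) {
    set.seed(100 + s)
    mutual_information(matrix(runif(256 * 256), 256),
                       matrix(runif(256 * 256), 256), bins = 16)
  }, numeric(1))
  expect_lt(max(mis), 0.01)

  expect_error(mutual_information(a, a[1:10, 1:10]), "dimensions")
  expect_gte(mutual_information(a, a + rnorm(length(a), 0, 0.1)), 0)
})

test_that("registration recovers identity and integer-pixel shifts", {
  drr <- tiny_drr()
  crop <- crop_of(drr, good_aperture())

  res0 <- register_translation(crop, crop, drr$pitch, bound = 2)
  expect_true(res0$converged)
  # residual is at most one terminal search step (tolerance-level, and
  # proportionally smaller at clinical detector pitch)
  expect_lt(abs(res0$dx_mm), 0.02)
  expect_lt(abs(res0$dy_mm), 0.02)

  # constructed by array rolling (full image, then crop, so no wrap seam
  # enters the window): the construction is the oracle
  roll <- function(m, kx, ky) {
    n1 <- nrow(m); n2 <- ncol(m)
    m[((seq_len(n1) - 1 - kx) %% n1) + 1, ((seq_len(n2) - 1 - ky) %% n2) + 1]
  }
  win <- mvroi:::aperture_window(drr, good_aperture())
  for (k in list(c(1, 0), c(-2, 3), c(2, 2))) {
    moved <- roll(drr$intensity, k[1], k[2])[win$rows, win$cols]
    res <- register_translation(crop, moved, drr$pitch, bound = 3.5)
    expect_lt(abs(res$dx_mm - k[1] * drr$pitch), 0.02)
    expect_lt(abs(res$dy_mm - k[2] * drr$pitch), 0.02)
  }
})

test_that("registration recovers constructed sub-pixel shifts on a good crop", {
  drr <- tiny_drr()
  # the fixture aperture must itself classify "good" for this guarantee
  sc <- classify_aperture(evaluate_apertures(
    drr, good_aperture(), shift_grid(1.5, 3), interp = "cubic",
    tol = 0.01, max_samples = NULL))
  expect_equal(sc$label, "good")

  win <- mvroi:::aperture_window(drr, good_aperture())
  fixed <- drr$intensity[win$rows, win$cols]
  for (s in list(c(0.37, 0.37), c(-0.53, 0.21), c(0.81, -0.37))) {
    moved <- mvroi:::shift_window(drr$intensity, win$rows, win$cols,
                                  s[1] / drr$pitch, s[2] / drr$pitch)
    res <- register_translation(fixed, moved, drr$pitch, bound = 3)
    expect_lt(abs(res$dx_mm - s[1]), 0.05)
    expect_lt(abs(res$dy_mm - s[2]), 0.05)
  }
})

test_that("registration is antisymmetric on random aperture crops", {
  drr <- tiny_drr()
  set.seed(9)
  aps <- sample_apertures(20, area_range = c(3, 12), field_mm = 100,
                          seed = 21)
  checked <- 0
  for (i in seq_len(nrow(aps))) {
    win <- mvroi:::aperture_window(drr, aps[i, ])
    a <- drr$intensity[win$rows, win$cols, drop = FALSE]
    b <- mvroi:::shift_window(drr$intensity, win$rows, win$cols,
                              0.83 / drr$pitch, -0.41 / drr$pitch)
    fwd <- register_translation(a, b, drr$pitch, bound = 2.5)
    rev <- register_translation(b, a, drr$pitch, bound = 2.5)
    if (!fwd$converged || !rev$converged) next
    # only assert on informative crops where the forward registration
    # itself locks on; swapping roles then at most doubles the
    # single-direction error, since only the moving image is resampled
    if (max(abs(c(fwd$dx_mm - 0.83, fwd$dy_mm + 0.41))) > 0.05) next
    expect_lt(abs(fwd$dx_mm + rev$dx_mm), 0.1)
    expect_lt(abs(fwd$dy_mm + rev$dy_mm), 0.1)
    checked <- checked + 1
  }
  expect_gte(checked, 8)
})

test_that("degenerate inputs yield a failure flag, not an answer", {
  flat <- matrix(1, 32, 32)
  res <- register_translation(flat, flat, 0.8, bound = 2)
  expect_false(res$converged)
  expect_true(is.na(res$dx_mm))
})

test_that("the MI shift surface has 121 elements with a central maximum", {
  drr <- tiny_drr()
  surf <- mi_shift_surface(drr, good_aperture())
  expect_equal(dim(surf$values), c(11, 11))
  expect_equal(length(surf$values), 121)
  ctr <- surf$values[6, 6]
  expect_equal(ctr, mutual_information(crop_of(drr, good_aperture()),
                                       crop_of(drr, good_aperture())))
  expect_true(all(surf$values[-61] < ctr))

  expect_error(mi_shift_surface(drr, good_aperture(), half_width = 2,
                                step = 0.8), "odd")
  expect_error(mi_shift_surface(drr, aperture(0, 0, 3, 3)), "8 x 8")
})

test_that("BB detection finds a small disk and suppresses larger blobs", {
  pitch <- 0.5
  n <- 101
  xs <- (seq_len(n) - (n + 1) / 2) * pitch
  # analytic coverage of a disk: attenuation dome like a projected sphere
  disk_att <- function(cx, cy, r, depth = 0.05) {
    d2 <- outer((xs - cx)^2, (xs - cy)^2, `+`)
    chord <- ifelse(d2 < r^2, sqrt(pmax(r^2 - d2, 0)) / r, 0)
    depth * chord
  }
  att <- disk_att(1.5, -0.7, 1)
  img <- exp(-att)
  hit <- detect_bb(img, bb_diameter = 2, pitch = pitch)
  expect_lt(abs(hit$x_mm - 1.5), 0.1)
  expect_lt(abs(hit$y_mm + 0.7), 0.1)

  # a 10-mm blob elsewhere must not capture the detection
  att2 <- att + disk_att(-15, 12, 5, depth = 0.2)
  hit2 <- detect_bb(exp(-att2), bb_diameter = 2, pitch = pitch)
  expect_lt(abs(hit2$x_mm - 1.5), 0.1)
  expect_lt(abs(hit2$y_mm + 0.7), 0.1)

  # featureless image: detection failure is an error
  expect_error(detect_bb(matrix(1, n, n), bb_diameter = 2, pitch = pitch),
               "detection failed")
})
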