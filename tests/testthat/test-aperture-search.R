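test_that("aperture sampling respects its distributional contract", {
  aps <- sample_apertures(3000, seed = 5)
  expect_equal(nrow(aps), 3000)
  expect_true(all(aps$area_cm2 >= 0.375 - 1e-9))
  expect_true(all(aps$area_cm2 <= 37.5 + 1e-9))
  # every rectangle inside the 22 x 22 cm^2 field
  expect_true(all(abs(aps$cx_mm) + aps$w_mm / 2 <= 110 + 1e-9))
  expect_true(all(abs(aps$cy_mm) + aps$h_mm / 2 <= 110 + 1e-9))
  # aspect ratio within bounds
  expect_true(all(aps$w_mm / aps$h_mm >= 1 / 3 - 1e-9))
  expect_true(all(aps$w_mm / aps$h_mm <= 3 + 1e-9))

  expect_identical(sample_apertures(50, seed = 8), sample_apertures(50, seed = 8))

  one <- sample_apertures(1, area_range = c(1, 1), aspect_range = c(1, 1),
                          seed = 1)
  expect_equal(c(one$w_mm, one$h_mm), c(10, 10))

  expect_error(sample_apertures(5, area_range = c(1, 400), field_mm = 100),
               "infeasible")
})

test_that("aperture evaluation flags uninformative crops and scores text-rich ones", {
  # synthetic BEV: uniform background with a high-contrast cross. The
  # edges are smoothed (as projection through a volume would): a strictly
  # piecewise-constant image gives histogram MI exact plateaus under
  # subpixel shifts and no unique optimum.
  n <- 161
  pitch <- 0.8
  img <- matrix(1, n, n)
  img[76:86, 20:140] <- 0.45
  img[40:130, 74:88] <- 0.55
  img <- EBImage::gblur(img, 1.5)
  drr <- structure(list(intensity = img,
                        x_mm = (seq_len(n) - (n + 1) / 2) * pitch,
                        y_mm = (seq_len(n) - (n + 1) / 2) * pitch,
                        pitch = pitch,
                        geometry = beam_geometry(0, 0)),
                   class = "drr_image")
  shifts <- shift_grid(1.5, 3)

  cross_ap <- aperture(0, 0, 50, 50)
  flat_ap <- aperture(-45, -45, 25, 25)
  scored <- evaluate_apertures(drr, dplyr::bind_rows(cross_ap, flat_ap),
                               shifts)
  expect_true(scored$valid[1])
  expect_false(scored$valid[2])
  expect_equal(scored$score[2], Inf)
  expect_lt(scored$range_e[1], 0.05)

  # determinism: identical inputs give identical stats
  again <- evaluate_apertures(drr, dplyr::bind_rows(cross_ap, flat_ap),
                              shifts)
  expect_identical(scored, again)
})

test_that("top-fraction selection counts and tie-breaks correctly", {
  aps <- sample_apertures(3000, seed = 2)
  set.seed(3)
  scored <- dplyr::mutate(aps, score = runif(3000), valid = TRUE)
  top <- select_top(scored, 0.1)
  expect_equal(nrow(top), 300)
  expect_true(all(top$score <= sort(scored$score)[300]))

  ten <- dplyr::mutate(sample_apertures(10, seed = 4),
                       score = c(0.5, 0.2, 0.9, 1, 1, 1, 1, 1, 1, 1),
                       valid = TRUE)
  expect_equal(select_top(ten, 0.1)$.draw, 2L)

  # equal scores: smaller area wins the single slot
  pair <- dplyr::bind_rows(aperture(0, 0, 30, 30), aperture(0, 0, 20, 20))
  pair$score <- c(0.5, 0.5)
  pair$valid <- TRUE
  pair$.draw <- 1:2
  sel <- select_top(dplyr::bind_rows(pair,
    dplyr::mutate(aperture(0, 0, 10, 100), score = 2, valid = TRUE,
                  .draw = 3L)), 1 / 3)
  expect_equal(sel$area_cm2, 4)

  allbad <- dplyr::mutate(aperture(0, 0, 10, 10), score = Inf, valid = FALSE)
  expect_error(select_top(allbad, 1), "no valid")
})

test_that("topographic maps count overlapping masks additively", {
  drr <- tiny_drr()
  one <- aperture(-10, 5, 20, 16)
  m1 <- build_topographic_map(one, drr)
  win <- mvroi:::aperture_window(drr, one)
  expect_equal(sum(m1$counts), length(win$rows) * length(win$cols))
  expect_true(all(m1$counts[win$rows, win$cols] == 1))
  expect_equal(max(m1$counts), 1)

  m2 <- build_topographic_map(dplyr::bind_rows(one, one), drr)
  expect_equal(max(m2$counts), 2)
  expect_equal(sum(m2$counts > 0 & m2$counts != 2), 0)

  aps <- sample_apertures(50, area_range = c(1, 9), field_mm = 100, seed = 6)
  m <- build_topographic_map(aps, drr)
  expect_lte(max(m$counts), 50)
  indiv <- sum(vapply(seq_len(50), function(i) {
    w <- mvroi:::aperture_window(drr, aps[i, ])
    length(w$rows) * length(w$cols)
  }, numeric(1)))
  expect_equal(sum(m$counts), indiv)
})

test_that("threshold apertures shrink monotonically with level", {
  drr <- tiny_drr()
  # single mask: any level returns that aperture (within one pixel)
  one <- aperture(-8, 4, 24, 18)
  m1 <- build_topographic_map(one, drr)
  back <- extract_threshold_aperture(m1, 50)
  expect_lt(abs(back$cx_mm - one$cx_mm), drr$pitch)
  expect_lt(abs(back$w_mm - one$w_mm), 2 * drr$pitch)

  # concentric overlay: superlevel sets nest, areas non-increasing
  nested <- dplyr::bind_rows(lapply(seq(60, 12, by = -6), function(s)
    aperture(3, -2, s, s * 0.8)))
  mm <- build_topographic_map(nested, drr)
  areas <- vapply(seq(50, 90, by = 10), function(lv) {
    extract_threshold_aperture(mm, lv)$area_cm2
  }, numeric(1))
  expect_true(all(diff(areas) <= 1e-9))

  ap90 <- extract_threshold_aperture(mm, 90)
  ap50 <- extract_threshold_aperture(mm, 50)
  expect_gte(ap90$cx_mm - ap90$w_mm / 2, ap50$cx_mm - ap50$w_mm / 2 - 1e-9)
  expect_lte(ap90$cx_mm + ap90$w_mm / 2, ap50$cx_mm + ap50$w_mm / 2 + 1e-9)

  expect_error(extract_threshold_aperture(m1, 0), "level")
})

test_that("cube-root scaling acts on every linear quantity", {
  ap <- aperture(12, -8, 30, 20)
  expect_identical(scale_aperture(ap, 2000, 2000), ap)

  s8 <- scale_aperture(ap, 1000, 8000)
  expect_equal(c(s8$cx_mm, s8$cy_mm, s8$w_mm, s8$h_mm),
               2 * c(12, -8, 30, 20))

  # clinical skull volumes around a ~2100 cm^3 reference give the reported
  # 1.06-1.18 range of linear factors
  vols <- c(2500, 2800, 3100, 3500)
  f <- vapply(vols, function(v) {
    scale_aperture(aperture(0, 10, 10, 10), 2100, v)$h_mm / 10
  }, numeric(1))
  expect_true(all(f >= 1.05 & f <= 1.19))
})

test_that("aperture classification follows the error-range definitions", {
  base <- aperture(0, 0, 25, 20)   # 5 cm^2
  stats <- dplyr::mutate(base, valid = TRUE, mean_ex = 0.02, mean_ey = 0.01,
                         range_x = 0.05, range_y = 0.04, range_e = 0.05)
  expect_equal(classify_aperture(stats)$label, "good")

  expect_equal(classify_aperture(
    dplyr::mutate(stats, range_x = 1.5, range_e = 1.5))$label, "bad")
  expect_equal(classify_aperture(
    dplyr::mutate(stats, range_x = 0.5, range_e = 0.5,
                  mean_ex = 0))$label, "neither")
  # small apertures are never labelled
  small <- dplyr::mutate(stats, w_mm = 10, h_mm = 10, area_cm2 = 1)
  expect_equal(classify_aperture(small)$label, "neither")
})
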