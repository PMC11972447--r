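test_that("noiseless calibration pairs are recovered to floating precision", {
  pr <- generate_calibration_pairs(0.01, c(12, 10), n = 15, seed = 4)
  cm <- fit_calibration(pr)
  expect_equal(cm$k, 0.01, tolerance = 1e-10)
  expect_equal(cm$p0, c(12, 10), tolerance = 1e-8)
  expect_equal(cm$diagnostics$r_squared, 1, tolerance = 1e-10)
})

test_that("calibration rejects underdetermined or inconsistent input", {
  one <- tibble::tibble(dx_px = 5, dy_px = 5, px_mm = 1, py_mm = 1)
  expect_error(fit_calibration(one), "underdetermined")
  same <- tibble::tibble(dx_px = c(5, 5), dy_px = c(5, 5),
                         px_mm = c(1, 1), py_mm = c(1, 1))
  expect_error(fit_calibration(same), "underdetermined")
  expect_error(calibration_model(-0.01), "inconsistent")
})

test_that("slope recovery stays within 5% under mild measurement noise", {
  pr <- generate_calibration_pairs(0.0113, c(0, 0), n = 20,
                                   noise_sigma_d = 2, noise_sigma_p = 0.1,
                                   seed = 9)
  cm <- fit_calibration(pr)
  expect_lt(abs(cm$k - 0.0113) / 0.0113, 0.05)
})

test_that("offset-to-position mapping follows the linear law", {
  m <- calibration_model(0.0113, c(0, 0))
  expect_identical(map_offset_to_lcd(c(0, 0), m), c(0, 0))
  expect_equal(map_offset_to_lcd(c(100, 0), m), c(1.13, 0))
  expect_equal(map_offset_to_lcd(c(-100, 0), m), c(-1.13, 0))

  m2 <- calibration_model(0.02, c(1, -2))
  expect_identical(map_offset_to_lcd(c(0, 0), m2), c(1, -2))
  expect_error(map_offset_to_lcd(c(NaN, 0), m2), "finite")
})

test_that("mapping is affine-linear in the offset", {
  m <- calibration_model(0.0113, c(0.7, -0.3))
  d1 <- c(37, -11); d2 <- c(-5, 90); a <- 2.5; b <- -1.25
  lhs <- map_offset_to_lcd(a * d1 + b * d2, m)
  rhs <- a * map_offset_to_lcd(d1, m) + b * map_offset_to_lcd(d2, m) -
    (a + b - 1) * m$p0
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("fitting the model on its own predictions recovers it exactly", {
  m <- calibration_model(0.0087, c(2.2, 1.1))
  d <- cbind(c(0, 10, -40, 120, 75), c(0, -30, 55, 80, -100))
  p <- t(apply(d, 1, map_offset_to_lcd, model = m))
  pairs <- tibble::tibble(dx_px = d[, 1], dy_px = d[, 2],
                          px_mm = p[, 1], py_mm = p[, 2])
  cm <- fit_calibration(pairs)
  expect_equal(cm$k, m$k, tolerance = 1e-12)
  expect_equal(cm$p0, m$p0, tolerance = 1e-12)
})

test_that("the rendered LCD raster matches the analytic ring geometry", {
  sp <- annulus_spec(center = c(240, 240) * 0.0805, r_inner = 5, r_outer = 6)
  fr <- render_annulus_frame(sp)
  expect_setequal(unique(as.vector(fr)), c(0, 255))
  expect_equal(sum(fr > 0), pi * (6^2 - 5^2) / 0.0805^2, tolerance = 0.02)

  white <- render_annulus_frame(sp, white_screen = TRUE)
  expect_true(all(white == 255))

  off <- annulus_spec(center = c(240 * 0.0805 + 1.13, 240 * 0.0805),
                      r_inner = 5, r_outer = 6)
  c1 <- bright_centroid(fr, 128)
  c2 <- bright_centroid(render_annulus_frame(off), 128)
  expect_lt(abs((c2[1] - c1[1]) - 1.13 / 0.0805), 1)
  expect_lt(abs(c2[2] - c1[2]), 1)

  gone <- annulus_spec(center = c(200, 200), r_inner = 5, r_outer = 6)
  expect_error(render_annulus_frame(gone), "clipped annulus")
})

test_that("calibration JSON round-trips", {
  m <- calibration_model(0.0113, c(12.25, 9.75))
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(m, path)
  m2 <- read_calibration(path)
  expect_equal(m2$k, m$k)
  expect_equal(m2$p0, m$p0)
})

test_that("one detect-map-render cycle compensates a meniscus-free offset", {
  # closed loop on the synthetic optics: an offset detected at the analysis
  # scale maps to an LCD correction that, applied to the annulus, leaves a
  # residual below 3 px
  k_true <- 0.0113 / 0.2  # mm per analysis-scale px
  model <- calibration_model(k_true, c(0, 0))
  tr <- bertrand_truth(offset = c(120, -70))
  img <- generate_bertrand_image(tr, meniscus_model(noise_sigma = 3),
                                 seed = 19)$image
  off <- detect_offset(img, phase_ring_center = tr$phase_ring_center)
  p <- map_offset_to_lcd(off, model)
  # the LCD shift moves the annulus image by -p / k_true analysis px
  corrected <- tr$offset * 0.2 - p / k_true
  img2 <- generate_bertrand_image(
    bertrand_truth(offset = corrected / 0.2),
    meniscus_model(noise_sigma = 3), seed = 20)$image
  off2 <- detect_offset(img2, phase_ring_center = tr$phase_ring_center)
  expect_lt(sqrt(sum(off2$delta_d^2)), 3)
})
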