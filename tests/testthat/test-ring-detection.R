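# Shared fixtures: one synthetic Bertrand scene with a known offset, reused
# across the detection tests (full-resolution offset (150, -60) corresponds
# to (30, -12) px at the default 20% analysis scale).
scene_truth <- bertrand_truth(offset = c(150, -60))
scene <- generate_bertrand_image(scene_truth, meniscus_model(noise_sigma = 5),
                                 distractors = 3, seed = 17)

test_that("preprocess downscales to 20% and is the identity when disabled", {
  big <- matrix(rep(seq(0, 255, length.out = 2000), 2400), nrow = 2000)
  out <- preprocess(big, detector_params(downscale = 0.2, clahe_clip = 0))
  expect_identical(dim(out), c(400L, 480L))

  small <- matrix(runif(64 * 64, 0, 255), 64, 64)
  expect_identical(preprocess(small, detector_params(downscale = 1,
                                                     clahe_clip = 0)),
                   small)
  expect_error(preprocess(small, detector_params(downscale = 0.1)),
               "smaller than 16")
})

test_that("CLAHE leaves a structureless constant image constant", {
  flat <- matrix(128, 64, 64)
  out <- preprocess(flat, detector_params(downscale = 1, clahe_clip = 2))
  expect_identical(out, flat)
})

test_that("segmentation recovers the annular band area and flags empty masks", {
  # hard-edged bright annulus, no CLAHE: analytic band area pi(rout^2 - rin^2)
  g <- expand.grid(y = 1:200, x = 1:200)
  r <- sqrt((g$x - 100)^2 + (g$y - 100)^2)
  img <- matrix(ifelse(r >= 40 & r <= 60, 220, 30), 200, 200)
  p <- detector_params(downscale = 1, clahe_clip = 0, binary_threshold = 128)
  mask <- segment_ring(img, p)
  expect_equal(sum(mask), pi * (60^2 - 40^2), tolerance = 0.05)

  expect_error(segment_ring(matrix(0, 50, 50), p), "no segmentation")
  pd <- detector_params(downscale = 1, clahe_clip = 0, binary_threshold = 128,
                        polarity = "dark")
  expect_error(segment_ring(matrix(255, 50, 50), pd), "no segmentation")
})

test_that("dark-ring polarity segments the phase ring at its location", {
  pre <- preprocess(scene$image, phase_ring_params())
  mask <- segment_ring(pre, phase_ring_params())
  found <- find_ring_contour(mask, phase_ring_params())
  fit <- fit_ellipse(found$contour, scale = 0.2)
  expect_lt(sqrt(sum((fit$center - scene_truth$phase_ring_center * 0.2)^2)), 3)
})

test_that("roundness follows 4*pi*A/P^2: circles pass, squares are rejected", {
  m <- disc_mask(201, c(101, 101), 70)
  p <- detector_params(downscale = 1, min_area = 100, min_roundness = 0.85)
  found <- find_ring_contour(m, p)
  expect_equal(found$stats$roundness, 1, tolerance = 0.05)
  # Eq-1 oracle: recompute from the stored A and P, and independently from
  # the contour's convex outline
  expect_identical(found$stats$roundness,
                   4 * pi * found$stats$area / found$stats$perimeter^2)
  hull <- found$contour[chull(found$contour), ]
  expect_equal(4 * pi * shoelace(hull) / perim(hull)^2, found$stats$roundness,
               tolerance = 1e-12)

  sq <- matrix(FALSE, 201, 201); sq[51:150, 51:150] <- TRUE
  st <- contour_stats(find_ring_contour(sq, detector_params(
    downscale = 1, min_area = 100, min_roundness = 0.1))$contour)
  expect_equal(st$roundness, pi / 4, tolerance = 0.03 / (pi / 4))
  expect_error(find_ring_contour(sq, p), "no ring found")
})

test_that("small reflection discs below min_area are ignored", {
  m <- disc_mask(301, c(151, 151), 80)
  for (c0 in list(c(30, 30), c(270, 40), c(40, 270))) {
    m <- m | disc_mask(301, c0, 8)
  }
  p <- detector_params(downscale = 1, min_area = 1000, min_roundness = 0.85)
  found <- find_ring_contour(m, p)
  expect_equal(found$stats$area, pi * 80^2, tolerance = 0.02)
})

test_that("ellipse fit is exact on noise-free conic data", {
  f1 <- fit_ellipse(circle_points(c(100, 80), 40))
  expect_equal(f1$center, c(100, 80), tolerance = 0.5 / 100)
  expect_equal(c(f1$semi_major, f1$semi_minor), c(40, 40), tolerance = 0.0125)

  th <- seq(0, 2 * pi, length.out = 121)[-121]
  f2 <- fit_ellipse(cbind(60 * cos(th), 40 * sin(th)))
  expect_lt(sqrt(sum(f2$center^2)), 0.5)
  expect_equal(c(f2$semi_major, f2$semi_minor), c(60, 40), tolerance = 0.0125)
})

test_that("ellipse fit rejects degenerate input", {
  expect_error(fit_ellipse(circle_points(c(0, 0), 10)[1:4, ]), "fit failed")
  line <- cbind(1:30, 2 * (1:30) + 1)
  expect_error(fit_ellipse(line), "fit failed")
})

test_that("convex hull restores support when a bite is removed from the band", {
  th <- seq(0, 2 * pi, length.out = 241)[-241]
  pts <- cbind(120 + 55 * cos(th), 110 + 45 * sin(th))
  full <- fit_ellipse(pts)
  bitten <- pts[th < 3 * pi / 2, ]  # quarter of the ellipse missing
  part <- fit_ellipse(bitten)
  expect_lt(sqrt(sum((part$center - full$center)^2)), 2)
})

test_that("detect_offset recovers known offsets at the analysis scale", {
  off <- detect_offset(scene$image,
                       phase_ring_center = scene_truth$phase_ring_center)
  expect_equal(off$scale, 0.2)
  expect_lt(sqrt(sum((off$delta_d - c(30, -12))^2)), 3)
  expect_equal(offset_full_resolution(off), off$delta_d / 0.2)

  # self-contained variant: phase ring detected from the same image
  off2 <- detect_offset(scene$image)
  expect_lt(sqrt(sum((off2$delta_d - c(30, -12))^2)), 3)

  conc <- generate_bertrand_image(bertrand_truth(), seed = 2)
  off0 <- detect_offset(conc$image, phase_ring_center = c(480, 400))
  expect_lt(sqrt(sum(off0$delta_d^2)), 2)

  expect_error(detect_offset(matrix(0, 400, 400)), "annulus")
})

test_that("detection is equivariant to integer scene translations", {
  m0 <- meniscus_model(noise_sigma = 0)
  shift <- c(40, -25)  # px, full resolution
  t1 <- bertrand_truth(offset = c(60, 25))
  t2 <- bertrand_truth(offset = c(60, 25),
                       phase_ring_center = t1$phase_ring_center + shift)
  f1 <- detect_ring(generate_bertrand_image(t1, m0)$image, annulus_params())
  f2 <- detect_ring(generate_bertrand_image(t2, m0)$image, annulus_params())
  expect_lt(max(abs(f2$center - (f1$center + shift * 0.2))), 1)
})

test_that("distractors and analysis scale do not distort the detected center", {
  tr <- bertrand_truth(offset = c(80, 40))
  m0 <- meniscus_model(noise_sigma = 0)
  clean <- generate_bertrand_image(tr, m0, distractors = 0, seed = 11)
  noisy <- generate_bertrand_image(tr, m0, distractors = 5, seed = 11)
  d_clean <- detect_offset(clean$image,
                           phase_ring_center = tr$phase_ring_center)$delta_d
  d_noisy <- detect_offset(noisy$image,
                           phase_ring_center = tr$phase_ring_center)$delta_d
  expect_lt(sqrt(sum((d_clean - d_noisy)^2)), 1)

  # scale bookkeeping: analysis-scale center / downscale matches a
  # full-resolution detection within 1/downscale px
  full <- detect_ring(clean$image, annulus_params(downscale = 1))
  scaled <- detect_ring(clean$image, annulus_params(downscale = 0.2))
  expect_lt(sqrt(sum((scaled$center / 0.2 - full$center)^2)), 1 / 0.2)
})

test_that("benchmark error statistics match an independent summary oracle", {
  bm <- run_benchmark(n = 12, offset_range = 50, distractors = 2, seed = 31)
  err <- bm$results$error_px
  expect_identical(bm$summary$median, median(err))
  expect_identical(bm$summary$mean, mean(err))
  expect_identical(bm$summary$sd, sd(err))
  expect_equal(bm$summary$frac_within_margin, mean(err <= 15))

  single <- run_benchmark(n = 1, offset_range = 0, distractors = 0,
                          noise_sigma = 0, seed = 1)
  expect_lt(single$results$error_px, 2)
})
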