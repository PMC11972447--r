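#' Parametric meniscus model
#'
#' Phenomenological model of the meniscus effect in a microtiter-plate well:
#' the curved liquid surface refracts the illumination, so the image of the
#' condenser annulus seen through the Bertrand lens is displaced radially
#' outward and slightly distorted as the imaged position moves from the well
#' center toward the rim. The model also fixes the gray levels used by the
#' synthetic image generators.
#'
#' The radial displacement law is linear, `s(r) = shift_gain * r * r_hat`,
#' the simplest monotone model consistent with a linear compensation mapping;
#' the axis ratio of the distorted annulus decays linearly with radius.
#'
#' @param shift_gain annulus displacement in Bertrand pixels per mm of radial
#'   distance from the well center.
#' @param well_radius well radius in mm (MTP-24 wells are ~7.8 mm).
#' @param distortion_gain reduction of the annulus axis ratio per mm of radial
#'   distance (dimensionless per mm).
#' @param brightfield_gray gray level (0-255) of brightfield background and of
#'   the bright condenser-annulus band.
#' @param phase_gray gray level (0-255) of the dark phase-contrast background.
#' @param noise_sigma standard deviation of additive Gaussian pixel noise in
#'   gray levels.
#' @return an object of class `meniscus_model`.
#' @export
meniscus_model <- function(shift_gain = 15, well_radius = 7.8,
                           distortion_gain = 0.02,
                           brightfield_gray = 220, phase_gray = 70,
                           noise_sigma = 3) {
  stopifnot(shift_gain >= 0, well_radius > 0, distortion_gain >= 0,
            noise_sigma >= 0)
  if (!(phase_gray >= 0 && phase_gray < brightfield_gray &&
        brightfield_gray <= 255)) {
    stop("gray levels must satisfy 0 <= phase_gray < brightfield_gray <= 255")
  }
  structure(
    list(shift_gain = shift_gain, well_radius = well_radius,
         distortion_gain = distortion_gain,
         brightfield_gray = brightfield_gray, phase_gray = phase_gray,
         noise_sigma = noise_sigma),
    class = "meniscus_model"
  )
}

#' Meniscus-induced annulus displacement at a well position
#'
#' @param model a [meniscus_model()].
#' @param position_mm numeric pair, position relative to the well center (mm).
#' @return list with `shift_px` (x, y displacement of the annulus image in
#'   Bertrand pixels) and `axis_ratio` of the distorted annulus.
#' @export
meniscus_displacement <- function(model, position_mm) {
  stopifnot(inherits(model, "meniscus_model"), length(position_mm) == 2)
  r <- sqrt(sum(position_mm^2))
  shift <- if (r == 0) c(0, 0) else model$shift_gain * r * (position_mm / r)
  list(shift_px = shift,
       axis_ratio = max(0.5, 1 - model$distortion_gain * r))
}

#' Ground truth for a synthetic Bertrand-lens image
#'
#' Describes the pupil-plane scene: the fixed dark phase ring and the bright
#' condenser annulus, whose center is displaced from the phase-ring center by
#' `offset` pixels (the quantity the detection pipeline must recover).
#'
#' @param offset numeric pair, annulus center minus phase-ring center (px).
#' @param width,height image dimensions in px.
#' @param phase_ring_center numeric pair (px); defaults to the image center.
#' @param phase_ring_radii inner/outer radius of the dark phase-ring band (px).
#' @param annulus_radii inner/outer radius of the bright annulus band (px).
#' @param axis_ratio minor/major axis ratio of the (meniscus-distorted)
#'   annulus, in (0, 1]; the minor axis lies along the offset direction.
#' @return an object of class `bertrand_truth`.
#' @export
bertrand_truth <- function(offset = c(0, 0), width = 960, height = 800,
                           phase_ring_center = c(width / 2, height / 2),
                           phase_ring_radii = c(120, 160),
                           annulus_radii = c(130, 150),
                           axis_ratio = 1) {
  stopifnot(length(offset) == 2, width > 0, height > 0,
            length(annulus_radii) == 2, annulus_radii[1] < annulus_radii[2],
            phase_ring_radii[1] < phase_ring_radii[2],
            axis_ratio > 0, axis_ratio <= 1)
  structure(
    list(width = width, height = height,
         phase_ring_center = as.numeric(phase_ring_center),
         annulus_center = as.numeric(phase_ring_center) + as.numeric(offset),
         offset = as.numeric(offset),
         phase_ring_radii = as.numeric(phase_ring_radii),
         annulus_radii = as.numeric(annulus_radii),
         axis_ratio = axis_ratio,
         incomplete_ring = FALSE),
    class = "bertrand_truth"
  )
}

# Soft band membership: 1 inside [r_in, r_out], error-function edges of
# `softness` px so segmentation is not trivially hard-edged.
band_weight <- function(r, r_in, r_out, softness = 2) {
  a <- (r - r_in) / softness
  b <- (r_out - r) / softness
  w <- (a > 0 & b > 0) * 1  # preserves dim attributes
  sel <- abs(a) < 8 | abs(b) < 8  # pnorm saturates beyond +/-8 sd
  w[sel] <- pnorm(a[sel]) * pnorm(b[sel])
  w
}

#' Generate a synthetic Bertrand-lens image
#'
#' Renders the pupil image seen through the Bertrand lens: a dark phase-ring
#' band on a mid-gray background and a bright, possibly elliptical condenser
#' annulus band whose center is offset per the ground truth. Optional bright
#' disc "reflections" outside the annulus emulate false-positive sources, and
#' additive Gaussian noise is applied. Output pixels are rounded to integer
#' gray levels so that fixed seeds give byte-identical images.
#'
#' @param truth a [bertrand_truth()].
#' @param model a [meniscus_model()] (supplies annulus intensity and noise).
#' @param distractors number of reflection discs to add outside the annulus.
#' @param seed integer seed; identical seeds yield identical images.
#' @param background_gray gray level of the open pupil background.
#' @param ring_gray gray level of the dark phase-ring band.
#' @return list with `image` (matrix, 0-255) and `truth` (the input ground
#'   truth, with `incomplete_ring` set when the annulus extends beyond the
#'   frame).
#' @export
generate_bertrand_image <- function(truth, model = meniscus_model(),
                                    distractors = 0, seed = NULL,
                                    background_gray = 140, ring_gray = 50) {
  stopifnot(inherits(truth, "bertrand_truth"), distractors >= 0)
  w <- truth$width; h <- truth$height
  if (w <= 0 || h <= 0) stop("image dimensions must be positive")
  with_seed(seed, {
    g <- pixel_grid(w, h)

    # dark phase ring on the background
    rp <- sqrt((g$x - truth$phase_ring_center[1])^2 +
               (g$y - truth$phase_ring_center[2])^2)
    wp <- band_weight(rp, truth$phase_ring_radii[1], truth$phase_ring_radii[2])
    img <- background_gray + wp * (ring_gray - background_gray)

    # bright annulus band, compressed along the offset direction
    dx <- g$x - truth$annulus_center[1]
    dy <- g$y - truth$annulus_center[2]
    off <- truth$offset
    u_hat <- if (sum(off^2) == 0) c(1, 0) else off / sqrt(sum(off^2))
    u <- dx * u_hat[1] + dy * u_hat[2]
    v <- -dx * u_hat[2] + dy * u_hat[1]
    r_eff <- sqrt((u / truth$axis_ratio)^2 + v^2)
    wa <- band_weight(r_eff, truth$annulus_radii[1], truth$annulus_radii[2])
    img <- img + wa * (model$brightfield_gray - img)

    # reflection distractors: bright discs outside the annulus
    if (distractors > 0) {
      r_out <- truth$annulus_radii[2]
      for (i in seq_len(distractors)) {
        repeat {
          disc_r <- runif(1, 5, 15)
          cx <- runif(1, 1 + disc_r, w - disc_r)
          cy <- runif(1, 1 + disc_r, h - disc_r)
          if (sqrt((cx - truth$annulus_center[1])^2 +
                   (cy - truth$annulus_center[2])^2) > r_out + disc_r + 10) {
            break
          }
        }
        rd <- sqrt((g$x - cx)^2 + (g$y - cy)^2)
        wd <- pnorm((disc_r - rd) / 2)
        img <- img + wd * (model$brightfield_gray - img)
      }
    }

    if (model$noise_sigma > 0) {
      img <- img + rnorm(length(img), 0, model$noise_sigma)
    }

    # flag an annulus that does not fit the frame
    ext <- truth$annulus_radii[2]
    if (truth$annulus_center[1] - ext < 1 || truth$annulus_center[1] + ext > w ||
        truth$annulus_center[2] - ext < 1 || truth$annulus_center[2] + ext > h) {
      truth$incomplete_ring <- TRUE
    }

    list(image = round(clamp8(img)), truth = truth)
  })
}

#' Generate synthetic calibration pairs
#'
#' Emulates the calibration experiment relating the observed annulus
#' displacement in Bertrand pixels to the LCD annulus position in mm: pairs
#' obey the linear law `p = k_true * delta_d + p0_true` exactly before
#' independent Gaussian noise is added to both the observed offset and the
#' recorded position.
#'
#' @param k_true true scaling factor (mm per px).
#' @param p0_true true default LCD position (mm pair).
#' @param n number of pairs (>= 2).
#' @param noise_sigma_d noise on observed offsets (px, per coordinate).
#' @param noise_sigma_p noise on recorded positions (mm, per coordinate).
#' @param seed integer seed.
#' @param offset_range offsets are drawn uniformly in `[-offset_range,
#'   offset_range]` px per axis.
#' @return tibble with columns `dx_px`, `dy_px`, `px_mm`, `py_mm`.
#' @export
generate_calibration_pairs <- function(k_true, p0_true = c(0, 0), n = 20,
                                       noise_sigma_d = 0, noise_sigma_p = 0,
                                       seed = NULL, offset_range = 200) {
  if (n < 2) stop("at least 2 calibration pairs are required")
  stopifnot(k_true > 0, length(p0_true) == 2)
  with_seed(seed, {
    dx <- runif(n, -offset_range, offset_range)
    dy <- runif(n, -offset_range, offset_range)
    px <- k_true * dx + p0_true[1]
    py <- k_true * dy + p0_true[2]
    tibble::tibble(
      dx_px = dx + rnorm(n, 0, noise_sigma_d),
      dy_px = dy + rnorm(n, 0, noise_sigma_d),
      px_mm = px + rnorm(n, 0, noise_sigma_p),
      py_mm = py + rnorm(n, 0, noise_sigma_p)
    )
  })
}

#' Generate a synthetic full-well mosaic image
#'
#' Renders a circular well whose background is near `phase_gray` inside a
#' centered disc covering `truth_fraction` of the well area (where phase
#' contrast holds) and ramps to `brightfield_gray` over a narrow logistic
#' transition band placed just outside that disc; regions outside the well
#' circle are brightfield. Optional cell-like speckle texture is overlaid,
#' stronger in the phase-contrast region where cells are visible with high
#' contrast.
#'
#' @param truth_fraction target phase-contrast area fraction, in (0, 1].
#' @param model a [meniscus_model()] (gray levels and noise).
#' @param texture add cell-like speckle texture?
#' @param seed integer seed.
#' @param size mosaic side length in px (square image).
#' @param well_radius well radius in px; defaults to 0.475 * size.
#' @return list with `image` and `truth`, the latter an object of class
#'   `well_truth` carrying `well_center`, `well_radius`, the ground-truth
#'   `phase_mask` and the pixel-counted `true_fraction`.
#' @export
generate_well_mosaic <- function(truth_fraction, model = meniscus_model(),
                                 texture = FALSE, seed = NULL,
                                 size = 2000, well_radius = NULL) {
  if (!(truth_fraction > 0 && truth_fraction <= 1)) {
    stop("truth_fraction must lie in (0, 1]")
  }
  R <- if (is.null(well_radius)) 0.475 * size else well_radius
  stopifnot(R > 0, 2 * R <= size)
  with_seed(seed, {
    ctr <- c(size / 2, size / 2)
    g <- pixel_grid(size, size)
    r <- sqrt((g$x - ctr[1])^2 + (g$y - ctr[2])^2)

    r_ph <- R * sqrt(truth_fraction)
    # transition band just outside the phase disc: logistic ramp whose
    # 10-90% width is 5% of the well radius
    s <- 0.05 * R / (2 * log(9))
    w_bright <- stats::plogis((r - (r_ph + 0.025 * R)) / s)
    img <- model$phase_gray + (model$brightfield_gray - model$phase_gray) * w_bright

    if (texture) {
      speckle <- blurred_noise_field(size, size, sigma = 1.5)
      amp <- 14 * (1 - w_bright) + 6 * w_bright
      img <- img + speckle * amp
    }

    img[r > R] <- model$brightfield_gray
    if (model$noise_sigma > 0) {
      img <- img + rnorm(length(img), 0, model$noise_sigma)
    }
    img <- round(clamp8(img))

    mask <- r <= r_ph
    truth <- structure(
      list(mosaic_size = size, well_center = ctr, well_radius = R,
           phase_mask = mask,
           true_fraction = sum(mask & r <= R) / (pi * R^2)),
      class = "well_truth"
    )
    list(image = img, truth = truth)
  })
}

# Unit-variance smooth noise field (cell-like speckle), width x height.
blurred_noise_field <- function(width, height, sigma) {
  noise <- matrix(rnorm(width * height), height, width)
  sm <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(noise)),
                                            sigma = sigma)))
  sm / sd(sm)
}

# Fraction of the annulus band still overlapping the phase-ring band when the
# annulus image is displaced by d px; evaluated on a polar sample of the band.
ring_overlap_fraction <- function(d, phase_ring_radii = c(120, 160),
                                  annulus_radii = c(130, 150)) {
  radii <- seq(annulus_radii[1], annulus_radii[2], length.out = 15)
  theta <- seq(0, 2 * pi, length.out = 181)[-181]
  pts_x <- outer(radii, cos(theta)) + d
  pts_y <- outer(radii, sin(theta))
  rr <- sqrt(pts_x^2 + pts_y^2)
  mean(rr >= phase_ring_radii[1] & rr <= phase_ring_radii[2])
}

#' Simulate an annulus displacement sweep
#'
#' Emulates the characterization experiment in which the virtual condenser
#' annulus is shifted stepwise on the LCD while specimen and Bertrand images
#' are recorded. As the annulus/phase-ring overlap shrinks, undeviated light
#' bypasses the phase ring: the specimen background brightens toward
#' brightfield and the specimen contrast (hence Tenengrad sharpness) drops.
#' The same seeded specimen texture is reused at every step so the sweep
#' varies only through the overlap.
#'
#' @param model a [meniscus_model()].
#' @param shift_steps LCD shifts in mm (non-empty; typically starting at 0).
#' @param seed integer seed.
#' @param k_mm_per_px optical scaling between LCD mm and Bertrand px.
#' @param specimen_size specimen image width/height in px.
#' @return tibble with columns `shift_mm`, `displacement_px`, `overlap`,
#'   and list-columns `specimen` and `bertrand` holding the image matrices.
#' @export
simulate_displacement_sweep <- function(model = meniscus_model(),
                                        shift_steps = seq(0, 1.5, by = 0.25),
                                        seed = NULL, k_mm_per_px = 0.0113,
                                        specimen_size = c(400, 300)) {
  if (length(shift_steps) < 1) stop("shift_steps must be non-empty")
  stopifnot(k_mm_per_px > 0)
  with_seed(seed, {
    w <- specimen_size[1]; h <- specimen_size[2]
    speckle <- blurred_noise_field(w, h, sigma = 2)

    rows <- lapply(shift_steps, function(shift) {
      d <- shift / k_mm_per_px
      omega <- ring_overlap_fraction(d)
      base <- model$phase_gray +
        (model$brightfield_gray - model$phase_gray) * (1 - omega)
      amp <- 2 + 18 * omega
      specimen <- base + amp * speckle
      if (model$noise_sigma > 0) {
        specimen <- specimen + rnorm(w * h, 0, model$noise_sigma)
      }
      specimen <- round(clamp8(specimen))
      bert <- generate_bertrand_image(bertrand_truth(offset = c(d, 0)), model)
      list(shift_mm = shift, displacement_px = d, overlap = omega,
           specimen = specimen, bertrand = bert$image)
    })
    tibble::tibble(
      shift_mm = vapply(rows, `[[`, numeric(1), "shift_mm"),
      displacement_px = vapply(rows, `[[`, numeric(1), "displacement_px"),
      overlap = vapply(rows, `[[`, numeric(1), "overlap"),
      specimen = lapply(rows, `[[`, "specimen"),
      bertrand = lapply(rows, `[[`, "bertrand")
    )
  })
}
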