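#' Detector parameter set
#'
#' Parameters of the classical ring-detection pipeline. Distinct parameter
#' sets are used for the bright condenser annulus and the dark phase ring;
#' [annulus_params()] and [phase_ring_params()] supply tuned presets.
#'
#' @param downscale analysis downscale factor in (0, 1]; detection runs and
#'   reports coordinates at this scale (default 0.2, i.e. 20% of full size).
#' @param clahe_clip CLAHE clip limit; `0` disables CLAHE.
#' @param clahe_tiles CLAHE tile grid size (tiles per image side).
#' @param binary_threshold segmentation threshold on the 0-255 scale, applied
#'   after CLAHE (and after inversion for dark-ring polarity).
#' @param min_area,max_area accepted contour area range in px^2 at analysis
#'   scale.
#' @param min_roundness minimum accepted contour roundness `4*pi*A/P^2`.
#' @param polarity `"bright"` for the annulus (bright band on darker
#'   background) or `"dark"` for the phase ring (dark band, inverted before
#'   thresholding so both share one code path).
#' @return an object of class `detector_params`.
#' @export
detector_params <- function(downscale = 0.2, clahe_clip = 2, clahe_tiles = 8,
                            binary_threshold = 190, min_area = 300,
                            max_area = 1e5, min_roundness = 0.7,
                            polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  stopifnot(downscale > 0, downscale <= 1, min_area < max_area,
            min_roundness > 0, min_roundness <= 1,
            binary_threshold >= 0, binary_threshold <= 255)
  structure(
    list(downscale = downscale, clahe_clip = clahe_clip,
         clahe_tiles = clahe_tiles, binary_threshold = binary_threshold,
         min_area = min_area, max_area = max_area,
         min_roundness = min_roundness, polarity = polarity),
    class = "detector_params"
  )
}

#' @rdname detector_params
#' @param ... overrides passed on to [detector_params()].
#' @export
annulus_params <- function(...) {
  detector_params(polarity = "bright", binary_threshold = 190, ...)
}

#' @rdname detector_params
#' @export
phase_ring_params <- function(...) {
  detector_params(polarity = "dark", binary_threshold = 130, ...)
}

#' Preprocess a Bertrand-lens image
#'
#' Downscales the image to the analysis scale (to cut computation time) and
#' applies contrast-limited adaptive histogram equalization to lift contrast
#' in regions darkened by the phase ring. With `downscale = 1` and
#' `clahe_clip = 0` the input is returned unchanged.
#'
#' @param image grayscale image matrix (0-255).
#' @param params a [detector_params()].
#' @return preprocessed grayscale image at analysis scale.
#' @export
preprocess <- function(image, params = annulus_params()) {
  stopifnot(is.matrix(image), length(image) > 0)
  w <- floor(params$downscale * img_width(image))
  h <- floor(params$downscale * img_height(image))
  if (min(w, h) < 16) stop("downscaled image smaller than 16 px")
  img <- image
  if (params$downscale < 1) {
    img <- from_ebimage(EBImage::resize(to_ebimage(image), w = w, h = h))
  }
  if (params$clahe_clip > 0 && diff(range(img)) > 0) {
    img <- from_ebimage(EBImage::clahe(to_ebimage(img),
                                       nx = params$clahe_tiles,
                                       ny = params$clahe_tiles,
                                       limit = params$clahe_clip))
  }
  clamp8(img)
}

#' Segment the ring as a binary mask
#'
#' Applies a binary threshold to isolate a continuous ring band. Dark-ring
#' polarity inverts the image first, so the dark phase ring and the bright
#' condenser annulus share one segmentation path.
#'
#' @inheritParams preprocess
#' @return logical matrix, `TRUE` on ring foreground.
#' @export
segment_ring <- function(image, params = annulus_params()) {
  stopifnot(is.matrix(image))
  img <- if (params$polarity == "dark") 255 - image else image
  mask <- img >= params$binary_threshold
  if (!any(mask) || all(mask)) stop("no segmentation: mask empty or full")
  mask
}

#' Contour shape statistics
#'
#' Area, perimeter and roundness `o = 4*pi*A/P^2` of a closed contour.
#' Statistics are computed on the convex outline of the contour (the exact
#' polygon through the convex hull of its points): chain-code step lengths
#' systematically overestimate perimeters of digitized curves, whereas the
#' hull polygon yields `o -> 1` for discrete circles and exactly `pi/4` for
#' squares, as the roundness filter requires.
#'
#' @param contour two-column (x, y) matrix of contour points.
#' @return object of class `contour_stats` with fields `area`, `perimeter`,
#'   `roundness`.
#' @export
contour_stats <- function(contour) {
  stopifnot(is.matrix(contour), ncol(contour) == 2, nrow(contour) >= 3)
  hull <- contour[grDevices::chull(contour), , drop = FALSE]
  A <- polygon_area(hull)
  P <- polygon_perimeter(hull)
  structure(list(area = A, perimeter = P, roundness = 4 * pi * A / P^2),
            class = "contour_stats")
}

#' Find the ring contour in a binary mask
#'
#' Labels connected components, fills holes, extracts each component's outer
#' boundary (Suzuki-style border following), and filters candidates on area
#' and roundness to reject reflections and noise; among the survivors the
#' largest-area contour is returned, the true ring being the dominant
#' structure in the pupil image.
#'
#' @param mask logical matrix from [segment_ring()].
#' @param params a [detector_params()].
#' @return list with `contour` (two-column (x, y) matrix of outer-boundary
#'   pixel centers, 1-based) and `stats` (a [contour_stats()] object).
#' @export
find_ring_contour <- function(mask, params = annulus_params()) {
  stopifnot(is.matrix(mask))
  labels <- EBImage::bwlabel(EBImage::Image(t(mask) * 1))
  labels <- EBImage::fillHull(labels)
  counts <- tabulate(as.integer(EBImage::imageData(labels)))
  # cheap pixel-count prefilter before polygon statistics
  cand <- which(counts >= params$min_area / 2 & counts <= params$max_area * 2)
  if (length(cand) == 0) stop("no ring found: no contour passes the filters")
  contours <- EBImage::ocontour(labels)

  best <- NULL
  for (id in cand) {
    pts <- contours[[id]] + 1  # 0-based EBImage coords -> 1-based (x, y)
    if (nrow(pts) < 3) next
    st <- contour_stats(pts)
    if (st$area < params$min_area || st$area > params$max_area) next
    if (st$roundness < params$min_roundness || st$roundness > 1.1) next
    if (is.null(best) || st$area > best$stats$area) {
      best <- list(contour = pts, stats = st)
    }
  }
  if (is.null(best)) stop("no ring found: no contour passes the filters")
  best
}

# Taubin approximate mean-square algebraic conic fit. Points are normalized
# isotropically, the gradient-weighted eigenproblem is solved in the reduced
# 5x5 form, and ellipse parameters are mapped back to the original frame.
taubin_conic <- function(pts) {
  n <- nrow(pts)
  m <- colMeans(pts)
  s <- sqrt(mean((pts[, 1] - m[1])^2 + (pts[, 2] - m[2])^2))
  if (s == 0) stop("fit failed: degenerate point set")
  x <- (pts[, 1] - m[1]) / s
  y <- (pts[, 2] - m[2]) / s

  Z <- cbind(x^2, x * y, y^2, x, y, 1)
  M <- crossprod(Z) / n

  # N = (1/n) sum (grad_x q)(grad_x q)' + (grad_y q)(grad_y q)'
  Px <- cbind(2 * x, y, 0, 1, 0, 0)
  Py <- cbind(0, x, 2 * y, 0, 1, 0)
  N <- (crossprod(Px) + crossprod(Py)) / n

  M5 <- M[1:5, 1:5] - tcrossprod(M[1:5, 6], M[6, 1:5]) / M[6, 6]
  N5 <- N[1:5, 1:5]
  R <- tryCatch(chol(N5), error = function(e) stop("fit failed: degenerate geometry"))
  Ri <- backsolve(R, diag(5))
  B <- t(Ri) %*% M5 %*% Ri
  ev <- eigen((B + t(B)) / 2, symmetric = TRUE)
  v <- ev$vectors[, 5]
  a5 <- Ri %*% v
  a6 <- -sum(M[6, 1:5] * a5) / M[6, 6]
  coefs <- c(a5, a6)  # conic in normalized frame
  list(coefs = coefs, center = m, scale = s)
}

conic_to_ellipse <- function(coefs) {
  a <- coefs[1]; b <- coefs[2]; cc <- coefs[3]
  d <- coefs[4]; e <- coefs[5]; f <- coefs[6]
  disc <- b^2 - 4 * a * cc
  if (!is.finite(disc) || disc >= 0) stop("fit failed: not an ellipse")
  xc <- (2 * cc * d - b * e) / disc
  yc <- (2 * a * e - b * d) / disc
  mu <- a * xc^2 + b * xc * yc + cc * yc^2 + d * xc + e * yc + f
  Q <- matrix(c(a, b / 2, b / 2, cc), 2, 2)
  eQ <- eigen(Q, symmetric = TRUE)
  ax <- -mu / eQ$values
  if (any(ax <= 0)) stop("fit failed: not an ellipse")
  semi <- sqrt(ax)  # paired with eQ$values (decreasing): smaller value -> major
  major_i <- which.max(semi)
  vmax <- eQ$vectors[, major_i]
  list(center = c(xc, yc),
       semi_major = max(semi), semi_minor = min(semi),
       orientation = atan2(vmax[2], vmax[1]) %% pi)
}

#' Fit an ellipse to a ring contour
#'
#' Computes the convex hull of the contour first — restoring support where
#' the band is dimmed or bitten — then fits an ellipse to the hull points by
#' Taubin's approximate mean-square algebraic criterion. The fit is exact on
#' noise-free conic data.
#'
#' @param contour two-column (x, y) matrix with at least 5 points.
#' @param stats optional [contour_stats()] to attach to the fit.
#' @param scale analysis downscale factor recorded in the fit (bookkeeping).
#' @return object of class `ring_fit` with fields `center`, `semi_major`,
#'   `semi_minor`, `orientation` (radians), `stats`, `scale`.
#' @export
fit_ellipse <- function(contour, stats = NULL, scale = 1) {
  if (!is.matrix(contour) || ncol(contour) != 2 || nrow(contour) < 5) {
    stop("fit failed: at least 5 contour points required")
  }
  hull <- contour[grDevices::chull(contour), , drop = FALSE]
  pts <- if (nrow(hull) >= 5) hull else contour
  fit <- taubin_conic(pts)
  ell <- conic_to_ellipse(fit$coefs)
  structure(
    list(center = fit$center + fit$scale * ell$center,
         semi_major = fit$scale * ell$semi_major,
         semi_minor = fit$scale * ell$semi_minor,
         orientation = ell$orientation,
         stats = stats, scale = scale),
    class = "ring_fit"
  )
}

#' Detect one ring in a Bertrand image
#'
#' Runs the full pipeline — preprocess, segment, contour filter, ellipse fit
#' — for a single parameter set.
#'
#' @inheritParams preprocess
#' @return a `ring_fit` whose `center` is at the analysis scale.
#' @export
detect_ring <- function(image, params = annulus_params()) {
  pre <- preprocess(image, params)
  mask <- segment_ring(pre, params)
  found <- find_ring_contour(mask, params)
  fit_ellipse(found$contour, stats = found$stats, scale = params$downscale)
}

#' Detect the annulus/phase-ring offset
#'
#' Determines the displacement between the condenser-annulus center and the
#' phase-ring center in a Bertrand-lens image. The phase-ring center is
#' typically detected once during calibration (from a white-screen image)
#' and supplied here in full-resolution pixels; when absent it is detected
#' from this image with the dark-ring parameter set.
#'
#' @param bertrand grayscale Bertrand-lens image (0-255 matrix).
#' @param annulus,phase_ring [detector_params()] for the bright annulus and
#'   the dark phase ring.
#' @param phase_ring_center optional (x, y) phase-ring center in
#'   full-resolution pixels.
#' @return object of class `ring_offset` with fields `delta_d` (annulus
#'   center minus phase-ring center, px at analysis scale), `scale`, and the
#'   underlying `annulus_fit` (plus `phase_fit` when detected).
#' @export
detect_offset <- function(bertrand, annulus = annulus_params(),
                          phase_ring = phase_ring_params(),
                          phase_ring_center = NULL) {
  ann <- tryCatch(detect_ring(bertrand, annulus),
                  error = function(e) stop("annulus: ", conditionMessage(e)))
  phase_fit <- NULL
  if (is.null(phase_ring_center)) {
    phase_fit <- tryCatch(detect_ring(bertrand, phase_ring),
                          error = function(e) stop("phase ring: ",
                                                   conditionMessage(e)))
    pc <- phase_fit$center
    if (abs(phase_ring$downscale - annulus$downscale) > 1e-12) {
      pc <- pc / phase_ring$downscale * annulus$downscale
    }
  } else {
    pc <- as.numeric(phase_ring_center) * annulus$downscale
  }
  delta <- ann$center - pc
  if (!all(is.finite(delta))) stop("non-finite offset")
  structure(
    list(delta_d = delta, scale = annulus$downscale,
         annulus_fit = ann, phase_fit = phase_fit),
    class = "ring_offset"
  )
}

#' Convert an offset to full-resolution pixels
#'
#' @param offset a `ring_offset`.
#' @return numeric (x, y) pair in full-resolution pixels.
#' @export
offset_full_resolution <- function(offset) {
  stopifnot(inherits(offset, "ring_offset"))
  offset$delta_d / offset$scale
}

#' Benchmark the ring-detection pipeline on synthetic images
#'
#' Generates `n` synthetic Bertrand images with uniformly random annulus
#' offsets and reflection distractors, runs [detect_offset()] on each (the
#' phase-ring center being known from calibration), and summarizes the
#' Euclidean annulus-center errors at the analysis scale against the ground
#' truth, including the fraction of images within the acceptance margin for
#' phase-contrast-preserving misalignment.
#'
#' @param n number of images.
#' @param offset_range offsets drawn uniformly in `[0, offset_range]` px per
#'   axis (full resolution), with random sign.
#' @param distractors maximum number of reflection discs per image (actual
#'   count uniform in `0:distractors`).
#' @param seed integer seed.
#' @param noise_sigma Gaussian pixel noise (gray levels).
#' @param margin acceptance margin in px at analysis scale (default 15).
#' @param annulus,phase_ring detector parameter sets.
#' @return list with `results` (tibble: true/estimated centers and
#'   `error_px`) and `summary` (median, mean, sd, 2.5/97.5 percentiles,
#'   fraction within margin, failure count).
#' @export
run_benchmark <- function(n = 500, offset_range = 60, distractors = 3,
                          seed = NULL, noise_sigma = 5, margin = 15,
                          annulus = annulus_params(),
                          phase_ring = phase_ring_params()) {
  stopifnot(n >= 1)
  with_seed(seed, {
    model <- meniscus_model(noise_sigma = noise_sigma)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      off <- runif(2, 0, offset_range) * sample(c(-1, 1), 2, replace = TRUE)
      truth <- bertrand_truth(offset = off)
      k <- if (distractors > 0) sample(0:distractors, 1) else 0
      gen <- generate_bertrand_image(truth, model, distractors = k)
      est <- tryCatch(
        detect_offset(gen$image, annulus, phase_ring,
                      phase_ring_center = truth$phase_ring_center),
        error = function(e) NULL
      )
      true_scaled <- truth$annulus_center * annulus$downscale
      est_center <- if (is.null(est)) c(NA_real_, NA_real_) else
        est$annulus_fit$center
      rows[[i]] <- c(truth$offset * annulus$downscale, est_center,
                     sqrt(sum((est_center - true_scaled)^2)))
    }
    res <- do.call(rbind, rows)
    results <- tibble::tibble(
      true_dx = res[, 1], true_dy = res[, 2],
      est_x = res[, 3], est_y = res[, 4], error_px = res[, 5]
    )
    err <- results$error_px
    ok <- !is.na(err)
    list(
      results = results,
      summary = list(
        median = median(err[ok]), mean = mean(err[ok]), sd = sd(err[ok]),
        p2.5 = unname(quantile(err[ok], 0.025)),
        p97.5 = unname(quantile(err[ok], 0.975)),
        frac_within_margin = mean(ok & err <= margin),
        margin = margin, n = n, n_failed = sum(!ok)
      )
    )
  })
}
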