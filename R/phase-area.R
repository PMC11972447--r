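#' Relative thresholds for phase-contrast background
#'
#' Derives the gray-value window that qualifies background as phase contrast.
#' The gray value at the image center (where the meniscus is flat and phase
#' contrast must hold) anchors the window; the brightfield level is estimated
#' as the mean of the highest values along the horizontal cross-section
#' through the center. The thresholds are 15% intervals between the two:
#' `t_upper/lower = g_ph +/- 0.15 * (g_br - g_ph)`.
#'
#' @param blurred blurred grayscale image matrix (0-255).
#' @param quantile fraction of the cross-section regarded as "highest values"
#'   when estimating the brightfield gray (default top 10%).
#' @param center optional (x, y) center; defaults to the image center.
#' @param min_contrast minimum `g_br - g_ph` below which no phase/brightfield
#'   distinction exists.
#' @param interval half-width of the threshold window as a fraction of the
#'   phase-to-brightfield gap (default 0.15).
#' @return object of class `threshold_pair` with fields `g_ph`, `g_br`,
#'   `t_upper`, `t_lower`.
#' @export
compute_thresholds <- function(blurred, quantile = 0.1, center = NULL,
                               min_contrast = 10, interval = 0.15) {
  stopifnot(is.matrix(blurred), length(blurred) > 0)
  w <- img_width(blurred); h <- img_height(blurred)
  if (is.null(center)) center <- c(round(w / 2), round(h / 2))
  cx <- round(center[1]); cy <- round(center[2])

  # g_ph: 5x5 neighborhood mean at the center, for noise robustness
  xs <- max(1, cx - 2):min(w, cx + 2)
  ys <- max(1, cy - 2):min(h, cy + 2)
  g_ph <- mean(blurred[ys, xs])

  # g_br: mean of the top fraction of the horizontal center cross-section
  cross <- blurred[cy, ]
  k <- max(1, ceiling(quantile * length(cross)))
  g_br <- mean(sort(cross, decreasing = TRUE)[seq_len(k)])

  if (g_br - g_ph < min_contrast) {
    stop("degenerate contrast: no phase/brightfield distinction (g_br - g_ph = ",
         round(g_br - g_ph, 2), ")")
  }
  threshold_pair(g_ph, g_br, interval = interval)
}

#' @rdname compute_thresholds
#' @param g_ph gray value at the well center (phase-contrast anchor).
#' @param g_br brightfield gray value.
#' @export
threshold_pair <- function(g_ph, g_br, interval = 0.15) {
  stopifnot(is.finite(g_ph), is.finite(g_br), interval > 0)
  structure(
    list(g_ph = g_ph, g_br = g_br,
         t_upper = g_ph + interval * (g_br - g_ph),
         t_lower = g_ph - interval * (g_br - g_ph)),
    class = "threshold_pair"
  )
}

#' Quantify the phase-contrast area of a full-well image
#'
#' Implements the background-brightness area algorithm: scale the mosaic
#' down, blur it with a Gaussian so the local background dominates, derive
#' the relative thresholds, binarize to the pixels within them, erode to
#' sever bridges to peripheral look-alike regions, keep only the most
#' central patch, dilate with the same element to restore it, restrict to
#' the well circle, and report the patch area relative to the well area
#' (a circle of known radius).
#'
#' @param mosaic grayscale full-well image matrix (0-255).
#' @param well_center (x, y) center of the well in `mosaic` pixels; defaults
#'   to the image center.
#' @param well_radius well radius in `mosaic` pixels; defaults to half the
#'   shorter image side minus one pixel.
#' @param blur_sigma Gaussian blur sigma in analysis-scale px.
#' @param morph_frac radius of the disc structuring element used for erosion
#'   and dilation, as a fraction of the well radius.
#' @param max_side the mosaic is downscaled so its longest side does not
#'   exceed this (full-well composites are very large).
#' @param quantile,min_contrast,interval passed to [compute_thresholds()].
#' @return object of class `area_result` with fields `mask` (analysis
#'   scale), `fraction`, `thresholds`, `well_radius_px` (analysis scale),
#'   `scale`.
#' @export
quantify_area <- function(mosaic, well_center = NULL, well_radius = NULL,
                          blur_sigma = 8, morph_frac = 0.02, max_side = 2000,
                          quantile = 0.1, min_contrast = 10, interval = 0.15) {
  stopifnot(is.matrix(mosaic))
  w <- img_width(mosaic); h <- img_height(mosaic)
  if (is.null(well_center)) well_center <- c(w / 2, h / 2)
  if (is.null(well_radius)) well_radius <- min(w, h) / 2 - 1
  if (well_center[1] - well_radius < 0 || well_center[1] + well_radius > w + 1 ||
      well_center[2] - well_radius < 0 || well_center[2] + well_radius > h + 1) {
    stop("well circle must lie within the image")
  }

  scale <- min(1, max_side / max(w, h))
  img <- mosaic
  if (scale < 1) {
    img <- from_ebimage(EBImage::resize(to_ebimage(mosaic),
                                        w = round(w * scale),
                                        h = round(h * scale)))
  }
  ctr <- well_center * scale
  R <- well_radius * scale

  blurred <- from_ebimage(EBImage::gblur(to_ebimage(img), sigma = blur_sigma))
  thr <- compute_thresholds(blurred, quantile = quantile, center = ctr,
                            min_contrast = min_contrast, interval = interval)

  binary <- blurred >= thr$t_lower & blurred <= thr$t_upper

  brush_r <- max(1, round(morph_frac * R))
  brush <- EBImage::makeBrush(2 * brush_r + 1, shape = "disc")
  eb <- EBImage::Image(t(binary) * 1)
  eroded <- EBImage::erode(eb, brush)

  labels <- EBImage::bwlabel(eroded)
  lab <- t(EBImage::imageData(labels))
  cx <- round(ctr[1]); cy <- round(ctr[2])
  central <- lab[cy, cx]
  if (central == 0 && max(lab) > 0) {
    # center pixel eroded away: take the component nearest the center
    g <- pixel_grid(ncol(lab), nrow(lab))
    d2 <- (g$x - ctr[1])^2 + (g$y - ctr[2])^2
    on <- lab > 0
    central <- lab[on][which.min(d2[on])]
  }
  if (central == 0) {
    warning("empty central component: no phase-contrast patch found")
    mask <- matrix(FALSE, nrow(lab), ncol(lab))
  } else {
    keep <- EBImage::Image(t(lab == central) * 1)
    mask <- t(EBImage::imageData(EBImage::dilate(keep, brush))) > 0
  }

  g <- pixel_grid(ncol(mask), nrow(mask))
  in_well <- (g$x - ctr[1])^2 + (g$y - ctr[2])^2 <= R^2
  mask <- mask & in_well

  structure(
    list(mask = mask, fraction = sum(mask) / (pi * R^2),
         thresholds = thr, well_radius_px = R, well_center_px = ctr,
         scale = scale),
    class = "area_result"
  )
}

#' Summarize per-well phase-contrast fractions
#'
#' Builds the per-well comparison between the conventional condenser annulus
#' and the adaptive LCD annulus: fractions, their means and standard
#' deviations, and per-well plus mean adaptive/conventional ratios. Ratios
#' are computed at full precision; round only for display.
#'
#' @param conventional,adaptive numeric vectors of area fractions (either
#'   proportions or percent, used as given) for the same wells.
#' @param wells optional well labels.
#' @return list with `per_well` (tibble: well, conventional, adaptive,
#'   ratio) and `summary` (tibble: means, sds, mean ratio). The spread over
#'   the wells is the population standard deviation (the wells measured are
#'   the wells reported, not a sample). A conventional fraction of zero
#'   yields an `NA` ratio marker.
#' @export
summarize_wells <- function(conventional, adaptive, wells = NULL) {
  stopifnot(length(conventional) >= 1,
            length(conventional) == length(adaptive))
  n <- length(conventional)
  if (is.null(wells)) wells <- as.character(seq_len(n))
  ratio <- ifelse(conventional == 0, NA_real_, adaptive / conventional)
  pop_sd <- function(x) sqrt(mean((x - mean(x, na.rm = TRUE))^2, na.rm = TRUE))
  per_well <- tibble::tibble(
    well = wells,
    conventional = conventional,
    adaptive = adaptive,
    ratio = ratio
  )
  summary <- tibble::tibble(
    statistic = c("mean", "sd"),
    conventional = c(mean(conventional), pop_sd(conventional)),
    adaptive = c(mean(adaptive), pop_sd(adaptive)),
    ratio = c(mean(ratio, na.rm = TRUE), pop_sd(ratio))
  )
  list(per_well = per_well, summary = summary)
}
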