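#' Linear calibration between ring offset and LCD position
#'
#' The optics between the LCD condenser annulus and the phase-ring plane are
#' linear, so the LCD position `p` (mm) that centers the annulus on the phase
#' ring relates to the observed Bertrand-lens displacement `delta_d` (px) by
#' `p = k * delta_d + p0`, where `p0` is the default LCD position with
#' perfect alignment and no meniscus.
#'
#' @param k scaling factor in mm per px (> 0).
#' @param p0 default LCD position, mm pair.
#' @return an object of class `calibration_model`.
#' @export
calibration_model <- function(k, p0 = c(0, 0)) {
  stopifnot(length(p0) == 2, is.finite(k))
  if (k <= 0) stop("inconsistent calibration: k must be positive")
  structure(list(k = k, p0 = as.numeric(p0)), class = "calibration_model")
}

#' Fit the offset-to-position calibration
#'
#' Estimates the scaling factor `k` and the default position `p0` from
#' calibration pairs of observed offsets (px) and LCD positions (mm). Since
#' `k` is identical in the x and y directions, the magnitudes `|p - p0|` are
#' pooled over both axes and regressed on `|delta_d|`. `p0` is taken from a
#' pair recorded at exactly zero offset when one exists, otherwise from the
#' per-axis regression intercepts.
#'
#' @param pairs data frame with columns `dx_px`, `dy_px`, `px_mm`, `py_mm`
#'   (the dialect written by [generate_calibration_pairs()]).
#' @param intercept if `TRUE` (default) the pooled magnitude regression has a
#'   free intercept; if `FALSE` the line is forced through the origin.
#' @param per_axis fit a separate slope per axis (diagnostic only; the model
#'   always carries the pooled `k`).
#' @return a `calibration_model` with `diagnostics` attached: residuals,
#'   `r_squared`, `intercept`, and per-axis slopes when requested.
#' @export
fit_calibration <- function(pairs, intercept = TRUE, per_axis = FALSE) {
  need <- c("dx_px", "dy_px", "px_mm", "py_mm")
  stopifnot(is.data.frame(pairs), all(need %in% names(pairs)))
  d <- cbind(pairs$dx_px, pairs$dy_px)
  p <- cbind(pairs$px_mm, pairs$py_mm)
  if (nrow(unique(round(d, 12))) < 2) {
    stop("underdetermined: at least 2 pairs with distinct offsets required")
  }

  zero <- which(d[, 1] == 0 & d[, 2] == 0)
  if (length(zero) > 0) {
    p0 <- colMeans(p[zero, , drop = FALSE])
  } else {
    p0 <- c(unname(coef(lm(p[, 1] ~ d[, 1]))[1]),
            unname(coef(lm(p[, 2] ~ d[, 2]))[1]))
  }

  dd <- c(abs(d[, 1]), abs(d[, 2]))
  dp <- c(abs(p[, 1] - p0[1]), abs(p[, 2] - p0[2]))
  fit <- if (intercept) lm(dp ~ dd) else lm(dp ~ dd + 0)
  k <- unname(coef(fit)[["dd"]])
  if (!is.finite(k) || k <= 0) stop("inconsistent calibration: fitted k <= 0")

  model <- calibration_model(k, p0)
  res <- unname(stats::residuals(fit))
  ss_tot <- sum((dp - mean(dp))^2)
  model$diagnostics <- list(
    residuals = res,
    r_squared = if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 1,
    intercept = if (intercept) unname(coef(fit)[1]) else 0
  )
  if (per_axis) {
    model$diagnostics$k_axis <- c(
      x = unname(coef(lm(abs(p[, 1] - p0[1]) ~ abs(d[, 1]) + 0))[1]),
      y = unname(coef(lm(abs(p[, 2] - p0[2]) ~ abs(d[, 2]) + 0))[1])
    )
  }
  model
}

#' Map an observed offset to a corrective LCD position
#'
#' Evaluates `p = k * delta_d + p0` componentwise. The offset must be in the
#' pixel scale at which the model was calibrated; a `ring_offset` object is
#' used at its analysis scale (the calibration experiments observe offsets at
#' the same analysis scale as detection).
#'
#' @param offset numeric (x, y) pair in px, or a `ring_offset`.
#' @param model a `calibration_model`.
#' @return LCD position, mm pair.
#' @export
map_offset_to_lcd <- function(offset, model) {
  stopifnot(inherits(model, "calibration_model"))
  d <- if (inherits(offset, "ring_offset")) offset$delta_d else as.numeric(offset)
  if (length(d) != 2 || !all(is.finite(d))) stop("offset must be a finite pair")
  model$k * d + model$p0
}

#' Geometry of the virtual annulus on the LCD
#'
#' @param center annulus center in LCD coordinates, mm pair.
#' @param r_inner,r_outer ring radii in mm (0 < r_inner < r_outer).
#' @param lcd_resolution LCD raster size, px pair (width, height).
#' @param pixel_pitch LCD pixel pitch in mm per px.
#' @return an object of class `annulus_spec`.
#' @export
annulus_spec <- function(center, r_inner, r_outer,
                         lcd_resolution = c(480, 480), pixel_pitch = 0.0805) {
  stopifnot(length(center) == 2, r_inner > 0, r_inner < r_outer,
            length(lcd_resolution) == 2, pixel_pitch > 0)
  structure(
    list(center = as.numeric(center), r_inner = r_inner, r_outer = r_outer,
         lcd_resolution = as.integer(lcd_resolution),
         pixel_pitch = pixel_pitch),
    class = "annulus_spec"
  )
}

#' Render the virtual annulus as an LCD raster
#'
#' Produces the black-and-white matrix shown on the transmissive LCD: white
#' (transmissive) pixels exactly where the distance from the ring center lies
#' within `[r_inner, r_outer]`, black elsewhere. `white_screen = TRUE`
#' returns an all-white raster (brightfield conditions, used to image the
#' phase ring during calibration). No anti-aliasing is applied.
#'
#' @param spec an [annulus_spec()]; ignored when `white_screen = TRUE` except
#'   for the raster size.
#' @param white_screen render a full white screen instead of the ring.
#' @return grayscale image matrix with values 0 or 255.
#' @export
render_annulus_frame <- function(spec, white_screen = FALSE) {
  stopifnot(inherits(spec, "annulus_spec"))
  w <- spec$lcd_resolution[1]; h <- spec$lcd_resolution[2]
  if (white_screen) return(new_image(w, h, 255))
  g <- pixel_grid(w, h)
  r_mm <- sqrt((g$x - spec$center[1] / spec$pixel_pitch)^2 +
               (g$y - spec$center[2] / spec$pixel_pitch)^2) * spec$pixel_pitch
  ring <- r_mm >= spec$r_inner & r_mm <= spec$r_outer
  if (!any(ring)) stop("clipped annulus: ring lies outside the LCD raster")
  new_image(w, h) + ring * 255
}

#' Serialize / restore a calibration model as JSON
#'
#' @param model a `calibration_model`.
#' @param path file path.
#' @return `write_calibration()` returns `path` invisibly;
#'   `read_calibration()` returns a `calibration_model`.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  jsonlite::write_json(list(k_mm_per_px = model$k, p0_mm = model$p0),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_model(obj$k_mm_per_px, obj$p0_mm)
}
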