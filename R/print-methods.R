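#' @export
print.meniscus_model <- function(x, ...) {
  cat("Meniscus model: shift", x$shift_gain, "px/mm, well radius",
      x$well_radius, "mm, distortion", x$distortion_gain, "/mm\n")
  cat("  gray levels: phase", x$phase_gray, "/ brightfield",
      x$brightfield_gray, ", noise sd", x$noise_sigma, "\n")
  invisible(x)
}

#' @export
print.ring_fit <- function(x, ...) {
  cat(sprintf("Ring fit: center (%.2f, %.2f) px, axes %.2f x %.2f px, angle %.1f deg (scale %g)\n",
              x$center[1], x$center[2], x$semi_major, x$semi_minor,
              x$orientation * 180 / pi, x$scale))
  if (!is.null(x$stats)) {
    cat(sprintf("  contour: A = %.1f px^2, P = %.1f px, roundness = %.3f\n",
                x$stats$area, x$stats$perimeter, x$stats$roundness))
  }
  invisible(x)
}

#' @export
print.ring_offset <- function(x, ...) {
  cat(sprintf("Ring offset: delta_d = (%.2f, %.2f) px at scale %g (|delta_d| = %.2f px)\n",
              x$delta_d[1], x$delta_d[2], x$scale, sqrt(sum(x$delta_d^2))))
  invisible(x)
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("Calibration: p = k * delta_d + p0, k = %.5f mm/px, p0 = (%.3f, %.3f) mm\n",
              x$k, x$p0[1], x$p0[2]))
  if (!is.null(x$diagnostics)) {
    cat(sprintf("  fit R^2 = %.4f\n", x$diagnostics$r_squared))
  }
  invisible(x)
}

#' @export
print.threshold_pair <- function(x, ...) {
  cat(sprintf("Thresholds: g_ph = %.1f, g_br = %.1f -> [t_lower, t_upper] = [%.1f, %.1f]\n",
              x$g_ph, x$g_br, x$t_lower, x$t_upper))
  invisible(x)
}

#' @export
print.area_result <- function(x, ...) {
  cat(sprintf("Phase-contrast area: %.1f%% of the well (radius %.0f px at analysis scale %g)\n",
              100 * x$fraction, x$well_radius_px, x$scale))
  print(x$thresholds)
  invisible(x)
}

#' @export
print.tile_plan <- function(x, ...) {
  cat(sprintf("Tile plan: %d tiles, fov %g x %g, overlap %g, well radius %g\n",
              nrow(x$centers), x$fov[1], x$fov[2], x$overlap, x$well_radius))
  invisible(x)
}
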