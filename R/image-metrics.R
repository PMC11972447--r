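#' Tenengrad sharpness
#'
#' Focus/contrast measure: the mean over interior pixels of the squared
#' gradient magnitude from 3x3 horizontal and vertical Sobel operators.
#' Per-pixel normalization makes scores comparable across image sizes. The
#' score is zero for constant images and scales with the square of image
#' contrast.
#'
#' @param image grayscale image matrix (0-255), at least 3x3.
#' @return non-negative sharpness score.
#' @export
tenengrad <- function(image) {
  stopifnot(is.matrix(image), nrow(image) >= 3, ncol(image) >= 3)
  a <- image
  nr <- nrow(a); nc <- ncol(a)
  i <- 2:(nr - 1); j <- 2:(nc - 1)
  # Sobel responses on the interior (rows = y, cols = x)
  gx <- (a[i - 1, j + 1] + 2 * a[i, j + 1] + a[i + 1, j + 1]) -
        (a[i - 1, j - 1] + 2 * a[i, j - 1] + a[i + 1, j - 1])
  gy <- (a[i + 1, j - 1] + 2 * a[i + 1, j] + a[i + 1, j + 1]) -
        (a[i - 1, j - 1] + 2 * a[i - 1, j] + a[i - 1, j + 1])
  mean(gx^2 + gy^2)
}

#' Mean gray value
#'
#' Background-brightness metric: the arithmetic mean intensity over the
#' whole image. Brightness is minimal when the condenser annulus and phase
#' ring overlap and rises as the overlap is lost.
#'
#' @param image grayscale image matrix (0-255).
#' @param background_only reserved for future background masking; the
#'   default whole-image mean matches the metric's definition.
#' @return mean gray value.
#' @export
mean_gray <- function(image, background_only = FALSE) {
  stopifnot(is.matrix(image), length(image) > 0)
  if (background_only) {
    warning("background masking not implemented; using whole image")
  }
  mean(image)
}

#' Compute sweep records from a displacement sweep
#'
#' Evaluates Tenengrad sharpness and mean gray on each specimen image of a
#' sweep (as produced by [simulate_displacement_sweep()]). With
#' `normalize = TRUE` both series are divided by their value at the
#' zero-displacement reference, so the reference record reads 1.0.
#'
#' @param sweep tibble with columns `displacement_px` and list-column
#'   `specimen`.
#' @param normalize normalize both series to the zero-displacement record?
#' @return tibble with columns `displacement_px`, `sharpness`, `mean_gray`.
#' @export
sweep_metrics <- function(sweep, normalize = FALSE) {
  stopifnot(is.data.frame(sweep),
            all(c("displacement_px", "specimen") %in% names(sweep)))
  sharp <- vapply(sweep$specimen, tenengrad, numeric(1))
  gray <- vapply(sweep$specimen, mean_gray, numeric(1))
  if (normalize) {
    ref <- which.min(abs(sweep$displacement_px))
    if (sweep$displacement_px[ref] != 0) {
      warning("no zero-displacement record; normalizing to the smallest")
    }
    sharp <- sharp / sharp[ref]
    gray <- gray / gray[ref]
  }
  tibble::tibble(displacement_px = sweep$displacement_px,
                 sharpness = sharp, mean_gray = gray)
}

#' Pearson correlation of sharpness vs. mean gray over a sweep
#'
#' @param records data frame with columns `sharpness` and `mean_gray`
#'   (>= 3 rows, both with non-zero variance).
#' @return Pearson product-moment correlation coefficient.
#' @export
sweep_correlation <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("sharpness", "mean_gray") %in% names(records)))
  if (nrow(records) < 3) stop("at least 3 records required")
  if (sd(records$sharpness) == 0 || sd(records$mean_gray) == 0) {
    stop("undefined correlation: zero variance in a series")
  }
  cor(records$sharpness, records$mean_gray)
}
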