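#' @importFrom stats coef cor lm median pnorm quantile rnorm runif sd setNames
#' @importFrom utils head tail
NULL

# Image convention used throughout the package:
#   a grayscale image is a numeric matrix indexed [y, x] (row 1 = top),
#   pixel centers at integer coordinates (x, y), x rightward, y downward,
#   gray values on the 8-bit scale 0..255 (stored as doubles).

#' Create a grayscale image matrix
#'
#' @param width,height image dimensions in pixels.
#' @param gray fill value on the 0-255 scale.
#' @return numeric matrix of dimension `height` x `width`.
#' @keywords internal
new_image <- function(width, height, gray = 0) {
  matrix(as.numeric(gray), nrow = height, ncol = width)
}

img_width <- function(img) ncol(img)
img_height <- function(img) nrow(img)

#' Clamp an image to the 8-bit range
#' @keywords internal
clamp8 <- function(img) {
  img[img < 0] <- 0
  img[img > 255] <- 255
  img
}

# Coordinate grids for a height x width image: matrices of pixel-center x and y.
pixel_grid <- function(width, height) {
  list(
    x = matrix(rep(seq_len(width), each = height), nrow = height),
    y = matrix(rep(seq_len(height), times = width), nrow = height)
  )
}

# EBImage stores images as [x, y] in [0, 1]; the package stores [y, x] in 0..255.
to_ebimage <- function(img) EBImage::Image(t(img) / 255)
from_ebimage <- function(eb) t(EBImage::imageData(eb)) * 255

#' Evaluate an expression under a fixed RNG seed, restoring the RNG state
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Read an 8-bit grayscale image from PNG or TIFF
#'
#' @param path file path; format inferred from the extension.
#' @return grayscale image matrix (0-255).
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the 'tiff' package")
    }
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  arr * 255
}

#' Write an image matrix as 8-bit grayscale PNG
#'
#' @param img grayscale image matrix (0-255).
#' @param path output path.
#' @export
write_gray_image <- function(img, path) {
  png::writePNG(clamp8(img) / 255, path)
  invisible(path)
}

# Gaussian blur with replicated-edge padding (avoids FFT wrap-around).
gblur_replicate <- function(img, sigma) {
  pad <- ceiling(3 * sigma)
  r <- c(rep(1, pad), seq_len(nrow(img)), rep(nrow(img), pad))
  cl <- c(rep(1, pad), seq_len(ncol(img)), rep(ncol(img), pad))
  padded <- img[r, cl]
  sm <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(padded)),
                                            sigma = sigma)))
  sm[pad + seq_len(nrow(img)), pad + seq_len(ncol(img))]
}

# Shoelace area of a polygon given as a two-column (x, y) matrix.
polygon_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  n <- nrow(pts)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Perimeter of a closed polygon given as a two-column (x, y) matrix.
polygon_perimeter <- function(pts) {
  d <- pts - pts[c(nrow(pts), seq_len(nrow(pts) - 1)), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}
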