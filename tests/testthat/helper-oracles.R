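# Independent oracles used across test files; deliberately written with
# different primitives than the package internals they check.

# Points sampled exactly on a circle.
circle_points <- function(center, radius, n = 180) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

# Brute-force intensity centroid of pixels above a gray threshold.
bright_centroid <- function(img, threshold) {
  idx <- which(img >= threshold, arr.ind = TRUE)
  wts <- img[idx]
  c(sum(idx[, 2] * wts) / sum(wts), sum(idx[, 1] * wts) / sum(wts))
}

# Shoelace area recomputed from scratch.
shoelace <- function(pts) {
  n <- nrow(pts)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s <- s + pts[i, 1] * pts[j, 2] - pts[j, 1] * pts[i, 2]
  }
  abs(s) / 2
}

# Closed-polygon perimeter recomputed from scratch.
perim <- function(pts) {
  n <- nrow(pts)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s <- s + sqrt(sum((pts[i, ] - pts[j, ])^2))
  }
  s
}

# Number of 8-connected foreground components in a logical mask.
n_components <- function(mask) {
  max(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask) * 1))))
}

# Binary image of a filled disc / filled axis-aligned square.
disc_mask <- function(size, center, radius) {
  g <- expand.grid(y = seq_len(size), x = seq_len(size))
  m <- matrix((g$x - center[1])^2 + (g$y - center[2])^2 <= radius^2,
              nrow = size)
  m
}
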