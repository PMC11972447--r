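#' Plan tile positions covering a circular well
#'
#' Lays out a rectangular grid of camera fields of view with pitch
#' `fov - overlap` so the whole well disc is covered with small overlaps
#' between neighboring tiles; tiles whose rectangle does not intersect the
#' well disc are pruned. Units are arbitrary but must be consistent (mm for
#' a stage, px in simulation).
#'
#' @param well_center (x, y) well center.
#' @param well_radius well radius (> 0).
#' @param fov field-of-view size, (width, height) pair or scalar.
#' @param overlap overlap between adjacent tiles; defaults to 10% of the
#'   smaller fov side. Must satisfy `0 <= overlap < min(fov)`.
#' @return object of class `tile_plan`: `centers` (tibble x, y), `fov`,
#'   `overlap`, `well_center`, `well_radius`.
#' @export
plan_tiles <- function(well_center, well_radius, fov, overlap = NULL) {
  stopifnot(length(well_center) == 2, well_radius > 0)
  fov <- rep(as.numeric(fov), length.out = 2)
  if (is.null(overlap)) overlap <- 0.1 * min(fov)
  if (overlap < 0 || overlap >= min(fov)) {
    stop("overlap must satisfy 0 <= overlap < min(fov)")
  }
  pitch <- fov - overlap
  n <- pmax(1, ceiling((2 * well_radius - fov) / pitch) + 1)
  xs <- well_center[1] + (seq_len(n[1]) - (n[1] + 1) / 2) * pitch[1]
  ys <- well_center[2] + (seq_len(n[2]) - (n[2] + 1) / 2) * pitch[2]
  centers <- expand.grid(x = xs, y = ys)

  # prune tiles whose rectangle misses the disc (clamped-distance test)
  ddx <- pmax(abs(centers$x - well_center[1]) - fov[1] / 2, 0)
  ddy <- pmax(abs(centers$y - well_center[2]) - fov[2] / 2, 0)
  keep <- ddx^2 + ddy^2 <= well_radius^2
  structure(
    list(centers = tibble::as_tibble(centers[keep, , drop = FALSE]),
         fov = fov, overlap = overlap,
         well_center = as.numeric(well_center), well_radius = well_radius),
    class = "tile_plan"
  )
}

#' Four-anchor autofocus map
#'
#' Focus is measured by image stacking at four well positions; focal
#' positions everywhere else come from the least-squares plane through the
#' anchors (linear interpolation and extrapolation). On coplanar anchors the
#' plane is exact.
#'
#' @param anchors data frame with columns `x`, `y`, `z` and exactly 4 rows.
#' @return object of class `focus_map`.
#' @export
focus_map <- function(anchors) {
  stopifnot(is.data.frame(anchors), all(c("x", "y", "z") %in% names(anchors)))
  if (nrow(anchors) != 4) stop("exactly 4 focus anchors required")
  if (qr(cbind(1, anchors$x, anchors$y))$rank < 3) {
    stop("degenerate focus anchors: positions are collinear")
  }
  structure(list(anchors = tibble::as_tibble(anchors), mode = "linear"),
            class = "focus_map")
}

#' Default focus-anchor layout
#'
#' Places the four equally spaced autofocus positions at half-radius on the
#' +/-x and +/-y axes through the well center.
#'
#' @param well_center (x, y) well center.
#' @param well_radius well radius.
#' @param z focus values at the four anchors (length 1 or 4).
#' @return data frame of anchors suitable for [focus_map()].
#' @export
default_focus_anchors <- function(well_center, well_radius, z = 0) {
  r <- well_radius / 2
  tibble::tibble(
    x = well_center[1] + c(r, -r, 0, 0),
    y = well_center[2] + c(0, 0, r, -r),
    z = rep(z, length.out = 4)
  )
}

#' Interpolate the focus position
#'
#' @param map a [focus_map()].
#' @param position (x, y) pair, or a two-column matrix of positions.
#' @return focal z position(s).
#' @export
interpolate_focus <- function(map, position) {
  stopifnot(inherits(map, "focus_map"))
  if (!is.matrix(position)) position <- matrix(position, ncol = 2)
  fit <- lm(z ~ x + y, data = map$anchors)
  unname(stats::predict(fit, data.frame(x = position[, 1], y = position[, 2])))
}

#' Assemble tiles into a mosaic at known coordinates
#'
#' Places each tile at its known grid position (tile positions are exact in
#' simulation, so no feature-based registration is needed), after optional
#' shading correction (division by the normalized blurred reference
#' flat-field) and histogram adjustment (an additive offset matching the
#' tile's mean to the already-assembled mosaic over their overlap). Overlaps
#' are resolved by linear feathering: each tile contributes with a tent
#' weight that falls off toward its edges.
#'
#' @param tiles list of `list(image = <matrix>, center = c(x, y))`, centers
#'   in mosaic pixel coordinates; all tiles the same size.
#' @param size mosaic (width, height) in px; inferred from tile extents when
#'   omitted.
#' @param shading_ref optional flat-field reference image (tile-sized).
#' @param adjust_histogram match overlap means with an additive offset?
#' @param fill_gray gray level used for uncovered pixels (a missing tile
#'   leaves a brightfield-gray hole, with a warning).
#' @return grayscale mosaic matrix (0-255).
#' @export
assemble_mosaic <- function(tiles, size = NULL, shading_ref = NULL,
                            adjust_histogram = TRUE, fill_gray = 220) {
  stopifnot(length(tiles) >= 1)
  th <- nrow(tiles[[1]]$image); tw <- ncol(tiles[[1]]$image)
  for (t in tiles) {
    if (nrow(t$image) != th || ncol(t$image) != tw) {
      stop("all tiles must have the same size")
    }
  }
  if (is.null(size)) {
    xs <- vapply(tiles, function(t) t$center[1], numeric(1))
    ys <- vapply(tiles, function(t) t$center[2], numeric(1))
    size <- c(ceiling(max(xs) + tw / 2), ceiling(max(ys) + th / 2))
  }
  W <- size[1]; H <- size[2]

  shade <- NULL
  if (!is.null(shading_ref)) {
    sm <- gblur_replicate(shading_ref, sigma = max(tw, th) / 10)
    shade <- sm / mean(sm)
    shade[shade <= 0] <- 1
  }

  wx <- pmin(seq_len(tw), rev(seq_len(tw)))
  wy <- pmin(seq_len(th), rev(seq_len(th)))
  wt <- outer(wy, wx)  # tent feathering weight

  num <- matrix(0, H, W)
  den <- matrix(0, H, W)
  for (t in tiles) {
    img <- t$image
    if (!is.null(shade)) img <- img / shade
    # rows r0+1 .. r0+th have pixel-center midpoint r0 + (th+1)/2
    x0 <- round(t$center[1] - (tw + 1) / 2)
    y0 <- round(t$center[2] - (th + 1) / 2)
    cols <- (x0 + 1):(x0 + tw); rows <- (y0 + 1):(y0 + th)
    ok_c <- cols >= 1 & cols <= W; ok_r <- rows >= 1 & rows <= H
    if (!any(ok_c) || !any(ok_r)) next
    sub_r <- which(ok_r); sub_c <- which(ok_c)
    tgt_r <- rows[sub_r]; tgt_c <- cols[sub_c]

    if (adjust_histogram) {
      ov <- den[tgt_r, tgt_c] > 0
      if (any(ov)) {
        cur <- (num[tgt_r, tgt_c] / pmax(den[tgt_r, tgt_c], 1e-12))[ov]
        img <- img + (mean(cur) - mean(img[sub_r, sub_c][ov]))
      }
    }
    num[tgt_r, tgt_c] <- num[tgt_r, tgt_c] + img[sub_r, sub_c] * wt[sub_r, sub_c]
    den[tgt_r, tgt_c] <- den[tgt_r, tgt_c] + wt[sub_r, sub_c]
  }

  hole <- den == 0
  if (any(hole)) warning("uncovered mosaic pixels filled with fill_gray")
  out <- ifelse(hole, fill_gray, num / pmax(den, 1e-12))
  clamp8(out)
}
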