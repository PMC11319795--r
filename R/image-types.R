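#' 8-bit grayscale image
#'
#' Container for a B-mode ultrasound-style image: an integer matrix of pixel
#' intensities in \[0, 255\] (0 = black, 255 = white) with an isotropic pixel
#' spacing in cm/pixel. Coordinates throughout the package are 0-based
#' `(row, col)` with row increasing downward, matching the usual image
#' convention.
#'
#' @param pixels integer matrix, values in \[0, 255\], at least 2 x 2.
#' @param pixel_spacing isotropic pixel size in cm/pixel.
#' @param id optional image identifier.
#' @return A `gray_image` object.
#' @export
gray_image <- function(pixels, pixel_spacing = 0.01, id = "image") {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 2 || ncol(pixels) < 2) {
    stopf("gray_image: need at least a 2 x 2 pixel grid")
  }
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > 255)) {
    stopf("gray_image: pixel values must lie in [0, 255]")
  }
  if (any(pixels != round(pixels))) {
    stopf("gray_image: pixel values must be integers (8-bit)")
  }
  if (!is.numeric(pixel_spacing) || pixel_spacing <= 0) {
    stopf("gray_image: pixel_spacing must be > 0")
  }
  structure(
    list(pixels = matrix(as.integer(pixels), nrow(pixels)),
         pixel_spacing = pixel_spacing, id = as.character(id)),
    class = "gray_image"
  )
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image '%s'> %d x %d px, %.4g cm/px, intensity %d..%d\n",
              x$id, nrow(x$pixels), ncol(x$pixels), x$pixel_spacing,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

#' Polygonal region of interest
#'
#' A simple (non-self-intersecting) polygon in 0-based `(row, col)` pixel
#' coordinates, used to outline a muscle cross-section for echo-intensity.
#' A pixel belongs to the ROI if its centre is inside or on the boundary
#' (even-odd rule), which is deterministic and orientation-independent.
#'
#' @param vertices numeric matrix with columns `(row, col)`, at least 3 rows.
#' @return A `polygon_roi` object.
#' @export
polygon_roi <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2 || nrow(vertices) < 3) {
    stopf("polygon_roi: need >= 3 (row, col) vertices")
  }
  if (anyNA(vertices)) stopf("polygon_roi: vertices must be finite")
  structure(list(vertices = vertices), class = "polygon_roi")
}

#' Rectangular region of interest
#'
#' Axis-aligned rectangle in 0-based pixel coordinates (top-left corner plus
#' extent), as required for the co-occurrence texture analysis.
#'
#' @param row0,col0 top-left pixel (0-based).
#' @param height,width extent in pixels (each >= 2).
#' @return A `rect_roi` object.
#' @export
rect_roi <- function(row0, col0, height, width) {
  for (v in list(row0, col0)) {
    if (!is_count(v)) stopf("rect_roi: row0/col0 must be non-negative integers")
  }
  if (!is_count(height) || !is_count(width) || height < 2 || width < 2) {
    stopf("rect_roi: height and width must be integers >= 2")
  }
  structure(list(row0 = as.integer(row0), col0 = as.integer(col0),
                 height = as.integer(height), width = as.integer(width)),
            class = "rect_roi")
}

#' Tissue-interface landmarks
#'
#' Depths (in pixels, along the image's central vertical line) of the skin
#' surface, the superficial aponeurosis, and the deep boundary (deep
#' aponeurosis or bone), from which subcutaneous-fat and muscle thickness are
#' measured.
#'
#' @param skin_depth,superficial_apo_depth,deep_boundary_depth depths in
#'   pixels; must satisfy `skin < superficial < deep` (equality of the two
#'   muscle borders is tolerated but flagged downstream).
#' @return A `landmark_set` object.
#' @export
landmark_set <- function(skin_depth, superficial_apo_depth,
                         deep_boundary_depth) {
  d <- c(skin_depth, superficial_apo_depth, deep_boundary_depth)
  if (anyNA(d) || any(d < 0)) stopf("landmark_set: depths must be >= 0")
  if (!(skin_depth < superficial_apo_depth &&
        superficial_apo_depth <= deep_boundary_depth)) {
    stopf(paste("landmark_set: depths must be ordered",
                "skin < superficial aponeurosis <= deep boundary"))
  }
  structure(list(skin_depth = skin_depth,
                 superficial_apo_depth = superficial_apo_depth,
                 deep_boundary_depth = deep_boundary_depth),
            class = "landmark_set")
}

# pixel-center membership mask of a polygon over an image, even-odd rule,
# boundary pixels included; returns logical matrix of the full image
polygon_mask <- function(image, roi) {
  stopifnot(inherits(image, "gray_image"), inherits(roi, "polygon_roi"))
  nr <- nrow(image$pixels); nc <- ncol(image$pixels)
  v <- roi$vertices
  if (any(v[, 1] < 0) || any(v[, 1] > nr - 1) ||
      any(v[, 2] < 0) || any(v[, 2] > nc - 1)) {
    stopf("polygon_roi lies outside the %d x %d image", nr, nc)
  }
  # restrict to the bounding box, then vectorized crossing-number test
  r0 <- max(0L, floor(min(v[, 1]))); r1 <- min(nr - 1L, ceiling(max(v[, 1])))
  c0 <- max(0L, floor(min(v[, 2]))); c1 <- min(nc - 1L, ceiling(max(v[, 2])))
  rows <- r0:r1; cols <- c0:c1
  py <- rep(rows, times = length(cols))   # y = row
  px <- rep(cols, each = length(rows))    # x = col
  inside <- rep(FALSE, length(px))
  onedge <- rep(FALSE, length(px))
  m <- nrow(v)
  eps <- 1e-9
  for (k in seq_len(m)) {
    y1 <- v[k, 1]; x1 <- v[k, 2]
    k2 <- if (k == m) 1L else k + 1L
    y2 <- v[k2, 1]; x2 <- v[k2, 2]
    # boundary: collinear and within the segment's bounding box
    cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    seg_len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
    if (seg_len > 0) {
      on_k <- abs(cross) <= eps * max(1, seg_len) &
        px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
        py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
      onedge <- onedge | on_k
    }
    # crossing number (half-open rule on y avoids double-counting vertices)
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < x1 + (py - y1) * (x2 - x1) / (y2 - y1))
    inside <- xor(inside, crosses & (y2 != y1))
  }
  mask <- matrix(FALSE, nr, nc)
  sel <- inside | onedge
  mask[cbind(py[sel] + 1L, px[sel] + 1L)] <- TRUE
  mask
}
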