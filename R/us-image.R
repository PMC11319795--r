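#' Echo-intensity of a muscle region
#'
#' Mean pixel intensity (0-255, arbitrary units) over the pixels whose centres
#' fall inside (or on the boundary of) the polygonal muscle cross-section ROI.
#' Higher values indicate more intramuscular fat / connective tissue.
#'
#' @param image a [gray_image()].
#' @param roi a [polygon_roi()] outlining the muscle cross-section.
#' @return Echo-intensity as a single number in \[0, 255\], with the pixel
#'   count in attribute `n_pixels`.
#' @export
compute_ei <- function(image, roi) {
  mask <- polygon_mask(image, roi)
  n <- sum(mask)
  if (n == 0) stopf("compute_ei: polygon ROI encloses zero pixel centres")
  ei <- mean(image$pixels[mask])
  attr(ei, "n_pixels") <- n
  ei
}

#' Muscle and subcutaneous-fat thickness from landmarks
#'
#' Subcutaneous adipose tissue thickness (SAT) is the distance from the skin
#' surface to the superficial aponeurosis; muscle thickness (MT) is the
#' distance from the superficial aponeurosis to the deep boundary (deep
#' aponeurosis or bone), both measured on the image's central vertical line
#' and converted to cm via the pixel spacing.
#'
#' @param lm a [landmark_set()].
#' @param pixel_spacing cm per pixel.
#' @return List with elements `MT_cm` and `SAT_cm`.
#' @export
measure_thickness <- function(lm, pixel_spacing) {
  stopifnot(inherits(lm, "landmark_set"))
  if (!is.numeric(pixel_spacing) || pixel_spacing <= 0) {
    stopf("measure_thickness: pixel_spacing must be > 0")
  }
  mt <- (lm$deep_boundary_depth - lm$superficial_apo_depth) * pixel_spacing
  sat <- (lm$superficial_apo_depth - lm$skin_depth) * pixel_spacing
  if (mt == 0) {
    warning("measure_thickness: superficial and deep boundaries coincide; MT = 0",
            call. = FALSE)
  }
  list(MT_cm = mt, SAT_cm = sat)
}

#' Co-occurrence analysis configuration
#'
#' Defaults follow common B-mode texture practice: full 8-bit depth (256 gray
#' levels, no requantization), unit pixel offset, and the four directions
#' 0, 90, 180, 270 degrees whose features are averaged to remove directional
#' effects. Entropy uses the natural logarithm by default; the base is
#' recorded in the feature output. Two Correlation variants are available:
#' `"standard"` (normalized by the marginal SDs, range \[-1, 1\]) and
#' `"plugin_compatible"` (the unnormalized co-moment; see
#' [haralick_features()]).
#'
#' @param levels number of gray levels (2-256); pixel values must be
#'   `< levels`.
#' @param distance pixel offset between the reference pixel and its neighbour.
#' @param directions angles in degrees; subset of \{0, 90, 180, 270\}.
#' @param log_base base of the logarithm used for Entropy.
#' @param correlation_variant `"standard"` or `"plugin_compatible"`.
#' @return A `glcm_config` object.
#' @export
glcm_config <- function(levels = 256, distance = 1,
                        directions = c(0, 90, 180, 270),
                        log_base = exp(1),
                        correlation_variant = c("standard",
                                                "plugin_compatible")) {
  if (!is_count(levels) || levels < 2 || levels > 256) {
    stopf("glcm_config: levels must be an integer in 2..256")
  }
  if (!is_count(distance) || distance < 1) {
    stopf("glcm_config: distance must be an integer >= 1")
  }
  directions <- as.numeric(directions)
  if (length(directions) == 0 || !all(directions %in% c(0, 90, 180, 270))) {
    stopf("glcm_config: directions must be a non-empty subset of {0, 90, 180, 270}")
  }
  if (!is.numeric(log_base) || log_base <= 1) {
    stopf("glcm_config: log_base must be > 1 (or e)")
  }
  structure(list(levels = as.integer(levels), distance = as.integer(distance),
                 directions = directions, log_base = log_base,
                 correlation_variant = match.arg(correlation_variant)),
            class = "glcm_config")
}

# (drow, dcol) pixel offset of a direction angle at a given distance;
# 0 deg points to the right neighbour, 90 deg up, row index grows downward
direction_offset <- function(angle, distance) {
  switch(as.character(angle),
         "0"   = c(0L, distance),
         "90"  = c(-distance, 0L),
         "180" = c(0L, -distance),
         "270" = c(distance, 0L),
         stopf("unsupported GLCM direction %s", angle))
}

#' Gray-level co-occurrence matrices of a rectangular ROI
#'
#' For each requested direction, counts ordered pixel pairs (reference,
#' neighbour at the directional offset) lying inside the ROI and normalizes
#' the counts to sum to 1. The direction-averaged matrix is the element-wise
#' mean over directions (and therefore also sums to 1). Counting opposite
#' directions (0/180, 90/270) separately and averaging equals symmetrizing the
#' matrix.
#'
#' @param image a [gray_image()] whose pixel values are `< cfg$levels`.
#' @param roi a [rect_roi()] fully inside the image.
#' @param cfg a [glcm_config()].
#' @return Object of class `glcm`: list with `per_direction` (named list of
#'   levels x levels matrices), `average`, and `config`.
#' @export
compute_glcm <- function(image, roi, cfg = glcm_config()) {
  stopifnot(inherits(image, "gray_image"), inherits(roi, "rect_roi"),
            inherits(cfg, "glcm_config"))
  nr <- nrow(image$pixels); nc <- ncol(image$pixels)
  if (roi$row0 + roi$height > nr || roi$col0 + roi$width > nc) {
    stopf("compute_glcm: rectangle ROI extends outside the %d x %d image", nr, nc)
  }
  sub <- image$pixels[(roi$row0 + 1L):(roi$row0 + roi$height),
                      (roi$col0 + 1L):(roi$col0 + roi$width), drop = FALSE]
  if (any(sub >= cfg$levels)) {
    stopf("compute_glcm: pixel values must be < levels (%d); requantize first",
          cfg$levels)
  }
  L <- cfg$levels
  per_dir <- list()
  for (ang in cfg$directions) {
    off <- direction_offset(ang, cfg$distance)
    h <- roi$height; w <- roi$width
    # reference-pixel window such that the neighbour stays inside the ROI
    r_from <- max(1L, 1L - off[1]); r_to <- min(h, h - off[1])
    c_from <- max(1L, 1L - off[2]); c_to <- min(w, w - off[2])
    if (r_from > r_to || c_from > c_to) {
      stopf("compute_glcm: ROI thinner than distance %d in direction %s",
            cfg$distance, ang)
    }
    rr <- seq.int(r_from, r_to)
    cc <- seq.int(c_from, c_to)
    ref <- sub[rr, cc, drop = FALSE]
    nb  <- sub[rr + off[1], cc + off[2], drop = FALSE]
    counts <- tabulate(as.integer(ref) * L + as.integer(nb) + 1L, nbins = L * L)
    m <- matrix(counts / sum(counts), L, L, byrow = TRUE)
    # row index = reference level i, col = neighbour level j (0-based levels)
    per_dir[[as.character(ang)]] <- m
  }
  avg <- Reduce(`+`, per_dir) / length(per_dir)
  structure(list(per_direction = per_dir, average = avg, config = cfg),
            class = "glcm")
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("<glcm> %d levels, distance %d, directions {%s}\n",
              x$config$levels, x$config$distance,
              paste(x$config$directions, collapse = ", ")))
  invisible(x)
}

#' Haralick texture features of a co-occurrence matrix
#'
#' Computes the five second-order texture statistics from a normalized
#' (direction-averaged) co-occurrence matrix `p(i, j)`:
#' \itemize{
#'   \item ASM (angular second moment / energy): `sum p(i,j)^2` — gray-level
#'     uniformity, 1 for a constant region;
#'   \item Contrast: `sum (i-j)^2 p(i,j)` — intensity variation between
#'     neighbours;
#'   \item Correlation: `sum (i-mu_i)(j-mu_j) p(i,j) / (sigma_i sigma_j)` —
#'     linear predictability of neighbour pairs (standard variant; the
#'     `plugin_compatible` variant reports the unnormalized co-moment
#'     `sum (i-mu_i)(j-mu_j) p(i,j)`, i.e. omits the SD normalization);
#'   \item IDM (inverse difference moment): `sum p(i,j) / (1 + (i-j)^2)` —
#'     local homogeneity;
#'   \item Entropy: `-sum p log p` over positive entries — textural disorder.
#' }
#' Increased ASM, Correlation and IDM indicate homogeneous texture; increased
#' Contrast and Entropy indicate heterogeneous texture. For a degenerate
#' matrix concentrated on a single gray level the standard Correlation is
#' undefined and returned as `NA`.
#'
#' @param glcm a `glcm` object from [compute_glcm()], or a normalized
#'   square matrix summing to 1.
#' @param cfg a [glcm_config()]; defaults to the one stored in `glcm`.
#' @return Named list with ASM, Contrast, Correlation, IDM, Entropy, and the
#'   entropy log base as attribute `log_base`.
#' @export
haralick_features <- function(glcm, cfg = NULL) {
  if (inherits(glcm, "glcm")) {
    if (is.null(cfg)) cfg <- glcm$config
    p <- glcm$average
  } else {
    p <- as.matrix(glcm)
    if (is.null(cfg)) cfg <- glcm_config(levels = nrow(p))
  }
  if (nrow(p) != ncol(p)) stopf("haralick_features: matrix must be square")
  if (abs(sum(p) - 1) > 1e-9) {
    stopf("haralick_features: matrix must be normalized to sum 1 (got %.12g)",
          sum(p))
  }
  if (any(p < 0)) stopf("haralick_features: negative entries")
  L <- nrow(p)
  i <- matrix(0:(L - 1), L, L)          # reference level (rows)
  j <- t(i)                             # neighbour level (cols)
  asm <- sum(p^2)
  contrast <- sum((i - j)^2 * p)
  idm <- sum(p / (1 + (i - j)^2))
  pos <- p > 0
  entropy <- -sum(p[pos] * log(p[pos], base = cfg$log_base))
  pi_m <- rowSums(p); pj_m <- colSums(p)
  mu_i <- sum((0:(L - 1)) * pi_m); mu_j <- sum((0:(L - 1)) * pj_m)
  var_i <- sum(((0:(L - 1)) - mu_i)^2 * pi_m)
  var_j <- sum(((0:(L - 1)) - mu_j)^2 * pj_m)
  comoment <- sum((i - mu_i) * (j - mu_j) * p)
  correlation <- if (cfg$correlation_variant == "plugin_compatible") {
    comoment
  } else if (var_i <= 0 || var_j <= 0) {
    NA_real_   # single gray level: linear predictability undefined
  } else {
    comoment / sqrt(var_i * var_j)
  }
  out <- list(ASM = asm, Contrast = contrast, Correlation = correlation,
              IDM = idm, Entropy = entropy)
  attr(out, "log_base") <- cfg$log_base
  attr(out, "correlation_variant") <- cfg$correlation_variant
  out
}

#' Average replicate measurements
#'
#' Element-wise arithmetic mean of repeated per-image records (typically the
#' three images acquired per muscle site); the replicate count is recorded.
#'
#' @param measures list of named numeric lists/vectors with identical names
#'   (e.g. outputs of [haralick_features()] or `MT/SAT/EI` records).
#' @return Named list of means with attribute `n_replicates`.
#' @export
average_replicates <- function(measures) {
  if (length(measures) == 0) stopf("average_replicates: empty replicate list")
  vecs <- lapply(measures, function(m) unlist(m))
  nms <- names(vecs[[1]])
  for (v in vecs) {
    if (!identical(names(v), nms)) {
      stopf("average_replicates: replicates carry different fields")
    }
  }
  avg <- as.list(colMeans(do.call(rbind, vecs)))
  attr(avg, "n_replicates") <- length(measures)
  avg
}
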