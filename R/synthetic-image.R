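#' Phenotype of a synthetic ultrasound-like image
#'
#' Parameters of the layered speckle image the generator draws: a dark gel
#' band, a bright skin band, a darker subcutaneous fat (SAT) band, a bright
#' superficial aponeurosis line, a muscle speckle region with controllable
#' mean intensity and coarse heterogeneity ("clutter"), and a bright deep
#' boundary. The defaults describe a young-like vastus lateralis (low
#' echo-intensity, homogeneous texture) at 0.01 cm/pixel; an old-like image is
#' obtained by raising `mean_intensity` and `heterogeneity_scale`.
#'
#' @param mean_intensity target mean gray level of the muscle region (0-255).
#' @param heterogeneity_scale SD (gray levels) of the coarse multiplicative
#'   intensity clutter underlying the speckle; 0 = maximally homogeneous.
#' @param speckle_corr_len correlation length of the fine speckle, pixels.
#' @param clutter_corr_len correlation length of the coarse clutter, pixels.
#' @param skin_depth_px depth of the skin surface, pixels.
#' @param sat_thickness_px,muscle_thickness_px layer thicknesses, pixels.
#' @param pixel_spacing cm/pixel metadata carried into the image.
#' @param image_size `c(rows, cols)`.
#' @return An `image_phenotype` object.
#' @export
image_phenotype <- function(mean_intensity = 32, heterogeneity_scale = 4,
                            speckle_corr_len = 2, clutter_corr_len = 12,
                            skin_depth_px = 50, sat_thickness_px = 98,
                            muscle_thickness_px = 221, pixel_spacing = 0.01,
                            image_size = c(450, 350)) {
  if (mean_intensity < 0 || mean_intensity > 255) {
    stopf("image_phenotype: mean_intensity must be in [0, 255]")
  }
  if (heterogeneity_scale < 0) {
    stopf("image_phenotype: heterogeneity_scale must be >= 0")
  }
  deep <- skin_depth_px + sat_thickness_px + muscle_thickness_px
  if (deep + 10 > image_size[1]) {
    stopf("image_phenotype: layers (deep boundary at %d px) exceed the %d-row image",
          deep, image_size[1])
  }
  if (skin_depth_px < 8) stopf("image_phenotype: skin_depth_px must be >= 8")
  structure(list(mean_intensity = mean_intensity,
                 heterogeneity_scale = heterogeneity_scale,
                 speckle_corr_len = speckle_corr_len,
                 clutter_corr_len = clutter_corr_len,
                 skin_depth_px = skin_depth_px,
                 sat_thickness_px = sat_thickness_px,
                 muscle_thickness_px = muscle_thickness_px,
                 pixel_spacing = pixel_spacing,
                 image_size = image_size),
            class = "image_phenotype")
}

# moving-average smoothing of a matrix with an odd-width box kernel in both
# dimensions, replicate-padded at the borders
box_smooth <- function(mat, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2 == 0) k <- k + 1L
  if (k == 1L) return(mat)
  half <- (k - 1L) %/% 2L
  smooth1 <- function(m) {   # along rows (down columns)
    n <- nrow(m)
    padded <- rbind(m[rep(1, half), , drop = FALSE], m,
                    m[rep(n, half), , drop = FALSE])
    cs <- apply(padded, 2, cumsum)
    (cs[(k):(k + n - 1L), , drop = FALSE] -
        rbind(0, cs[seq_len(n - 1L), , drop = FALSE])) / k
  }
  t(smooth1(t(smooth1(mat))))
}

# unit-SD correlated Gaussian field of a given size
noise_field <- function(nr, nc, corr_len) {
  f <- box_smooth(matrix(rnorm(nr * nc), nr, nc), corr_len)
  f / sd(f)
}

#' Generate a synthetic ultrasound-like image with ground truth
#'
#' Draws a layered 8-bit speckle image from an [image_phenotype()] and returns
#' it together with the annotations used to synthesize it: the tissue
#' landmarks (exact layer depths), a polygonal echo-intensity ROI and a
#' rectangular texture ROI, both inset well inside the muscle region so they
#' exclude aponeurosis and bone. The realized mean intensity of the muscle
#' ROI is driven to within +/- 2 gray levels of `mean_intensity`
#' (clipping-bias corrected). Deterministic given the seed.
#'
#' @param phenotype an [image_phenotype()].
#' @param seed integer seed.
#' @param id image identifier.
#' @return List with elements `image` ([gray_image()]), `landmarks`
#'   ([landmark_set()]), `ei_roi` ([polygon_roi()]), `glcm_roi`
#'   ([rect_roi()]), and `phenotype`.
#' @export
generate_us_image <- function(phenotype, seed = 1L, id = "synthetic") {
  stopifnot(inherits(phenotype, "image_phenotype"))
  ph <- phenotype
  nr <- ph$image_size[1]; nc <- ph$image_size[2]
  skin <- ph$skin_depth_px
  sup <- skin + ph$sat_thickness_px
  deep <- sup + ph$muscle_thickness_px
  with_seed(seed, {
    img <- matrix(0, nr, nc)
    row_band <- function(from, to) (from:to) + 1L   # 0-based depths -> rows
    # gel above the skin
    img[row_band(0, skin - 1), ] <- 8 + 2 * rnorm((skin) * nc)
    # bright skin band
    img[row_band(skin, skin + 4), ] <- 190 + 12 * rnorm(5 * nc)
    # subcutaneous fat: dark, mildly speckled
    if (sup - 1 >= skin + 5) {
      sat_rows <- row_band(skin + 5, sup - 1)
      img[sat_rows, ] <- 28 +
        6 * noise_field(length(sat_rows), nc, ph$speckle_corr_len)
    }
    # superficial aponeurosis
    img[row_band(sup, sup + 2), ] <- 210 + 10 * rnorm(3 * nc)
    # muscle: fine additive speckle on a multiplicative coarse clutter.
    # Clutter is lognormal (unit mean, SD heterogeneity_scale in gray
    # levels): echo texture contrast is multiplicative in nature, and a
    # positive multiplicative field avoids piling clipped pixels at 0,
    # which would fabricate a degenerate co-occurrence spike
    mus_rows <- row_band(sup + 3, deep - 1)
    speckle <- 8 * noise_field(length(mus_rows), nc, ph$speckle_corr_len)
    clutter <- if (ph$heterogeneity_scale > 0 && ph$mean_intensity > 0) {
      s2 <- log(1 + (ph$heterogeneity_scale / ph$mean_intensity)^2)
      exp(sqrt(s2) * noise_field(length(mus_rows), nc, ph$clutter_corr_len) -
            s2 / 2)
    } else 1
    img[mus_rows, ] <- ph$mean_intensity * clutter + speckle
    # deep boundary (deep aponeurosis / bone) and shadow below
    img[row_band(deep, deep + 2), ] <- 200 + 10 * rnorm(3 * nc)
    if (deep + 3 <= nr - 1) {
      below <- row_band(deep + 3, nr - 1)
      img[below, ] <- 12 + 3 * rnorm(length(below) * nc)
    }
    quantize <- function(m) matrix(pmin(255L, pmax(0L, as.integer(round(m)))),
                                   nrow(m))
    # ground-truth ROIs, inset to avoid the bright interfaces
    margin_r <- 8; margin_c <- 20
    r_top <- sup + margin_r; r_bot <- deep - margin_r
    c_l <- margin_c; c_r <- nc - 1 - margin_c
    mid <- (r_top + r_bot) / 2
    ei_roi <- polygon_roi(rbind(
      c(r_top, c_l + 10), c(r_top, c_r - 10), c(mid, c_r),
      c(r_bot, c_r - 10), c(r_bot, c_l + 10), c(mid, c_l)
    ))
    glcm_roi <- rect_roi(row0 = sup + 10, col0 = 30,
                         height = deep - sup - 20, width = nc - 60)
    # drive the realized EI-ROI mean to the target (quantization/clipping
    # introduces a small bias for low-mean, high-clutter phenotypes)
    qimg <- quantize(img)
    gi <- gray_image(qimg, ph$pixel_spacing, id)
    mask <- polygon_mask(gi, ei_roi)
    for (it in 1:3) {
      delta <- ph$mean_intensity - mean(qimg[mask])
      if (abs(delta) <= 1) break
      img[mus_rows, ] <- img[mus_rows, ] + delta
      qimg <- quantize(img)
    }
    list(image = gray_image(qimg, ph$pixel_spacing, id),
         landmarks = landmark_set(skin, sup, deep),
         ei_roi = ei_roi, glcm_roi = glcm_roi, phenotype = ph)
  })
}

#' Write an image and its annotations to disk
#'
#' The image is written as an 8-bit grayscale PNG; the landmarks and ROIs as a
#' JSON sidecar (polygon vertices as 0-based `(row, col)` pixel coordinates,
#' rectangle as `row0, col0, height, width`, depths in pixels).
#'
#' @param gen output of [generate_us_image()].
#' @param png_path,json_path output files.
#' @return `png_path`, invisibly.
#' @export
write_us_image <- function(gen, png_path, json_path) {
  png::writePNG(gen$image$pixels / 255, png_path)
  side <- list(
    id = gen$image$id,
    pixel_spacing_cm = gen$image$pixel_spacing,
    coordinates = "0-based (row, col), row increases downward",
    landmarks_px = unclass(gen$landmarks),
    ei_polygon_row_col = unname(apply(gen$ei_roi$vertices, 1, as.numeric,
                                      simplify = FALSE)),
    glcm_rect = unclass(gen$glcm_roi)
  )
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA)
  invisible(png_path)
}

#' Read an image and its annotation sidecar
#'
#' @param png_path 8-bit grayscale PNG (first channel used).
#' @param json_path JSON sidecar written by [write_us_image()].
#' @return List with `image`, `landmarks`, `ei_roi`, `glcm_roi`.
#' @export
read_us_image <- function(png_path, json_path) {
  arr <- png::readPNG(png_path)
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  side <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  img <- gray_image(round(arr * 255), side$pixel_spacing_cm, side$id)
  lm <- landmark_set(side$landmarks_px$skin_depth,
                     side$landmarks_px$superficial_apo_depth,
                     side$landmarks_px$deep_boundary_depth)
  p <- side$ei_polygon_row_col
  verts <- if (is.matrix(p)) p else do.call(rbind, lapply(p, as.numeric))
  rr <- side$glcm_rect
  list(image = img, landmarks = lm, ei_roi = polygon_roi(verts),
       glcm_roi = rect_roi(rr$row0, rr$col0, rr$height, rr$width))
}
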