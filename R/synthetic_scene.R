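#' Parameters for one synthetic scene
#'
#' Describes a composite quadrat scene with known ground truth: a sand/
#' vegetation background at a requested cover fraction, a horizontally aligned
#' skink body with a dorsal pattern, separate ventral and ventral-tail patches
#' (as composited from the ventral-side photograph), an 18\%-reflectance gray
#' card, and a camera model. The camera applies a per-channel gain, compresses
#' with exponent \eqn{1/\gamma}, adds Gaussian sensor noise, and quantizes to
#' 8 bits; sensor noise precedes quantization so it dithers the quantizer,
#' exactly as a real sensor does. The default camera (gains 1.2/1.0/0.8,
#' \eqn{\gamma = 2.2}, noise sd 0.005) is deliberately non-neutral so that
#' calibration is doing real work in every test.
#'
#' @param cover true vegetation cover fraction in \eqn{[0, 1]}.
#' @param sand_rgb,veg_rgb true reflectance triples of sand and vegetation.
#' @param dorsal_rgb,ventral_rgb,ventral_tail_rgb true region reflectances.
#' @param background_rgb optional flat reflectance for the two background
#'   patches; when \code{NULL} they sample the sand/vegetation texture.
#' @param speckle_fraction target dark-speckle fraction of the dorsal body.
#' @param midline_fraction target mid-dorsal line coverage of the body axis.
#' @param gains per-channel camera gains (positive).
#' @param gamma camera gamma (compression exponent is \code{1/gamma}).
#' @param noise_sd Gaussian pixel noise sd in the encoded domain.
#' @param gray_reflectance gray-card reflectance, default 0.18.
#' @param width,height scene size in pixels.
#' @param seed scene seed; all scene randomness flows from it via named
#'   substreams.
#' @return list of class \code{scene_params}.
#' @export
scene_params <- function(cover = 0.3,
                         sand_rgb = c(0.55, 0.50, 0.42),
                         veg_rgb = c(0.16, 0.24, 0.10),
                         dorsal_rgb = c(0.32, 0.30, 0.26),
                         ventral_rgb = c(0.48, 0.30, 0.16),
                         ventral_tail_rgb = c(0.50, 0.27, 0.15),
                         background_rgb = NULL,
                         speckle_fraction = 0.25,
                         midline_fraction = 0.8,
                         gains = c(1.2, 1.0, 0.8),
                         gamma = 2.2,
                         noise_sd = 0.005,
                         gray_reflectance = 0.18,
                         width = 160, height = 120,
                         seed = 1L) {
  check_that(cover >= 0 && cover <= 1, "cover must be in [0, 1]")
  check_that(all(gains > 0), "gains must be positive")
  check_that(noise_sd >= 0, "noise_sd must be >= 0")
  check_that(width >= 160 && height >= 120,
             "scene must be at least 160 x 120 to hold the fixed layout")
  structure(as.list(environment()), class = "scene_params")
}

# Pattern paint multipliers: speckles darker, mid-dorsal line lighter than the
# dorsal base color. Kept moderate so patterned bodies stay inside the
# camera's dynamic range under the default gains.
.speckle_mult <- 0.6
.midline_mult <- 1.25

# Fixed scene layout: pixel ranges (0-based, inclusive) of painted patches and
# their slightly inset sampling ROIs.
scene_layout <- function() {
  list(
    body_center = c(col = 80, row = 62), body_ax = c(a = 42, b = 13),
    dorsal_roi = c(55, 105, 57, 67),        # c0, c1, r0, r1
    ventral_rect = c(12, 52, 92, 116), ventral_roi = c(14, 50, 94, 114),
    tail_rect = c(60, 100, 92, 116), tail_roi = c(62, 98, 94, 114),
    gray_rect = c(112, 150, 88, 114), gray_roi = c(114, 148, 90, 112),
    bg1_roi = c(6, 46, 4, 34), bg2_roi = c(96, 152, 4, 30)
  )
}

# Rectangle ROI over pixels cols c0..c1, rows r0..r1 (0-based inclusive).
# Vertices are offset 0.4 px outward so no pixel center sits on an edge.
rect_roi <- function(label, c0, c1, r0, r1) {
  polygon_roi(label, rbind(c(c0 - 0.4, r0 - 0.4), c(c1 + 0.4, r0 - 0.4),
                           c(c1 + 0.4, r1 + 0.4), c(c0 - 0.4, r1 + 0.4)))
}

# Quadrant-wise vegetation mask aligned to the 5% scoring grid.
# Returns a logical h x w matrix whose quadrant areas are exact multiples of
# 5% of the whole image, summing to the grid-rounded target cover.
grid_vegetation_mask <- function(height, width, cover) {
  total_pct <- 5 * round(100 * cover / 5)
  q <- numeric(4)
  left <- total_pct
  while (left > 0) {          # deal 5%-blocks round-robin, 25% cap per quadrant
    for (i in 1:4) {
      if (left > 0 && q[i] < 25) {
        q[i] <- q[i] + 5
        left <- left - 5
      }
    }
  }
  mask <- matrix(FALSE, height, width)
  npix <- height * width
  hr <- height %/% 2; wc <- width %/% 2
  quads <- list(list(1:hr, 1:wc), list(1:hr, (wc + 1):width),
                list((hr + 1):height, 1:wc),
                list((hr + 1):height, (wc + 1):width))
  for (i in 1:4) {
    n_i <- round(npix * q[i] / 100)
    if (n_i == 0) next
    rs <- quads[[i]][[1]]; cs <- quads[[i]][[2]]
    sub <- matrix(FALSE, length(rs), length(cs))
    sub[seq_len(min(n_i, length(sub)))] <- TRUE   # column-major fill
    mask[rs, cs] <- sub
  }
  mask
}

paint_rect <- function(img, rect, rgb) {
  rs <- (rect[3]:rect[4]) + 1L; cs <- (rect[1]:rect[2]) + 1L
  for (ch in 1:3) img[rs, cs, ch] <- rgb[ch]
  img
}

# Build the dorsal pattern map (body/speckle/midline) on the scene grid and
# return both the in-image masks and the cropped, axis-aligned pattern map.
build_pattern_masks <- function(p, layout) {
  h <- p$height; w <- p$width
  ctr <- layout$body_center; ax <- layout$body_ax
  cols <- matrix(0:(w - 1), h, w, byrow = TRUE)
  rows <- matrix(0:(h - 1), h, w)
  body <- ((cols - ctr["col"]) / ax["a"])^2 + ((rows - ctr["row"]) / ax["b"])^2 <= 1
  body_idx <- which(body)
  n_sp <- round(p$speckle_fraction * length(body_idx))
  speckle <- matrix(FALSE, h, w)
  if (n_sp > 0) {
    pick <- with_seed(derive_seed(p$seed, "speckle"),
                      sample(body_idx, n_sp, replace = FALSE))
    speckle[pick] <- TRUE
  }
  midline <- matrix(FALSE, h, w)
  axis_cols <- which(colSums(body) > 0)
  k <- round(p$midline_fraction * length(axis_cols))
  if (k > 0) {
    mid_cols <- axis_cols[seq_len(k)]
    mid_rows <- (ctr["row"] - 1):(ctr["row"] + 1) + 1L
    midline[mid_rows, mid_cols] <- TRUE
    midline <- midline & body
  }
  list(body = body, speckle = speckle, midline = midline)
}

#' Render a synthetic scene
#'
#' Produces the full test fixture: an 8-bit RGB image rendered through the
#' camera model, the ROI set (dorsal, ventral, ventral tail, two background
#' patches, gray standard), the dorsal pattern map, the vegetation mask of the
#' quadrat (as photographed before the animal is composited over it), and the
#' ground truth. Ground-truth region colors are the exact means of the true
#' reflectance image over each ROI's interior pixels, so they account for
#' speckles and mixed sand/vegetation inside the sampling polygons. Identical
#' seeds give identical bundles.
#'
#' @param p a [scene_params()].
#' @return list of class \code{scene_bundle} with elements \code{image}
#'   (h x w x 3, \eqn{[0,1]}, 8-bit quantized), \code{rois} (named list of
#'   [polygon_roi()]), \code{pattern_map} ([body_pattern_map()]),
#'   \code{vegetation_mask}, \code{ground_truth}, \code{params}.
#' @export
render_scene <- function(p) {
  check_that(inherits(p, "scene_params"), "p must be scene_params")
  h <- p$height; w <- p$width
  layout <- scene_layout()
  veg_mask <- grid_vegetation_mask(h, w, p$cover)

  truth_img <- array(0, c(h, w, 3))
  for (ch in 1:3) {
    truth_img[, , ch] <- p$sand_rgb[ch]
    truth_img[, , ch][veg_mask] <- p$veg_rgb[ch]
  }
  if (!is.null(p$background_rgb)) {
    truth_img <- paint_rect(truth_img, layout$bg1_roi, p$background_rgb)
    truth_img <- paint_rect(truth_img, layout$bg2_roi, p$background_rgb)
  }
  truth_img <- paint_rect(truth_img, layout$ventral_rect, p$ventral_rgb)
  truth_img <- paint_rect(truth_img, layout$tail_rect, p$ventral_tail_rgb)
  truth_img <- paint_rect(truth_img, layout$gray_rect,
                          rep(p$gray_reflectance, 3))

  pm <- build_pattern_masks(p, layout)
  # The dorsal base paint is scaled so that the mean over the dorsal ROI —
  # base, dark speckles, and light midline together — equals dorsal_rgb
  # exactly. dorsal_rgb is thus the region's mean color as the field protocol
  # measures it, not the color between the markings.
  roi_px <- matrix(FALSE, h, w)
  dr <- layout$dorsal_roi
  roi_px[(dr[3]:dr[4]) + 1L, (dr[1]:dr[2]) + 1L] <- TRUE
  n_roi <- sum(roi_px)
  n_mid <- sum(roi_px & pm$midline)
  n_sp <- sum(roi_px & pm$speckle & !pm$midline)
  pat_factor <- (n_roi - n_mid - n_sp + .speckle_mult * n_sp +
                   .midline_mult * n_mid) / n_roi
  base_rgb <- p$dorsal_rgb / pat_factor
  for (ch in 1:3) {
    pl <- truth_img[, , ch]
    pl[pm$body] <- base_rgb[ch]
    pl[pm$speckle] <- base_rgb[ch] * .speckle_mult
    pl[pm$midline] <- base_rgb[ch] * .midline_mult
    truth_img[, , ch] <- pl
  }

  rois <- list(
    dorsal = do.call(rect_roi, c(list("dorsal"), as.list(layout$dorsal_roi))),
    ventral = do.call(rect_roi, c(list("ventral"), as.list(layout$ventral_roi))),
    ventral_tail = do.call(rect_roi, c(list("ventral_tail"), as.list(layout$tail_roi))),
    background_1 = do.call(rect_roi, c(list("background_1"), as.list(layout$bg1_roi))),
    background_2 = do.call(rect_roi, c(list("background_2"), as.list(layout$bg2_roi))),
    gray_standard = do.call(rect_roi, c(list("gray_standard"), as.list(layout$gray_roi)))
  )

  truth_mean <- function(roi) {
    pix <- roi_interior_pixels(roi, c(h, w))
    i <- pix[, 2] + 1L; j <- pix[, 1] + 1L
    c(R = mean(truth_img[cbind(i, j, 1L)]),
      G = mean(truth_img[cbind(i, j, 2L)]),
      B = mean(truth_img[cbind(i, j, 3L)]))
  }
  gt_regions <- lapply(rois, truth_mean)
  gt_regions$background <- (gt_regions$background_1 + gt_regions$background_2) / 2

  # camera: gain -> gamma-compress -> sensor noise -> 8-bit quantization
  enc <- array(0, c(h, w, 3))
  for (ch in 1:3) {
    enc[, , ch] <- pmin(pmax(p$gains[ch] * truth_img[, , ch], 0), 1)^(1 / p$gamma)
  }
  if (p$noise_sd > 0) {
    noise <- with_seed(derive_seed(p$seed, "pixel_noise"),
                       array(stats::rnorm(h * w * 3, 0, p$noise_sd), c(h, w, 3)))
    enc <- enc + noise
  }
  image <- round(pmin(pmax(enc, 0), 1) * 255) / 255

  # axis-aligned crop of the pattern masks around the body
  body_rows <- range(which(rowSums(pm$body) > 0))
  body_cols <- range(which(colSums(pm$body) > 0))
  crop <- function(m) m[body_rows[1]:body_rows[2], body_cols[1]:body_cols[2]]
  pattern_map <- body_pattern_map(crop(pm$body), crop(pm$speckle), crop(pm$midline))

  structure(list(
    image = image, rois = rois, pattern_map = pattern_map,
    vegetation_mask = veg_mask,
    ground_truth = list(regions = gt_regions,
                        cover_pct = 5 * round(100 * p$cover / 5),
                        speckle_fraction = p$speckle_fraction,
                        midline_fraction = p$midline_fraction),
    params = p
  ), class = "scene_bundle")
}
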