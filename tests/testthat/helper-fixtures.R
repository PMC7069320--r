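# Shared fixture builders. Everything is generated in code at test time.

# Rectangle ROI covering pixel columns c0..c1 and rows r0..r1 (0-based,
# inclusive); vertices offset so no pixel center lies on an edge.
square_roi <- function(c0, c1, r0, r1, label = "region") {
  polygon_roi(label, rbind(c(c0 - 0.4, r0 - 0.4), c(c1 + 0.4, r0 - 0.4),
                           c(c1 + 0.4, r1 + 0.4), c(c0 - 0.4, r1 + 0.4)))
}

# Uniform-color image, value per channel.
flat_image <- function(h, w, rgb) {
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- rgb[ch]
  img
}

# Seeded iid-noise image (channels independent), values in [0, 1].
noise_image <- function(h, w, seed) {
  set.seed(seed)
  array(runif(h * w * 3), c(h, w, 3))
}

# Synthetic camera encode of a reflectance triple: per-channel gain, then
# gamma compression. The independent forward model for calibration tests.
camera_encode <- function(rgb, gains, gamma) {
  pmin(pmax(gains * rgb, 0), 1)^(1 / gamma)
}

# Elliptical body pattern map with given speckle fraction and midline axis
# coverage; returns a body_pattern_map built the same way for every test.
make_pattern_map <- function(speckle_fraction, midline_fraction, seed = 1,
                             a = 40, b = 10) {
  h <- 2 * b + 3; w <- 2 * a + 3
  cols <- matrix(0:(w - 1), h, w, byrow = TRUE)
  rows <- matrix(0:(h - 1), h, w)
  body <- ((cols - a - 1) / a)^2 + ((rows - b - 1) / b)^2 <= 1
  set.seed(seed)
  idx <- which(body)
  speckle <- matrix(FALSE, h, w)
  nsp <- round(speckle_fraction * length(idx))
  if (nsp > 0) speckle[sample(idx, nsp)] <- TRUE
  midline <- matrix(FALSE, h, w)
  axis_cols <- which(colSums(body) > 0)
  k <- round(midline_fraction * length(axis_cols))
  if (k > 0) {
    midline[(b):(b + 2) + 1, axis_cols[seq_len(k)]] <- TRUE
    midline <- midline & body
  }
  body_pattern_map(body, speckle, midline)
}
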