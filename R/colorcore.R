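#' Linearize a camera-encoded channel value
#'
#' Removes the camera tone curve by inverse-gamma mapping,
#' \eqn{v_{lin} = v_{raw}^{\gamma}}. A single in-frame gray standard cannot
#' identify the full camera response curve, so a fixed-exponent model is used;
#' the default \code{gamma = 2.2} is the standard sRGB-class approximation.
#'
#' @param raw_value numeric vector of camera-encoded channel values in
#'   \eqn{[0, 1]} (8-bit values divided by 255).
#' @param gamma positive decoding exponent. Default 2.2.
#' @return linear channel values, same length as \code{raw_value}.
#' @examples
#' linearize(0.5)          # ~0.2176
#' linearize(c(0, 1), 2.2) # endpoints are fixed points
#' @export
linearize <- function(raw_value, gamma = 2.2) {
  check_that(is.numeric(raw_value) && !anyNA(raw_value),
             "raw_value must be numeric and non-missing")
  check_that(is.numeric(gamma) && length(gamma) == 1L && gamma > 0,
             "gamma must be a single positive number")
  check_that(all(raw_value >= 0 & raw_value <= 1),
             "raw_value outside [0, 1]")
  raw_value^gamma
}

#' Equalize a linearized RGB triple against the gray standard
#'
#' Per-channel multiplicative scaling so that the in-frame gray standard maps
#' exactly to its known reflectance: \eqn{c_{out} = t \cdot c_{in} / g_c},
#' where \eqn{g_c} is the linearized gray-card value of channel \eqn{c} and
#' \eqn{t} the card's reflectance (18\% for a standard photographic gray card).
#'
#' @param linear_rgb length-3 numeric, linearized R, G, B of the target region.
#' @param gray_linear_rgb length-3 numeric, linearized R, G, B of the gray
#'   standard in the same frame; all channels must be strictly positive.
#' @param reflectance_target known card reflectance in (0, 1). Default 0.18.
#' @return named numeric vector \code{c(R, G, B, V)} on the reflectance scale,
#'   with brightness \code{V = (R + G + B) / 3}.
#' @examples
#' equalize(c(0.72, 0.45, 0.15), c(0.36, 0.45, 0.30))  # (0.36, 0.18, 0.09, V)
#' @export
equalize <- function(linear_rgb, gray_linear_rgb, reflectance_target = 0.18) {
  check_that(is.numeric(linear_rgb) && length(linear_rgb) == 3L &&
               all(linear_rgb >= 0), "linear_rgb must be 3 non-negative values")
  check_that(is.numeric(gray_linear_rgb) && length(gray_linear_rgb) == 3L,
             "gray_linear_rgb must be length 3")
  if (!all(gray_linear_rgb > 0)) {
    stop("calibration error: gray standard channel <= 0", call. = FALSE)
  }
  check_that(reflectance_target > 0 && reflectance_target < 1,
             "reflectance_target must be in (0, 1)")
  out <- reflectance_target * unname(linear_rgb) / unname(gray_linear_rgb)
  c(R = out[1], G = out[2], B = out[3], V = mean(out))
}

#' Calibrate a raw camera RGB triple
#'
#' Convenience composition: linearize both the region and the gray-standard
#' observation with the same exponent, then equalize.
#'
#' @inheritParams linearize
#' @inheritParams equalize
#' @param raw_rgb length-3 camera-encoded R, G, B in \eqn{[0,1]}.
#' @param gray_rgb length-3 camera-encoded gray-standard R, G, B in \eqn{(0,1]}.
#' @return named numeric vector \code{c(R, G, B, V)} (see [equalize()]).
#' @export
calibrate_color <- function(raw_rgb, gray_rgb, gamma = 2.2,
                            reflectance_target = 0.18) {
  equalize(linearize(raw_rgb, gamma), linearize(gray_rgb, gamma),
           reflectance_target)
}

#' Chromaticity coordinates of a calibrated color
#'
#' The 2-D color space used throughout: standardized channel differences
#' \eqn{x = (R - G)/(R + G + B)} and \eqn{y = (G - B)/(R + G + B)}.
#' Both are invariant to overall brightness scaling.
#'
#' @param rgb length-3 (or length-4 \code{c(R,G,B,V)}) calibrated color with
#'   non-negative channels and positive sum.
#' @return named numeric vector \code{c(x, y)}.
#' @examples
#' chromaticity(c(0, 1, 0))  # c(x = -1, y = 1)
#' @export
chromaticity <- function(rgb) {
  rgb <- unname(rgb[1:3])
  check_that(is.numeric(rgb) && !anyNA(rgb) && all(rgb >= 0),
             "rgb must be 3 non-negative numbers")
  s <- sum(rgb)
  if (s <= 0) {
    stop("undefined chromaticity: R + G + B = 0", call. = FALSE)
  }
  c(x = (rgb[1] - rgb[2]) / s, y = (rgb[2] - rgb[3]) / s)
}

#' Saturation: distance from the achromatic origin
#'
#' \eqn{S = \sqrt{x^2 + y^2}}; zero exactly when R = G = B.
#'
#' @param x,y chromaticity coordinates (see [chromaticity()]).
#' @return non-negative saturation.
#' @export
saturation <- function(x, y) {
  check_that(is.numeric(x) && is.numeric(y), "x and y must be numeric")
  sqrt(x^2 + y^2)
}

#' Hue: angle in the chromaticity plane
#'
#' Full-quadrant angle of \eqn{(x, y)} in radians, range \eqn{(-\pi, \pi]}.
#' A single-argument arctangent of \eqn{y/x} is quadrant-ambiguous; gray-green
#' colors have negative \eqn{x}, so the two-argument angle is used. Achromatic
#' colors (\eqn{x = y = 0}) have no hue and raise an error rather than
#' returning 0, which would silently bias circular summaries.
#'
#' @inheritParams saturation
#' @return hue angle in radians.
#' @export
hue <- function(x, y) {
  check_that(is.numeric(x) && is.numeric(y) && length(x) == length(y),
             "x and y must be numeric vectors of equal length")
  if (any(x == 0 & y == 0)) {
    stop("undefined hue: achromatic color (x = y = 0)", call. = FALSE)
  }
  atan2(y, x)
}

#' Brightness of a calibrated color
#'
#' \eqn{V = (R + G + B)/3}, the channel mean, consistent with the achromatic
#' contrast index built on channel sums.
#'
#' @inheritParams chromaticity
#' @return brightness V.
#' @export
brightness <- function(rgb) {
  rgb <- unname(rgb[1:3])
  check_that(is.numeric(rgb) && !anyNA(rgb) && all(rgb >= 0),
             "rgb must be 3 non-negative numbers")
  mean(rgb)
}

#' Calibrate and annotate a table of raw colors
#'
#' Tabular front end over the calibration chain. Takes a data frame with raw
#' region channels \code{R_raw, G_raw, B_raw} and gray-standard channels
#' \code{R_gray, G_gray, B_gray} (all camera-encoded, \eqn{[0,1]}) and appends
#' the calibrated \code{R, G, B, V} and the color-space metrics
#' \code{x, y, S, H}. \code{H} is \code{NA} for achromatic rows.
#'
#' @param tbl data frame with the six raw channel columns.
#' @inheritParams calibrate_color
#' @return the input as a [tibble::tibble()] with eight columns appended.
#' @export
calibrate_table <- function(tbl, gamma = 2.2, reflectance_target = 0.18) {
  need <- c("R_raw", "G_raw", "B_raw", "R_gray", "G_gray", "B_gray")
  check_that(all(need %in% names(tbl)),
             paste("missing columns:",
                   paste(setdiff(need, names(tbl)), collapse = ", ")))
  n <- nrow(tbl)
  out <- matrix(NA_real_, n, 8,
                dimnames = list(NULL, c("R", "G", "B", "V", "x", "y", "S", "H")))
  for (i in seq_len(n)) {
    cal <- calibrate_color(
      c(tbl$R_raw[i], tbl$G_raw[i], tbl$B_raw[i]),
      c(tbl$R_gray[i], tbl$G_gray[i], tbl$B_gray[i]),
      gamma = gamma, reflectance_target = reflectance_target
    )
    xy <- chromaticity(cal)
    out[i, 1:4] <- cal
    out[i, 5:6] <- xy
    out[i, 7] <- saturation(xy[1], xy[2])
    out[i, 8] <- if (xy[1] == 0 && xy[2] == 0) NA_real_ else hue(xy[1], xy[2])
  }
  tibble::as_tibble(cbind(tbl, as.data.frame(out)))
}
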