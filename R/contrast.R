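#' Achromatic (brightness) contrast between animal and background
#'
#' Signed relative brightness difference,
#' \deqn{(\Sigma RGB_s - \Sigma RGB_b) / (\Sigma RGB_s + \Sigma RGB_b),}
#' where subscripts \eqn{s} and \eqn{b} denote the animal region and its
#' background. Lies in \eqn{[-1, 1]}; negative means the animal is darker than
#' its background. Lower magnitude means closer brightness matching.
#'
#' @param s,b length-3 (or \code{c(R,G,B,V)}) calibrated colors, channels
#'   non-negative.
#' @return signed achromatic contrast.
#' @examples
#' achromatic_contrast(c(0.2, 0.2, 0.2), c(0.4, 0.4, 0.4))  # -1/3
#' @export
achromatic_contrast <- function(s, b) {
  s <- unname(s[1:3]); b <- unname(b[1:3])
  check_that(all(s >= 0) && all(b >= 0), "channels must be non-negative")
  tot <- sum(s) + sum(b)
  if (tot <= 0) {
    stop("undefined contrast: both colors have zero channel sum", call. = FALSE)
  }
  (sum(s) - sum(b)) / tot
}

#' Chromatic contrast between animal and background
#'
#' Euclidean distance between the two colors expressed as RGB proportions
#' (each channel divided by the channel sum, so proportions sum to 1):
#' \deqn{\sqrt{(R_{ps}-R_{pb})^2 + (G_{ps}-G_{pb})^2 + (B_{ps}-B_{pb})^2}.}
#' Brightness-invariant, symmetric, and a metric on the simplex; range
#' \eqn{[0, \sqrt 2]}. Lower values mean closer color matching.
#'
#' @inheritParams achromatic_contrast
#' @return chromatic contrast (non-negative).
#' @examples
#' chromatic_contrast(c(0.5, 0.25, 0.25), c(0.25, 0.5, 0.25))  # sqrt(0.125)
#' @export
chromatic_contrast <- function(s, b) {
  s <- unname(s[1:3]); b <- unname(b[1:3])
  check_that(all(s >= 0) && all(b >= 0), "channels must be non-negative")
  if (sum(s) <= 0 || sum(b) <= 0) {
    stop("undefined proportions: color with zero channel sum", call. = FALSE)
  }
  sqrt(sum((s / sum(s) - b / sum(b))^2))
}

#' Per-region contrast table for one individual
#'
#' Computes both contrast indices between each body region and the shared
#' background. Missing regions (NULL or any NA channel) yield NA contrasts with
#' \code{missing = TRUE} rather than being dropped, so incomplete field records
#' stay visible downstream.
#'
#' @param regions named list of calibrated colors, typically
#'   \code{list(dorsal = ..., ventral = ..., ventral_tail = ...)}.
#' @param background calibrated background color.
#' @return tibble with columns \code{region, achromatic, abs_achromatic,
#'   chromatic, missing}.
#' @export
region_contrast_table <- function(regions, background) {
  check_that(is.list(regions) && length(regions) > 0 &&
               !is.null(names(regions)), "regions must be a named list")
  rows <- lapply(names(regions), function(nm) {
    col <- regions[[nm]]
    if (is.null(col) || anyNA(col[1:3])) {
      return(tibble::tibble(region = nm, achromatic = NA_real_,
                            abs_achromatic = NA_real_, chromatic = NA_real_,
                            missing = TRUE))
    }
    a <- achromatic_contrast(col, background)
    tibble::tibble(region = nm, achromatic = a, abs_achromatic = abs(a),
                   chromatic = chromatic_contrast(col, background),
                   missing = FALSE)
  })
  do.call(rbind, rows)
}
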