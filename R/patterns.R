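#' Construct a body pattern map
#'
#' Binary rasters describing one dorsal pattern: the body silhouette, the dark
#' speckle pixels, and the mid-dorsal line pixels (both subsets of the body).
#' Maps are axis-aligned: the body axis runs along raster columns, so the
#' generator (or upstream alignment) has already rotated the body horizontal.
#'
#' @param body_mask,speckle_mask,midline_mask logical matrices of equal
#'   dimension; \code{speckle_mask} and \code{midline_mask} must be subsets of
#'   \code{body_mask}.
#' @return object of class \code{body_pattern_map}.
#' @export
body_pattern_map <- function(body_mask, speckle_mask, midline_mask) {
  body_mask <- body_mask != 0
  speckle_mask <- speckle_mask != 0
  midline_mask <- midline_mask != 0
  check_that(all(dim(body_mask) == dim(speckle_mask)) &&
               all(dim(body_mask) == dim(midline_mask)),
             "masks must share dimensions")
  check_that(!any(speckle_mask & !body_mask), "speckle_mask must lie inside body_mask")
  check_that(!any(midline_mask & !body_mask), "midline_mask must lie inside body_mask")
  structure(list(body_mask = body_mask, speckle_mask = speckle_mask,
                 midline_mask = midline_mask),
            class = "body_pattern_map")
}

#' Fraction of the body axis covered by the mid-dorsal line
#'
#' The body axis is the set of raster columns containing body pixels; a column
#' is covered when it holds at least one midline pixel.
#'
#' @param map a [body_pattern_map()].
#' @return fraction in \eqn{[0, 1]}.
#' @export
midline_coverage <- function(map) {
  check_that(inherits(map, "body_pattern_map"), "map must be a body_pattern_map")
  body_cols <- colSums(map$body_mask) > 0
  if (!any(body_cols)) stop("empty body mask", call. = FALSE)
  mid_cols <- colSums(map$midline_mask) > 0
  sum(mid_cols & body_cols) / sum(body_cols)
}

#' Speckle density of the dorsal body
#'
#' Speckle pixels as a fraction of body pixels.
#'
#' @inheritParams midline_coverage
#' @return fraction in \eqn{[0, 1]}.
#' @export
speckle_score <- function(map) {
  check_that(inherits(map, "body_pattern_map"), "map must be a body_pattern_map")
  nb <- sum(map$body_mask)
  if (nb == 0) stop("empty body mask", call. = FALSE)
  sum(map$speckle_mask) / nb
}

#' Classify a dorsal pattern into one of four types
#'
#' Deterministic operationalization of the four-morph scheme as a 2x2 rule:
#' \describe{
#'   \item{plain}{no/weak speckling, midline on half the body length or less}
#'   \item{midplain}{no/weak speckling, midline on more than half}
#'   \item{spot}{dense speckling, midline on half or less}
#'   \item{midspot}{dense speckling, midline on more than half}
#' }
#' "Dense" means \code{speckle_score >= dense_threshold}; "more than half"
#' means \code{midline_coverage > midline_threshold} (strict, matching the
#' "more than 50\%" field rule). The field criterion for dense speckling is a
#' by-eye judgment; the default threshold of 0.10 is an operationalization, not
#' a recovered parameter, and is configurable.
#'
#' @inheritParams midline_coverage
#' @param dense_threshold speckle fraction at or above which speckling counts
#'   as dense. Default 0.10.
#' @param midline_threshold body-length fraction above which the midline
#'   counts as present. Default 0.5.
#' @return one of \code{"plain", "midplain", "spot", "midspot"}.
#' @export
classify_pattern <- function(map, dense_threshold = 0.10,
                             midline_threshold = 0.5) {
  dense <- speckle_score(map) >= dense_threshold
  lined <- midline_coverage(map) > midline_threshold
  if (dense) {
    if (lined) "midspot" else "spot"
  } else {
    if (lined) "midplain" else "plain"
  }
}

#' The four pattern-type labels, in complexity order
#' @export
pattern_levels <- function() c("plain", "midplain", "spot", "midspot")
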