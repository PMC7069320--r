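#' Construct a polygon region of interest
#'
#' Coordinates are 0-based \code{(col, row)} pixel positions; pixel centers sit
#' at integer coordinates. Containment everywhere in the package uses the
#' even-odd rule applied to pixel centers, which fixes an otherwise unstated
#' rasterization convention bit-exactly across platforms.
#'
#' @param label region label, e.g. \code{"dorsal"}, \code{"background_1"},
#'   \code{"gray_standard"}.
#' @param vertices numeric matrix (or list of pairs) of \code{(col, row)}
#'   vertices, at least 3, describing a simple polygon.
#' @return object of class \code{polygon_roi}.
#' @export
polygon_roi <- function(label, vertices) {
  if (is.list(vertices)) vertices <- do.call(rbind, lapply(vertices, as.numeric))
  vertices <- as.matrix(vertices)
  check_that(is.numeric(vertices) && ncol(vertices) == 2 && nrow(vertices) >= 3,
             "vertices must be an n x 2 numeric matrix with n >= 3")
  structure(list(label = as.character(label), vertices = unname(vertices)),
            class = "polygon_roi")
}

# Interior pixel centers of a polygon by scanline even-odd filling.
# Returns an integer matrix with columns (col, row), 0-based.
roi_interior_pixels <- function(roi, image_shape) {
  check_that(inherits(roi, "polygon_roi"), "roi must be a polygon_roi")
  h <- image_shape[1]; w <- image_shape[2]
  v <- roi$vertices
  x1 <- v[, 1]; y1 <- v[, 2]
  x2 <- v[c(2:nrow(v), 1), 1]; y2 <- v[c(2:nrow(v), 1), 2]
  rows <- max(0L, floor(min(y1))):min(h - 1L, ceiling(max(y1)))
  pts <- vector("list", length(rows))
  for (k in seq_along(rows)) {
    y <- rows[k]
    crosses <- (y1 > y) != (y2 > y)
    if (!any(crosses)) next
    xint <- x1[crosses] + (y - y1[crosses]) / (y2[crosses] - y1[crosses]) *
      (x2[crosses] - x1[crosses])
    xint <- sort(xint)
    cols <- 0:(w - 1L)
    inside <- (length(xint) - findInterval(cols, xint)) %% 2L == 1L
    if (any(inside)) pts[[k]] <- cbind(col = cols[inside], row = y)
  }
  out <- do.call(rbind, pts)
  if (is.null(out)) out <- matrix(integer(), 0, 2,
                                  dimnames = list(NULL, c("col", "row")))
  out
}

#' Sample random points inside a polygon ROI
#'
#' Draws \code{n} points uniformly, with replacement, from the pixel centers
#' that fall inside the polygon (even-odd rule). The same seed always yields
#' the same points.
#'
#' @param roi a [polygon_roi()].
#' @param image_shape integer \code{c(height, width)} of the host image.
#' @param n number of points (default 400, the standard per-region protocol).
#' @param seed integer seed for the draw.
#' @return integer matrix with columns \code{col, row} (0-based), \code{n} rows.
#' @export
sample_points <- function(roi, image_shape, n = 400, seed = 1L) {
  check_that(is.numeric(n) && length(n) == 1L && n >= 1, "n must be >= 1")
  pix <- roi_interior_pixels(roi, image_shape)
  if (nrow(pix) == 0L) {
    stop("empty ROI: polygon '", roi$label, "' contains no pixel centers",
         call. = FALSE)
  }
  idx <- with_seed(seed, sample.int(nrow(pix), size = n, replace = TRUE))
  pix[idx, , drop = FALSE]
}

# Coerce an image to a [0,1] double array h x w x 3.
as_image01 <- function(image) {
  check_that(is.array(image) && length(dim(image)) == 3 && dim(image)[3] >= 3,
             "image must be an h x w x 3 array")
  image <- image[, , 1:3, drop = FALSE]
  if (max(image) > 1) image <- image / 255
  image
}

#' Mean region color from random-point sampling
#'
#' Channel means of the image over \code{n} random points inside the ROI,
#' on the \eqn{[0, 1]} scale.
#'
#' @param image \code{h x w x 3} array, values in \eqn{[0,1]} (or 0–255).
#' @inheritParams sample_points
#' @return named numeric vector \code{c(R, G, B)}.
#' @export
region_mean_color <- function(image, roi, n = 400, seed = 1L) {
  image <- as_image01(image)
  pts <- sample_points(roi, dim(image)[1:2], n = n, seed = seed)
  i <- pts[, 2] + 1L; j <- pts[, 1] + 1L
  c(R = mean(image[cbind(i, j, 1L)]),
    G = mean(image[cbind(i, j, 2L)]),
    B = mean(image[cbind(i, j, 3L)]))
}

#' Exhaustive mean region color
#'
#' Exact channel means over every interior pixel of the ROI; the oracle that
#' the random-point sampler converges to.
#'
#' @inheritParams region_mean_color
#' @return named numeric vector \code{c(R, G, B)}.
#' @export
full_region_mean <- function(image, roi) {
  image <- as_image01(image)
  pix <- roi_interior_pixels(roi, dim(image)[1:2])
  if (nrow(pix) == 0L) {
    stop("empty ROI: polygon '", roi$label, "' contains no pixel centers",
         call. = FALSE)
  }
  i <- pix[, 2] + 1L; j <- pix[, 1] + 1L
  c(R = mean(image[cbind(i, j, 1L)]),
    G = mean(image[cbind(i, j, 2L)]),
    B = mean(image[cbind(i, j, 3L)]))
}

#' Mean background color from two background patches
#'
#' The field protocol samples two background polygons of roughly animal size
#' and averages them; this is the plain (unweighted) mean of the two region
#' means. Each region is sampled with the same seed, so identical ROIs give
#' identical draws.
#'
#' @inheritParams region_mean_color
#' @param roi_1,roi_2 the two background [polygon_roi()]s.
#' @return named numeric vector \code{c(R, G, B)}.
#' @export
background_mean <- function(image, roi_1, roi_2, n = 400, seed = 1L) {
  m1 <- region_mean_color(image, roi_1, n = n, seed = seed)
  m2 <- region_mean_color(image, roi_2, n = n, seed = seed)
  (m1 + m2) / 2
}
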