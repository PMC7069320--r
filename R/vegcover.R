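#' Vegetation score of one grid section
#'
#' The background photograph (1 x 1 m quadrat) is partitioned into 2 x 2
#' quadrant sections; each section is scored as its vegetation area expressed
#' as a percentage of the whole image, rounded to the nearest multiple of 5 and
#' capped at 25 (a fully vegetated quadrant is a quarter of the image). The
#' smallest nonzero score is 5: any trace of vegetation below 2.5\% of the
#' image still scores 5, mirroring the field protocol's scoring granularity.
#'
#' Sections are indexed 0–3 row-major: 0 = top-left, 1 = top-right,
#' 2 = bottom-left, 3 = bottom-right.
#'
#' @param mask logical (or 0/1) matrix, \code{TRUE} = vegetation pixel.
#' @param section_index section number in 0..3.
#' @return section score, one of 0, 5, 10, 15, 20, 25.
#' @export
section_cover <- function(mask, section_index) {
  mask <- as.matrix(mask) != 0
  check_that(length(mask) > 0, "mask must be nonempty")
  check_that(is.numeric(section_index) && length(section_index) == 1L &&
               section_index %in% 0:3, "section_index must be in 0..3")
  h <- nrow(mask); w <- ncol(mask)
  rs <- if (section_index %/% 2 == 0) 1:(h %/% 2) else (h %/% 2 + 1):h
  cs <- if (section_index %% 2 == 0) 1:(w %/% 2) else (w %/% 2 + 1):w
  pct <- 100 * sum(mask[rs, cs]) / length(mask)
  if (pct == 0) return(0)
  score <- 5 * round(pct / 5)
  max(5, min(25, score))
}

#' Total vegetation-cover score
#'
#' Sum of the four quadrant section scores; a percentage in \eqn{[0, 100]},
#' always a multiple of 5. Monotone non-decreasing in added vegetation.
#'
#' @inheritParams section_cover
#' @return list with \code{section_scores} (length 4) and \code{total}.
#' @export
total_cover <- function(mask) {
  scores <- vapply(0:3, function(i) section_cover(mask, i), numeric(1))
  list(section_scores = scores, total = sum(scores))
}
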