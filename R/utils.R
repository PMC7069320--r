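#' @keywords internal
"_PACKAGE"

#' Derive a reproducible sub-seed from a base seed and a stream name
#'
#' All randomness in the package flows from one top-level seed through named
#' substreams (scene, population, per-ROI sampling, ...), so fixtures and
#' pipeline runs are bitwise reproducible while the substreams stay
#' statistically unrelated.
#'
#' @param seed integer base seed.
#' @param stream character stream label.
#' @return a positive integer seed below 2^31.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, length(stream) == 1L)
  h <- as.double(seed) %% 2147483629
  for (code in utf8ToInt(as.character(stream))) {
    h <- (h * 31 + code) %% 2147483629
  }
  as.integer(h + 1)  # strictly positive, < 2^31
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Internal assertion helper with a terse message.
check_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
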